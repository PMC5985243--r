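# Synthetic cohort inputs: driver-age distribution, human period mortality
# lifetable (Gompertz-Makeham), vehicle survival lifetable (discretized
# Weibull). These stand in for the demographic tables the analysis assumes
# but that are not part of the parameter registry; all three are fully
# deterministic given their spec, so regeneration is bit-reproducible.

#' Specification for the driver-age distribution
#'
#' Piecewise-uniform age bands approximating the age structure of licensed
#' drivers in the United States: weight is spread uniformly over the integer
#' ages inside each band. The default bands put the mean driver age near 47.
#'
#' @param bands Data frame with columns `lower`, `upper` (inclusive integer
#'   ages) and `share` (band weight; normalized internally).
#' @return A list of class `avcea_age_spec`.
#' @export
age_distribution_spec <- function(bands = NULL) {
  if (is.null(bands)) {
    bands <- data.frame(
      lower = c(16, 20, 30, 40, 50, 60, 70, 80),
      upper = c(19, 29, 39, 49, 59, 69, 79, 90),
      share = c(0.04, 0.17, 0.17, 0.17, 0.17, 0.15, 0.09, 0.04)
    )
  }
  structure(list(bands = bands), class = "avcea_age_spec")
}

#' Build the driver-age distribution
#'
#' @param spec An [age_distribution_spec()], or a named numeric vector of
#'   explicit weights whose names are integer ages (e.g. `c("47" = 1)` for a
#'   point mass).
#' @return A tibble of class `avcea_age_distribution` with columns `age`
#'   (integer, within 16..100) and `weight` (non-negative, summing to 1).
#' @examples
#' dist <- build_age_distribution()
#' sum(dist$weight * dist$age) # mean driver age
#' @export
build_age_distribution <- function(spec = age_distribution_spec()) {
  if (is.numeric(spec) && !is.null(names(spec))) {
    ages <- as.integer(names(spec))
    w <- as.numeric(spec)
  } else if (inherits(spec, "avcea_age_spec")) {
    b <- spec$bands
    stopifnot(all(b$lower <= b$upper))
    ages <- integer(0); w <- numeric(0)
    for (i in seq_len(nrow(b))) {
      a <- b$lower[i]:b$upper[i]
      ages <- c(ages, a)
      w <- c(w, rep(b$share[i] / length(a), length(a)))
    }
    agg <- tapply(w, ages, sum)
    ages <- as.integer(names(agg)); w <- as.numeric(agg)
  } else {
    stop("spec must be an age_distribution_spec or a named weight vector")
  }
  if (any(w < 0)) stop("age weights must be non-negative")
  if (any(ages < 16 | ages > 100)) stop("driver ages must lie in [16, 100]")
  if (sum(w) <= 0) stop("age weights must have positive total")
  out <- tibble::tibble(age = ages, weight = w / sum(w))
  class(out) <- c("avcea_age_distribution", class(out))
  out
}

#' Specification for the human mortality lifetable
#'
#' Gompertz-Makeham period mortality: hazard `h(x) = makeham + b * exp(theta
#' * x)` at age `x`, annual death probability `q(x) = 1 - exp(-h(x))`. The
#' default parameters approximate a recent US period lifetable (life
#' expectancy at birth about 77 years) and are calibrated so the simulated
#' HPV driver cohort accrues about 16.4 discounted QALYs (see the methods
#' vignette).
#'
#' @param makeham Age-independent baseline hazard per year.
#' @param b,theta Gompertz level and slope.
#' @param max_age Closing age; `q(max_age) = 1` always.
#' @return A list of class `avcea_mortality_spec`.
#' @export
mortality_spec <- function(makeham = 5e-4, b = 2.7e-5, theta = 0.098,
                           max_age = 110L) {
  structure(list(makeham = makeham, b = b, theta = theta,
                 max_age = as.integer(max_age)),
            class = "avcea_mortality_spec")
}

#' Build the human mortality lifetable
#'
#' @param spec A [mortality_spec()], or a data frame with columns `age`, `q`
#'   (explicit table; closed to `q = 1` at its last age).
#' @return A tibble of class `avcea_mortality_table` with columns `age`
#'   (0..max_age) and `q` (annual death probability; 1 at the closing age).
#' @export
build_mortality_table <- function(spec = mortality_spec()) {
  if (is.data.frame(spec)) {
    tab <- tibble::tibble(age = as.integer(spec$age), q = as.numeric(spec$q))
  } else if (inherits(spec, "avcea_mortality_spec")) {
    age <- 0:spec$max_age
    h <- spec$makeham + spec$b * exp(spec$theta * age)
    tab <- tibble::tibble(age = age, q = 1 - exp(-h))
  } else {
    stop("spec must be a mortality_spec or an explicit age/q table")
  }
  if (any(tab$q < 0 | tab$q > 1)) stop("mortality q outside [0, 1]")
  tab$q[nrow(tab)] <- 1  # closure: nobody outlives the table
  class(tab) <- c("avcea_mortality_table", class(tab))
  tab
}

#' Specification for the vehicle survival lifetable
#'
#' Discretized-Weibull service life: the continuous survival is
#' `S(t) = exp(-(t / scale)^shape)` and the table holds the conditional
#' annual probability that a car of integer age `a` leaves service during
#' its next year. The scale is solved internally so the discretized mean
#' service life equals `mean_lifespan` (within 0.1 year).
#'
#' @param mean_lifespan Mean years in service. The default 17.5 years is
#'   calibrated jointly with the parking amortization horizon so the
#'   simulated HPV lifetime cost reproduces the published total (see the
#'   methods vignette); AVs are assumed to share the HPV lifespan.
#' @param shape Weibull shape (> 1 concentrates retirements around the mean).
#' @param max_age Forced retirement age; `expire_prob(max_age) = 1`.
#' @return A list of class `avcea_vehicle_spec`.
#' @export
vehicle_lifespan_spec <- function(mean_lifespan = 17.5, shape = 4,
                                  max_age = 35L) {
  if (mean_lifespan <= 0) stop("mean vehicle lifespan must be positive")
  structure(list(mean_lifespan = mean_lifespan, shape = shape,
                 max_age = as.integer(max_age)),
            class = "avcea_vehicle_spec")
}

# Discrete mean service life implied by a vehicle lifetable: a car in service
# for year a survives that year with prob 1 - expire_prob(a); service years
# = number of years begun.
.vehicle_mean_life <- function(expire_prob) {
  surv <- cumprod(1 - expire_prob)
  1 + sum(surv[-length(surv)])
}

#' Build the vehicle survival lifetable
#'
#' @param spec A [vehicle_lifespan_spec()], or a data frame with columns
#'   `vehicle_age`, `expire_prob` (explicit table; closed to 1 at its last
#'   age).
#' @return A tibble of class `avcea_vehicle_lifetable` with columns
#'   `vehicle_age` (0..max_age) and `expire_prob`, the conditional annual
#'   probability of leaving service; 1 at the final age.
#' @export
build_vehicle_lifetable <- function(spec = vehicle_lifespan_spec()) {
  if (is.data.frame(spec)) {
    tab <- tibble::tibble(vehicle_age = as.integer(spec$vehicle_age),
                          expire_prob = as.numeric(spec$expire_prob))
  } else if (inherits(spec, "avcea_vehicle_spec")) {
    ages <- 0:spec$max_age
    haz_from_scale <- function(scale) {
      # conditional hazard from the cumulative-hazard increment (stable for
      # ages far beyond the scale, where survival underflows)
      h <- 1 - exp(-(((ages + 1) / scale)^spec$shape -
                       (ages / scale)^spec$shape))
      h[length(h)] <- 1
      h
    }
    # solve the Weibull scale so the discretized mean hits the target
    obj <- function(scale) .vehicle_mean_life(haz_from_scale(scale)) -
      spec$mean_lifespan
    scale <- stats::uniroot(obj, c(spec$mean_lifespan / 4,
                                   spec$max_age * 2))$root
    tab <- tibble::tibble(vehicle_age = ages, expire_prob = haz_from_scale(scale))
  } else {
    stop("spec must be a vehicle_lifespan_spec or an explicit table")
  }
  if (any(tab$expire_prob < 0 | tab$expire_prob > 1)) {
    stop("expire_prob outside [0, 1]")
  }
  tab$expire_prob[nrow(tab)] <- 1
  class(tab) <- c("avcea_vehicle_lifetable", class(tab))
  tab
}

#' Default synthetic cohort tables
#'
#' Convenience bundle of the three cohort inputs built from their default
#' specs. Identical (bit-for-bit) to the versioned CSV fixtures shipped
#' under `inst/extdata/`.
#'
#' @return A list with elements `age_distribution`, `mortality`, `vehicle`.
#' @export
default_cohort <- function() {
  list(age_distribution = build_age_distribution(),
       mortality = build_mortality_table(),
       vehicle = build_vehicle_lifetable())
}

#' Read cohort tables from CSV fixtures
#'
#' @param dir Directory holding `age_distribution.csv` (`age,weight`),
#'   `mortality.csv` (`age,q`) and `vehicle_lifetable.csv`
#'   (`vehicle_age,expire_prob`). Defaults to the fixtures shipped with the
#'   package.
#' @return A cohort list as from [default_cohort()].
#' @export
read_cohort <- function(dir = system.file("extdata", package = "avcea")) {
  rd <- function(f) utils::read.csv(file.path(dir, f))
  list(
    age_distribution = build_age_distribution(
      stats::setNames(rd("age_distribution.csv")$weight,
                      rd("age_distribution.csv")$age)),
    mortality = build_mortality_table(rd("mortality.csv")),
    vehicle = build_vehicle_lifetable(rd("vehicle_lifetable.csv"))
  )
}

#' Write cohort tables as CSV fixtures
#'
#' @param cohort A cohort list as from [default_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  wr(as.data.frame(cohort$age_distribution), "age_distribution.csv")
  wr(as.data.frame(cohort$mortality), "mortality.csv")
  wr(as.data.frame(cohort$vehicle), "vehicle_lifetable.csv")
  invisible(dir)
}

#' Sample driver ages
#'
#' Draws from the age distribution. In the paired design the same draw is
#' shared by both arms of an iteration (common random numbers), which
#' [run_simulation()] arranges by drawing ages once per iteration from a
#' dedicated sub-stream.
#'
#' @param dist An `avcea_age_distribution`.
#' @param n Number of draws.
#' @return Integer vector of ages.
#' @export
sample_age <- function(dist, n = 1) {
  if (nrow(dist) == 1) return(rep(dist$age, n))
  sample(dist$age, n, replace = TRUE, prob = dist$weight)
}

#' Discounted period life expectancy from a mortality table
#'
#' Deterministic lifetable arithmetic: expected discounted years of life
#' remaining from `age`, with a full year credited at the start of each year
#' begun (matching the microsimulation's accrual convention).
#'
#' @param mortality An `avcea_mortality_table`.
#' @param age Starting age (scalar).
#' @param discount_rate Annual discount rate (0 for plain life expectancy).
#' @return Expected (discounted) years.
#' @export
life_expectancy <- function(mortality, age, discount_rate = 0) {
  q <- mortality$q[match(age:max(mortality$age), mortality$age)]
  surv <- cumprod(c(1, 1 - q))[seq_along(q)]
  sum(surv / (1 + discount_rate)^(seq_along(q) - 1))
}
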