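# Crash incidence and severity. The simulation consumes the published
# annual crash probabilities and severity splits directly; the delta-V
# machinery documents how a per-crash severity split can be derived from a
# crash-speed distribution and is a calibration/validation tool, not on the
# simulation's critical path.

.severities <- c("PDO", "MINOR", "SEVERE", "FATAL")
.strategies <- c("HPV", "AV", "AV_5YR", "AV_TAXI", "HPT")

#' Model strategies
#'
#' The five transport strategies: privately owned human-piloted vehicle
#' (`HPV`), privately owned autonomous vehicle at today's price (`AV`), AV
#' at its 5-year Moore's-law price projection (`AV_5YR`), autonomous taxi
#' (`AV_TAXI`), and human-piloted taxi (`HPT`).
#'
#' @return Character vector of strategy names.
#' @export
strategies <- function() .strategies

#' Observed autonomous-fleet crash record
#'
#' The public test-fleet record the AV crash rate derives from: 14 reported
#' crashes over 2,102,047 fully autonomous miles (October 2012 to August
#' 2016), 7 further crashes predicted by the operator's counterfactual
#' simulations, a mean collision speed change (delta-V) of 3.91 mph, and
#' mean collision speeds of 0.23 mph (AV) and 7.54 mph (other vehicle).
#'
#' @return Named list of the record's counts and speeds.
#' @export
waymo_fleet_record <- function() {
  list(observed_crashes = 14L, simulated_additional_crashes = 7L,
       miles = 2102047L, mean_delta_v = 3.91,
       av_speed_at_collision = 0.23, other_speed_at_collision = 7.54)
}

#' Annual crash profile for a strategy
#'
#' Taxis inherit the crash profile of their vehicle type: `AV`, `AV_5YR`
#' and `AV_TAXI` share the AV profile (future AVs are not assigned increased
#' effectiveness), `HPV` and `HPT` share the HPV profile. Severity splits
#' are renormalized to sum exactly to one (the published splits carry
#' rounding residues of about 1e-4).
#'
#' @param strategy One of [strategies()].
#' @param params An `avcea_parameters` object.
#' @return A list of class `avcea_crash_profile` with `annual_crash_prob`
#'   and `severity_split` (named probabilities over PDO/MINOR/SEVERE/FATAL).
#' @examples
#' crash_profile("HPV", default_parameters())
#' @export
crash_profile <- function(strategy, params = default_parameters()) {
  strategy <- match.arg(strategy, .strategies)
  pre <- if (strategy %in% c("HPV", "HPT")) "hpv" else "av"
  split <- param_value(params, paste0(pre, "_split_",
                                      c("pdo", "minor", "severe", "fatal")))
  names(split) <- .severities
  p <- param_value(params, paste0(pre, "_crash_prob"))
  if (pre == "hpv") {
    p <- min(1, p * param_value(params, "unreported_crash_multiplier"))
  }
  structure(list(annual_crash_prob = p, severity_split = split / sum(split)),
            class = "avcea_crash_profile")
}

#' Convert a per-mile crash rate to an annual probability
#'
#' @param rate_per_mile Crash probability per mile, in `[0, 1]`.
#' @param annual_vmt Annual vehicle miles travelled.
#' @param method `"complement"` (default) computes
#'   `1 - (1 - rate)^vmt`, treating each mile as an independent Bernoulli
#'   trial; `"product"` returns the simple expectation `rate * vmt`.
#' @return Annual probability (complement form) or expected annual count
#'   (product form).
#' @export
per_mile_to_annual <- function(rate_per_mile, annual_vmt,
                               method = c("complement", "product")) {
  method <- match.arg(method)
  if (any(rate_per_mile < 0)) stop("rate must be non-negative")
  if (any(rate_per_mile > 1)) stop("per-mile rate cannot exceed 1")
  if (any(annual_vmt <= 0)) stop("annual_vmt must be positive")
  switch(method,
         complement = 1 - (1 - rate_per_mile)^annual_vmt,
         product = rate_per_mile * annual_vmt)
}

#' Relative risk of two probabilities
#'
#' @param p_a,p_b Probabilities (numerator, denominator).
#' @param digits Rounding for the reported ratio (default 2, the convention
#'   used when quoting crash and fatality relative risks).
#' @return `round(p_a / p_b, digits)`.
#' @export
relative_risk <- function(p_a, p_b, digits = 2) {
  if (any(p_b <= 0)) stop("denominator probability must be positive")
  round(p_a / p_b, digits)
}

#' Sample annual crash outcomes
#'
#' With probability `1 - annual_crash_prob` no crash occurs (`"NONE"`);
#' otherwise the severity is drawn from the profile's split.
#'
#' @param profile An `avcea_crash_profile`.
#' @param n Number of independent driver-years to sample.
#' @return Character vector over `NONE`, `PDO`, `MINOR`, `SEVERE`, `FATAL`.
#' @export
sample_crash_outcome <- function(profile, n = 1) {
  u <- stats::runif(n)
  crash <- u < profile$annual_crash_prob
  out <- rep("NONE", n)
  if (any(crash)) {
    k <- sum(crash)
    cum <- cumsum(profile$severity_split)
    out[crash] <- .severities[findInterval(stats::runif(k), cum) + 1L]
  }
  out
}

#' Default crash-speed (delta-V) distribution
#'
#' A discretized lognormal distribution of the change in vehicle speed at
#' collision, with mean 3.91 mph (the fleet-record mean) and coefficient of
#' variation 1 (the record's speed variance is not published; CV 1 is a
#' typical dispersion for low-speed urban collisions).
#'
#' @param mean Mean delta-V, mph.
#' @param cv Coefficient of variation.
#' @param grid Evaluation grid of delta-V values, mph.
#' @return A tibble with columns `delta_v` and `weight` (summing to 1).
#' @export
default_delta_v_distribution <- function(mean = 3.91, cv = 1,
                                         grid = seq(0.05, 60, by = 0.1)) {
  s2 <- log(1 + cv^2)
  mu <- log(mean) - s2 / 2
  w <- stats::dlnorm(grid, mu, sqrt(s2))
  tibble::tibble(delta_v = grid, weight = w / sum(w))
}

#' Default delta-V injury risk curve
#'
#' Per-crash probabilities on the KABCO scale as a function of delta-V:
#' `p(v) = 1 - exp(-k v)` for K (killed), A (incapacitating injury) and B
#' (non-incapacitating injury), with C/O (possible or no injury) the
#' remainder. The coefficients are calibrated so that, averaged over
#' [default_delta_v_distribution()], the implied severity split matches the
#' AV split in the parameter registry; they are a synthetic stand-in for
#' published delta-V injury-risk regressions, not estimates from crash data.
#'
#' @return A function mapping a numeric vector of delta-V values (mph) to a
#'   matrix with columns `p_K`, `p_A`, `p_B`, `p_C`.
#' @export
default_risk_curve <- function() {
  k <- c(K = 2.373212019e-05, A = 0.000768483508, B = 0.008328350277)
  function(delta_v) {
    pK <- 1 - exp(-k[["K"]] * delta_v)
    pA <- 1 - exp(-k[["A"]] * delta_v)
    pB <- 1 - exp(-k[["B"]] * delta_v)
    cbind(p_K = pK, p_A = pA, p_B = pB, p_C = 1 - pK - pA - pB)
  }
}

#' Read a delta-V risk curve from CSV
#'
#' Expects columns `delta_v, p_K, p_A, p_B, p_C`; values are linearly
#' interpolated between grid points (constant beyond the grid ends).
#'
#' @param path CSV file path.
#' @return A risk-curve function as in [default_risk_curve()].
#' @export
read_risk_curve <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("delta_v", "p_K", "p_A", "p_B", "p_C")
  if (!all(need %in% names(tab))) {
    stop("risk curve CSV must have columns: ", paste(need, collapse = ", "))
  }
  function(delta_v) {
    f <- function(col) stats::approx(tab$delta_v, tab[[col]], xout = delta_v,
                                     rule = 2)$y
    cbind(p_K = f("p_K"), p_A = f("p_A"), p_B = f("p_B"), p_C = f("p_C"))
  }
}

#' Severity split implied by a delta-V distribution
#'
#' Takes the expectation of a KABCO risk curve over a discrete delta-V
#' distribution and maps it onto the model's crash categories using the
#' KABCO-to-MAIS correspondence: K (MAIS 6) to `FATAL`, A (MAIS 3-5) to
#' `SEVERE`, B (MAIS 1-2) to `MINOR`, C/O (MAIS 0) to `PDO`.
#'
#' @param delta_v_dist A data frame with columns `delta_v`, `weight`, or a
#'   numeric vector of delta-V values (taken equally weighted).
#' @param risk_curve A function as returned by [default_risk_curve()].
#' @return Named severity split over PDO/MINOR/SEVERE/FATAL, summing to 1.
#' @export
severity_from_delta_v <- function(delta_v_dist = default_delta_v_distribution(),
                                  risk_curve = default_risk_curve()) {
  if (is.numeric(delta_v_dist)) {
    delta_v_dist <- tibble::tibble(delta_v = delta_v_dist,
                                   weight = rep(1 / length(delta_v_dist),
                                                length(delta_v_dist)))
  }
  w <- delta_v_dist$weight / sum(delta_v_dist$weight)
  p <- risk_curve(delta_v_dist$delta_v)
  if (any(p < -1e-12) || any(rowSums(p[, c("p_K", "p_A", "p_B"), drop = FALSE])
                             > 1 + 1e-12)) {
    stop("risk curve outputs must be probabilities with p_K+p_A+p_B <= 1")
  }
  e <- colSums(p * w)
  split <- c(PDO = e[["p_C"]], MINOR = e[["p_B"]], SEVERE = e[["p_A"]],
             FATAL = e[["p_K"]])
  split / sum(split)
}
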