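# Parameter registry: every model input with base value, plausible bounds and
# the distribution used when it is varied in sensitivity analyses.

# Columns: name, kind, low, base, high, distribution.
# Costs are 2016 USD. Probabilities are per driver-year (crash) or conditional
# on a crash (severity split). Parameters with no published range are fixed.
.parameter_registry <- function() {
  p <- function(name, kind, low, base, high,
                distribution = if (is.na(low)) "fixed" else "triangular") {
    if (is.na(low)) low <- base
    if (is.na(high)) high <- base
    data.frame(name = name, kind = kind, low = low, base = base, high = high,
               distribution = distribution, stringsAsFactors = FALSE)
  }
  rows <- list(
    # -- crash costs, HPV column -------------------------------------------
    p("crash_cost_pdo_hpv",      "cost", 2976,      4251,      5526),
    p("crash_cost_minor_hpv",    "cost", 3129,      12282,     61352),
    p("crash_cost_severe_hpv",   "cost", 200241,    274553,    1101865),
    p("crash_cost_fatal_hpv",    "cost", 1072412,   1532018,   1991623),
    # -- crash costs, AV column (HPV cost plus damage to the AV equipment) --
    p("crash_cost_pdo_av",       "cost", 3123,      4615,      5799),
    p("crash_cost_minor_av",     "cost", 3864,      13332,     62717),
    p("crash_cost_severe_av",    "cost", 214206,    294503,    1127800),
    p("crash_cost_fatal_av",     "cost", 1086965,   1552808,   2018650),
    # -- vehicle purchase prices -------------------------------------------
    p("av_vehicle_cost",         "cost", 122218,    183666,    265648),
    p("av5_vehicle_cost",        "cost", 33229,     56539,     100383),
    p("hpv_vehicle_cost",        "cost", 17218,     33666,     70648),
    p("taxi_vehicle_cost",       "cost", 92699,     132427,    172155),
    p("av_taxi_vehicle_cost",    "cost", 197699,    282427,    367155),
    # -- recurring and event costs -----------------------------------------
    p("annual_ownership_cost",   "cost", NA,        8536,      NA),
    p("av_ownership_premium",    "cost", 0,         2000,      4000),
    p("funeral_cost",            "cost", 6206,      7332,      8687),
    p("productivity_cost",       "cost", 552,       1657,      2762),
    p("parking_spot_cost",       "cost", 47600,     102000,    176800),
    p("taxi_parking_spot_cost",  "cost", 0,         30000,     80000),
    p("taxi_salary",             "cost", 19432,     27760,     36088),
    # -- crash probabilities and severity splits ---------------------------
    p("hpv_crash_prob",          "probability", NA, 0.0646,    NA),
    p("hpv_split_pdo",           "probability", NA, 0.6091,    NA),
    p("hpv_split_minor",         "probability", NA, 0.3766,    NA),
    p("hpv_split_severe",        "probability", NA, 0.0090,    NA),
    p("hpv_split_fatal",         "probability", NA, 0.0054,    NA),
    p("av_crash_prob",           "probability", 0.06729,  0.08385,  0.09319),
    p("av_split_pdo",            "probability", 0.9551,   0.9654,   0.9777),
    p("av_split_minor",          "probability", 0.0220,   0.0315,   0.0409),
    p("av_split_severe",         "probability", 2.09e-04, 2.99e-03, 3.88e-03),
    p("av_split_fatal",          "probability", 6.48e-05, 9.26e-05, 1.20e-04),
    # -- utilities ----------------------------------------------------------
    p("healthy_utility",         "utility", 0.70,   0.85,      0.95),
    p("severe_injury_utility",   "utility", 0.40,   0.60,      0.80),
    # -- model constants ----------------------------------------------------
    p("discount_rate",           "rate",  NA,       0.03,      NA),
    p("annual_vmt",              "count", NA,       14133,     NA),
    p("productivity_fraction",   "rate",  NA,       0.3,       NA),
    p("parking_spot_ratio",      "rate",  NA,       3.4,       NA),
    p("parking_amortization_years", "count", NA,    35,        NA),
    p("moore_halving_period",    "count", NA,       2,         NA),
    p("wtp_threshold",           "cost",  NA,       140000,    NA),
    p("unreported_crash_multiplier", "rate", NA,    1.0,       NA),
    p("n_iterations",            "count", NA,       10000,     NA),
    p("n_timesteps",             "count", NA,       100,       NA)
  )
  out <- do.call(rbind, rows)
  class(out) <- c("avcea_parameters", "data.frame")
  out
}

#' Default model parameter set
#'
#' Returns the full registry of model inputs: crash costs for human-piloted
#' vehicles (HPVs) and their autonomous-vehicle (AV) counterparts, vehicle
#' purchase prices (including the 5-year Moore's-law AV projection and taxi
#' vehicles), recurring ownership/parking/productivity/salary costs, annual
#' crash probabilities with conditional severity splits over
#' PDO/minor/severe/fatal outcomes, health-state utilities, and the model
#' constants (3\% discount rate, 14,133 annual VMT, productivity fraction
#' 0.3, parking-spot ratio 3.4, $140,000/QALY willingness-to-pay threshold,
#' 10,000 iterations over 100 annual timesteps).
#'
#' Parameters with a published plausible range carry `low`/`high` bounds and
#' a `triangular` sampling distribution for sensitivity analyses; parameters
#' with a point estimate only are `fixed`.
#'
#' @return An object of class `avcea_parameters`: a data frame with columns
#'   `name`, `kind` (`cost`, `probability`, `rate`, `count`, `utility`),
#'   `low`, `base`, `high`, `distribution`.
#' @examples
#' params <- default_parameters()
#' param_value(params, "av_vehicle_cost")
#' @export
default_parameters <- function() .parameter_registry()

.validate_parameters <- function(params) {
  stopifnot(is.data.frame(params))
  bad <- params$low > params$base | params$base > params$high
  if (any(bad)) {
    stop("parameter bounds violated (low <= base <= high) for: ",
         paste(params$name[bad], collapse = ", "))
  }
  pr <- params$kind %in% c("probability", "utility", "rate") &
    params$name != "parking_spot_ratio"
  bad <- pr & (params$low < 0 | params$high > 1) &
    !params$name %in% c("unreported_crash_multiplier")
  if (any(bad)) {
    stop("probability/utility parameter outside [0, 1]: ",
         paste(params$name[bad], collapse = ", "))
  }
  bad <- params$kind == "cost" & params$low < 0
  if (any(bad)) {
    stop("negative cost parameter: ", paste(params$name[bad], collapse = ", "))
  }
  invisible(params)
}

#' Look up a parameter's current (base) value
#'
#' @param params An `avcea_parameters` object.
#' @param name Parameter name (scalar or vector).
#' @return Numeric value(s).
#' @export
param_value <- function(params, name) {
  idx <- match(name, params$name)
  if (anyNA(idx)) {
    stop("unknown parameter: ", paste(name[is.na(idx)], collapse = ", "))
  }
  params$base[idx]
}

#' Override a parameter value
#'
#' Sets the base (current) value of one parameter, re-validating the whole
#' set. Out-of-kind values (probability above 1, negative cost) are rejected.
#'
#' @inheritParams param_value
#' @param value New value.
#' @param clamp_bounds If `TRUE` the low/high bounds are widened to keep
#'   `low <= base <= high`; the default widens, since an override outside the
#'   published range is an explicit user choice.
#' @return The modified parameter set.
#' @export
set_param <- function(params, name, value, clamp_bounds = TRUE) {
  idx <- match(name, params$name)
  if (is.na(idx)) stop("unknown parameter: ", name)
  params$base[idx] <- value
  if (clamp_bounds) {
    params$low[idx] <- min(params$low[idx], value)
    params$high[idx] <- max(params$high[idx], value)
  }
  .validate_parameters(params)
  params
}

# Keys in a run configuration that are not model parameters.
.reserved_config_keys <- c("seed", "strategies", "trace", "out_dir", "cohort",
                           "psa_draws", "psa_inner_iterations")

#' Load parameters from a configuration file
#'
#' Reads a flat YAML key-value document of parameter overrides. Any parameter
#' absent from the file keeps its default base value. Unknown keys are
#' rejected (reserved run-control keys such as `seed` and `strategies` are
#' ignored here and consumed by [cmd_run()]).
#'
#' @param config Path to a YAML file, a named list of overrides, or `NULL`
#'   for all defaults.
#' @return An `avcea_parameters` object.
#' @examples
#' load_parameters(list(discount_rate = 0))
#' @export
load_parameters <- function(config = NULL) {
  params <- default_parameters()
  if (is.null(config)) return(params)
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- tryCatch(
      yaml::read_yaml(config),
      error = function(e) stop("malformed config file: ", conditionMessage(e))
    )
    if (is.null(config)) return(params)
  }
  if (!is.list(config)) stop("config must be a file path or a named list")
  overrides <- config[!names(config) %in% .reserved_config_keys]
  unknown <- setdiff(names(overrides), params$name)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  for (nm in names(overrides)) {
    v <- overrides[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("parameter '", nm, "' must be a single finite number")
    }
    params <- set_param(params, nm, v)
  }
  params
}

#' Write the effective parameter values as a flat YAML config
#'
#' The written document round-trips: `load_parameters(path)` reproduces the
#' same effective values bit-for-bit.
#'
#' @param params An `avcea_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  vals <- as.list(params$base)
  names(vals) <- params$name
  yaml::write_yaml(vals, path, precision = 17)
  invisible(path)
}

#' Dump the parameter registry as CSV
#'
#' Columns `name,kind,low,base,high,distribution`.
#'
#' @inheritParams write_config
#' @return `path`, invisibly.
#' @export
write_parameters_csv <- function(params, path) {
  utils::write.csv(as.data.frame(params)[, c("name", "kind", "low", "base",
                                             "high", "distribution")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Triangular random deviates
#'
#' Inverse-CDF sampler for the triangular distribution on `[low, high]` with
#' mode `mode`. Degenerate cases (`low == high`) return the point mass.
#'
#' @param n Number of draws.
#' @param low,mode,high Distribution support and mode, `low <= mode <= high`.
#' @return Numeric vector of `n` draws in `[low, high]`.
#' @export
rtriangular <- function(n, low, mode, high) {
  stopifnot(low <= mode, mode <= high)
  if (high == low) return(rep(low, n))
  u <- stats::runif(n)
  fc <- (mode - low) / (high - low)
  ifelse(u < fc,
         low + sqrt(u * (high - low) * (mode - low)),
         high - sqrt((1 - u) * (high - low) * (high - mode)))
}

#' Draw one probabilistic-sensitivity-analysis parameter set
#'
#' Every parameter with `distribution == "triangular"` and `low < high` is
#' replaced by a single draw from a triangular distribution with mode at the
#' base value; fixed parameters (and degenerate ranges) are unchanged. The
#' four AV severity-split components are renormalized to sum to one after
#' sampling so the draw remains a valid probability vector.
#'
#' Draws consume the session RNG stream; seed with `set.seed()` (or let
#' [run_psa()] manage seeding) for reproducibility.
#'
#' @param params An `avcea_parameters` object.
#' @return A new `avcea_parameters` object with sampled base values.
#' @export
sample_psa <- function(params) {
  varied <- params$distribution == "triangular" & params$low < params$high
  for (i in which(varied)) {
    params$base[i] <- rtriangular(1, params$low[i], params$base[i],
                                  params$high[i])
  }
  # keep each sampled severity split a probability vector
  split <- paste0("av_split_", c("pdo", "minor", "severe", "fatal"))
  idx <- match(split, params$name)
  tot <- sum(params$base[idx])
  params$base[idx] <- params$base[idx] / tot
  params$low[idx] <- pmin(params$low[idx], params$base[idx])
  params$high[idx] <- pmax(params$high[idx], params$base[idx])
  .validate_parameters(params)
  params
}
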