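# Decision metrics: ICERs, dominance verdicts, willingness-to-pay
# comparisons, one-way sensitivity analyses and probabilistic sensitivity
# analysis (PSA) with triangular parameter distributions.

#' Incremental cost-effectiveness ratio with dominance verdict
#'
#' For an intervention versus a comparator, computes
#' `delta_cost / delta_qalys` and classifies the result:
#' \describe{
#'   \item{ICER}{`delta_cost` and `delta_qalys` share a sign (and
#'     `delta_qalys != 0`): the ratio is meaningful.}
#'   \item{DOMINANT}{cheaper and more effective (`delta_cost < 0`,
#'     `delta_qalys > 0`): "saves money and QALYs".}
#'   \item{DOMINATED}{more expensive and less effective.}
#'   \item{UNDEFINED}{`delta_qalys == 0`: no ratio is reported.}
#' }
#'
#' @param delta_cost Incremental cost, USD.
#' @param delta_qalys Incremental QALYs.
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @return An object of class `avcea_cea`: list with `delta_cost`,
#'   `delta_qalys`, `icer` (`NA` unless verdict is `ICER`), `verdict`,
#'   `wtp_threshold` and `cost_effective`.
#' @examples
#' compute_icer(425757 - 286146, 16.51 - 16.41)
#' @export
compute_icer <- function(delta_cost, delta_qalys, wtp = 140000) {
  if (delta_qalys == 0) {
    verdict <- "UNDEFINED"; icer <- NA_real_
  } else if (delta_cost < 0 && delta_qalys > 0) {
    verdict <- "DOMINANT"; icer <- NA_real_
  } else if (delta_cost > 0 && delta_qalys < 0) {
    verdict <- "DOMINATED"; icer <- NA_real_
  } else {
    verdict <- "ICER"; icer <- delta_cost / delta_qalys
  }
  structure(list(delta_cost = delta_cost, delta_qalys = delta_qalys,
                 icer = icer, verdict = verdict, wtp_threshold = wtp,
                 cost_effective = threshold_verdict(
                   if (verdict %in% c("DOMINANT", "DOMINATED")) verdict
                   else icer, wtp)),
            class = "avcea_cea")
}

#' @export
print.avcea_cea <- function(x, ...) {
  cat(sprintf("delta cost: $%s, delta QALYs: %.4g\n",
              format(round(x$delta_cost), big.mark = ","), x$delta_qalys))
  if (x$verdict == "ICER") {
    cat(sprintf("ICER: $%s/QALY (%scost-effective at $%s/QALY)\n",
                format(round(x$icer), big.mark = ","),
                if (x$cost_effective) "" else "not ",
                format(x$wtp_threshold, big.mark = ",")))
  } else {
    cat("verdict:", x$verdict, "\n")
  }
  invisible(x)
}

#' Willingness-to-pay verdict
#'
#' `TRUE` iff the ICER is at or below the threshold (boundary inclusive) or
#' the intervention is dominant; `FALSE` for a dominated intervention or an
#' undefined ratio.
#'
#' @param icer A numeric ICER (USD/QALY), or one of the strings
#'   `"DOMINANT"`, `"DOMINATED"`, `"UNDEFINED"`.
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @return Logical.
#' @export
threshold_verdict <- function(icer, wtp = 140000) {
  if (is.character(icer)) {
    return(switch(icer, DOMINANT = TRUE, DOMINATED = FALSE,
                  UNDEFINED = FALSE,
                  stop("unknown verdict string: ", icer)))
  }
  if (is.na(icer)) return(FALSE)
  icer <= wtp
}

#' Results table of a simulation with pairwise ICERs
#'
#' Builds the standard cost-effectiveness results table: per-strategy mean
#' discounted cost and QALYs with empirical 2.5/97.5 percentile intervals,
#' and for every non-comparator strategy, the ICER (or dominance verdict)
#' against the comparator.
#'
#' @param sim An `avcea_simulation` from [run_simulation()].
#' @param comparator Strategy name used as the baseline (default the first
#'   simulated strategy).
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @return A tibble with the summary columns plus `icer` (numeric, `NA`
#'   when a verdict replaces it) and `verdict`.
#' @export
icer_table <- function(sim, comparator = sim$summary$strategy[1],
                       wtp = 140000) {
  s <- sim$summary
  if (!comparator %in% s$strategy) stop("comparator not simulated: ",
                                        comparator)
  base <- s[s$strategy == comparator, ]
  res <- s
  res$icer <- NA_real_
  res$verdict <- ""
  for (i in seq_len(nrow(res))) {
    if (res$strategy[i] == comparator) next
    ce <- compute_icer(res$mean_cost[i] - base$mean_cost,
                       res$mean_qalys[i] - base$mean_qalys, wtp)
    res$icer[i] <- ce$icer
    res$verdict[i] <- ce$verdict
  }
  res
}

#' One-way sensitivity analysis
#'
#' Re-runs the paired simulation (same seed, so the only change is the
#' parameter under study) with the parameter at its low and at its high
#' bound, and reports the ICER of `strategy_pair[2]` versus
#' `strategy_pair[1]` at each endpoint together with the swing. Parameters
#' without a range (`distribution == "fixed"` or `low == high`) are skipped
#' with a message.
#'
#' @param params An `avcea_parameters` object.
#' @param varied Character vector of parameter names; default all
#'   triangular-distributed parameters.
#' @param strategy_pair Comparator and intervention strategies.
#' @param cohort Cohort tables.
#' @param n_iterations Iterations per run.
#' @param seed Master seed shared by every run.
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @return A tibble with one row per varied parameter: `parameter`, `low`,
#'   `high`, `icer_low`, `icer_high`, `verdict_low`, `verdict_high`,
#'   `swing` (absolute ICER difference; `NA` if either endpoint has a
#'   dominance verdict).
#' @export
one_way_sensitivity <- function(params = default_parameters(),
                                varied = NULL,
                                strategy_pair = c("HPV", "AV"),
                                cohort = default_cohort(),
                                n_iterations = 1000,
                                seed = 1L,
                                wtp = 140000) {
  if (is.null(varied)) {
    varied <- params$name[params$distribution == "triangular" &
                            params$low < params$high]
  }
  rows <- lapply(varied, function(nm) {
    row <- params[params$name == nm, ]
    if (row$distribution == "fixed" || row$low >= row$high) {
      message("skipping fixed parameter: ", nm)
      return(NULL)
    }
    icer_at <- function(value) {
      p2 <- set_param(params, nm, value)
      sim <- run_simulation(strategy_pair, p2, cohort, n_iterations, seed)
      ce <- compute_icer(
        sim$summary$mean_cost[2] - sim$summary$mean_cost[1],
        sim$summary$mean_qalys[2] - sim$summary$mean_qalys[1], wtp)
      list(icer = ce$icer, verdict = ce$verdict)
    }
    lo <- icer_at(row$low); hi <- icer_at(row$high)
    tibble::tibble(parameter = nm, low = row$low, high = row$high,
                   icer_low = lo$icer, icer_high = hi$icer,
                   verdict_low = lo$verdict, verdict_high = hi$verdict,
                   swing = abs(hi$icer - lo$icer))
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Probabilistic sensitivity analysis
#'
#' For each draw, samples every triangular-distributed parameter jointly
#' (see [sample_psa()]), runs a reduced-size paired simulation, and records
#' the incremental cost, incremental QALYs and ICER/verdict of
#' `strategy_pair[2]` versus `strategy_pair[1]`.
#'
#' @param params An `avcea_parameters` object.
#' @param n_draws Number of PSA parameter draws.
#' @param strategy_pair Comparator and intervention strategies.
#' @param cohort Cohort tables.
#' @param n_iterations Inner simulation size per draw (default 1,000, a
#'   tractable inner loop; increase for production runs).
#' @param seed Master seed; draw d uses a child seed derived from it.
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @return An object of class `avcea_psa`: list with `draws` (tibble:
#'   `draw`, `delta_cost`, `delta_qalys`, `icer`, `verdict`,
#'   `cost_effective`), `prob_cost_effective` at `wtp`, and `wtp_threshold`.
#' @export
run_psa <- function(params = default_parameters(),
                    n_draws = 200,
                    strategy_pair = c("HPV", "AV"),
                    cohort = default_cohort(),
                    n_iterations = 1000,
                    seed = 1L,
                    wtp = 140000) {
  stopifnot(n_draws >= 1)
  # one simulation seed for every draw: parameter uncertainty is then the
  # only difference between draws (common random numbers across the PSA)
  sim_seed <- .substream_seed(seed, "psa-sim")
  rows <- lapply(seq_len(n_draws), function(d) {
    set.seed(.substream_seed(seed, paste0("psa:", d)))
    pd <- sample_psa(params)
    sim <- run_simulation(strategy_pair, pd, cohort, n_iterations,
                          seed = sim_seed)
    ce <- compute_icer(sim$summary$mean_cost[2] - sim$summary$mean_cost[1],
                       sim$summary$mean_qalys[2] - sim$summary$mean_qalys[1],
                       wtp)
    tibble::tibble(draw = d, delta_cost = ce$delta_cost,
                   delta_qalys = ce$delta_qalys, icer = ce$icer,
                   verdict = ce$verdict, cost_effective = ce$cost_effective)
  })
  draws <- do.call(rbind, rows)
  structure(list(draws = draws,
                 prob_cost_effective = mean(draws$cost_effective),
                 wtp_threshold = wtp),
            class = "avcea_psa")
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA draws cost-effective at each willingness-to-pay value.
#' Non-decreasing in the threshold by construction.
#'
#' @param psa An `avcea_psa` from [run_psa()].
#' @param wtp_grid Numeric vector of thresholds, USD/QALY.
#' @return A tibble with columns `wtp` and `prob_cost_effective`.
#' @export
acceptability_curve <- function(psa, wtp_grid = seq(0, 500000, by = 20000)) {
  prob <- vapply(wtp_grid, function(w) {
    mean(mapply(function(icer, verdict) {
      threshold_verdict(if (verdict %in% c("DOMINANT", "DOMINATED",
                                           "UNDEFINED")) verdict else icer, w)
    }, psa$draws$icer, psa$draws$verdict))
  }, 0)
  tibble::tibble(wtp = wtp_grid, prob_cost_effective = prob)
}
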