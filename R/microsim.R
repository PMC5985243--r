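# The Markov-chain Monte Carlo engine. Paired arms share the draws of every
# strategy-independent process (driver age, background mortality, vehicle
# lifespan) -- common random numbers, so the incremental estimate reflects
# only the strategy effect -- while crash and severity draws come from
# per-strategy sub-streams derived from the master seed.
#
# Per annual timestep t (state occupied during year t accrues first):
#   accrue:   utility(state) discounted at t; recurring costs while driving
#   (1) crash (driving states): severity from the profile's split; FATAL ->
#       DEAD (+ fatal cost + funeral), SEVERE -> DRIVING_INJURED (+ cost),
#       MINOR/PDO -> stay (+ cost)
#   (2) lifetable death by current age (all living states; funeral if the
#       death falls inside the analytic horizon, i.e. while driving)
#   (3) vehicle expiration: driving states move to the POST_HORIZON states
#       (QALYs continue to accrue, vehicle costs stop; no replacement)
# The mortality table closes at q = 1 and T = 100 covers the maximum age
# from any start age, so every subject is dead when the model ends.

.states <- c("DRIVING", "DRIVING_INJURED", "DEAD", "POST_HORIZON_HEALTHY",
             "POST_HORIZON_INJURED")
.ST_DRIVING <- 1L; .ST_INJURED <- 2L; .ST_DEAD <- 3L
.ST_POST <- 4L; .ST_POST_INJ <- 5L

# Deterministic sub-stream seed: hash a label into [1, 2^31 - 2] together
# with the master seed, so each named stream gets its own reproducible
# R RNG seeding.
.substream_seed <- function(seed, label) {
  m <- 2147483647
  s <- as.double(seed %% m)
  for (c in utf8ToInt(label)) s <- (s * 31 + c) %% m
  as.integer(s %% (m - 1) + 1)
}

# n x t_max matrix of uniforms from a named sub-stream.
.stream_uniforms <- function(seed, label, n, t_max) {
  set.seed(.substream_seed(seed, label))
  matrix(stats::runif(n * t_max), nrow = n, ncol = t_max)
}

# Lookup vectors used by both engines.
.mortality_vector <- function(mortality) {
  stopifnot(identical(mortality$age, seq(0L, max(mortality$age))))
  mortality$q
}

.model_inputs <- function(strategy, params, cohort) {
  list(schedule = build_cost_schedule(strategy, params),
       profile = crash_profile(strategy, params),
       q = .mortality_vector(cohort$mortality),
       hv = cohort$vehicle$expire_prob,
       rate = param_value(params, "discount_rate"),
       u_healthy = param_value(params, "healthy_utility"),
       u_injured = param_value(params, "severe_injury_utility"))
}

# Vectorized engine: simulates n iterations of one strategy arm at once.
# draws: list of n x t_max matrices u_crash, u_sev, u_mort, u_exp.
.simulate_strategy <- function(strategy, params, cohort, ages, draws, t_max,
                               keep_states = FALSE) {
  inp <- .model_inputs(strategy, params, cohort)
  n <- length(ages)
  cum_split <- cumsum(inp$profile$severity_split)
  util_by_state <- c(inp$u_healthy, inp$u_injured, 0, inp$u_healthy,
                     inp$u_injured)
  max_age <- length(inp$q) - 1L
  max_vage <- length(inp$hv) - 1L

  state <- rep(.ST_DRIVING, n)
  cost <- rep(inp$schedule$purchase, n)
  qaly <- numeric(n)
  death_time <- rep(NA_integer_, n)
  states_mat <- if (keep_states) matrix(NA_integer_, n, t_max) else NULL

  for (t in 0:(t_max - 1L)) {
    tc <- t + 1L
    if (keep_states) states_mat[, tc] <- state
    disc <- (1 + inp$rate)^(-t)
    driving <- state <= .ST_INJURED
    qaly <- qaly + util_by_state[state] * disc
    cost[driving] <- cost[driving] + inp$schedule$annual_recurring * disc

    # (1) crash
    crash <- driving & draws$u_crash[, tc] < inp$profile$annual_crash_prob
    if (any(crash)) {
      sev <- findInterval(draws$u_sev[, tc], cum_split) + 1L
      cost[crash] <- cost[crash] + inp$schedule$crash_costs[sev[crash]] * disc
      fatal <- crash & sev == 4L
      cost[fatal] <- cost[fatal] + inp$schedule$funeral * disc
      death_time[fatal] <- t
      state[fatal] <- .ST_DEAD
      state[crash & sev == 3L & state != .ST_DEAD] <- .ST_INJURED
    }

    # (2) lifetable death on survivors
    qv <- inp$q[pmin(ages + t, max_age) + 1L]
    die <- state != .ST_DEAD & draws$u_mort[, tc] < qv
    if (any(die)) {
      in_horizon <- die & state <= .ST_INJURED
      cost[in_horizon] <- cost[in_horizon] + inp$schedule$funeral * disc
      death_time[die] <- t
      state[die] <- .ST_DEAD
    }

    # (3) vehicle expiration (vehicle age = t; no replacement)
    hvt <- inp$hv[min(t, max_vage) + 1L]
    expd <- state <= .ST_INJURED & draws$u_exp[, tc] < hvt
    state[expd & state == .ST_DRIVING] <- .ST_POST
    state[expd & state == .ST_INJURED] <- .ST_POST_INJ
  }

  list(cost = cost, qalys = qaly, death_time = death_time,
       final_state = state, states = states_mat)
}

# Crash and severity streams are per-strategy; mortality and expiration are
# shared across strategies (they model the same person and the same vehicle
# lifespan process, which all strategies assume equivalent), maximizing the
# variance reduction of the paired design.
.arm_draws <- function(seed, strategy, n, t_max, shared = FALSE) {
  tag <- if (shared) "" else paste0(":", strategy)
  list(u_crash = .stream_uniforms(seed, paste0("crash", tag), n, t_max),
       u_sev = .stream_uniforms(seed, paste0("severity", tag), n, t_max),
       u_mort = .stream_uniforms(seed, "mortality", n, t_max),
       u_exp = .stream_uniforms(seed, "expiration", n, t_max))
}

# Scalar reference engine for a single arm: same event order and draw
# consumption as .simulate_strategy, but emits a per-timestep event log so a
# trace can be replayed and re-summed independently.
.simulate_arm_trace <- function(strategy, params, cohort, age, draws, t_max) {
  inp <- .model_inputs(strategy, params, cohort)
  cum_split <- cumsum(inp$profile$severity_split)
  util_by_state <- c(inp$u_healthy, inp$u_injured, 0, inp$u_healthy,
                     inp$u_injured)
  max_age <- length(inp$q) - 1L
  max_vage <- length(inp$hv) - 1L

  state <- .ST_DRIVING
  cost <- 0; qaly <- 0
  death_time <- NA_integer_
  crash_history <- list()
  rows <- list(list(t = 0L, state = .states[state], event = "purchase",
                    cost = inp$schedule$purchase, qaly = 0))
  cost <- cost + inp$schedule$purchase

  for (t in 0:(t_max - 1L)) {
    tc <- t + 1L
    disc <- (1 + inp$rate)^(-t)
    driving <- state <= .ST_INJURED
    dq <- util_by_state[state] * disc
    dc <- if (driving) inp$schedule$annual_recurring * disc else 0
    qaly <- qaly + dq
    cost <- cost + dc
    rows[[length(rows) + 1L]] <- list(t = t, state = .states[state],
                                      event = "accrual", cost = dc, qaly = dq)

    if (driving && draws$u_crash[tc] < inp$profile$annual_crash_prob) {
      sev <- findInterval(draws$u_sev[tc], cum_split) + 1L
      cc <- unname(inp$schedule$crash_costs[sev]) * disc
      cost <- cost + cc
      rows[[length(rows) + 1L]] <- list(t = t, state = .states[state],
                                        event = paste0("crash_",
                                                       .severities[sev]),
                                        cost = unname(cc), qaly = 0)
      crash_history[[length(crash_history) + 1L]] <-
        list(t = t, severity = .severities[sev])
      if (sev == 4L) {
        cost <- cost + inp$schedule$funeral * disc
        rows[[length(rows) + 1L]] <- list(t = t, state = "DEAD",
                                          event = "funeral",
                                          cost = inp$schedule$funeral * disc,
                                          qaly = 0)
        death_time <- t
        state <- .ST_DEAD
      } else if (sev == 3L) {
        state <- .ST_INJURED
      }
    }

    if (state != .ST_DEAD &&
        draws$u_mort[tc] < inp$q[min(age + t, max_age) + 1L]) {
      if (state <= .ST_INJURED) {
        cost <- cost + inp$schedule$funeral * disc
        rows[[length(rows) + 1L]] <- list(t = t, state = "DEAD",
                                          event = "funeral",
                                          cost = inp$schedule$funeral * disc,
                                          qaly = 0)
      }
      rows[[length(rows) + 1L]] <- list(t = t, state = "DEAD",
                                        event = "death_lifetable",
                                        cost = 0, qaly = 0)
      death_time <- t
      state <- .ST_DEAD
    }

    if (state <= .ST_INJURED &&
        draws$u_exp[tc] < inp$hv[min(t, max_vage) + 1L]) {
      state <- if (state == .ST_DRIVING) .ST_POST else .ST_POST_INJ
      rows[[length(rows) + 1L]] <- list(t = t, state = .states[state],
                                        event = "vehicle_expired",
                                        cost = 0, qaly = 0)
    }
  }

  trace <- do.call(rbind, lapply(rows, function(r) {
    data.frame(t = r$t, state = r$state, event = r$event, cost = r$cost,
               qaly = r$qaly)
  }))
  ch <- if (length(crash_history)) {
    do.call(rbind, lapply(crash_history, function(r) {
      data.frame(t = r$t, severity = r$severity)
    }))
  } else data.frame(t = integer(0), severity = character(0))
  list(cost = cost, qalys = qaly, death_time = death_time,
       final_state = .states[state], crash_history = ch,
       trace = tibble::as_tibble(trace))
}

#' Run one paired iteration
#'
#' Simulates the arms of a single iteration: each arm's driver has the same
#' randomly selected age, background-mortality draws and vehicle-lifespan
#' draws (common random numbers), while each strategy follows its own crash
#' and severity sub-streams. Returns the full event log of each arm, so a
#' trace can be audited or replayed.
#'
#' @param strategy_pair Character vector of strategies (usually two), see
#'   [strategies()].
#' @param params An `avcea_parameters` object.
#' @param cohort Cohort tables, see [default_cohort()].
#' @param seed Integer seed for this iteration.
#' @param shared_streams If `TRUE`, both arms consume identical event
#'   streams (useful for verifying the common-random-number machinery:
#'   identical strategies then produce identical records).
#' @param n_timesteps Number of annual timesteps (default from `params`).
#' @return An object of class `avcea_iteration`: a list with `start_age`
#'   and one entry per arm holding `cost`, `qalys`, `death_time`,
#'   `final_state`, `crash_history` and a `trace` tibble with columns
#'   `t, state, event, cost, qaly` (discounted contributions).
#' @export
run_iteration <- function(strategy_pair = c("HPV", "AV"),
                          params = default_parameters(),
                          cohort = default_cohort(),
                          seed = 1L,
                          shared_streams = FALSE,
                          n_timesteps = param_value(params, "n_timesteps")) {
  strategy_pair <- vapply(strategy_pair, match.arg, "", choices = .strategies)
  t_max <- as.integer(n_timesteps)
  set.seed(.substream_seed(seed, "age"))
  age <- sample_age(cohort$age_distribution, 1)
  arms <- lapply(seq_along(strategy_pair), function(i) {
    s <- strategy_pair[i]
    tag <- if (shared_streams) "" else paste0(":", s, ":", i)
    draws <- list(
      u_crash = .stream_uniforms(seed, paste0("crash", tag), 1, t_max)[1, ],
      u_sev = .stream_uniforms(seed, paste0("severity", tag), 1, t_max)[1, ],
      u_mort = .stream_uniforms(seed, "mortality", 1, t_max)[1, ],
      u_exp = .stream_uniforms(seed, "expiration", 1, t_max)[1, ])
    .simulate_arm_trace(s, params, cohort, age, draws, t_max)
  })
  names(arms) <- make.unique(strategy_pair)
  structure(list(start_age = age, arms = arms), class = "avcea_iteration")
}

#' Run the Monte Carlo microsimulation
#'
#' Simulates `n_iterations` paired iterations for each requested strategy.
#' All strategies share each iteration's age, background-mortality and
#' vehicle-expiration draws (common random numbers across arms); each
#' strategy has its own crash and severity sub-streams derived from the
#' master seed, so any pair of strategies forms a paired design. Results
#' are bit-reproducible for a fixed seed.
#'
#' @param strategies Character vector of strategies to simulate.
#' @param params An `avcea_parameters` object.
#' @param cohort Cohort tables, see [default_cohort()].
#' @param n_iterations Number of iterations (default from `params`: 10,000).
#' @param seed Master integer seed.
#' @param n_timesteps Annual timesteps (default from `params`: 100).
#' @param keep_states If `TRUE`, retain the full per-timestep state matrix
#'   of every strategy (memory grows as iterations x timesteps).
#' @return An object of class `avcea_simulation`: list with `summary` (a
#'   tibble: strategy, mean/2.5\%/97.5\% of discounted cost and QALYs),
#'   `iterations` (per-strategy lists of per-iteration vectors `cost`,
#'   `qalys`, `death_time`), `ages`, `seed`, `n_iterations`, `n_timesteps`.
#' @examples
#' sim <- run_simulation(c("HPV", "AV"), n_iterations = 200, seed = 1)
#' sim$summary
#' @export
run_simulation <- function(strategies = c("HPV", "AV"),
                           params = default_parameters(),
                           cohort = default_cohort(),
                           n_iterations = param_value(params, "n_iterations"),
                           seed = 1L,
                           n_timesteps = param_value(params, "n_timesteps"),
                           keep_states = FALSE) {
  strategies <- vapply(strategies, match.arg, "", choices = .strategies)
  if (anyDuplicated(strategies)) stop("duplicate strategies requested")
  n <- as.integer(n_iterations)
  if (n < 1) stop("n_iterations must be at least 1")
  t_max <- as.integer(n_timesteps)
  if (t_max < 1) stop("n_timesteps must be at least 1")

  set.seed(.substream_seed(seed, "age"))
  ages <- sample_age(cohort$age_distribution, n)

  per_strategy <- lapply(strategies, function(s) {
    draws <- .arm_draws(seed, s, n, t_max)
    res <- .simulate_strategy(s, params, cohort, ages, draws, t_max,
                              keep_states = keep_states)
    draws <- NULL
    res
  })
  names(per_strategy) <- strategies

  qtl <- function(x, p) unname(stats::quantile(x, p, type = 7))
  summary <- do.call(rbind, lapply(strategies, function(s) {
    r <- per_strategy[[s]]
    tibble::tibble(strategy = s,
                   mean_cost = mean(r$cost),
                   cost_lo = qtl(r$cost, 0.025),
                   cost_hi = qtl(r$cost, 0.975),
                   mean_qalys = mean(r$qalys),
                   qalys_lo = qtl(r$qalys, 0.025),
                   qalys_hi = qtl(r$qalys, 0.975))
  }))

  structure(list(summary = summary, iterations = per_strategy, ages = ages,
                 seed = seed, n_iterations = n, n_timesteps = t_max),
            class = "avcea_simulation")
}

#' @export
print.avcea_simulation <- function(x, ...) {
  cat("Markov microsimulation:", x$n_iterations, "iterations,",
      x$n_timesteps, "timesteps, seed", x$seed, "\n")
  print(x$summary)
  invisible(x)
}
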