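test_that("forced death in year one accrues one year of life and cost", {
  # no crashes, certain death at the start age, full utility
  params <- no_crash_params()
  params <- set_param(params, "healthy_utility", 1)
  cohort <- fixed_age_cohort(47)
  cohort$mortality <- certain_death_table()
  it <- run_iteration(c("HPV", "AV"), params, cohort, seed = 7)
  for (arm in names(it$arms)) {
    sched <- build_cost_schedule(arm, params)
    expect_equal(it$arms[[arm]]$qalys, 1.0)
    # purchase + one year recurring + funeral (death inside the horizon)
    expect_equal(it$arms[[arm]]$cost,
                 sched$purchase + sched$annual_recurring + sched$funeral)
    expect_equal(it$arms[[arm]]$death_time, 0L)
  }
})

test_that("a guaranteed fatal crash at t=0 produces the hand-computed totals", {
  params <- always_fatal_params()
  params <- set_param(params, "healthy_utility", 1)
  cohort <- fixed_age_cohort(30)
  cohort$mortality <- build_mortality_table(data.frame(age = 0:110,
                                                       q = c(rep(0, 110), 1)))
  it <- run_iteration("HPV", params, cohort, seed = 3)
  sched <- build_cost_schedule("HPV", params)
  arm <- it$arms$HPV
  expect_equal(arm$cost, sched$purchase + sched$annual_recurring +
                 sched$crash_costs[["FATAL"]] + sched$funeral)
  expect_equal(arm$qalys, 1.0)
  expect_equal(arm$death_time, 0L)
  expect_identical(arm$crash_history$severity, "FATAL")
})

test_that("identical strategies with fully shared streams give identical records", {
  it <- run_iteration(c("HPV", "HPV"), seed = 11, shared_streams = TRUE)
  expect_identical(it$arms[[1]]$cost, it$arms[[2]]$cost)
  expect_identical(it$arms[[1]]$qalys, it$arms[[2]]$qalys)
  expect_identical(it$arms[[1]]$trace, it$arms[[2]]$trace)
})

test_that("simulations are bit-reproducible for a fixed seed", {
  a <- run_simulation(c("HPV", "AV"), n_iterations = 100, seed = 123)
  b <- run_simulation(c("HPV", "AV"), n_iterations = 100, seed = 123)
  expect_identical(a$summary, b$summary)
  expect_identical(a$iterations$AV$cost, b$iterations$AV$cost)
  c <- run_simulation(c("HPV", "AV"), n_iterations = 100, seed = 124)
  expect_false(identical(a$summary, c$summary))
})

test_that("scalar trace engine and vectorized engine agree draw-for-draw", {
  params <- default_parameters()
  cohort <- default_cohort()
  n <- 50; t_max <- 100; seed <- 21
  set.seed(avcea:::.substream_seed(seed, "age"))
  ages <- sample_age(cohort$age_distribution, n)
  for (s in c("HPV", "AV_TAXI")) {
    draws <- avcea:::.arm_draws(seed, s, n, t_max)
    vec <- avcea:::.simulate_strategy(s, params, cohort, ages, draws, t_max)
    for (i in c(1, 17, 50)) {
      row <- list(u_crash = draws$u_crash[i, ], u_sev = draws$u_sev[i, ],
                  u_mort = draws$u_mort[i, ], u_exp = draws$u_exp[i, ])
      sc <- avcea:::.simulate_arm_trace(s, params, cohort, ages[i], row, t_max)
      expect_equal(sc$cost, vec$cost[i])
      expect_equal(sc$qalys, vec$qalys[i])
      expect_equal(sc$death_time, vec$death_time[i])
    }
  }
})

test_that("a single-iteration simulation summarizes to that iteration", {
  sim <- run_simulation("HPV", n_iterations = 1, seed = 9)
  expect_equal(sim$summary$mean_cost, sim$iterations$HPV$cost)
  expect_equal(sim$summary$mean_qalys, sim$iterations$HPV$qalys)
})

test_that("every subject is dead when the model closes", {
  sim <- run_simulation(c("HPV", "AV"), n_iterations = 2000, seed = 31)
  for (s in c("HPV", "AV")) {
    expect_true(all(is.finite(sim$iterations[[s]]$death_time)))
    expect_true(all(sim$iterations[[s]]$death_time < sim$n_timesteps))
    expect_true(all(sim$iterations[[s]]$final_state == 3L))
  }
})

test_that("raising the crash probability never raises mean QALYs", {
  cohort <- default_cohort()
  qs <- vapply(c(0, 0.1, 0.3, 0.6, 0.9), function(p) {
    params <- set_param(default_parameters(), "hpv_crash_prob", p)
    run_simulation("HPV", params, cohort, 800, seed = 5)$summary$mean_qalys
  }, 0)
  expect_true(all(diff(qs) <= 0))
})

test_that("the paired standard error shrinks like one over root n", {
  cohort <- fixed_age_cohort(47)
  mean_cost <- function(n, seed) {
    run_simulation("HPV", default_parameters(), cohort, n,
                   seed = seed)$summary$mean_cost
  }
  m250 <- vapply(1:30, function(s) mean_cost(250, s), 0)
  m500 <- vapply(31:60, function(s) mean_cost(500, s), 0)
  ratio <- sd(m250) / sd(m500)
  expect_gt(ratio, 1.05)
  expect_lt(ratio, 1.95)
})

test_that("input validation rejects impossible run sizes", {
  expect_error(run_simulation("HPV", n_iterations = 0), "at least 1")
  expect_error(run_simulation(c("HPV", "HPV")), "duplicate")
  expect_error(run_simulation("HPV", n_iterations = 5, n_timesteps = 0),
               "at least 1")
})
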