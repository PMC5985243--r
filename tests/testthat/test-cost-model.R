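test_that("discounting matches independent arithmetic", {
  expect_equal(discount(100, 0, 0.03), 100)
  expect_equal(discount(100, 1, 0.03), 97.0874, tolerance = 1e-6)
  expect_equal(discount(1000, 10, 0.03), 744.094, tolerance = 1e-6)
  expect_equal(discount(500, 7, 0), 500) # zero rate is the identity
  expect_error(discount(1, -1, 0.03))
})

test_that("Moore projection halves the technology component per period", {
  expect_equal(moore_projection(183666, 0, 2, 0), 183666)
  expect_equal(moore_projection(183666, 5, 2, 33666),
               33666 + 150000 * 2^(-2.5))
  expect_equal(moore_projection(183666, 5, 2, 33666), 60183, tolerance = 1)
  for (C in c(100, 5000)) {
    expect_equal(moore_projection(C, 3, 3, 0), C / 2)
  }
  # continuous and strictly decreasing while technology dominates
  y <- moore_projection(183666, seq(0, 20, by = 0.25), 2, 33666)
  expect_true(all(diff(y) < 0))
})

test_that("parking amortization covers straight-line and annuity forms", {
  expect_equal(amortize_parking(102000, 3.4, 40, 0), 8670)
  expect_equal(amortize_parking(30000, 1.0, 40, 0), 750)
  expect_equal(amortize_parking(1234, 2.5, 1, 0), 1234 * 2.5)
  # annuity at 3%: principal equals the discounted payment stream
  pay <- amortize_parking(102000, 3.4, 40, 0.03)
  expect_equal(sum(pay / 1.03^(1:40)), 102000 * 3.4, tolerance = 1e-6)
})

test_that("crash-cost scaling reproduces the published AV column", {
  params <- default_parameters()
  shares <- default_damage_shares(params)
  hpv <- param_value(params, paste0("crash_cost_",
                                    c("pdo", "minor", "severe", "fatal"),
                                    "_hpv"))
  av <- param_value(params, paste0("crash_cost_",
                                   c("pdo", "minor", "severe", "fatal"),
                                   "_av"))
  scaled <- scale_crash_cost(hpv, shares, 33666, 183666)
  expect_equal(unname(scaled / av), rep(1, 4), tolerance = 0.01)
  expect_equal(scaled[[1]], 4615, tolerance = 1)
  expect_equal(scaled[[3]], 294503, tolerance = 1)
  # no damage share, no scaling
  expect_equal(scale_crash_cost(4251, 0, 33666, 183666), 4251)
  # cheaper AV clamps at the HPV cost, with a warning
  expect_warning(out <- scale_crash_cost(4251, 0.5, 33666, 20000), "clamped")
  expect_equal(out, 4251)
})

test_that("cost schedules assemble each strategy's published flows", {
  params <- default_parameters()
  hpv <- build_cost_schedule("HPV", params)
  expect_equal(hpv$purchase, 33666)
  expect_equal(hpv$recurring_components[["productivity"]], 1657)
  expect_equal(hpv$recurring_components[["salary"]], 0)
  expect_equal(hpv$crash_costs[["FATAL"]], 1532018)

  av <- build_cost_schedule("AV", params)
  expect_equal(av$purchase, 183666)
  expect_equal(av$recurring_components[["productivity"]], 0)
  expect_equal(av$crash_costs[["FATAL"]], 1552808)
  # non-taxi parking basis: spot cost x spots-per-car ratio, amortized
  expect_equal(av$recurring_components[["parking"]],
               102000 * 3.4 / param_value(params,
                                          "parking_amortization_years"))
  av5 <- build_cost_schedule("AV_5YR", params)
  expect_equal(av5$purchase, 56539)
  expect_equal(av5$annual_recurring, av$annual_recurring)

  avt <- build_cost_schedule("AV_TAXI", params)
  expect_equal(avt$purchase, 282427)
  expect_equal(avt$recurring_components[["salary"]], 0)
  expect_equal(avt$recurring_components[["parking"]],
               30000 / param_value(params, "parking_amortization_years"))
  expect_equal(avt$crash_costs[["PDO"]], 4615) # AV column: the vehicle is an AV

  hpt <- build_cost_schedule("HPT", params)
  expect_equal(hpt$purchase, 132427)
  expect_equal(hpt$recurring_components[["salary"]], 27760)
  expect_equal(hpt$recurring_components[["productivity"]], 0)
  expect_equal(hpt$crash_costs[["PDO"]], 4251)
  expect_error(build_cost_schedule("SCOOTER", params))
})

test_that("AV crash costs dominate their HPV counterparts by category", {
  params <- default_parameters()
  for (sev in c("pdo", "minor", "severe", "fatal")) {
    expect_gte(param_value(params, paste0("crash_cost_", sev, "_av")),
               param_value(params, paste0("crash_cost_", sev, "_hpv")))
  }
})

test_that("with all costs zero, every strategy accrues zero cost", {
  params <- default_parameters()
  for (nm in params$name[params$kind == "cost"]) {
    params$base[params$name == nm] <- 0
    params$low[params$name == nm] <- 0
  }
  cohort <- default_cohort()
  for (s in strategies()) {
    sim <- run_simulation(s, params, cohort, n_iterations = 50, seed = 2)
    expect_identical(unname(sim$iterations[[s]]$cost), rep(0, 50))
    expect_true(all(sim$iterations[[s]]$qalys > 0))
  }
})

test_that("lifetime cost responds monotonically to cost parameters", {
  cohort <- default_cohort()
  base_params <- default_parameters()
  base <- run_simulation("HPV", base_params, cohort, 300, seed = 4)
  for (nm in c("hpv_vehicle_cost", "annual_ownership_cost", "funeral_cost",
               "crash_cost_fatal_hpv", "parking_spot_cost")) {
    bumped <- set_param(base_params, nm, param_value(base_params, nm) * 1.5)
    sim <- run_simulation("HPV", bumped, cohort, 300, seed = 4)
    expect_gte(sim$summary$mean_cost, base$summary$mean_cost)
  }
})

test_that("cost schedule CSV dump covers every strategy and component", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_cost_schedules_csv(default_parameters(), path)
  tab <- read.csv(path)
  expect_setequal(unique(tab$strategy), strategies())
  expect_true(all(c("purchase", "ownership", "parking", "funeral") %in%
                    tab$component))
  expect_true(all(tab$amount >= 0))
})
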