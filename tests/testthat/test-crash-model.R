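test_that("strategies map onto the two published crash profiles", {
  params <- default_parameters()
  hpv <- crash_profile("HPV", params)
  expect_equal(hpv$annual_crash_prob, 0.0646)
  expect_equal(unname(hpv$severity_split * sum(c(0.6091, 0.3766, 0.0090,
                                                 0.0054))),
               c(0.6091, 0.3766, 0.0090, 0.0054))
  av <- crash_profile("AV", params)
  expect_equal(av$annual_crash_prob, 0.08385)
  # taxis and the 5-year projection inherit their vehicle type's profile
  expect_identical(crash_profile("AV_5YR", params), av)
  expect_identical(crash_profile("AV_TAXI", params), av)
  expect_identical(crash_profile("HPT", params), hpv)
  expect_error(crash_profile("BICYCLE", params))
})

test_that("per-mile rates annualize in both conventions", {
  expect_equal(per_mile_to_annual(0, 14133), 0)
  rate <- 14 / 2102047 # observed fleet crashes per autonomous mile
  complement <- 1 - (1 - rate)^14133
  expect_equal(per_mile_to_annual(rate, 14133), complement)
  expect_equal(complement, 0.0899, tolerance = 2e-3)
  expect_equal(per_mile_to_annual(rate, 14133, "product"), rate * 14133)
  expect_equal(rate * 14133, 0.0941, tolerance = 2e-3)
  expect_equal(per_mile_to_annual(1e-9, 1), 1e-9, tolerance = 1e-6)
  expect_error(per_mile_to_annual(1.5, 100), "exceed")
})

test_that("relative risks reproduce the published ratios", {
  expect_equal(relative_risk(0.08385, 0.0646), 1.30)
  # annual fatality probability = crash prob x P(death | crash)
  expect_equal(relative_risk(0.08385 * 9.26e-05, 0.0646 * 0.0054), 0.02)
  expect_equal(relative_risk(0.4242, 0.4242), 1.00)
  # scale invariance
  for (k in c(0.1, 2, 17)) {
    expect_equal(relative_risk(k * 0.03, k * 0.01, digits = 8),
                 relative_risk(0.03, 0.01, digits = 8))
  }
  expect_error(relative_risk(0.1, 0), "positive")
})

test_that("sampled crash outcomes converge to the profile's distribution", {
  none <- structure(list(annual_crash_prob = 0,
                         severity_split = c(PDO = 1, MINOR = 0, SEVERE = 0,
                                            FATAL = 0)),
                    class = "avcea_crash_profile")
  expect_true(all(sample_crash_outcome(none, 50) == "NONE"))
  pdo_only <- structure(list(annual_crash_prob = 1,
                             severity_split = c(PDO = 1, MINOR = 0,
                                                SEVERE = 0, FATAL = 0)),
                        class = "avcea_crash_profile")
  expect_true(all(sample_crash_outcome(pdo_only, 50) == "PDO"))

  profile <- crash_profile("HPV")
  set.seed(9)
  draws <- sample_crash_outcome(profile, 1e6)
  p_fatal <- profile$annual_crash_prob * profile$severity_split[["FATAL"]]
  expect_equal(p_fatal, 0.0646 * 0.0054, tolerance = 2e-4)
  expect_lt(abs(mean(draws == "FATAL") - p_fatal),
            3 * sqrt(p_fatal * (1 - p_fatal) / 1e6))
  # chi-square goodness of fit over all five outcomes
  expected <- c(NONE = 1 - profile$annual_crash_prob,
                profile$annual_crash_prob * profile$severity_split)
  names(expected) <- c("NONE", names(profile$severity_split))
  observed <- table(factor(draws, levels = names(expected)))
  gof <- suppressWarnings(chisq.test(observed, p = expected))
  expect_gt(gof$p.value, 0.001)
})

test_that("delta-V severity mapping is an expectation over the speed distribution", {
  curve <- default_risk_curve()
  # a zero-energy crash damages property only
  expect_equal(unname(severity_from_delta_v(0, curve)), c(1, 0, 0, 0))
  # linearity: a two-point mixture averages the pointwise splits
  mix <- severity_from_delta_v(c(2, 10), curve)
  avg <- (severity_from_delta_v(2, curve) + severity_from_delta_v(10, curve)) / 2
  expect_equal(mix, avg, tolerance = 1e-12)
  # the default curve reproduces the AV severity split within 10% per category
  split <- severity_from_delta_v()
  target <- crash_profile("AV")$severity_split
  expect_true(all(abs(split / target - 1) < 0.10))
  # a pointwise-dominating curve yields a stochastically worse split
  worse_curve <- function(v) {
    p <- curve(v)
    p[, c("p_K", "p_A", "p_B")] <- pmin(p[, c("p_K", "p_A", "p_B")] * 2, 1 / 3)
    p[, "p_C"] <- 1 - rowSums(p[, c("p_K", "p_A", "p_B"), drop = FALSE])
    p
  }
  worse <- severity_from_delta_v(risk_curve = worse_curve)
  # survival-function dominance over the PDO < MINOR < SEVERE < FATAL order
  for (k in 2:4) {
    expect_gte(sum(worse[k:4]), sum(split[k:4]))
  }
  bad_curve <- function(v) cbind(p_K = rep(0.6, length(v)),
                                 p_A = rep(0.6, length(v)),
                                 p_B = 0, p_C = 0)
  expect_error(severity_from_delta_v(3, bad_curve), "probabilities")
})

test_that("risk curves round-trip through CSV with interpolation", {
  grid <- seq(0, 50, by = 0.5)
  p <- default_risk_curve()(grid)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(delta_v = grid, p), path, row.names = FALSE)
  curve2 <- read_risk_curve(path)
  expect_equal(curve2(c(1.25, 3.91, 17.3)),
               default_risk_curve()(c(1.25, 3.91, 17.3)), tolerance = 1e-4)
  expect_error(read_risk_curve(
    { f <- withr::local_tempfile(fileext = ".csv")
      write.csv(data.frame(x = 1), f, row.names = FALSE); f }),
    "columns")
})

test_that("the fleet record constants are internally coherent", {
  rec <- waymo_fleet_record()
  expect_equal(rec$observed_crashes, 14L)
  expect_equal(rec$miles, 2102047L)
  # per-mile crash rate annualized at the model's VMT brackets the
  # published annual AV crash probability
  annual <- per_mile_to_annual(rec$observed_crashes / rec$miles, 14133)
  expect_gt(annual, 0.06729)
  expect_lt(annual, 0.09319)
})
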