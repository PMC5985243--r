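# Shared builders for deterministic test scenarios.

# Cohort with every driver starting at the same age.
fixed_age_cohort <- function(age = 47) {
  cohort <- default_cohort()
  cohort$age_distribution <- build_age_distribution(stats::setNames(1, age))
  cohort
}

# Mortality table with certain death every year.
certain_death_table <- function() {
  build_mortality_table(data.frame(age = 0:110, q = 1))
}

# Parameter set with all crash probabilities zeroed.
no_crash_params <- function(params = default_parameters()) {
  params <- set_param(params, "hpv_crash_prob", 0)
  set_param(params, "av_crash_prob", 0)
}

# Parameter set whose crashes are always fatal (HPV profile).
always_fatal_params <- function(params = default_parameters()) {
  params <- set_param(params, "hpv_crash_prob", 1)
  params <- set_param(params, "hpv_split_pdo", 0)
  params <- set_param(params, "hpv_split_minor", 0)
  params <- set_param(params, "hpv_split_severe", 0)
  set_param(params, "hpv_split_fatal", 1)
}

# Independent lifetable arithmetic (start-of-year accrual), kept separate
# from the package's life_expectancy() so oracle checks do not share code
# with the path under test.
oracle_life_expectancy <- function(q_by_age, start_age, discount = 0) {
  total <- 0; surv <- 1
  for (t in 0:(length(q_by_age) - start_age - 1)) {
    total <- total + surv / (1 + discount)^t
    surv <- surv * (1 - q_by_age[start_age + t + 1])
  }
  total
}
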