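test_that("certain transplant access means every first wait is one year", {
  p <- base_params()
  p <- set_param(p, "p_dialysis_to_kt_ddkt", 1)
  coh <- generate_cohort(p, n_per_strategy = c("NP-DDKT" = 50),
                         horizon = 5, seed = 1,
                         mortality = zero_mortality())
  kt <- coh[coh$event_kt, ]
  first_wait <- tapply(kt$year, kt$id, min)
  expect_length(first_wait, 50)
  expect_true(all(first_wait == 1))
})

test_that("without mortality or graft failure all patients end transplanted", {
  p <- base_params()
  p <- set_param(p, "p_graft_loss_year1", 0)
  p <- set_param(p, "p_graft_loss_subsequent", 0)
  p <- set_param(p, "p_dialysis_to_kt_lrkt", 1)
  coh <- generate_cohort(p, n_per_strategy = c("P-LRKT" = 30,
                                               "NP-LRKT" = 30),
                         horizon = 8, seed = 2,
                         mortality = zero_mortality())
  last <- coh[coh$year == 8, ]
  expect_equal(nrow(last), 60)
  expect_true(all(last$state == "subsequent"))
  expect_false(any(coh$event_death))
})

test_that("waiting times are geometric with the configured annual access", {
  p <- base_params()
  n <- 2000
  coh <- generate_cohort(p, n_per_strategy = c("NP-DDKT" = n),
                         horizon = 60, seed = 3,
                         mortality = zero_mortality(),
                         age_range = c(30, 30))
  kt <- coh[coh$event_kt, ]
  waits <- tapply(kt$year, kt$id, min)  # first transplant per patient
  # geometric mean 1/0.18 = 5.56; censoring at the age-65 access limit
  # (35 years) is negligible
  se <- sqrt(1 - 0.18) / 0.18 / sqrt(length(waits))
  expect_gt(length(waits), 0.99 * n)
  expect_lt(abs(mean(waits) - 1 / 0.18), 3 * se)
})

test_that("probability estimates use person-year risk sets with binomial SE", {
  # hand-built cohort: 100 transplant-years, 4 graft losses
  coh <- data.frame(
    id = 1:100, strategy = "NP-LRKT", entry_age = 50, year = 1, age = 50,
    state = "kt", event_kt = FALSE,
    event_graft_loss = c(rep(TRUE, 4), rep(FALSE, 96)),
    event_death = FALSE, cost = 15000)
  class(coh) <- c("kt_cohort", "data.frame")
  est <- estimate_inputs(coh)
  r <- est$probabilities[est$probabilities$name == "p_graft_loss_year1", ]
  expect_equal(r$estimate, 0.04)
  expect_equal(unname(r$se), sqrt(0.04 * 0.96 / 100), tolerance = 1e-12)
  expect_equal(unname(r$se), 0.0196, tolerance = 1e-3)
  # no person-years at risk: flagged missing, not zero
  d <- est$probabilities[est$probabilities$name == "p_dialysis_to_kt_ddkt", ]
  expect_true(is.na(d$estimate))
  # single observed state-year: undefined cost SE
  coh1 <- coh[1, ]
  class(coh1) <- c("kt_cohort", "data.frame")
  est1 <- estimate_inputs(coh1)
  expect_true(is.na(est1$costs$se[1]))
  expect_equal(est1$costs$mean[1], 15000)
})

test_that("estimates recover the generating values at moderate n", {
  p <- base_params()
  coh <- generate_cohort(p, n_per_strategy = c("P-LRKT" = 1500,
                                               "NP-LRKT" = 1500,
                                               "NP-DDKT" = 1500),
                         horizon = 10, seed = 11)
  est <- estimate_inputs(coh, kt_stop_age = p$kt_stop_age)
  pr <- est$probabilities
  truth <- c(p_dialysis_to_kt_lrkt = 0.36, p_dialysis_to_kt_ddkt = 0.18,
             p_graft_loss_year1 = 0.04, p_graft_loss_subsequent = 0.01)
  for (nm in names(truth)) {
    r <- pr[pr$name == nm, ]
    expect_lt(abs(r$estimate - truth[[nm]]), 3.5 * r$se)
  }
  # estimated SEs shrink roughly as 1/sqrt(n)
  coh2 <- generate_cohort(p, n_per_strategy = c("P-LRKT" = 300,
                                                "NP-LRKT" = 300,
                                                "NP-DDKT" = 300),
                          horizon = 10, seed = 12)
  est2 <- estimate_inputs(coh2, kt_stop_age = p$kt_stop_age)
  expect_true(all(est2$probabilities$se > pr$se, na.rm = TRUE))
})

test_that("cohorts round-trip through delimited text", {
  coh <- generate_cohort(base_params(), seed = 4)
  f <- tempfile(fileext = ".csv")
  write_cohort(coh, f)
  coh2 <- read_cohort(f)
  expect_equal(as.data.frame(coh2), as.data.frame(coh), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("overlaying estimates onto a parameter set keeps it valid", {
  p <- base_params()
  coh <- generate_cohort(p, n_per_strategy = c("P-LRKT" = 400,
                                               "NP-LRKT" = 400,
                                               "NP-DDKT" = 400),
                         horizon = 10, seed = 21)
  est <- estimate_inputs(coh, kt_stop_age = p$kt_stop_age)
  p2 <- apply_estimates(p, est)
  expect_s3_class(p2, "kt_params")
  # informed parameters moved to their estimates
  r <- est$probabilities[est$probabilities$name == "p_graft_loss_year1", ]
  expect_equal(param_value(p2, "p_graft_loss_year1"), r$estimate)
  # untouched parameters (utilities, mortality) unchanged
  expect_equal(param_value(p2, "utility_kt"), param_value(p, "utility_kt"))
  expect_equal(param_value(p2, "smr_50_59"), param_value(p, "smr_50_59"))
  # the model still runs with the re-estimated inputs
  cua <- run_base_case(p2)
  expect_equal(nrow(cua$outcomes), 3)
})
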