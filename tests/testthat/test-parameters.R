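test_that("packaged default configuration reproduces the base-case inputs", {
  p <- load_parameters()
  expect_s3_class(p, "kt_params")
  expect_equal(param_value(p, "utility_dialysis"), 0.68)
  expect_equal(param_value(p, "p_dialysis_to_kt_lrkt"), 0.36)
  expect_equal(param_value(p, "p_dialysis_to_kt_ddkt"), 0.18)
  expect_equal(param_value(p, "p_graft_loss_year1"), 0.04)
  expect_equal(param_value(p, "cost_dialysis"), 13734)
  expect_equal(param_value(p, "smr_80plus"), 7.8)
  expect_equal(p$discount_rate, 0.03)
  expect_equal(p$wtp, 5113)
  expect_equal(p$start_age, 50L)
  expect_equal(p$kt_stop_age, 65L)
  expect_identical(p$specs[["utility_kt"]]$family, "beta")
  expect_identical(p$specs[["cost_kt_plrkt"]]$family, "gamma")
})

test_that("parameter validation rejects invalid values and missing names", {
  expect_error(kt_parameter("u", value = 1.2, family = "beta"),
               "\\[0, 1\\]")
  expect_error(kt_parameter("c", value = -5, family = "gamma"),
               "non-negative")
  expect_error(kt_parameter("x", value = 2, low = 3, high = 5,
                            family = "fixed", role = "cost"),
               "low <= value <= high")
  p <- load_parameters()
  p$specs[["utility_kt"]] <- NULL
  expect_error(validate_parameters(p), "utility_kt")
  p2 <- load_parameters()
  p2$discount_rate <- 0.2
  expect_error(validate_parameters(p2), "discount_rate")
})

test_that("beta-incompatible SE is shrunk with a warning", {
  expect_warning(
    sp <- kt_parameter("u", value = 0.95, se = 0.4, family = "beta",
                       role = "utility"),
    "shrunk")
  expect_lt(sp$se^2, 0.95 * 0.05)
})

test_that("dsa_bounds follows the CI / fallback / clamping rules", {
  b <- dsa_bounds(kt_parameter("p", 0.36, se = 0.084, family = "beta"))
  expect_equal(unname(b), c(0.19536, 0.52464))
  b <- dsa_bounds(kt_parameter("c", 100, family = "gamma", role = "cost"))
  expect_equal(unname(b), c(85, 115))
  b <- dsa_bounds(kt_parameter("p", 0.04, se = 0.004, family = "beta"))
  expect_equal(unname(b), c(0.03216, 0.04784))
  # utility CI crossing 1 is clamped
  b <- dsa_bounds(kt_parameter("u", 0.889, se = 0.133, family = "beta",
                               role = "utility"))
  expect_equal(unname(b[2]), 1)
  # explicit bounds win over the SE
  b <- dsa_bounds(kt_parameter("r", 0.03, se = 0.5, low = 0, high = 0.06,
                               family = "fixed", role = "rate-config"))
  expect_equal(unname(b), c(0, 0.06))
  # invariant: low <= value <= high for every packaged parameter
  for (sp in load_parameters()$specs) {
    b <- dsa_bounds(sp)
    expect_true(b[["low"]] <= sp$value && sp$value <= b[["high"]],
                info = sp$name)
  }
})

test_that("moment-matched beta and gamma fits recover mean and SD", {
  ab <- fit_beta_moments(0.36, 0.084)
  expect_equal(unname(ab), c(11.3951020, 20.2579592), tolerance = 1e-6)
  ab <- fit_beta_moments(0.68, 0.1)
  expect_equal(unname(ab), c(14.1168, 6.6432), tolerance = 1e-6)
  gs <- fit_gamma_moments(13734, 2060)
  expect_equal(unname(gs), c((13734 / 2060)^2, 2060^2 / 13734),
               tolerance = 1e-9)
  gs <- fit_gamma_moments(7816, 507)
  expect_equal(unname(gs[1]), 237.6566, tolerance = 1e-4)
  expect_equal(unname(gs[2]), 32.888, tolerance = 1e-3)
  expect_equal(unname(fit_gamma_moments(10, 10)), c(1, 10))
  expect_error(fit_beta_moments(0.5, 0.6, name = "u"), "u")
  expect_error(fit_gamma_moments(-1, 2), "positive")

  # analytic round trip to 1e-12 over a parameter sweep
  for (m in c(0.04, 0.36, 0.68, 0.889)) {
    for (se in c(0.004, 0.05, 0.1)) {
      ab <- fit_beta_moments(m, se)
      a <- ab[["alpha"]]; b <- ab[["beta"]]
      expect_equal(a / (a + b), m, tolerance = 1e-12)
      expect_equal(sqrt(a * b / ((a + b)^2 * (a + b + 1))), se,
                   tolerance = 1e-12)
    }
  }
  for (m in c(481, 7816, 13734)) {
    for (se in c(50, 507, 2060)) {
      gs <- fit_gamma_moments(m, se)
      expect_equal(gs[["shape"]] * gs[["scale"]], m, tolerance = 1e-12)
      expect_equal(sqrt(gs[["shape"]]) * gs[["scale"]], se,
                   tolerance = 1e-12)
    }
  }
})

test_that("parameter sets round-trip through YAML serialization", {
  p <- load_parameters()
  f <- tempfile(fileext = ".yaml")
  write_parameters(p, f)
  p2 <- load_parameters(f)
  expect_equal(p2$discount_rate, p$discount_rate)
  expect_equal(p2$wtp, p$wtp)
  expect_identical(names(p2$specs), names(p$specs))
  for (nm in names(p$specs))
    expect_equal(p2$specs[[nm]], p$specs[[nm]], info = nm)
})

test_that("PSA draws respect distribution support and fixed families", {
  p <- load_parameters()
  set.seed(99)
  d <- ktcua:::draw_parameters(p)
  for (nm in names(p$specs)) {
    s <- p$specs[[nm]]
    v <- d$specs[[nm]]$value
    if (s$family == "fixed") expect_identical(v, s$value)
    if (s$family == "beta") expect_true(v >= 0 && v <= 1)
    if (s$family == "gamma") expect_gt(v, 0)
  }
  # law of large numbers: sample means sit within 3 SE of the input mean
  set.seed(100)
  n <- 4000
  draws <- replicate(n, {
    d <- ktcua:::draw_parameters(p)
    c(d$specs[["p_dialysis_to_kt_lrkt"]]$value,
      d$specs[["cost_dialysis"]]$value,
      d$specs[["utility_dialysis"]]$value)
  })
  means <- rowMeans(draws)
  truth <- c(0.36, 13734, 0.68)
  ses <- c(0.084, 2060, 0.1) / sqrt(n)
  expect_true(all(abs(means - truth) < 3 * ses))
})
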