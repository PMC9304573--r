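test_that("transition matrices carry the printed structural probabilities", {
  p <- base_params()
  zm <- zero_mortality()
  st <- default_strategies(p)
  m <- build_transition_matrix(p, zm, st[["NP-DDKT"]], age = 55)
  expect_equal(unname(m["dialysis", ]), c(0.82, 0.18, 0, 0, 0))
  expect_equal(unname(m["kt", ]), c(0.04, 0, 0.96, 0, 0))
  expect_equal(unname(m["post1", ]), c(0.01, 0, 0, 0.99, 0))
  expect_equal(unname(m["subsequent", ]), c(0.01, 0, 0, 0.99, 0))
  expect_equal(unname(m["death", ]), c(0, 0, 0, 0, 1))
  # transplant access shuts off above the stop age
  m66 <- build_transition_matrix(p, zm, st[["NP-DDKT"]], age = 66)
  expect_equal(m66["dialysis", "kt"], 0)
  expect_equal(m66["dialysis", "dialysis"], 1)
})

test_that("death is applied first and every row sums to one at all ages", {
  p <- base_params()
  mort <- default_mortality(p)
  st <- default_strategies(p)
  for (s in st) {
    for (age in c(50, 59, 60, 69, 70, 79, 80, 95, 100)) {
      m <- build_transition_matrix(p, mort, s, age)
      expect_equal(unname(rowSums(m)), rep(1, 5), tolerance = 1e-12)
      expect_true(all(m >= 0 & m <= 1))
      qd <- death_prob(mort, age, "dialysis")
      qk <- death_prob(mort, age, "kt")
      expect_equal(m["dialysis", "death"], qd)
      expect_equal(m["kt", "death"], qk)
      # non-death exits are conditioned on surviving the cycle
      if (age <= p$kt_stop_age)
        expect_equal(m["dialysis", "kt"],
                     s$p_dialysis_to_kt * (1 - qd), tolerance = 1e-12)
      expect_equal(m["kt", "dialysis"], 0.04 * (1 - qk), tolerance = 1e-12)
    }
  }
})

test_that("discount factors follow (1+r)^-t", {
  expect_equal(discount_factor(0.03, 0), 1)
  expect_equal(discount_factor(0.03, 2), 1 / 1.03^2)
  expect_equal(discount_factor(0.03, 2), 0.942596, tolerance = 1e-6)
  expect_equal(discount_factor(0, 0:10), rep(1, 11))
})

test_that("a deterministic two-cycle toy cohort hand-computes exactly", {
  # no deaths in the first two years, certain death afterwards,
  # dialysis-only strategy at 100 USD/yr, utility 0.5, no discounting
  p <- base_params()
  p$discount_rate <- 0
  p <- set_param(p, "utility_dialysis", 0.5)
  lt <- flat_life_table(0, ages = 30:110)
  lt$q[lt$age >= 51] <- 1 - 1e-12
  mort <- identity_mortality(lt)
  s <- strategy_spec("toy", entry_state = "dialysis",
                     p_dialysis_to_kt = 0, cost_kt_event = 0,
                     cost_post1 = 0, cost_subsequent = 0,
                     cost_dialysis_annual = 100)
  tr <- run_cohort(p, mort, s)
  expect_equal(tr$totals[["cost"]], 200)
  expect_equal(tr$totals[["ly"]], 2)
  expect_equal(tr$totals[["qaly"]], 1)
})

test_that("QALYs equal life-years exactly when all utilities are one", {
  p <- base_params()
  for (u in c("utility_dialysis", "utility_kt", "utility_post1",
              "utility_subsequent"))
    p <- set_param(p, u, 1)
  mort <- default_mortality(p)
  for (s in default_strategies(p)) {
    tr <- run_cohort(p, mort, s)
    expect_equal(tr$totals[["qaly"]], tr$totals[["ly"]], tolerance = 1e-12)
  }
})

test_that("occupancy mass is conserved every cycle", {
  p <- base_params()
  mort <- default_mortality(p)
  for (s in default_strategies(p)) {
    tr <- run_cohort(p, mort, s)
    occ <- rowSums(tr$trace[, c("dialysis", "kt", "post1", "subsequent",
                                "death")])
    expect_true(all(abs(occ - 1) < 1e-9))
    expect_true(all(tr$trace[, c("dialysis", "kt", "post1",
                                 "subsequent", "death")] >= 0))
  }
})

test_that("discounted totals are non-increasing in the discount rate", {
  p <- base_params()
  mort <- default_mortality(p)
  s <- default_strategies(p)[["P-LRKT"]]
  rates <- seq(0, 0.06, by = 0.01)
  tot <- sapply(rates, function(r)
    run_cohort(p, mort, s, discount_rate = r)$totals)
  for (i in 1:3) expect_true(all(diff(tot[i, ]) < 0))
})

test_that("without graft loss the preemptive cohort never touches dialysis", {
  p <- base_params()
  p <- set_param(p, "p_graft_loss_year1", 0)
  p <- set_param(p, "p_graft_loss_subsequent", 0)
  tr <- run_cohort(p, default_mortality(p),
                   default_strategies(p)[["P-LRKT"]])
  expect_true(all(tr$trace$dialysis == 0))
})

test_that("disallowing retransplantation reduces transplant entries", {
  p <- base_params()
  mort <- default_mortality(p)
  tr_on <- run_cohort(p, mort,
                      default_strategies(p)[["NP-DDKT"]])
  tr_off <- run_cohort(p, mort,
                       default_strategies(p,
                                          allow_retransplant = FALSE)[["NP-DDKT"]])
  expect_lt(sum(tr_off$trace$entrants_kt), sum(tr_on$trace$entrants_kt))
})

test_that("cost attachments differ by exactly one subsequent-year cost", {
  # entry attachment charges the first-year cost in the transplant year
  # and already applies the subsequent-year cost to the 1-yr-post state;
  # state attachment charges the first-year cost there instead, so under
  # full survival and no discounting the totals differ by exactly one
  # subsequent-year cost
  p <- base_params()
  p$discount_rate <- 0
  p <- set_param(p, "p_graft_loss_year1", 0)
  p <- set_param(p, "p_graft_loss_subsequent", 0)
  lt <- flat_life_table(0, ages = 30:110)
  lt$q[lt$age >= 70] <- 1 - 1e-12
  mort <- identity_mortality(lt)
  tr_entry <- run_cohort(p, mort,
                         default_strategies(p)[["P-LRKT"]])
  tr_state <- run_cohort(p, mort,
                         default_strategies(p,
                                            cost_attachment = "state")[["P-LRKT"]])
  expect_equal(tr_entry$totals[["cost"]] - tr_state$totals[["cost"]],
               param_value(p, "cost_subsequent_plrkt"), tolerance = 1e-9)
})

test_that("a cohort still alive at the horizon triggers a truncation warning", {
  p <- base_params()
  mort <- identity_mortality(flat_life_table(0.001))
  expect_warning(run_cohort(p, mort, default_strategies(p)[["P-LRKT"]]),
                 "truncated")
})

test_that("cost per life-year divides discounted cost by discounted LY", {
  expect_equal(cost_per_ly(0, 10), 0)
  expect_error(cost_per_ly(100, 0), "positive")
  p <- base_params()
  tr <- run_cohort(p, default_mortality(p),
                   default_strategies(p)[["P-LRKT"]])
  expect_equal(cost_per_ly(tr),
               tr$totals[["cost"]] / tr$totals[["ly"]])
})
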