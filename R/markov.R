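# Canonical health states of the cohort model. Internally the engine runs a
# sixth copy of the dialysis state ("dialysis_nr") for cohort members whose
# graft failed when retransplantation is disallowed; it shares the dialysis
# state's cost, utility and mortality but has no transplant access.
.states5 <- c("dialysis", "kt", "post1", "subsequent", "death")
.states6 <- c("dialysis", "kt", "post1", "subsequent", "dialysis_nr", "death")

#' Define a treatment strategy
#'
#' A strategy fixes the model entry state, the annual probability of moving
#' from dialysis to transplantation, and the strategy's cost schedule.
#'
#' @param name Strategy label, e.g. `"P-LRKT"`.
#' @param entry_state `"kt"` (preemptive: the cohort enters the model at
#'   transplantation) or `"dialysis"` (non-preemptive).
#' @param p_dialysis_to_kt Per-cycle probability of receiving a transplant
#'   while on dialysis and not older than the KT stop age (0 for the
#'   preemptive strategy after entry).
#' @param cost_kt_event One-off transplantation cost charged per entry into
#'   the KT state (USD/visit).
#' @param cost_post1 Annual cost of the first post-transplant year (USD/yr).
#' @param cost_subsequent Annual cost of subsequent post-transplant years
#'   (USD/yr).
#' @param cost_dialysis_annual Annual cost of a dialysis year, including
#'   direct non-medical costs (USD/yr).
#' @param cost_waiting One-off pre-transplant evaluation/waiting cost
#'   charged at model entry (USD; 0 when not applicable).
#' @param allow_retransplant Whether graft failures regain transplant
#'   access at `p_dialysis_to_kt` while within the KT age window.
#' @param cost_attachment `"entry"` (default): the transplant-event cost is
#'   charged on entry to the KT state and the first-year cost is attached
#'   to the KT-state year, so the transplant year carries the high
#'   first-year cost; subsequent-year cost applies to both post-KT states.
#'   `"state"`: the first-year cost is attached to the 1-year-post state
#'   instead and the KT-state year carries only the event cost.
#' @return An object of class `kt_strategy`.
#' @export
strategy_spec <- function(name, entry_state = c("dialysis", "kt"),
                          p_dialysis_to_kt,
                          cost_kt_event, cost_post1, cost_subsequent,
                          cost_dialysis_annual, cost_waiting = 0,
                          allow_retransplant = TRUE,
                          cost_attachment = c("entry", "state")) {
  entry_state <- match.arg(entry_state)
  cost_attachment <- match.arg(cost_attachment)
  costs <- c(cost_kt_event, cost_post1, cost_subsequent,
             cost_dialysis_annual, cost_waiting)
  if (any(!is.finite(costs) | costs < 0))
    stop("strategy '", name, "': all costs must be finite and >= 0",
         call. = FALSE)
  if (!(p_dialysis_to_kt >= 0 && p_dialysis_to_kt <= 1))
    stop("strategy '", name, "': p_dialysis_to_kt must lie in [0, 1]",
         call. = FALSE)
  structure(list(name = name, entry_state = entry_state,
                 p_dialysis_to_kt = p_dialysis_to_kt,
                 cost_kt_event = cost_kt_event, cost_post1 = cost_post1,
                 cost_subsequent = cost_subsequent,
                 cost_dialysis_annual = cost_dialysis_annual,
                 cost_waiting = cost_waiting,
                 allow_retransplant = isTRUE(allow_retransplant),
                 cost_attachment = cost_attachment),
            class = "kt_strategy")
}

#' @export
print.kt_strategy <- function(x, ...) {
  cat(sprintf(
    "<kt_strategy> %s: enters at %s, p(dialysis->KT) = %.3g/yr\n",
    x$name, x$entry_state, x$p_dialysis_to_kt))
  cat(sprintf(
    "  costs (USD): KT event %s, first yr %s, subsequent %s/yr, dialysis %s/yr, waiting %s\n",
    format(x$cost_kt_event), format(x$cost_post1),
    format(x$cost_subsequent), format(x$cost_dialysis_annual),
    format(x$cost_waiting)))
  invisible(x)
}

#' The three modelled kidney-transplantation strategies
#'
#' Builds the preemptive LRKT, non-preemptive LRKT and non-preemptive DDKT
#' strategies from a parameter set. The preemptive cohort enters at the KT
#' state (transplant-to-KT access probability 0 afterwards) and carries the
#' one-off waiting/evaluation cost; the non-preemptive cohorts enter at
#' dialysis with annual transplant access 0.36 (living-related) or 0.18
#' (deceased-donor).
#'
#' @param params A `kt_params` object.
#' @param allow_retransplant Passed to [strategy_spec()] for the
#'   non-preemptive strategies.
#' @param cost_attachment Passed to [strategy_spec()].
#' @param dialysis_costing `"cohort"` (default): dialysis year costed at
#'   the cohort-derived total plus direct non-medical cost. `"literature"`:
#'   literature dialysis cost plus monthly complication cost plus direct
#'   non-medical cost.
#' @return Named list of three `kt_strategy` objects.
#' @export
default_strategies <- function(params, allow_retransplant = TRUE,
                               cost_attachment = c("entry", "state"),
                               dialysis_costing = c("cohort", "literature")) {
  cost_attachment <- match.arg(cost_attachment)
  dialysis_costing <- match.arg(dialysis_costing)
  pv <- function(n) param_value(params, n)
  dial <- if (dialysis_costing == "cohort") {
    pv("cost_dialysis") + pv("cost_nonmedical")
  } else {
    pv("cost_dialysis_literature") +
      12 * pv("cost_dialysis_complication") + pv("cost_nonmedical")
  }
  list(
    "P-LRKT" = strategy_spec(
      "P-LRKT", entry_state = "kt", p_dialysis_to_kt = 0,
      cost_kt_event = pv("cost_kt_plrkt"),
      cost_post1 = pv("cost_post1_plrkt"),
      cost_subsequent = pv("cost_subsequent_plrkt"),
      cost_dialysis_annual = dial,
      cost_waiting = pv("cost_waiting_plrkt"),
      allow_retransplant = allow_retransplant,
      cost_attachment = cost_attachment),
    "NP-LRKT" = strategy_spec(
      "NP-LRKT", entry_state = "dialysis",
      p_dialysis_to_kt = pv("p_dialysis_to_kt_lrkt"),
      cost_kt_event = pv("cost_kt_nplrkt"),
      cost_post1 = pv("cost_post1_nplrkt"),
      cost_subsequent = pv("cost_subsequent_nplrkt"),
      cost_dialysis_annual = dial,
      allow_retransplant = allow_retransplant,
      cost_attachment = cost_attachment),
    "NP-DDKT" = strategy_spec(
      "NP-DDKT", entry_state = "dialysis",
      p_dialysis_to_kt = pv("p_dialysis_to_kt_ddkt"),
      cost_kt_event = pv("cost_kt_npddkt"),
      cost_post1 = pv("cost_post1_npddkt"),
      cost_subsequent = pv("cost_subsequent_npddkt"),
      cost_dialysis_annual = dial,
      allow_retransplant = allow_retransplant,
      cost_attachment = cost_attachment)
  )
}

#' Discount factor for a model cycle
#'
#' `(1 + rate)^(-cycle)` with cycle 0 at model entry.
#'
#' @param rate Annual discount rate (>= 0).
#' @param cycle Cycle index (>= 0).
#' @return Discount factor in (0, 1\].
#' @export
discount_factor <- function(rate, cycle) {
  stopifnot(all(rate >= 0), all(cycle >= 0))
  (1 + rate)^(-cycle)
}

# 6-state transition row block builder. Death is applied first within a
# cycle; the conditional probabilities of the non-death moves are scaled by
# (1 - p_death), which keeps every row summing to exactly 1.
tmat6 <- function(params, mortality, strategy, age,
                  dp = NULL) {
  p_fail1 <- param_value(params, "p_graft_loss_year1")
  p_fail <- param_value(params, "p_graft_loss_subsequent")
  if (is.null(dp)) {
    qd <- death_prob(mortality, age, "dialysis")
    qk <- death_prob(mortality, age, "kt")
  } else {
    qd <- dp[["dialysis"]]; qk <- dp[["kt"]]
  }
  p_kt <- if (age <= params$kt_stop_age) strategy$p_dialysis_to_kt else 0
  fail_dest <- if (strategy$allow_retransplant) "dialysis" else "dialysis_nr"
  m <- matrix(0, 6, 6, dimnames = list(.states6, .states6))
  # dialysis (with transplant access)
  m["dialysis", "death"] <- qd
  m["dialysis", "kt"] <- p_kt * (1 - qd)
  m["dialysis", "dialysis"] <- 1 - qd - m["dialysis", "kt"]
  # transplant year
  m["kt", "death"] <- qk
  m["kt", fail_dest] <- p_fail1 * (1 - qk)
  m["kt", "post1"] <- 1 - qk - m["kt", fail_dest]
  # first post-transplant year
  m["post1", "death"] <- qk
  m["post1", fail_dest] <- p_fail * (1 - qk)
  m["post1", "subsequent"] <- 1 - qk - m["post1", fail_dest]
  # subsequent post-transplant years
  m["subsequent", "death"] <- qk
  m["subsequent", fail_dest] <- p_fail * (1 - qk)
  m["subsequent", "subsequent"] <- 1 - qk - m["subsequent", fail_dest]
  # dialysis after graft failure without retransplant access
  m["dialysis_nr", "death"] <- qd
  m["dialysis_nr", "dialysis_nr"] <- 1 - qd
  m["death", "death"] <- 1
  if (any(m < -1e-12 | m > 1 + 1e-12))
    stop("transition probability outside [0, 1] at age ", age,
         call. = FALSE)
  m
}

#' Age-specific transition matrix of the five-state model
#'
#' Rows and columns are ordered dialysis, KT, 1-year post-KT,
#' subsequent-years post-KT, death. Death is applied first within the
#' cycle and all other exits are scaled by the survival probability, so
#' every row sums to exactly 1. Transplant access from dialysis is shut
#' off above the KT stop age.
#'
#' @param params A `kt_params` object.
#' @param mortality A `kt_mortality` object.
#' @param strategy A `kt_strategy` object.
#' @param age Cohort age (years) at the start of the cycle.
#' @return 5 x 5 numeric matrix with row sums 1.
#' @export
build_transition_matrix <- function(params, mortality, strategy, age) {
  m6 <- tmat6(params, mortality, strategy, age)
  # collapse the no-access dialysis copy (exact when no mass flows there)
  m <- m6[.states5, .states5]
  m[, "dialysis"] <- m6[.states5, "dialysis"] + m6[.states5, "dialysis_nr"]
  stopifnot(all(abs(rowSums(m) - 1) < 1e-12))
  m
}

#' Run the Markov cohort model for one strategy
#'
#' Propagates a closed cohort from the strategy's entry state at
#' `start_age` through annual cycles to the lifetime horizon, accruing
#' discounted costs, life-years and QALYs. Occupancy is measured at cycle
#' start and accrues full-cycle costs and outcomes (no half-cycle
#' correction). The one-off transplant cost is charged on each entry into
#' the KT state (including the initial entry of the preemptive cohort) and
#' the waiting cost once at model entry. The run stops when living
#' occupancy falls below `1e-9` or the horizon `max_age` is reached; a
#' truncation with material living mass (> 1e-6) raises a warning.
#'
#' @param params A `kt_params` object.
#' @param mortality A `kt_mortality` object (default built from `params`).
#' @param strategy A `kt_strategy` object.
#' @param discount_rate Override of the parameter set's discount rate.
#' @return An object of class `kt_trace` with elements `trace` (per-cycle
#'   data frame), `totals` (discounted cost/LY/QALY), `undiscounted`, and
#'   run metadata.
#' @examples
#' p <- load_parameters()
#' tr <- run_cohort(p, strategy = default_strategies(p)[["P-LRKT"]])
#' tr$totals
#' @export
run_cohort <- function(params, mortality = default_mortality(params),
                       strategy, discount_rate = params$discount_rate) {
  stopifnot(inherits(params, "kt_params"), inherits(strategy, "kt_strategy"))
  ages <- params$start_age:params$max_age
  dps <- death_prob_schedule(mortality, ages)
  util <- c(param_value(params, "utility_dialysis"),
            param_value(params, "utility_kt"),
            param_value(params, "utility_post1"),
            param_value(params, "utility_subsequent"),
            param_value(params, "utility_dialysis"), 0)
  state_cost <- if (strategy$cost_attachment == "entry") {
    c(strategy$cost_dialysis_annual, strategy$cost_post1,
      strategy$cost_subsequent, strategy$cost_subsequent,
      strategy$cost_dialysis_annual, 0)
  } else {
    c(strategy$cost_dialysis_annual, 0, strategy$cost_post1,
      strategy$cost_subsequent, strategy$cost_dialysis_annual, 0)
  }
  occ <- setNames(numeric(6), .states6)
  occ[strategy$entry_state] <- 1
  entrants <- unname(occ["kt"])
  n <- length(ages)
  rec <- matrix(NA_real_, n, 12,
                dimnames = list(NULL, c("cycle", "age", .states6,
                                        "entrants_kt", "cost", "ly",
                                        "qaly")))
  disc <- discount_factor(discount_rate, seq_len(n) - 1L)
  tot <- c(cost = 0, ly = 0, qaly = 0)
  raw <- c(cost = 0, ly = 0, qaly = 0)
  t_used <- 0L
  truncated <- FALSE
  for (t in seq_len(n)) {
    age <- ages[t]
    if (abs(sum(occ) - 1) > 1e-9)
      stop("occupancy mass not conserved at cycle ", t - 1L, call. = FALSE)
    living <- sum(occ) - occ["death"]
    if (living < 1e-9) break
    cost_t <- sum(occ * state_cost) + strategy$cost_kt_event * entrants +
      if (t == 1L) strategy$cost_waiting else 0
    ly_t <- living
    qaly_t <- sum(occ * util)
    rec[t, ] <- c(t - 1L, age, occ, entrants, cost_t, ly_t, qaly_t)
    tot <- tot + disc[t] * c(cost_t, ly_t, qaly_t)
    raw <- raw + c(cost_t, ly_t, qaly_t)
    t_used <- t
    if (age == params$max_age) {
      if (living > 1e-6) {
        truncated <- TRUE
        warning(sprintf(
          "cohort truncated at max_age %d with living occupancy %.3g",
          params$max_age, living), call. = FALSE)
      }
      break
    }
    m <- tmat6(params, mortality, strategy, age, dp = dps[t, ])
    entrants <- unname(occ["dialysis"] * m["dialysis", "kt"])
    occ <- setNames(as.numeric(occ %*% m), .states6)
  }
  trace <- as.data.frame(rec[seq_len(t_used), , drop = FALSE])
  trace$discount <- disc[seq_len(t_used)]
  trace$dialysis <- trace$dialysis + trace$dialysis_nr
  trace$dialysis_nr <- NULL
  structure(list(strategy = strategy$name, trace = trace,
                 totals = tot, undiscounted = raw,
                 discount_rate = discount_rate,
                 start_age = params$start_age, truncated = truncated),
            class = "kt_trace")
}

#' @export
print.kt_trace <- function(x, ...) {
  cat(sprintf("<kt_trace> %s: %d cycles from age %d (discount %.3g)\n",
              x$strategy, nrow(x$trace), x$start_age, x$discount_rate))
  cat(sprintf("  discounted totals: cost %s USD, %s LY, %s QALY\n",
              format(round(x$totals[["cost"]], 2), big.mark = ","),
              round(x$totals[["ly"]], 2), round(x$totals[["qaly"]], 2)))
  invisible(x)
}

#' @export
summary.kt_trace <- function(object, ...) {
  tr <- object$trace
  out <- list(
    strategy = object$strategy,
    cycles = nrow(tr),
    totals = object$totals,
    undiscounted = object$undiscounted,
    cost_per_ly = cost_per_ly(object),
    years_on_dialysis = sum(tr$dialysis),
    years_transplanted = sum(tr$kt + tr$post1 + tr$subsequent),
    transplanted_ever = sum(tr$entrants_kt)
  )
  class(out) <- "summary.kt_trace"
  out
}

#' @export
print.summary.kt_trace <- function(x, ...) {
  cat(sprintf("%s over %d annual cycles\n", x$strategy, x$cycles))
  cat(sprintf("  discounted:   cost %s, LY %.2f, QALY %.2f (%s USD/LY)\n",
              format(round(x$totals[["cost"]], 2), big.mark = ","),
              x$totals[["ly"]], x$totals[["qaly"]],
              format(round(x$cost_per_ly, 2), big.mark = ",")))
  cat(sprintf("  undiscounted: cost %s, LY %.2f, QALY %.2f\n",
              format(round(x$undiscounted[["cost"]], 2), big.mark = ","),
              x$undiscounted[["ly"]], x$undiscounted[["qaly"]]))
  cat(sprintf("  person-years: %.2f dialysis, %.2f transplanted; KT entries %.3f\n",
              x$years_on_dialysis, x$years_transplanted,
              x$transplanted_ever))
  invisible(x)
}

#' Occupancy trace plot
#' @param x A `kt_trace`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.kt_trace <- function(x, ...) {
  tr <- x$trace
  graphics::matplot(tr$age, tr[, c("dialysis", "kt", "post1",
                                   "subsequent", "death")],
                    type = "l", lty = 1, lwd = 2,
                    col = c("#D55E00", "#0072B2", "#009E73", "#117733",
                            "grey40"),
                    xlab = "Age (years)", ylab = "State occupancy",
                    main = x$strategy, ...)
  graphics::legend("right", legend = c("dialysis", "KT", "1-yr post",
                                       "subsequent", "death"),
                   lty = 1, lwd = 2,
                   col = c("#D55E00", "#0072B2", "#009E73", "#117733",
                           "grey40"), bty = "n")
  invisible(x)
}

#' Cost per life-year gained
#'
#' Total discounted cost divided by total discounted life-years.
#'
#' @param x A `kt_trace`, or a total cost (USD).
#' @param ly Total discounted life-years (when `x` is numeric).
#' @return USD per life-year.
#' @export
cost_per_ly <- function(x, ly = NULL) {
  if (inherits(x, "kt_trace")) {
    cost <- x$totals[["cost"]]
    ly <- x$totals[["ly"]]
  } else {
    cost <- x
    if (is.null(ly)) stop("supply total life-years", call. = FALSE)
  }
  if (any(ly <= 0)) stop("life-years must be positive", call. = FALSE)
  cost / ly
}
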