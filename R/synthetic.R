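#' Generate a synthetic patient-level transplant cohort
#'
#' Simulates patient-level records emulating a single-centre KT cohort
#' (default 40 preemptive LRKT, 50 non-preemptive LRKT, 50 non-preemptive
#' DDKT patients followed for up to 10 years), so the parameter-estimation
#' to Markov-model pipeline can be exercised end-to-end without hospital
#' data. Waiting time on dialysis is geometric with annual success equal
#' to the strategy's true dialysis-to-KT probability (memoryless, matching
#' the Markov assumption); graft failure is drawn yearly at the true
#' first-year/subsequent probabilities; deaths follow the mortality model
#' (applied first within a year, like the cohort engine); each observed
#' state-year draws a cost from the moment-matched gamma of the true state
#' cost. Entry ages are drawn from a truncated normal (mean 44, SD 13,
#' range 30-70) matching the cohort's age structure.
#'
#' @param truth A `kt_params` object holding the true generating values.
#' @param n_per_strategy Named integer vector of patients per strategy.
#' @param horizon Follow-up horizon in years.
#' @param seed Integer seed.
#' @param mortality A `kt_mortality` object (default built from `truth`).
#' @param age_mean,age_sd,age_range Entry-age distribution.
#' @return A `kt_cohort` data frame, one row per patient-year: `id`,
#'   `strategy`, `entry_age`, `year`, `age`, `state`, `event_kt`,
#'   `event_graft_loss`, `event_death`, `cost`. The year of death is
#'   recorded with `event_death = TRUE`.
#' @export
generate_cohort <- function(truth = default_parameters(),
                            n_per_strategy = c("P-LRKT" = 40,
                                               "NP-LRKT" = 50,
                                               "NP-DDKT" = 50),
                            horizon = 10, seed = NULL,
                            mortality = default_mortality(truth),
                            age_mean = 44, age_sd = 13,
                            age_range = c(30, 70)) {
  stopifnot(all(n_per_strategy >= 1), horizon >= 1)
  if (!is.null(seed)) set.seed(seed)
  pv <- function(n) param_value(truth, n)
  p_fail1 <- pv("p_graft_loss_year1")
  p_fail <- pv("p_graft_loss_subsequent")
  suffix <- c("P-LRKT" = "plrkt", "NP-LRKT" = "nplrkt",
              "NP-DDKT" = "npddkt")
  p_access <- c("P-LRKT" = 0,
                "NP-LRKT" = pv("p_dialysis_to_kt_lrkt"),
                "NP-DDKT" = pv("p_dialysis_to_kt_ddkt"))
  cost_gamma <- function(nm) {
    s <- truth$specs[[nm]]
    gs <- fit_gamma_moments(s$value, s$se, nm)
    function(n) stats::rgamma(n, shape = gs[["shape"]],
                              scale = gs[["scale"]])
  }
  draw_ages <- function(n) {
    out <- numeric(0)
    while (length(out) < n) {
      a <- round(stats::rnorm(n, age_mean, age_sd))
      out <- c(out, a[a >= age_range[1] & a <= age_range[2]])
    }
    as.integer(out[seq_len(n)])
  }
  # states coded 1 dialysis, 2 transplant year, 3 first post-KT year,
  # 4 subsequent years
  slab <- c("dialysis", "kt", "post1", "subsequent")
  chunks <- list()
  id0 <- 0L
  for (strat in names(n_per_strategy)) {
    n <- n_per_strategy[[strat]]
    sfx <- suffix[[strat]]
    rc <- list(cost_gamma("cost_dialysis"),
               cost_gamma(paste0("cost_post1_", sfx)),
               cost_gamma(paste0("cost_subsequent_", sfx)),
               cost_gamma(paste0("cost_subsequent_", sfx)))
    entry_age <- draw_ages(n)
    state <- rep(if (strat == "P-LRKT") 2L else 1L, n)
    alive <- rep(TRUE, n)
    for (yr in seq_len(horizon)) {
      idx <- which(alive)
      if (!length(idx)) break
      st <- state[idx]
      age <- entry_age[idx] + yr - 1L
      qd <- death_prob(mortality, age, "dialysis")
      qk <- death_prob(mortality, age, "kt")
      died <- stats::runif(length(idx)) < ifelse(st == 1L, qd, qk)
      u <- stats::runif(length(idx))
      ev_kt <- !died & st == 1L & age <= truth$kt_stop_age &
        u < p_access[[strat]]
      ev_fail <- !died & ((st == 2L & u < p_fail1) |
                            (st >= 3L & u < p_fail))
      cost <- numeric(length(idx))
      for (s in 1:4) {
        sel <- st == s
        if (any(sel)) cost[sel] <- rc[[s]](sum(sel))
      }
      chunks[[length(chunks) + 1L]] <- data.frame(
        id = id0 + idx, strategy = strat, entry_age = entry_age[idx],
        year = yr, age = age, state = slab[st], event_kt = ev_kt,
        event_graft_loss = ev_fail, event_death = died, cost = cost,
        stringsAsFactors = FALSE)
      nxt <- st
      nxt[st == 1L] <- ifelse(ev_kt[st == 1L], 2L, 1L)
      nxt[st == 2L] <- ifelse(ev_fail[st == 2L], 1L, 3L)
      nxt[st >= 3L] <- ifelse(ev_fail[st >= 3L], 1L, 4L)
      state[idx] <- nxt
      alive[idx[died]] <- FALSE
    }
    id0 <- id0 + n
  }
  out <- do.call(rbind, chunks)
  out <- out[order(out$id, out$year), ]
  rownames(out) <- NULL
  class(out) <- c("kt_cohort", "data.frame")
  attr(out, "horizon") <- horizon
  out
}

#' @export
print.kt_cohort <- function(x, ...) {
  cat(sprintf("<kt_cohort> %d patients, %d patient-years\n",
              length(unique(x$id)), nrow(x)))
  print(table(x$strategy[!duplicated(x$id)]))
  invisible(x)
}

#' Write / read a synthetic cohort as delimited text
#' @param cohort A `kt_cohort` data frame.
#' @param path File path (CSV, one row per patient-year).
#' @return `path` (write) or a `kt_cohort` (read).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("kt_cohort", "data.frame")
  df
}

binom_se <- function(p, n) sqrt(p * (1 - p) / n)

#' Estimate model inputs from a patient-level cohort
#'
#' Transition probabilities are estimated as events divided by
#' person-years at risk with binomial standard errors (person-year risk
#' sets, matching the annual-cycle model; years in which the patient died
#' are excluded from the risk set because the engine applies death first
#' within a cycle); per-state mean annual costs carry standard errors
#' `sd/sqrt(n)`. Quantities with no person-years at risk are flagged
#' missing (`NA`), never reported as zero; a single observed state-year
#' yields an undefined (NA) cost SE.
#'
#' @param cohort A `kt_cohort` data frame.
#' @param kt_stop_age Transplant-access age limit used to define the
#'   dialysis risk set.
#' @return A `kt_estimates` object: list with `probabilities` and `costs`
#'   data frames.
#' @export
estimate_inputs <- function(cohort, kt_stop_age = 65) {
  stopifnot(nrow(cohort) >= 1)
  est_p <- function(events, n) {
    if (n == 0) return(c(NA_real_, NA_real_, 0))
    p <- events / n
    c(p, binom_se(p, n), n)
  }
  probs <- list()
  for (strat in c("NP-LRKT", "NP-DDKT")) {
    at_risk <- cohort$strategy == strat & cohort$state == "dialysis" &
      cohort$age <= kt_stop_age & !cohort$event_death
    probs[[paste0("p_dialysis_to_kt_",
                  if (strat == "NP-LRKT") "lrkt" else "ddkt")]] <-
      est_p(sum(cohort$event_kt[at_risk]), sum(at_risk))
  }
  kt_years <- cohort$state == "kt" & !cohort$event_death
  probs[["p_graft_loss_year1"]] <-
    est_p(sum(cohort$event_graft_loss[kt_years]), sum(kt_years))
  sub_years <- cohort$state %in% c("post1", "subsequent") &
    !cohort$event_death
  probs[["p_graft_loss_subsequent"]] <-
    est_p(sum(cohort$event_graft_loss[sub_years]), sum(sub_years))
  pr <- data.frame(name = names(probs),
                   estimate = vapply(probs, `[`, numeric(1), 1),
                   se = vapply(probs, `[`, numeric(1), 2),
                   n_years = vapply(probs, `[`, numeric(1), 3),
                   stringsAsFactors = FALSE, row.names = NULL)
  grp <- interaction(cohort$strategy, cohort$state, drop = TRUE)
  cost_mean <- tapply(cohort$cost, grp, mean)
  cost_n <- tapply(cohort$cost, grp, length)
  cost_se <- tapply(cohort$cost, grp, function(x)
    if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_)
  key <- do.call(rbind, strsplit(names(cost_mean), ".", fixed = TRUE))
  costs <- data.frame(strategy = key[, 1], state = key[, 2],
                      mean = as.numeric(cost_mean),
                      se = as.numeric(cost_se),
                      n_years = as.integer(cost_n),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(probabilities = pr, costs = costs),
            class = "kt_estimates")
}

#' @export
print.kt_estimates <- function(x, ...) {
  cat("Estimated transition probabilities:\n")
  print(x$probabilities, row.names = FALSE, digits = 4)
  cat("Estimated mean annual costs (USD):\n")
  print(x$costs, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Overlay cohort estimates onto a parameter set
#'
#' Replaces the transition-probability and cost values (and their SEs) of
#' a parameter set with the cohort estimates, leaving parameters the
#' cohort cannot inform (utilities, mortality ratios, one-off costs)
#' untouched. The transplant-year state cost maps to the first-post-KT
#'-year cost parameter (the model attaches the first-year cost to the
#' transplant year); post1 and subsequent state-years pool into the
#' subsequent-year cost. Missing estimates are skipped.
#'
#' @param params A `kt_params` object.
#' @param estimates A `kt_estimates` object from [estimate_inputs()].
#' @return An updated, re-validated `kt_params` object.
#' @export
apply_estimates <- function(params, estimates) {
  stopifnot(inherits(estimates, "kt_estimates"))
  for (i in seq_len(nrow(estimates$probabilities))) {
    r <- estimates$probabilities[i, ]
    if (is.na(r$estimate) || is.null(params$specs[[r$name]])) next
    params$specs[[r$name]]$value <- r$estimate
    params$specs[[r$name]]$se <- r$se
  }
  suffix <- c("P-LRKT" = "plrkt", "NP-LRKT" = "nplrkt",
              "NP-DDKT" = "npddkt")
  dial <- estimates$costs[estimates$costs$state == "dialysis", ]
  if (nrow(dial))
    params$specs[["cost_dialysis"]]$value <-
      sum(dial$mean * dial$n_years) / sum(dial$n_years)
  for (strat in names(suffix)) {
    kt <- estimates$costs[estimates$costs$strategy == strat &
                            estimates$costs$state == "kt", ]
    if (nrow(kt)) {
      nm <- paste0("cost_post1_", suffix[[strat]])
      params$specs[[nm]]$value <- kt$mean
      if (!is.na(kt$se)) params$specs[[nm]]$se <- kt$se
    }
    sub <- estimates$costs[estimates$costs$strategy == strat &
                             estimates$costs$state %in%
                             c("post1", "subsequent"), ]
    if (nrow(sub)) {
      nm <- paste0("cost_subsequent_", suffix[[strat]])
      params$specs[[nm]]$value <-
        sum(sub$mean * sub$n_years) / sum(sub$n_years)
    }
  }
  validate_parameters(params)
}
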