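# shared fixtures ------------------------------------------------------

# flat life table: constant annual death probability q over a wide age span
flat_life_table <- function(q, ages = 30:110) {
  ktcua:::as_life_table(data.frame(age = ages, q = q))
}

# mortality model in which every state sees exactly the life-table q
identity_mortality <- function(life_table = flat_life_table(0.01)) {
  mortality_model(life_table,
                  data.frame(age_low = 0, age_high = 200, smr = 1),
                  eskd_kt_ratio = 1)
}

zero_mortality <- function() identity_mortality(flat_life_table(0))

base_params <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- load_parameters()
    p
  }
})

set_param <- function(params, name, value) {
  params$specs[[name]]$value <- value
  params
}

# independent individual-level microsimulation oracle: same age-specific
# transition matrices and accrual rules as the cohort engine, but applied
# to n simulated patients rather than to a cohort occupancy vector.
microsim_totals <- function(params, mortality, strategy, n = 1e5,
                            seed = 1) {
  set.seed(seed)
  ages <- params$start_age:params$max_age
  dps <- ktcua:::death_prob_schedule(mortality, ages)
  states <- ktcua:::.states6
  util <- c(param_value(params, "utility_dialysis"),
            param_value(params, "utility_kt"),
            param_value(params, "utility_post1"),
            param_value(params, "utility_subsequent"),
            param_value(params, "utility_dialysis"), 0)
  scost <- if (strategy$cost_attachment == "entry") {
    c(strategy$cost_dialysis_annual, strategy$cost_post1,
      strategy$cost_subsequent, strategy$cost_subsequent,
      strategy$cost_dialysis_annual, 0)
  } else {
    c(strategy$cost_dialysis_annual, 0, strategy$cost_post1,
      strategy$cost_subsequent, strategy$cost_dialysis_annual, 0)
  }
  r <- params$discount_rate
  state <- rep(match(strategy$entry_state, states), n)
  cost <- rep(strategy$cost_waiting, n) +
    strategy$cost_kt_event * (state == 2L)
  ly <- numeric(n)
  qaly <- numeric(n)
  for (t in seq_along(ages)) {
    alive <- state != 6L
    if (!any(alive)) break
    disc <- (1 + r)^(-(t - 1))
    cost <- cost + disc * scost[state]
    ly <- ly + disc * as.numeric(alive)
    qaly <- qaly + disc * util[state]
    if (ages[t] == params$max_age) break
    m <- ktcua:::tmat6(params, mortality, strategy, ages[t],
                       dp = dps[t, ])
    u <- stats::runif(n)
    prev <- state
    for (s in unique(prev[alive])) {
      idx <- which(alive & prev == s)
      state[idx] <- findInterval(u[idx], cumsum(m[s, ])) + 1L
    }
    newkt <- state == 2L & prev != 2L
    cost[newkt] <- cost[newkt] + (1 + r)^(-t) * strategy$cost_kt_event
  }
  list(mean = c(cost = mean(cost), ly = mean(ly), qaly = mean(qaly)),
       se = c(cost = stats::sd(cost), ly = stats::sd(ly),
              qaly = stats::sd(qaly)) / sqrt(n))
}

# naive pairwise dominance oracle used against dominance_frontier()
brute_force_dominated <- function(cost, qaly) {
  n <- length(cost)
  out <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j != i && qaly[j] >= qaly[i] && cost[j] < cost[i]) {
        out[i] <- TRUE
        break
      }
    }
  }
  out
}
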