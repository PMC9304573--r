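# evaluate the incremental outcome of reference vs comparator under a
# given parameter set (shared by the DSA loop)
eval_increment <- function(params, reference, comparator, life_table,
                           metric, wtp, ...) {
  strat <- default_strategies(params, ...)
  mort <- default_mortality(params, life_table)
  ref <- run_cohort(params, mort, strat[[reference]])
  comp <- run_cohort(params, mort, strat[[comparator]])
  dc <- ref$totals[["cost"]] - comp$totals[["cost"]]
  dq <- ref$totals[["qaly"]] - comp$totals[["qaly"]]
  if (metric == "inc_cost") dc else wtp * dq - dc
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the reference/comparator pair with each parameter set to its
#' lower and upper deterministic bound (see [dsa_bounds()]; the discount
#' rate uses its explicit 0-6% range) while all other parameters stay at
#' base case, and records the incremental outcome at each extreme. Entries
#' are sorted by decreasing spread. The default outcome metric is the
#' incremental net monetary benefit at the willingness-to-pay threshold
#' (which responds to utilities as well as costs); incremental cost is
#' available via `metric = "inc_cost"`.
#'
#' @param params A `kt_params` object.
#' @param reference,comparator Strategy names (see [default_strategies()]).
#' @param metric `"inc_nmb"` or `"inc_cost"`.
#' @param life_table General-population life table.
#' @param wtp Willingness-to-pay used by the NMB metric.
#' @param ... Passed to [default_strategies()].
#' @return A `kt_dsa` data frame with one row per parameter: bounds,
#'   outcomes at each bound, and spread; sorted by descending spread.
#' @export
one_way_dsa <- function(params, reference = "P-LRKT",
                        comparator = "NP-DDKT",
                        metric = c("inc_nmb", "inc_cost"),
                        life_table = synthetic_life_table(),
                        wtp = params$wtp, ...) {
  metric <- match.arg(metric)
  base <- eval_increment(params, reference, comparator, life_table,
                         metric, wtp, ...)
  set_value <- function(p, nm, v) {
    if (nm == "discount_rate") p$discount_rate <- v
    else p$specs[[nm]]$value <- v
    p
  }
  items <- c(names(params$specs), "discount_rate")
  rows <- lapply(items, function(nm) {
    b <- if (nm == "discount_rate") {
      c(low = params$discount_bounds[1], high = params$discount_bounds[2])
    } else {
      dsa_bounds(params$specs[[nm]])
    }
    out <- tryCatch(
      c(low = eval_increment(set_value(params, nm, b[["low"]]),
                             reference, comparator, life_table, metric,
                             wtp, ...),
        high = eval_increment(set_value(params, nm, b[["high"]]),
                              reference, comparator, life_table, metric,
                              wtp, ...)),
      error = function(e) {
        warning("DSA for '", nm, "' failed at an extreme: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(out)) return(NULL)
    data.frame(parameter = nm, low_input = b[["low"]],
               high_input = b[["high"]],
               outcome_at_low = out[["low"]],
               outcome_at_high = out[["high"]],
               spread = abs(out[["high"]] - out[["low"]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  class(out) <- c("kt_dsa", "data.frame")
  attr(out, "metric") <- metric
  attr(out, "base_outcome") <- base
  attr(out, "pair") <- c(reference, comparator)
  out
}

#' @export
print.kt_dsa <- function(x, n = 10, ...) {
  pair <- attr(x, "pair")
  cat(sprintf("One-way DSA of %s vs %s (%s; base %s)\n", pair[1], pair[2],
              attr(x, "metric"),
              format(round(attr(x, "base_outcome"), 2), big.mark = ",")))
  print(utils::head(as.data.frame(x), n), row.names = FALSE)
  invisible(x)
}

#' Tornado diagram
#' @param x A `kt_dsa` object.
#' @param n Number of top parameters shown.
#' @param ... Unused.
#' @export
plot.kt_dsa <- function(x, n = 12, ...) {
  d <- utils::head(as.data.frame(x), n)
  d <- d[order(d$spread), ]
  base <- attr(x, "base_outcome")
  lo <- pmin(d$outcome_at_low, d$outcome_at_high)
  hi <- pmax(d$outcome_at_low, d$outcome_at_high)
  op <- graphics::par(mar = c(5, 14, 3, 2))
  on.exit(graphics::par(op))
  graphics::plot(NULL, xlim = range(lo, hi, base), ylim = c(0.5, nrow(d) + 0.5),
                 yaxt = "n", xlab = attr(x, "metric"), ylab = "",
                 main = paste(attr(x, "pair"), collapse = " vs "))
  graphics::rect(lo, seq_len(nrow(d)) - 0.35, hi, seq_len(nrow(d)) + 0.35,
                 col = "#88AACC", border = "grey30")
  graphics::abline(v = base, lty = 2)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$parameter, las = 1,
                 cex.axis = 0.7)
  invisible(x)
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` independent joint parameter samples (beta for probabilities
#' and utilities, gamma for costs, both moment-matched to their base-case
#' mean and SE; fixed-family parameters stay at base case), evaluates the
#' cohort model for all three strategies under each common draw, and
#' returns per-draw costs and QALYs. Standardized mortality ratios and the
#' ESKD-vs-KT ratio are held fixed by default; `vary_mortality = TRUE`
#' draws them from moment-matched gamma distributions.
#'
#' @param params A `kt_params` object.
#' @param n Number of Monte Carlo draws (>= 1).
#' @param seed Integer seed for reproducibility.
#' @param life_table General-population life table.
#' @param vary_mortality Also vary SMRs and the ESKD/KT ratio.
#' @param ... Passed to [default_strategies()].
#' @return A `kt_psa` object: data frame with one row per draw and columns
#'   `cost_<strategy>` / `qaly_<strategy>`, plus the parameter draws in
#'   `attr(, "draws")`.
#' @export
run_psa <- function(params, n = 1000, seed = NULL,
                    life_table = synthetic_life_table(),
                    vary_mortality = FALSE, ...) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (vary_mortality) {
    for (nm in c("smr_50_59", "smr_60_69", "smr_70_79", "smr_80plus",
                 "mortality_ratio_eskd_kt"))
      params$specs[[nm]]$family <- "gamma"
  }
  strat_names <- names(default_strategies(params, ...))
  mort0 <- default_mortality(params, life_table)
  par_names <- names(params$specs)
  draws <- matrix(NA_real_, n, length(par_names),
                  dimnames = list(NULL, par_names))
  res <- matrix(NA_real_, n, 2 * length(strat_names))
  colnames(res) <- c(paste0("cost_", strat_names),
                     paste0("qaly_", strat_names))
  for (i in seq_len(n)) {
    p_i <- draw_parameters(params)
    draws[i, ] <- vapply(p_i$specs, `[[`, numeric(1), "value")
    mort <- if (vary_mortality) default_mortality(p_i, life_table) else mort0
    strat <- default_strategies(p_i, ...)
    for (s in strat_names) {
      tr <- run_cohort(p_i, mort, strat[[s]])
      res[i, paste0("cost_", s)] <- tr$totals[["cost"]]
      res[i, paste0("qaly_", s)] <- tr$totals[["qaly"]]
    }
  }
  out <- as.data.frame(res)
  out <- cbind(draw = seq_len(n), out)
  class(out) <- c("kt_psa", "data.frame")
  attr(out, "draws") <- draws
  attr(out, "strategies") <- strat_names
  attr(out, "wtp") <- params$wtp
  attr(out, "seed") <- seed
  out
}

#' @export
print.kt_psa <- function(x, ...) {
  s <- attr(x, "strategies")
  cat(sprintf("<kt_psa> %d Monte Carlo draws, strategies: %s\n",
              nrow(x), paste(s, collapse = ", ")))
  for (nm in s)
    cat(sprintf("  %s: mean cost %s USD, mean QALY %.2f\n", nm,
                format(round(mean(x[[paste0("cost_", nm)]]), 0),
                       big.mark = ","),
                mean(x[[paste0("qaly_", nm)]])))
  invisible(x)
}

#' Cost-effectiveness plane summary
#'
#' Classifies each PSA draw's incremental QALYs and costs of a reference
#' strategy versus a comparator into the four plane quadrants and as
#' below/above the willingness-to-pay line `delta cost = wtp * delta QALY`.
#' The lower-right (southeast) quadrant - more QALYs for less cost - is
#' the dominant, cost-saving region.
#'
#' @param psa A `kt_psa` object.
#' @param reference,comparator Strategy names present in the PSA.
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @return A `kt_ce_plane` object: per-draw data frame with `dqaly`,
#'   `dcost`, `quadrant`, `below_wtp`; fractions in `attr(, "fractions")`.
#' @export
ce_plane <- function(psa, reference = "P-LRKT", comparator = "NP-DDKT",
                     wtp = attr(psa, "wtp")) {
  stopifnot(inherits(psa, "kt_psa"))
  need <- c(paste0(c("qaly_", "cost_"), reference),
            paste0(c("qaly_", "cost_"), comparator))
  if (!all(need %in% names(psa)))
    stop("strategies not present in PSA object", call. = FALSE)
  dq <- psa[[paste0("qaly_", reference)]] - psa[[paste0("qaly_", comparator)]]
  dc <- psa[[paste0("cost_", reference)]] - psa[[paste0("cost_", comparator)]]
  quadrant <- ifelse(dq >= 0,
                     ifelse(dc >= 0, "NE", "SE"),
                     ifelse(dc >= 0, "NW", "SW"))
  below <- dc < wtp * dq
  d <- data.frame(draw = psa$draw, dqaly = dq, dcost = dc,
                  quadrant = quadrant, below_wtp = below,
                  stringsAsFactors = FALSE)
  fr <- c(NE = mean(quadrant == "NE"), SE = mean(quadrant == "SE"),
          SW = mean(quadrant == "SW"), NW = mean(quadrant == "NW"),
          below_wtp = mean(below), above_wtp = mean(!below))
  structure(d, class = c("kt_ce_plane", "data.frame"),
            fractions = fr, wtp = wtp, pair = c(reference, comparator))
}

#' @export
print.kt_ce_plane <- function(x, ...) {
  p <- attr(x, "pair")
  fr <- attr(x, "fractions")
  cat(sprintf("CE plane: %s vs %s over %d draws (WTP %s)\n", p[1], p[2],
              nrow(x), format(attr(x, "wtp"))))
  cat(sprintf("  quadrants: NE %.1f%%, SE (dominant) %.1f%%, SW %.1f%%, NW %.1f%%\n",
              100 * fr[["NE"]], 100 * fr[["SE"]], 100 * fr[["SW"]],
              100 * fr[["NW"]]))
  cat(sprintf("  below WTP line: %.1f%%\n", 100 * fr[["below_wtp"]]))
  invisible(x)
}

#' @export
plot.kt_ce_plane <- function(x, ...) {
  p <- attr(x, "pair")
  graphics::plot(x$dqaly, x$dcost, pch = 16, cex = 0.5,
                 col = grDevices::adjustcolor("#0072B2", 0.4),
                 xlab = "Incremental QALYs", ylab = "Incremental cost (USD)",
                 main = paste(p, collapse = " vs "), ...)
  graphics::abline(h = 0, v = 0, col = "grey60")
  graphics::abline(0, attr(x, "wtp"), lty = 2, col = "#D55E00")
  invisible(x)
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value on a grid, the fraction of PSA draws
#' in which each strategy attains the maximal net monetary benefit; exact
#' ties split the probability mass equally. Probabilities sum to 1 across
#' strategies at every grid point.
#'
#' @param psa A `kt_psa` object.
#' @param wtp_grid Vector of willingness-to-pay values (USD/QALY).
#' @return A `kt_ceac` data frame: column `wtp` plus one probability
#'   column per strategy.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 20000, by = 250)) {
  stopifnot(inherits(psa, "kt_psa"), length(wtp_grid) >= 1)
  strat <- attr(psa, "strategies")
  costs <- as.matrix(psa[paste0("cost_", strat)])
  qalys <- as.matrix(psa[paste0("qaly_", strat)])
  prob <- vapply(wtp_grid, function(w) {
    nb <- w * qalys - costs
    best <- nb == row_maxs(nb)
    colMeans(best / rowSums(best))
  }, numeric(length(strat)))
  out <- data.frame(wtp = wtp_grid, t(prob))
  names(out) <- c("wtp", strat)
  class(out) <- c("kt_ceac", "data.frame")
  out
}

# row maxima via parallel max over columns
row_maxs <- function(m) do.call(pmax, as.data.frame(m))

#' @export
plot.kt_ceac <- function(x, ...) {
  strat <- setdiff(names(x), "wtp")
  cols <- c("#0072B2", "#D55E00", "#009E73", "#CC79A7")[seq_along(strat)]
  graphics::matplot(x$wtp, as.matrix(x[strat]), type = "l", lty = 1,
                    lwd = 2, col = cols, ylim = c(0, 1),
                    xlab = "Willingness to pay (USD/QALY)",
                    ylab = "Probability cost-effective",
                    main = "Cost-effectiveness acceptability curves", ...)
  graphics::legend("right", legend = strat, lty = 1, lwd = 2, col = cols,
                   bty = "n")
  invisible(x)
}
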