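as_outcome <- function(x, name = NULL) {
  if (inherits(x, "kt_trace")) {
    list(strategy = x$strategy, cost = x$totals[["cost"]],
         qaly = x$totals[["qaly"]], ly = x$totals[["ly"]])
  } else if (is.list(x) && all(c("cost", "qaly") %in% names(x))) {
    list(strategy = x$strategy %||% name %||% "strategy",
         cost = as.numeric(x$cost), qaly = as.numeric(x$qaly),
         ly = as.numeric(x$ly %||% NA_real_))
  } else {
    stop("expected a kt_trace or a list with cost and qaly", call. = FALSE)
  }
}

#' Incremental cost-effectiveness ratio
#'
#' @param delta_cost Incremental cost (USD).
#' @param delta_qaly Incremental QALYs (non-zero).
#' @return USD per QALY gained.
#' @export
icer <- function(delta_cost, delta_qaly) {
  if (any(delta_qaly == 0))
    stop("ICER undefined for zero QALY difference; compare costs/dominance instead",
         call. = FALSE)
  delta_cost / delta_qaly
}

#' Net monetary benefit
#'
#' `wtp * QALY - cost`: the strategy with maximal NMB at a given
#' willingness-to-pay is the cost-effective choice.
#'
#' @param outcome A `kt_trace` or list with `cost` and `qaly`, or a total
#'   cost (USD) when `qaly` is given.
#' @param wtp Willingness-to-pay threshold (USD/QALY, >= 0).
#' @param qaly Total QALYs (when `outcome` is a bare cost).
#' @return NMB in USD.
#' @export
nmb <- function(outcome, wtp, qaly = NULL) {
  stopifnot(wtp >= 0)
  if (is.numeric(outcome) && !is.null(qaly))
    return(wtp * qaly - outcome)
  o <- as_outcome(outcome)
  wtp * o$qaly - o$cost
}

#' Compare two strategies: increments, ICER and classification
#'
#' Classification rules: *cost-saving* when the reference costs less and
#' yields at least as many QALYs; *dominated* when it costs more and yields
#' no more QALYs (at least one strictly); otherwise *cost-effective* when
#' the ICER does not exceed the willingness-to-pay (for a QALY gain), with
#' the sign-reversed rule (savings per QALY forgone must reach the
#' threshold) for a QALY loss. An exact tie classifies as cost-effective.
#'
#' @param reference The strategy under evaluation (`kt_trace` or list with
#'   `cost`/`qaly`).
#' @param comparator The strategy compared against.
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @return A `kt_comparison` object (one-row data frame) with columns
#'   `reference`, `comparator`, `incremental_cost`, `qaly_gained`, `icer`,
#'   `classification`.
#' @export
compare_strategies <- function(reference, comparator, wtp) {
  ref <- as_outcome(reference)
  comp <- as_outcome(comparator)
  dc <- ref$cost - comp$cost
  dq <- ref$qaly - comp$qaly
  ic <- if (dq != 0) dc / dq else NA_real_
  cls <- if (dc == 0 && dq == 0) {
    "cost-effective"
  } else if (dc < 0 && dq >= 0) {
    "cost-saving"
  } else if (dc > 0 && dq <= 0) {
    "dominated"
  } else if (dq > 0) {
    if (ic <= wtp) "cost-effective" else "not cost-effective"
  } else {
    # QALY loss with cost saving: acceptable only if the saving per QALY
    # forgone reaches the threshold
    if (ic >= wtp) "cost-effective" else "not cost-effective"
  }
  out <- data.frame(reference = ref$strategy, comparator = comp$strategy,
                    incremental_cost = dc, qaly_gained = dq, icer = ic,
                    classification = cls, stringsAsFactors = FALSE)
  class(out) <- c("kt_comparison", "data.frame")
  attr(out, "wtp") <- wtp
  out
}

#' @export
print.kt_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s (WTP %s USD/QALY)\n", x$reference, x$comparator,
              format(attr(x, "wtp"))))
  cat(sprintf("  incremental cost %s USD, QALYs gained %.4f%s -> %s\n",
              format(round(x$incremental_cost, 2), big.mark = ","),
              x$qaly_gained,
              if (is.na(x$icer)) "" else
                sprintf(", ICER %s USD/QALY",
                        format(round(x$icer, 2), big.mark = ",")),
              x$classification))
  invisible(x)
}

#' Dominance frontier across strategies
#'
#' Sorts strategies by increasing QALYs (ties broken by decreasing cost so
#' a dominated equal-QALY strategy is listed before the strategy that
#' dominates it), flags strictly dominated strategies (some other strategy
#' yields at least as many QALYs for strictly lower cost), and computes
#' incremental costs, QALYs and ICERs of each non-dominated strategy
#' against the next-less-effective non-dominated one. Dominated strategies
#' show their increments against the least-effective (reference) strategy.
#'
#' @param outcomes Data frame with columns `strategy`, `cost`, `qaly`
#'   (e.g. from [run_base_case()]), or a list of `kt_trace` objects.
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @return A `kt_frontier` data frame with dominance flags,
#'   increments, ICERs and classifications.
#' @export
dominance_frontier <- function(outcomes, wtp) {
  if (!is.data.frame(outcomes)) {
    rows <- lapply(outcomes, as_outcome)
    outcomes <- data.frame(
      strategy = vapply(rows, `[[`, character(1), "strategy"),
      cost = vapply(rows, `[[`, numeric(1), "cost"),
      qaly = vapply(rows, `[[`, numeric(1), "qaly"),
      stringsAsFactors = FALSE)
  }
  stopifnot(nrow(outcomes) >= 2,
            all(c("strategy", "cost", "qaly") %in% names(outcomes)))
  o <- outcomes[order(outcomes$qaly, -outcomes$cost), , drop = FALSE]
  n <- nrow(o)
  dominated <- vapply(seq_len(n), function(i)
    any(o$qaly >= o$qaly[i] & o$cost < o$cost[i]), logical(1))
  inc_cost <- inc_qaly <- icer_v <- rep(NA_real_, n)
  cls <- character(n)
  last_nd <- NA_integer_
  for (i in seq_len(n)) {
    if (dominated[i]) {
      cls[i] <- "dominated"
      inc_cost[i] <- o$cost[i] - o$cost[1L]
      inc_qaly[i] <- o$qaly[i] - o$qaly[1L]
      next
    }
    if (is.na(last_nd)) {
      cls[i] <- "reference"
    } else {
      inc_cost[i] <- o$cost[i] - o$cost[last_nd]
      inc_qaly[i] <- o$qaly[i] - o$qaly[last_nd]
      if (inc_qaly[i] != 0) icer_v[i] <- inc_cost[i] / inc_qaly[i]
      cls[i] <- compare_strategies(
        list(strategy = o$strategy[i], cost = o$cost[i], qaly = o$qaly[i]),
        list(strategy = o$strategy[last_nd], cost = o$cost[last_nd],
             qaly = o$qaly[last_nd]), wtp)$classification
    }
    last_nd <- i
  }
  out <- data.frame(strategy = o$strategy, cost = o$cost, qaly = o$qaly,
                    dominated = dominated, incremental_cost = inc_cost,
                    qaly_gained = inc_qaly, icer = icer_v,
                    classification = cls, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("kt_frontier", "data.frame")
  attr(out, "wtp") <- wtp
  out
}

#' @export
print.kt_frontier <- function(x, digits = 2, ...) {
  cat(sprintf("Dominance frontier (WTP %s USD/QALY)\n",
              format(attr(x, "wtp"))))
  y <- as.data.frame(x)
  for (col in c("cost", "incremental_cost", "icer"))
    y[[col]] <- round(y[[col]], digits)
  y$qaly <- round(y$qaly, 2)
  y$qaly_gained <- round(y$qaly_gained, 4)
  print(y, row.names = FALSE)
  invisible(x)
}
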