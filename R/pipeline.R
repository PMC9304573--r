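#' Run configuration for the analysis pipeline
#'
#' Bundles and validates everything a full run needs: parameter file,
#' life table, analysis set, PSA size, seed, output directory and
#' overrides.
#'
#' @param params_file Path to a YAML parameter configuration, or `NULL`
#'   for the packaged default.
#' @param life_table Path to a life-table file, or `"builtin"` for the
#'   packaged synthetic table.
#' @param analyses Subset of `c("base", "dsa", "psa", "ceac",
#'   "synthetic")`.
#' @param n_psa Number of PSA draws (>= 1 when `"psa"` or `"ceac"`
#'   requested).
#' @param seed Integer seed for all stochastic stages.
#' @param out Output directory for delimited-text exports, or `NULL` to
#'   skip writing.
#' @param wtp,discount Optional overrides of the configured
#'   willingness-to-pay and discount rate.
#' @param n_synthetic Patients per strategy for the synthetic-cohort
#'   round trip.
#' @return A `kt_config` object.
#' @export
run_config <- function(params_file = NULL, life_table = "builtin",
                       analyses = c("base", "dsa", "psa", "ceac"),
                       n_psa = 1000, seed = 1, out = NULL,
                       wtp = NULL, discount = NULL,
                       n_synthetic = c("P-LRKT" = 40, "NP-LRKT" = 50,
                                       "NP-DDKT" = 50)) {
  analyses <- match.arg(analyses,
                        c("base", "dsa", "psa", "ceac", "synthetic"),
                        several.ok = TRUE)
  if (any(c("psa", "ceac") %in% analyses) && n_psa < 1)
    stop("n_psa must be >= 1 when a probabilistic analysis is requested",
         call. = FALSE)
  params <- load_parameters(params_file)
  if (!is.null(discount)) params$discount_rate <- discount
  if (!is.null(wtp)) params$wtp <- wtp
  validate_parameters(params)
  lt <- if (identical(life_table, "builtin")) synthetic_life_table()
        else read_life_table(life_table)
  if (!is.null(out) && !dir.exists(out))
    dir.create(out, recursive = TRUE)
  structure(list(params = params, life_table = lt, analyses = analyses,
                 n_psa = as.integer(n_psa), seed = as.integer(seed),
                 out = out, n_synthetic = n_synthetic,
                 params_file = params_file %||% "builtin"),
            class = "kt_config")
}

# short polynomial content hash (mod 2^31 - 1) so exports are auditable
config_hash <- function(config) {
  txt <- paste(utils::capture.output(utils::str(config$params)),
               collapse = "\n")
  h <- 17
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Base-case cost-utility analysis of the three strategies
#'
#' Runs the lifetime Markov cohort model for preemptive LRKT,
#' non-preemptive LRKT and non-preemptive DDKT, and assembles the
#' per-strategy discounted totals, the dominance frontier, and the three
#' pairwise comparisons (preemptive vs each non-preemptive strategy, and
#' non-preemptive LRKT vs non-preemptive DDKT).
#'
#' @param params A `kt_params` object.
#' @param life_table General-population life table.
#' @param wtp Willingness-to-pay threshold override.
#' @param discount Discount-rate override.
#' @param ... Passed to [default_strategies()].
#' @return A `kt_cua` object with elements `outcomes` (data frame),
#'   `frontier`, `comparisons` (list of `kt_comparison`), `traces`.
#' @examples
#' cua <- run_base_case(load_parameters())
#' print(cua)
#' @export
run_base_case <- function(params = default_parameters(),
                          life_table = synthetic_life_table(),
                          wtp = NULL, discount = NULL, ...) {
  if (!is.null(discount)) params$discount_rate <- discount
  if (!is.null(wtp)) params$wtp <- wtp
  validate_parameters(params)
  strat <- default_strategies(params, ...)
  mort <- default_mortality(params, life_table)
  traces <- lapply(strat, function(s) run_cohort(params, mort, s))
  outcomes <- data.frame(
    strategy = vapply(traces, `[[`, character(1), "strategy"),
    cost = vapply(traces, function(t) t$totals[["cost"]], numeric(1)),
    ly = vapply(traces, function(t) t$totals[["ly"]], numeric(1)),
    qaly = vapply(traces, function(t) t$totals[["qaly"]], numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  outcomes$cost_per_ly <- outcomes$cost / outcomes$ly
  pairs <- list(c("P-LRKT", "NP-DDKT"), c("P-LRKT", "NP-LRKT"),
                c("NP-LRKT", "NP-DDKT"))
  comparisons <- lapply(pairs, function(p)
    compare_strategies(traces[[p[1]]], traces[[p[2]]], params$wtp))
  names(comparisons) <- vapply(pairs, paste, character(1),
                               collapse = " vs ")
  structure(list(outcomes = outcomes,
                 frontier = dominance_frontier(outcomes, params$wtp),
                 comparisons = comparisons, traces = traces,
                 wtp = params$wtp, discount_rate = params$discount_rate),
            class = "kt_cua")
}

#' @export
print.kt_cua <- function(x, ...) {
  cat(sprintf("Lifetime cost-utility analysis (discount %.3g, WTP %s USD/QALY)\n\n",
              x$discount_rate, format(x$wtp)))
  o <- x$outcomes
  o$cost <- round(o$cost, 2)
  o$ly <- round(o$ly, 2)
  o$qaly <- round(o$qaly, 2)
  o$cost_per_ly <- round(o$cost_per_ly, 2)
  print(o, row.names = FALSE)
  cat("\n")
  print(x$frontier)
  cat("\nPairwise comparisons:\n")
  for (cmp in x$comparisons) print(cmp)
  invisible(x)
}

#' @export
summary.kt_cua <- function(object, ...) {
  lapply(object$traces, summary)
}

#' Full analysis pipeline: base case, DSA, PSA, CE plane and CEAC
#'
#' Runs the requested analysis stages under one configuration, optionally
#' writing every result table as delimited text (each file stamped with
#' the configuration hash and seed), and collects the headline numbers in
#' a machine-readable `summary` vector. A failing stage is recorded and
#' later stages still run where independent.
#'
#' @param config A `kt_config` from [run_config()].
#' @return A `kt_pipeline` list with elements `base`, `dsa`, `psa`,
#'   `ce_plane`, `ceac`, `synthetic` (as requested), `summary`, `errors`.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "kt_config"))
  params <- config$params
  lt <- config$life_table
  res <- list(config = config)
  errors <- character()
  summ <- c()
  hash <- config_hash(config)
  stamp <- sprintf("# config %s seed %d", hash, config$seed)
  emit <- function(df, file) {
    if (is.null(config$out)) return(invisible())
    path <- file.path(config$out, file)
    writeLines(stamp, path)
    suppressWarnings(utils::write.table(
      as.data.frame(df), path, sep = "\t", row.names = FALSE,
      quote = FALSE, append = TRUE))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      message("stage '", name, "' failed: ", conditionMessage(e))
      NULL
    })
  }
  if ("base" %in% config$analyses) {
    res$base <- stage("base", {
      cua <- run_base_case(params, lt)
      emit(cua$outcomes, "base_outcomes.tsv")
      emit(as.data.frame(cua$frontier), "frontier.tsv")
      emit(do.call(rbind, lapply(cua$comparisons, as.data.frame)),
           "comparisons.tsv")
      for (nm in names(cua$traces))
        emit(cua$traces[[nm]]$trace, paste0("trace_", nm, ".tsv"))
      o <- cua$outcomes
      key <- c("P-LRKT" = "plrkt", "NP-LRKT" = "nplrkt",
               "NP-DDKT" = "npddkt")
      for (i in seq_len(nrow(o))) {
        k <- key[[o$strategy[i]]]
        summ[paste0(c("cost_", "ly_", "qaly_", "cost_per_ly_"), k)] <-
          c(o$cost[i], o$ly[i], o$qaly[i], o$cost_per_ly[i])
      }
      summ["inc_cost_plrkt_vs_npddkt"] <-
        cua$comparisons[[1]]$incremental_cost
      summ["qaly_gained_plrkt_vs_npddkt"] <-
        cua$comparisons[[1]]$qaly_gained
      summ["icer_nplrkt_vs_npddkt"] <- cua$comparisons[[3]]$icer
      cua
    })
  }
  if ("dsa" %in% config$analyses) {
    res$dsa <- stage("dsa", {
      d <- one_way_dsa(params, life_table = lt)
      emit(as.data.frame(d), "tornado.tsv")
      summ["dsa_top_spread"] <- d$spread[1]
      d
    })
  }
  psa <- NULL
  if (any(c("psa", "ceac") %in% config$analyses)) {
    psa <- stage("psa", {
      p <- run_psa(params, n = config$n_psa, seed = config$seed,
                   life_table = lt)
      emit(as.data.frame(p), "psa_samples.tsv")
      p
    })
    res$psa <- psa
  }
  if (!is.null(psa) && "psa" %in% config$analyses) {
    res$ce_plane <- stage("ce_plane", {
      cp <- ce_plane(psa, "P-LRKT", "NP-DDKT", wtp = params$wtp)
      cp2 <- ce_plane(psa, "NP-LRKT", "NP-DDKT", wtp = params$wtp)
      emit(as.data.frame(cp), "ce_plane_plrkt_vs_npddkt.tsv")
      emit(as.data.frame(cp2), "ce_plane_nplrkt_vs_npddkt.tsv")
      fr <- attr(cp, "fractions")
      summ["psa_dominant_pct"] <- 100 * fr[["SE"]]
      summ["psa_below_wtp_pct"] <- 100 * fr[["below_wtp"]]
      summ["psa_nplrkt_above_wtp_pct"] <-
        100 * attr(cp2, "fractions")[["above_wtp"]]
      list(plrkt_vs_npddkt = cp, nplrkt_vs_npddkt = cp2)
    })
  }
  if (!is.null(psa) && "ceac" %in% config$analyses) {
    res$ceac <- stage("ceac", {
      cc <- ceac(psa)
      emit(as.data.frame(cc), "ceac.tsv")
      cc
    })
  }
  if ("synthetic" %in% config$analyses) {
    res$synthetic <- stage("synthetic", {
      coh <- generate_cohort(params, n_per_strategy = config$n_synthetic,
                             seed = config$seed,
                             mortality = default_mortality(params, lt))
      est <- estimate_inputs(coh, kt_stop_age = params$kt_stop_age)
      emit(as.data.frame(coh), "synthetic_cohort.tsv")
      emit(est$probabilities, "synthetic_estimates_probabilities.tsv")
      emit(est$costs, "synthetic_estimates_costs.tsv")
      list(cohort = coh, estimates = est,
           recovered = apply_estimates(params, est))
    })
  }
  res$summary <- summ
  res$errors <- errors
  res$hash <- hash
  if (!is.null(config$out))
    emit(data.frame(key = names(summ), value = unname(summ)),
         "summary.tsv")
  class(res) <- "kt_pipeline"
  res
}

#' @export
print.kt_pipeline <- function(x, ...) {
  cat("<kt_pipeline> config ", x$hash, ", stages: ",
      paste(x$config$analyses, collapse = ", "), "\n", sep = "")
  if (length(x$errors))
    cat("  failed stages:", paste(names(x$errors), collapse = ", "), "\n")
  if (length(x$summary)) {
    cat("  headline numbers:\n")
    for (nm in names(x$summary))
      cat(sprintf("    %-28s %s\n", nm,
                  format(round(x$summary[[nm]], 3), big.mark = ",")))
  }
  invisible(x)
}
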