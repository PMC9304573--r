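#' Single model input parameter with its uncertainty specification
#'
#' Builds one validated parameter record: a base-case value, an optional
#' standard error, optional explicit sensitivity bounds, a sampling family
#' for probabilistic sensitivity analysis, and a role that determines how
#' deterministic sensitivity bounds are clamped.
#'
#' Invariants enforced: `value >= 0`; beta-family values lie in \[0, 1\];
#' gamma-family values are strictly positive; when both bounds are given,
#' `low <= value <= high`. A beta parameter whose stated SE is incompatible
#' with the beta family (`se^2 >= value * (1 - value)`, which happens for
#' utilities near 1 with wide uncertainty) has its SE shrunk to
#' `0.99 * sqrt(value * (1 - value))` with a warning, so that moment
#' matching stays feasible.
#'
#' @param name Identifier (unique within a parameter set).
#' @param value Base-case value (non-negative).
#' @param se Standard error, or `NA` when unknown.
#' @param low,high Explicit deterministic-sensitivity bounds, or `NA`.
#' @param family Sampling family: `"beta"`, `"gamma"` or `"fixed"`.
#' @param units Free-text units (e.g. `"USD/yr"`).
#' @param role One of `"probability"`, `"cost"`, `"utility"`, `"ratio"`,
#'   `"rate-config"`; controls clamping in [dsa_bounds()].
#' @return An object of class `kt_parameter`.
#' @seealso [load_parameters()], [dsa_bounds()]
#' @export
kt_parameter <- function(name, value, se = NA_real_, low = NA_real_,
                         high = NA_real_,
                         family = c("fixed", "beta", "gamma"),
                         units = "",
                         role = c("probability", "cost", "utility",
                                  "ratio", "rate-config")) {
  family <- match.arg(family)
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  value <- as.numeric(value)
  se <- as.numeric(se)
  low <- as.numeric(low)
  high <- as.numeric(high)
  if (!is.finite(value) || value < 0)
    stop("parameter '", name, "': value must be a non-negative number",
         call. = FALSE)
  if (family == "beta") {
    if (value > 1)
      stop("parameter '", name, "': beta family requires value in [0, 1]",
           call. = FALSE)
    if (!is.na(se) && se > 0 && se^2 >= value * (1 - value)) {
      se_max <- 0.99 * sqrt(value * (1 - value))
      warning("parameter '", name, "': se ", se,
              " incompatible with beta family; shrunk to ",
              signif(se_max, 4), call. = FALSE)
      se <- se_max
    }
  }
  if (family == "gamma" && value <= 0)
    stop("parameter '", name, "': gamma family requires value > 0",
         call. = FALSE)
  if (!is.na(se) && se < 0)
    stop("parameter '", name, "': se must be non-negative", call. = FALSE)
  if (!is.na(low) && !is.na(high) && !(low <= value && value <= high))
    stop("parameter '", name, "': need low <= value <= high", call. = FALSE)
  structure(
    list(name = name, value = value, se = se, low = low, high = high,
         family = family, units = units, role = role),
    class = "kt_parameter"
  )
}

#' @export
print.kt_parameter <- function(x, ...) {
  unc <- if (!is.na(x$low) || !is.na(x$high)) {
    sprintf("[%s, %s]", format(x$low), format(x$high))
  } else if (!is.na(x$se)) {
    sprintf("se %s", format(x$se))
  } else "+/- 15%"
  cat(sprintf("<kt_parameter> %s = %s (%s, %s, %s)\n",
              x$name, format(x$value), x$family, x$role, unc))
  invisible(x)
}

# names every base-case run needs; validation refuses a set without them
.required_parameters <- c(
  "p_dialysis_to_kt_lrkt", "p_dialysis_to_kt_ddkt",
  "p_graft_loss_year1", "p_graft_loss_subsequent",
  "smr_50_59", "smr_60_69", "smr_70_79", "smr_80plus",
  "mortality_ratio_eskd_kt",
  "cost_dialysis", "cost_nonmedical",
  "cost_kt_plrkt", "cost_post1_plrkt", "cost_subsequent_plrkt",
  "cost_waiting_plrkt",
  "cost_kt_nplrkt", "cost_post1_nplrkt", "cost_subsequent_nplrkt",
  "cost_kt_npddkt", "cost_post1_npddkt", "cost_subsequent_npddkt",
  "utility_dialysis", "utility_kt", "utility_post1", "utility_subsequent"
)

#' Assemble a validated parameter set
#'
#' @param specs List of [kt_parameter()] objects (names taken from the specs).
#' @param discount_rate Annual discount rate applied to costs and outcomes.
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @param start_age Cohort entry age (years).
#' @param kt_stop_age Oldest age at which transplantation is performed.
#' @param max_age Horizon cap (years).
#' @param discount_bounds Range explored by deterministic sensitivity
#'   analysis of the discount rate.
#' @return An object of class `kt_params`.
#' @export
kt_parameter_set <- function(specs, discount_rate = 0.03, wtp = 5113,
                             start_age = 50, kt_stop_age = 65, max_age = 100,
                             discount_bounds = c(0, 0.06)) {
  stopifnot(is.list(specs))
  names(specs) <- vapply(specs, function(s) s$name, character(1))
  ps <- structure(
    list(specs = specs,
         discount_rate = as.numeric(discount_rate),
         wtp = as.numeric(wtp),
         start_age = as.integer(start_age),
         kt_stop_age = as.integer(kt_stop_age),
         max_age = as.integer(max_age),
         discount_bounds = as.numeric(discount_bounds)),
    class = "kt_params"
  )
  validate_parameters(ps)
}

#' Validate a parameter set
#'
#' Checks that every parameter the Markov model and the mortality model
#' require is present and that global settings are coherent
#' (`start_age < kt_stop_age < max_age`, discount rate within its bounds,
#' positive WTP).
#'
#' @param params A `kt_params` object.
#' @return `params`, invisibly usable, after validation.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "kt_params"))
  missing <- setdiff(.required_parameters, names(params$specs))
  if (length(missing))
    stop("parameter set is missing required parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!(params$discount_rate >= 0 && params$discount_rate <= 0.06))
    stop("invalid field 'discount_rate': must lie in [0, 0.06]",
         call. = FALSE)
  if (!(params$wtp > 0))
    stop("invalid field 'wtp': must be positive", call. = FALSE)
  if (!(params$start_age < params$kt_stop_age &&
        params$kt_stop_age < params$max_age))
    stop("invalid ages: need start_age < kt_stop_age < max_age",
         call. = FALSE)
  params
}

#' Look up a parameter's base-case value
#'
#' @param params A `kt_params` object.
#' @param name Parameter name.
#' @return The numeric base-case value.
#' @export
param_value <- function(params, name) {
  sp <- params$specs[[name]]
  if (is.null(sp)) stop("unknown parameter: ", name, call. = FALSE)
  sp$value
}

#' Load a parameter configuration from YAML
#'
#' Reads a structured YAML file with a `settings` block (discount rate, WTP,
#' ages) and a `parameters` list (one block per parameter with fields
#' `name`/`value`/`se`/`low`/`high`/`family`/`units`/`role`), validates it,
#' and returns a `kt_params` object. With no argument, the packaged default
#' configuration is loaded; it reproduces the model's published Thai
#' base-case inputs (2020 USD).
#'
#' @param path Path to a YAML configuration, or `NULL` for the packaged
#'   default (`params_siriraj_2020usd.yaml`).
#' @return A validated `kt_params` object.
#' @examples
#' p <- load_parameters()
#' param_value(p, "utility_dialysis")  # 0.68
#' @export
load_parameters <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "params_siriraj_2020usd.yaml",
                        package = "ktcua", mustWork = TRUE)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$settings) || is.null(raw$parameters))
    stop("config must contain 'settings' and 'parameters' blocks",
         call. = FALSE)
  st <- raw$settings
  specs <- lapply(raw$parameters, function(p) {
    if (is.null(p$name) || is.null(p$value))
      stop("every parameter block needs at least 'name' and 'value'",
           call. = FALSE)
    kt_parameter(
      name = p$name, value = p$value,
      se = if (is.null(p$se)) NA_real_ else p$se,
      low = if (is.null(p$low)) NA_real_ else p$low,
      high = if (is.null(p$high)) NA_real_ else p$high,
      family = if (is.null(p$family)) "fixed" else p$family,
      units = if (is.null(p$units)) "" else p$units,
      role = if (is.null(p$role)) "cost" else p$role
    )
  })
  kt_parameter_set(
    specs,
    discount_rate = st$discount_rate %||% 0.03,
    wtp = st$wtp %||% 5113,
    start_age = st$start_age %||% 50,
    kt_stop_age = st$kt_stop_age %||% 65,
    max_age = st$max_age %||% 100,
    discount_bounds = unlist(st$discount_bounds %||% c(0, 0.06))
  )
}

#' Serialize a parameter set back to YAML
#'
#' Inverse of [load_parameters()]: `load_parameters(write_parameters(p, f))`
#' returns a set equal to `p`.
#'
#' @param params A `kt_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "kt_params"))
  drop_na <- function(x) x[!vapply(x, function(v)
    length(v) == 1L && is.na(v), logical(1))]
  out <- list(
    settings = list(
      discount_rate = params$discount_rate,
      wtp = params$wtp,
      start_age = params$start_age,
      kt_stop_age = params$kt_stop_age,
      max_age = params$max_age,
      discount_bounds = params$discount_bounds
    ),
    parameters = unname(lapply(params$specs, function(s)
      drop_na(s[c("name", "value", "se", "low", "high",
                  "family", "units", "role")])))
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Default (packaged) base-case parameter set
#'
#' Convenience wrapper for `load_parameters(NULL)`.
#' @return A validated `kt_params` object.
#' @export
default_parameters <- function() load_parameters(NULL)

#' @export
print.kt_params <- function(x, ...) {
  cat("<kt_params> ", length(x$specs), " parameters\n", sep = "")
  cat(sprintf("  discount %.3g, WTP %s USD/QALY, ages %d -> %d (KT until %d)\n",
              x$discount_rate, format(x$wtp), x$start_age, x$max_age,
              x$kt_stop_age))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic sensitivity bounds of a parameter
#'
#' Explicit bounds win; otherwise a 95% confidence interval
#' (`value +/- 1.96 se`) when an SE is available; otherwise `+/- 15%` of the
#' base-case value. Probabilities and utilities are clamped to \[0, 1\];
#' costs and ratios are clamped to be non-negative.
#'
#' @param spec A [kt_parameter()] object.
#' @return Numeric vector `c(low, high)` with `low <= value <= high`.
#' @export
dsa_bounds <- function(spec) {
  stopifnot(inherits(spec, "kt_parameter"))
  if (!is.na(spec$low) && !is.na(spec$high)) {
    b <- c(spec$low, spec$high)
  } else if (!is.na(spec$se) && spec$se > 0) {
    b <- spec$value + c(-1.96, 1.96) * spec$se
  } else {
    b <- spec$value * c(0.85, 1.15)
  }
  if (spec$role %in% c("probability", "utility")) {
    b <- pmin(pmax(b, 0), 1)
  } else {
    b <- pmax(b, 0)
  }
  c(low = min(b[1], spec$value), high = max(b[2], spec$value))
}

#' Moment-matched beta parameters
#'
#' Method-of-moments fit of a beta distribution with the given mean and
#' standard deviation: with `k = mean (1 - mean) / se^2 - 1`,
#' `alpha = mean k` and `beta = (1 - mean) k`.
#'
#' @param mean Mean in (0, 1).
#' @param se Standard deviation (must satisfy `se^2 < mean (1 - mean)`).
#' @param name Optional parameter name for error messages.
#' @return Numeric vector `c(alpha, beta)`.
#' @export
fit_beta_moments <- function(mean, se, name = NULL) {
  lbl <- if (is.null(name)) "" else paste0(" for '", name, "'")
  if (!(mean > 0 && mean < 1))
    stop("beta moment fit", lbl, ": mean must lie in (0, 1)", call. = FALSE)
  if (!(se > 0))
    stop("beta moment fit", lbl, ": se must be positive", call. = FALSE)
  if (se^2 >= mean * (1 - mean))
    stop("beta moment fit", lbl, ": se^2 must be < mean*(1-mean)",
         call. = FALSE)
  k <- mean * (1 - mean) / se^2 - 1
  c(alpha = mean * k, beta = (1 - mean) * k)
}

#' Moment-matched gamma parameters
#'
#' `shape = (mean/se)^2`, `scale = se^2/mean`, so the fitted gamma has
#' exactly the requested mean and standard deviation.
#'
#' @inheritParams fit_beta_moments
#' @return Numeric vector `c(shape, scale)`.
#' @export
fit_gamma_moments <- function(mean, se, name = NULL) {
  lbl <- if (is.null(name)) "" else paste0(" for '", name, "'")
  if (!(mean > 0) || !(se > 0))
    stop("gamma moment fit", lbl, ": mean and se must be positive",
         call. = FALSE)
  c(shape = (mean / se)^2, scale = se^2 / mean)
}

# One PSA draw of every stochastic parameter; fixed-family parameters (and
# se = 0 / missing-se ones) keep their base-case value.
draw_parameters <- function(params) {
  specs <- params$specs
  for (nm in names(specs)) {
    s <- specs[[nm]]
    if (s$family == "fixed" || is.na(s$se) || s$se == 0) next
    if (s$family == "beta") {
      ab <- fit_beta_moments(s$value, s$se, nm)
      specs[[nm]]$value <- stats::rbeta(1L, ab[["alpha"]], ab[["beta"]])
    } else if (s$family == "gamma") {
      gs <- fit_gamma_moments(s$value, s$se, nm)
      specs[[nm]]$value <- stats::rgamma(1L, shape = gs[["shape"]],
                                         scale = gs[["scale"]])
    }
  }
  out <- params
  out$specs <- specs
  out
}
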