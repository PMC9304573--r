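#' Convert an annual death probability to a hazard rate
#'
#' Standard actuarial conversion assuming a constant hazard within the
#' year: the rate is `-log(1 - q)`.
#'
#' @param q Annual death probability in \[0, 1).
#' @return Hazard rate per year.
#' @export
prob_to_rate <- function(q) {
  if (any(q < 0 | q >= 1))
    stop("probability must lie in [0, 1)", call. = FALSE)
  -log(1 - q)
}

#' Convert a hazard rate to an annual death probability
#'
#' Inverse of [prob_to_rate()]: `q = 1 - exp(-r)`.
#'
#' @param r Non-negative hazard rate per year.
#' @return Annual probability in \[0, 1).
#' @export
rate_to_prob <- function(r) {
  if (any(r < 0)) stop("rate must be non-negative", call. = FALSE)
  1 - exp(-r)
}

#' Synthetic general-population life table (Gompertz)
#'
#' Smooth adult life table with hazard `h(x) = a exp(b x)` and annual death
#' probability `q(x) = 1 - exp(-h(x))`. The default coefficients were fit to
#' the WHO Thailand both-sexes abridged life table so that the packaged
#' table is Thai-like (roughly q(50) = 0.006, q(80) = 0.077); a real life
#' table can be supplied instead via [read_life_table()]. The table is
#' synthetic: it stands in for the external WHO download.
#'
#' @param ages Integer ages covered (contiguous).
#' @param a,b Gompertz coefficients (per year).
#' @return A `kt_life_table`: data frame with columns `age`, `q`.
#' @export
synthetic_life_table <- function(ages = 30:110, a = 8.2e-5, b = 0.086) {
  q <- 1 - exp(-a * exp(b * ages))
  as_life_table(data.frame(age = as.integer(ages), q = q))
}

as_life_table <- function(df) {
  stopifnot(all(c("age", "q") %in% names(df)))
  df <- df[order(df$age), c("age", "q")]
  if (any(diff(df$age) != 1L))
    stop("life-table ages must be contiguous integers", call. = FALSE)
  if (any(df$q < 0 | df$q > 1))
    stop("life-table q values must lie in [0, 1]", call. = FALSE)
  class(df) <- c("kt_life_table", "data.frame")
  df
}

#' Read a life table from a delimited text file
#'
#' Expects a header row with columns `age` (integer years) and `q` (annual
#' death probability); tab- or comma-delimited.
#'
#' @param path File path.
#' @return A `kt_life_table` data frame.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "", header = TRUE,
                          check.names = FALSE)
  if (ncol(df) == 1L) df <- utils::read.csv(path)
  as_life_table(df)
}

#' Write a life table to tab-delimited text
#' @param lt A `kt_life_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  utils::write.table(as.data.frame(lt), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mortality model: life table + SMR bands + ESKD-vs-KT ratio
#'
#' Combines a general-population life table with age-banded standardized
#' mortality ratios (SMR) for dialysis patients and a pooled
#' dialysis-vs-transplant mortality ratio. Dialysis-state mortality at age
#' `x` is the general-population hazard times `smr(x)`; mortality in the
#' three transplanted states is the general-population hazard times
#' `smr(x) / eskd_kt_ratio`. All scaling is done on the hazard (rate)
#' scale, which keeps the resulting probabilities in \[0, 1\] for any SMR.
#'
#' @param life_table A `kt_life_table` (default: the packaged synthetic
#'   Thai-like Gompertz table).
#' @param smr_bands Data frame with columns `age_low`, `age_high`, `smr`;
#'   bands must tile the ages of interest without gaps or overlaps.
#' @param eskd_kt_ratio Positive mortality ratio of dialysis-ESKD vs
#'   transplanted patients.
#' @return An object of class `kt_mortality`.
#' @seealso [death_prob()], [default_mortality()]
#' @export
mortality_model <- function(life_table = synthetic_life_table(),
                            smr_bands, eskd_kt_ratio) {
  stopifnot(inherits(life_table, "kt_life_table"),
            is.data.frame(smr_bands),
            all(c("age_low", "age_high", "smr") %in% names(smr_bands)))
  smr_bands <- smr_bands[order(smr_bands$age_low), ]
  if (any(smr_bands$smr <= 0) || eskd_kt_ratio <= 0)
    stop("all mortality ratios must be positive", call. = FALSE)
  if (nrow(smr_bands) > 1L &&
      any(smr_bands$age_low[-1L] != smr_bands$age_high[-nrow(smr_bands)] + 1L))
    stop("SMR bands must be contiguous (no gaps or overlaps)", call. = FALSE)
  structure(list(life_table = life_table, smr_bands = smr_bands,
                 eskd_kt_ratio = as.numeric(eskd_kt_ratio)),
            class = "kt_mortality")
}

#' Default mortality model from a parameter set
#'
#' Builds the banded-SMR mortality model from the `smr_*` and
#' `mortality_ratio_eskd_kt` parameters. The youngest band (50-59 years) is
#' extended downward so that simulated patients entering below age 50 are
#' covered.
#'
#' @param params A `kt_params` object.
#' @param life_table Optional life table override.
#' @return A `kt_mortality` object.
#' @export
default_mortality <- function(params, life_table = synthetic_life_table()) {
  bands <- data.frame(
    age_low = c(0L, 60L, 70L, 80L),
    age_high = c(59L, 69L, 79L, 200L),
    smr = c(param_value(params, "smr_50_59"),
            param_value(params, "smr_60_69"),
            param_value(params, "smr_70_79"),
            param_value(params, "smr_80plus"))
  )
  mortality_model(life_table, bands,
                  param_value(params, "mortality_ratio_eskd_kt"))
}

smr_at_age <- function(model, age) {
  b <- model$smr_bands
  idx <- findInterval(age, c(b$age_low, b$age_high[nrow(b)] + 1L))
  if (any(idx < 1L | idx > nrow(b)))
    stop("age outside SMR band coverage", call. = FALSE)
  b$smr[idx]
}

#' Annual death probability by age and health state
#'
#' General-population `q(age)` is converted to a hazard, multiplied by the
#' age-band SMR (dialysis state) or SMR divided by the ESKD-vs-KT ratio
#' (the three transplanted states), and converted back to a probability.
#'
#' @param model A `kt_mortality` object.
#' @param age Age(s) in years; must be covered by the life table.
#' @param state Health-state label: `"dialysis"`, `"kt"`, `"post1"` or
#'   `"subsequent"`.
#' @return Annual death probability (vectorized over `age`).
#' @export
death_prob <- function(model, age,
                       state = c("dialysis", "kt", "post1", "subsequent")) {
  state <- match.arg(state)
  lt <- model$life_table
  i <- match(age, lt$age)
  if (anyNA(i)) stop("age outside life table range", call. = FALSE)
  mult <- smr_at_age(model, age)
  if (state != "dialysis") mult <- mult / model$eskd_kt_ratio
  rate_to_prob(prob_to_rate(lt$q[i]) * mult)
}

# per-cycle death-probability schedule for the cohort engine:
# matrix with one row per age, columns dialysis / kt
death_prob_schedule <- function(model, ages) {
  cbind(dialysis = death_prob(model, ages, "dialysis"),
        kt = death_prob(model, ages, "kt"))
}

#' @export
print.kt_mortality <- function(x, ...) {
  cat("<kt_mortality> life table ages ",
      min(x$life_table$age), "-", max(x$life_table$age),
      "; ESKD/KT ratio ", x$eskd_kt_ratio, "\n", sep = "")
  print(x$smr_bands, row.names = FALSE)
  invisible(x)
}
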