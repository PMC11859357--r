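# OGTT analysis: per-case linear calibration between the 1550 nm differential
# absorbance and reference glucose, and cohort-level summaries.

#' An OGTT time-series case
#'
#' @param time Sampling times (minutes), strictly increasing.
#' @param cg Reference blood glucose (mmol/L, mean of two meter readings),
#'   positive.
#' @param ad_1550 Differential absorbance at 1550 nm (a.u.).
#' @param condition `"pre_stimulated"` (blood flow pre-stimulated by heating)
#'   or `"control"` (natural skin temperature).
#' @param subject_meta Optional list (age group, sex, ...).
#' @return An object of class `ogtt_case`.
#' @export
ogtt_case <- function(time, cg, ad_1550,
                      condition = c("pre_stimulated", "control"),
                      subject_meta = list()) {
  condition <- if (is.character(condition) && length(condition) == 1 &&
                   !condition %in% c("pre_stimulated", "control")) condition
               else match.arg(condition)
  if (length(time) != length(cg) || length(time) != length(ad_1550))
    stop("`time`, `cg`, `ad_1550` must have equal length", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE))
    stop("`time` must be strictly increasing", call. = FALSE)
  if (any(cg <= 0)) stop("`cg` must be positive", call. = FALSE)
  structure(list(time = as.numeric(time), cg = as.numeric(cg),
                 ad_1550 = as.numeric(ad_1550), condition = condition,
                 subject_meta = subject_meta),
            class = "ogtt_case")
}

#' @export
print.ogtt_case <- function(x, ...) {
  cat(sprintf("<ogtt_case> %s, %d samples over %g min, cg %.1f-%.1f mmol/L\n",
              x$condition, length(x$time), max(x$time) - min(x$time),
              min(x$cg), max(x$cg)))
  invisible(x)
}

#' Linear calibration fit for one OGTT case
#'
#' Ordinary least squares predicting glucose from the optical signal,
#' Cg = intercept + slope * A_D, so residuals -- and hence the RMSE -- are in
#' mmol/L. The reported R is the Pearson correlation between A_D and Cg.
#'
#' @param case An [ogtt_case()] with at least 3 samples.
#' @return A `case_fit`: list with `slope` (mmol/L per a.u.), `intercept`
#'   (mmol/L), `r`, `rmse` (mmol/L), `n` and `condition`.
#' @export
fit_case <- function(case) {
  stopifnot(inherits(case, "ogtt_case"))
  if (length(case$time) < 3)
    stop("need at least 3 samples to fit", call. = FALSE)
  if (sd(case$ad_1550) == 0)
    stop("degenerate fit: A_D is constant", call. = FALSE)
  fit <- lm(cg ~ ad_1550, data = data.frame(cg = case$cg,
                                            ad_1550 = case$ad_1550))
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = cor(case$ad_1550, case$cg),
                 rmse = sqrt(mean(residuals(fit)^2)),
                 n = length(case$time),
                 condition = case$condition),
            class = "case_fit")
}

#' @export
print.case_fit <- function(x, ...) {
  cat(sprintf("<case_fit> R=%.3f, RMSE=%.2f mmol/L, slope=%.1f mmol/L per a.u. (n=%d)\n",
              x$r, x$rmse, x$slope, x$n))
  invisible(x)
}

#' Cohort summary of OGTT calibration fits
#'
#' Bins cases by correlation coefficient at the thresholds 0.85, 0.7 and 0.5
#' (strict ">": a case with R exactly at a threshold falls into the lower
#' bin) and averages the RMSE across cases.
#'
#' @param fits List of `case_fit` objects from [fit_case()].
#' @param condition Condition label for the summary row.
#' @return A `cohort_summary`: list with `counts` (named vector over the four
#'   R bins), `average_rmse` (mmol/L), `n_cases`, `condition`.
#' @export
summarize_cohort <- function(fits, condition = "unspecified") {
  if (!length(fits)) stop("no fits to summarise", call. = FALSE)
  r <- vapply(fits, `[[`, 0, "r")
  counts <- c(
    "R>0.85" = sum(r > 0.85),
    "0.85>=R>0.7" = sum(r <= 0.85 & r > 0.7),
    "0.7>=R>0.5" = sum(r <= 0.7 & r > 0.5),
    "R<=0.5" = sum(r <= 0.5))
  structure(list(counts = counts,
                 average_rmse = mean(vapply(fits, `[[`, 0, "rmse")),
                 n_cases = length(fits),
                 condition = condition),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %s (n=%d): ", x$condition, x$n_cases))
  cat(paste(names(x$counts), x$counts, sep = "=", collapse = ", "))
  cat(sprintf("; average RMSE %.2f mmol/L\n", x$average_rmse))
  invisible(x)
}

#' Cohort summary as a one-row data.frame
#'
#' @param summary A `cohort_summary`.
#' @return data.frame row suitable for rbind-ing across conditions.
#' @export
cohort_summary_row <- function(summary) {
  stopifnot(inherits(summary, "cohort_summary"))
  data.frame(condition = summary$condition,
             n_cases = summary$n_cases,
             r_gt_0.85 = unname(summary$counts[1]),
             r_0.7_to_0.85 = unname(summary$counts[2]),
             r_0.5_to_0.7 = unname(summary$counts[3]),
             r_le_0.5 = unname(summary$counts[4]),
             average_rmse = summary$average_rmse)
}
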