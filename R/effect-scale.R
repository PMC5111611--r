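#' Standard error from a 95% confidence interval
#'
#' `(upper - lower) / 3.92` after an optional natural-log transform of both
#' bounds. The log transform is the route for adjusted ratio measures whose
#' SE is not reported directly: the sampling distribution of a ratio estimate
#' is approximately normal on the log scale, and a published 95% CI spans
#' 3.92 standard errors there. The divisor is 3.92 by convention (not
#' 2 * qnorm(0.975)).
#'
#' @param ci_lower,ci_upper Confidence bounds, `ci_upper > ci_lower`; both
#'   must be positive when `log_scale = TRUE`.
#' @param log_scale Transform bounds by `log()` first (ratio measures).
#' @return The standard error, a positive scalar.
#' @examples
#' se_from_ci(0.5, 2.0, log_scale = TRUE)   # 0.353646
#' @export
se_from_ci <- function(ci_lower, ci_upper, log_scale = FALSE) {
  if (!is.numeric(ci_lower) || !is.numeric(ci_upper) ||
      !is.finite(ci_lower) || !is.finite(ci_upper))
    stop("confidence bounds must be finite numbers", call. = FALSE)
  if (ci_upper <= ci_lower)
    stop("ci_upper must exceed ci_lower", call. = FALSE)
  if (log_scale) {
    if (ci_lower <= 0)
      stop("log-scale bounds must be positive", call. = FALSE)
    (log(ci_upper) - log(ci_lower)) / 3.92
  } else {
    (ci_upper - ci_lower) / 3.92
  }
}

#' Standard error of a log odds ratio from 2x2 counts
#'
#' `sqrt(1/a + 1/b + 1/c + 1/d)` where `a`/`b` are the experimental-arm
#' counts with/without the outcome and `c`/`d` the control-arm counts
#' with/without (so OR = (a/b)/(c/d)). Valid when none of the counts is very
#' small; zero cells are rejected rather than continuity-corrected.
#'
#' @param a,b,c,d Cell counts, all at least 1.
#' @return The standard error of the log odds ratio.
#' @examples
#' se_log_or_from_counts(10, 10, 10, 10)   # sqrt(0.4)
#' @export
se_log_or_from_counts <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (!is.numeric(counts) || length(counts) != 4L || any(!is.finite(counts)) ||
      any(counts != round(counts)) || any(counts < 0))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(counts == 0))
    stop("zero cell count: the log-OR standard error is undefined; ",
         "continuity corrections are out of scope", call. = FALSE)
  sqrt(sum(1 / counts))
}

#' Standard error of a mean difference from group summaries
#'
#' `sqrt(sd1^2/n1 + sd2^2/n2)`, the usual two-sample standard error of the
#' difference in means.
#'
#' @param sd1,sd2 Group standard deviations, positive.
#' @param n1,n2 Group sizes, at least 2.
#' @return The standard error of the mean difference.
#' @examples
#' se_md_from_groups(3, 9, 4, 16)   # sqrt(2)
#' @export
se_md_from_groups <- function(sd1, n1, sd2, n2) {
  if (!all(is.finite(c(sd1, n1, sd2, n2))))
    stop("group summaries must be finite", call. = FALSE)
  if (sd1 <= 0 || sd2 <= 0)
    stop("group SDs must be positive", call. = FALSE)
  if (n1 < 2 || n2 < 2 || n1 != round(n1) || n2 != round(n2))
    stop("group sizes must be integers >= 2", call. = FALSE)
  sqrt(sd1^2 / n1 + sd2^2 / n2)
}

#' Standard error from an effect and its t statistic
#'
#' `|effect / t|`, the back-calculation used when a paper reports a mean
#' difference (or regression coefficient) and its t-test value but no SE.
#'
#' @param effect The reported effect.
#' @param t_value The t statistic; must be nonzero.
#' @return The standard error.
#' @examples
#' se_from_t(2.0, 4.0)   # 0.5
#' @export
se_from_t <- function(effect, t_value) {
  if (!is.finite(effect) || !is.finite(t_value))
    stop("effect and t_value must be finite", call. = FALSE)
  if (t_value == 0)
    stop("t_value must be nonzero", call. = FALSE)
  abs(effect / t_value)
}

#' Published trial effect summary
#'
#' Collects a published effect in the form papers print it: a measure type
#' (`"MD"` mean difference, `"OR"` odds ratio, `"RR"` relative risk, `"RaR"`
#' rate ratio), the reported value, and at least one source from which its
#' standard error can be derived — a reported SE, a 95% CI, a t statistic,
#' 2x2 counts, or group SDs and sizes. The SE is resolved on construction
#' (in that order of preference); for ratio measures the resolved SE is on
#' the natural-log scale.
#'
#' @param measure_type One of `"MD"`, `"OR"`, `"RR"`, `"RaR"`.
#' @param value The reported effect; ratio measures must be positive.
#' @param se Reported SE (log scale for ratio measures), if available.
#' @param ci_lower,ci_upper 95% CI bounds on the reported (raw) scale.
#' @param t_value t statistic for a mean difference.
#' @param counts Length-4 vector `c(a, b, c, d)` of 2x2 cell counts.
#' @param group_sd,group_n Length-2 vectors of per-arm SDs and sizes.
#' @return An object of class `bfrct_published` with the resolved `se`.
#' @examples
#' published_effect("OR", 0.51, se = 0.50)
#' published_effect("MD", 2.0, t_value = 4.0)
#' @export
published_effect <- function(measure_type = c("MD", "OR", "RR", "RaR"), value,
                             se = NULL, ci_lower = NULL, ci_upper = NULL,
                             t_value = NULL, counts = NULL,
                             group_sd = NULL, group_n = NULL) {
  measure_type <- match.arg(measure_type)
  ratio <- measure_type != "MD"
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("value must be a single finite number", call. = FALSE)
  if (ratio && value <= 0)
    stop(sprintf("a %s must be positive", measure_type), call. = FALSE)
  resolved <- if (!is.null(se)) {
    if (!is.numeric(se) || se <= 0) stop("se must be positive", call. = FALSE)
    se
  } else if (!is.null(ci_lower) && !is.null(ci_upper)) {
    se_from_ci(ci_lower, ci_upper, log_scale = ratio)
  } else if (!is.null(t_value)) {
    if (ratio) stop("t-based SEs apply to mean differences", call. = FALSE)
    se_from_t(value, t_value)
  } else if (!is.null(counts)) {
    se_log_or_from_counts(counts[1], counts[2], counts[3], counts[4])
  } else if (!is.null(group_sd) && !is.null(group_n)) {
    se_md_from_groups(group_sd[1], group_n[1], group_sd[2], group_n[2])
  } else {
    stop("no standard-error source given (se, CI, t, counts, or group SDs)",
         call. = FALSE)
  }
  structure(list(measure_type = measure_type, value = value, se = resolved),
            class = "bfrct_published")
}

#' Convert a published effect to the analysis scale
#'
#' Mean differences pass through unchanged; ratio measures (OR/RR/RaR) are
#' taken to the natural-log scale, on which their sampling distribution is
#' approximately normal (the SE is interpreted as already being on the log
#' scale). The value is then replaced by its magnitude with
#' `oriented = TRUE`, matching the half-normal engine's convention that the
#' observed effect is entered as a distance from the null along the
#' predicted direction of benefit. Note the magnitude is taken even when the
#' observed effect opposes the prediction — the convention under which the
#' packaged re-analysis fixture reproduces its published Bayes factors.
#'
#' @param pub A [published_effect()], or a measure-type string (with `value`
#'   and `se`).
#' @param predicted_direction `"benefit_up"` or `"benefit_down"`; recorded
#'   for provenance (the magnitude convention makes the conversion itself
#'   direction-free).
#' @param value,se Effect and SE when `pub` is a measure-type string.
#' @return An oriented [effect_estimate()].
#' @examples
#' to_analysis_scale("OR", value = 0.51, se = 0.50)   # |ln 0.51| = 0.67334
#' to_analysis_scale("MD", value = -1.87, se = 2.31)  # 1.87
#' @export
to_analysis_scale <- function(pub, predicted_direction = c("benefit_up", "benefit_down"),
                              value = NULL, se = NULL) {
  predicted_direction <- match.arg(predicted_direction)
  if (!inherits(pub, "bfrct_published"))
    pub <- published_effect(pub, value = value, se = se)
  v <- if (pub$measure_type == "MD") pub$value else log(pub$value)
  effect_estimate(abs(v), pub$se, oriented = TRUE)
}

#' Half-normal prior SD from a predicted effect
#'
#' The expected effect size, on the analysis scale, used as the SD of the
#' half-normal H1 prior: `|predicted|` for a mean difference,
#' `|ln(predicted)|` for a ratio measure. A prediction equal to the measure's
#' null value (0 for MD, 1 for ratios) is rejected — it would collapse the
#' prior to the null point.
#'
#' @param measure_type One of `"MD"`, `"OR"`, `"RR"`, `"RaR"`.
#' @param predicted_value The expected effect as printed (raw scale).
#' @return The prior SD, a positive scalar.
#' @examples
#' prior_sd_from_prediction("MD", 4.65)    # 4.65
#' prior_sd_from_prediction("OR", 1.51)    # ln 1.51 = 0.41211
#' @export
prior_sd_from_prediction <- function(measure_type = c("MD", "OR", "RR", "RaR"),
                                     predicted_value) {
  measure_type <- match.arg(measure_type)
  if (!is.numeric(predicted_value) || length(predicted_value) != 1L ||
      !is.finite(predicted_value))
    stop("predicted_value must be a single finite number", call. = FALSE)
  if (measure_type == "MD") {
    if (predicted_value == 0)
      stop("a predicted mean difference of 0 gives a degenerate prior",
           call. = FALSE)
    abs(predicted_value)
  } else {
    if (predicted_value <= 0)
      stop(sprintf("a predicted %s must be positive", measure_type), call. = FALSE)
    if (predicted_value == 1)
      stop(sprintf("a predicted %s of 1 (the null value) gives a degenerate prior",
                   measure_type), call. = FALSE)
    abs(log(predicted_value))
  }
}
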