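#' Evidence classification of Bayes factors
#'
#' Two conventional schemes for reading a Bayes factor (H1 over H0):
#'
#' * [jeffreys_band()] assigns the full eleven-band Jeffreys scale with
#'   boundaries at 1/100, 1/30, 1/10, 1/3, 1, 3, 10, 30, 100. Bands are
#'   left-closed and right-open on the BF axis, so a boundary value belongs
#'   to the band it opens (BF = 3 is already "moderate evidence for the
#'   experimental hypothesis"); exact ties are vanishingly rare at full
#'   precision anyway.
#' * [threeway()] applies the working rule that BF > 3 is sufficient
#'   evidence for the experimental hypothesis, BF < 1/3 sufficient evidence
#'   for the null, and anything between means the data are insensitive —
#'   they fail to discriminate the hypotheses, which is distinct from
#'   evidence of no effect.
#' * [direction_subclass()] splits the insensitive zone by which hypothesis
#'   the data lean toward, judged on the 1-decimal reported value: above 1
#'   leaning toward an effect, below 1 toward the null, exactly 1 (after
#'   rounding) no evidence either way.
#'
#' All three are vectorized over `bf`.
#'
#' @param bf Positive Bayes factor(s).
#' @return For `jeffreys_band`, a factor with the eleven band labels (null
#'   to experimental). For `threeway`, a factor with levels `supports_null`,
#'   `insensitive`, `supports_effect`. For `direction_subclass`, a factor
#'   with levels `toward_null`, `no_evidence`, `toward_effect`.
#' @examples
#' jeffreys_band(c(17.5, 1, 0.01))
#' threeway(c(5.6, 0.2, 2.8))
#' direction_subclass(c(1.4, 0.9, 1.04))
#' @name evidence
NULL

jeffreys_levels <- c(
  "extreme evidence for null hypothesis",
  "very strong evidence for null hypothesis",
  "strong evidence for null hypothesis",
  "moderate evidence for null hypothesis",
  "anecdotal evidence for null hypothesis",
  "no evidence",
  "anecdotal evidence for experimental hypothesis",
  "moderate evidence for experimental hypothesis",
  "strong evidence for experimental hypothesis",
  "very strong evidence for experimental hypothesis",
  "extreme evidence for experimental hypothesis")

check_bf <- function(bf) {
  if (!is.numeric(bf) || any(!is.finite(bf)) || any(bf <= 0))
    stop("Bayes factors must be finite and positive", call. = FALSE)
}

#' @rdname evidence
#' @export
jeffreys_band <- function(bf) {
  check_bf(bf)
  cuts <- c(1/100, 1/30, 1/10, 1/3, 1, 3, 10, 30, 100)
  # bands are left-closed / right-open on the BF axis (so BF = 3 is already
  # moderate evidence for an effect and BF = 1/100 is still "very strong",
  # not "extreme", for the null); exactly 1 is its own "no evidence" point.
  idx <- ifelse(bf < 1, findInterval(bf, cuts) + 1L,
         ifelse(bf == 1, 6L, findInterval(bf, cuts) + 2L))
  factor(jeffreys_levels[idx], levels = jeffreys_levels)
}

#' @rdname evidence
#' @export
threeway <- function(bf) {
  check_bf(bf)
  out <- ifelse(bf > 3, "supports_effect",
         ifelse(bf < 1/3, "supports_null", "insensitive"))
  factor(out, levels = c("supports_null", "insensitive", "supports_effect"))
}

#' @rdname evidence
#' @export
direction_subclass <- function(bf) {
  check_bf(bf)
  if (any(bf < 1/3 | bf > 3))
    stop("direction_subclass is defined only inside the insensitive zone ",
         "[1/3, 3]", call. = FALSE)
  r <- round(bf, 1)
  out <- ifelse(r > 1, "toward_effect",
         ifelse(r < 1, "toward_null", "no_evidence"))
  factor(out, levels = c("toward_null", "no_evidence", "toward_effect"))
}
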