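#' Two-arm trial scenario
#'
#' Describes the data-generating process for a synthetic two-arm randomized
#' trial reported only through summary statistics, the input form the Bayes
#' factor engine works on.
#'
#' * `continuous`: each arm is an i.i.d. normal sample with SD `sd_outcome`;
#'   the treated-arm mean exceeds the control mean by `true_effect` (a mean
#'   difference). The trial reports the difference in sample means and its
#'   standard error from the sample SDs ([se_md_from_groups()]).
#' * `binary`: each arm is a binomial count; the control event probability
#'   is `control_rate` and the treated probability is shifted by
#'   `true_effect` on the log-odds scale. The trial reports the sample log
#'   odds ratio and its 2x2-count standard error
#'   ([se_log_or_from_counts()]).
#'
#' @param outcome_kind `"continuous"` or `"binary"`.
#' @param n_per_arm Participants per arm, at least 2.
#' @param true_effect True mean difference, or true log odds ratio.
#' @param sd_outcome Outcome SD (continuous only), positive.
#' @param control_rate Control-arm event probability (binary only), in (0,1).
#' @return An object of class `bfrct_scenario`.
#' @examples
#' trial_scenario("continuous", n_per_arm = 50, true_effect = 0.5)
#' trial_scenario("binary", n_per_arm = 200, true_effect = log(1.5),
#'                control_rate = 0.3)
#' @export
trial_scenario <- function(outcome_kind = c("continuous", "binary"),
                           n_per_arm, true_effect,
                           sd_outcome = 1, control_rate = NULL) {
  outcome_kind <- match.arg(outcome_kind)
  if (!is.numeric(n_per_arm) || n_per_arm < 2 || n_per_arm != round(n_per_arm))
    stop("n_per_arm must be an integer >= 2", call. = FALSE)
  if (!is.numeric(true_effect) || !is.finite(true_effect))
    stop("true_effect must be finite", call. = FALSE)
  if (outcome_kind == "continuous") {
    if (!is.numeric(sd_outcome) || sd_outcome <= 0)
      stop("sd_outcome must be positive", call. = FALSE)
    control_rate <- NULL
  } else {
    if (is.null(control_rate) || !is.numeric(control_rate) ||
        control_rate <= 0 || control_rate >= 1)
      stop("binary scenarios need control_rate in (0, 1)", call. = FALSE)
    treated <- stats::plogis(stats::qlogis(control_rate) + true_effect)
    if (treated <= 0 || treated >= 1)
      stop("implied treated-arm rate is outside (0, 1)", call. = FALSE)
  }
  structure(list(outcome_kind = outcome_kind, n_per_arm = as.integer(n_per_arm),
                 true_effect = true_effect, sd_outcome = sd_outcome,
                 control_rate = control_rate),
            class = "bfrct_scenario")
}

#' Simulate one trial's summary statistics
#'
#' Draws one synthetic trial under a scenario and returns its summary-level
#' effect estimate (un-oriented: the sign of the estimate is kept).
#' Binary trials with a zero cell in the 2x2 table — where the log-OR
#' standard error is undefined — are redrawn, and the number of redraws is
#' recorded in the result's `resamples` attribute.
#'
#' @param scn A [trial_scenario()].
#' @param seed Optional integer seed for reproducibility.
#' @return An (un-oriented) [effect_estimate()]; binary results carry a
#'   `resamples` attribute.
#' @examples
#' simulate_trial_summary(trial_scenario("continuous", 50, 0.5), seed = 1)
#' @export
simulate_trial_summary <- function(scn, seed = NULL) {
  stopifnot(inherits(scn, "bfrct_scenario"))
  if (!is.null(seed)) set.seed(seed)
  if (scn$outcome_kind == "continuous") {
    ctrl <- stats::rnorm(scn$n_per_arm, 0, scn$sd_outcome)
    trt <- stats::rnorm(scn$n_per_arm, scn$true_effect, scn$sd_outcome)
    est <- effect_estimate(
      mean(trt) - mean(ctrl),
      se_md_from_groups(stats::sd(ctrl), scn$n_per_arm,
                        stats::sd(trt), scn$n_per_arm))
    est
  } else {
    p0 <- scn$control_rate
    p1 <- stats::plogis(stats::qlogis(p0) + scn$true_effect)
    n <- scn$n_per_arm
    resamples <- 0L
    repeat {
      a <- stats::rbinom(1L, n, p1)   # treated with outcome
      c_ <- stats::rbinom(1L, n, p0)  # control with outcome
      b <- n - a
      d <- n - c_
      if (all(c(a, b, c_, d) > 0)) break
      resamples <- resamples + 1L
      if (resamples > 10000L)
        stop("zero cells persist after 10000 resamples; ",
             "the scenario's rates are too extreme for n_per_arm", call. = FALSE)
    }
    est <- effect_estimate(log((a / b) / (c_ / d)),
                           se_log_or_from_counts(a, b, c_, d))
    attr(est, "resamples") <- resamples
    est
  }
}

#' Monte-Carlo operating characteristics of the Bayes factor
#'
#' Repeatedly simulates trials under a scenario, computes the Bayes factor
#' of each against the given H1 prior (with the observed effect
#' magnitude-oriented toward the predicted direction of benefit, as in the
#' engine's convention), and reports the long-run proportions of runs
#' crossing the efficacy threshold (BF > 3), the futility threshold
#' (BF < 1/3), or remaining insensitive.
#'
#' @param scn A [trial_scenario()].
#' @param prior A `bfrct_prior` for H1.
#' @param n_reps Number of simulated trials, at least 100.
#' @param seed Integer seed.
#' @param method Bayes factor path; the closed form is the default for
#'   speed (it matches quadrature to the integration tolerance).
#' @return An object of class `bfrct_oc`: list with `p_bf_above_3`,
#'   `p_bf_below_third`, `p_insensitive` (summing to 1), `n_reps`,
#'   `scenario`, `prior`, and the vector of simulated `bf` values.
#' @examples
#' operating_characteristics(
#'   trial_scenario("continuous", 50, 0), prior_halfnormal(0.5),
#'   n_reps = 200, seed = 1)
#' @export
operating_characteristics <- function(scn, prior, n_reps, seed = 1,
                                      method = "closed_form") {
  stopifnot(inherits(scn, "bfrct_scenario"), inherits(prior, "bfrct_prior"))
  if (!is.numeric(n_reps) || n_reps < 100)
    stop("n_reps must be at least 100", call. = FALSE)
  set.seed(seed)
  bf <- vapply(seq_len(n_reps), function(i) {
    est <- simulate_trial_summary(scn)
    oriented <- effect_estimate(abs(est$value), est$se, oriented = TRUE)
    bayes_factor(oriented, prior, method = method)$bf
  }, numeric(1))
  out <- list(p_bf_above_3 = mean(bf > 3),
              p_bf_below_third = mean(bf < 1/3),
              p_insensitive = mean(bf >= 1/3 & bf <= 3),
              n_reps = as.integer(n_reps), scenario = scn, prior = prior,
              bf = bf)
  class(out) <- "bfrct_oc"
  out
}

#' @export
print.bfrct_oc <- function(x, ...) {
  cat(sprintf("Operating characteristics over %d simulated trials:\n", x$n_reps))
  cat(sprintf("  P(BF > 3)   = %.3f   (evidence for an effect)\n", x$p_bf_above_3))
  cat(sprintf("  P(BF < 1/3) = %.3f   (evidence for the null)\n", x$p_bf_below_third))
  cat(sprintf("  P(insensitive) = %.3f\n", x$p_insensitive))
  invisible(x)
}

#' Sequential Bayes-factor monitoring of one trial
#'
#' Accrues participants in batches and recomputes the Bayes factor at each
#' batch boundary, stopping recruitment when the accumulating data give
#' sufficient evidence for the effect (BF > 3, efficacy) or for the null
#' (BF < 1/3, futility), or when `max_n` per arm is reached. While the data
#' remain insensitive, recruitment continues. No multiplicity adjustment is
#' applied across looks: the Bayes factor at each look is simply the
#' current evidence.
#'
#' For binary outcomes, a look whose cumulative 2x2 table still contains a
#' zero cell is skipped (recruitment continues), since the log-OR standard
#' error is undefined there.
#'
#' @param scn A [trial_scenario()]; its `n_per_arm` is ignored in favour of
#'   the accrual schedule.
#' @param prior A `bfrct_prior` for H1.
#' @param batch Participants per arm added between looks, at least 1.
#' @param max_n Maximum participants per arm, at least `batch`.
#' @param seed Integer seed.
#' @param method Bayes factor path (closed form by default).
#' @return An object of class `bfrct_stop`: list with `stop_reason`
#'   (`"efficacy"`, `"futility"` or `"max_n"`), `n_at_stop` (per arm),
#'   `bf_at_stop`, and a `looks` data frame (`n`, `estimate`, `se`, `bf`).
#' @examples
#' sequential_bf_monitor(trial_scenario("continuous", 2, 1),
#'                       prior_halfnormal(1), batch = 25, max_n = 100, seed = 1)
#' @export
sequential_bf_monitor <- function(scn, prior, batch, max_n, seed = 1,
                                  method = "closed_form") {
  stopifnot(inherits(scn, "bfrct_scenario"), inherits(prior, "bfrct_prior"))
  if (!is.numeric(batch) || batch < 1 || batch != round(batch))
    stop("batch must be an integer >= 1", call. = FALSE)
  if (!is.numeric(max_n) || max_n < batch)
    stop("max_n must be at least batch", call. = FALSE)
  set.seed(seed)
  looks <- seq(batch, max_n, by = batch)
  if (looks[length(looks)] < max_n) looks <- c(looks, max_n)

  continuous <- scn$outcome_kind == "continuous"
  if (continuous) {
    ctrl <- stats::rnorm(max_n, 0, scn$sd_outcome)
    trt <- stats::rnorm(max_n, scn$true_effect, scn$sd_outcome)
  } else {
    p0 <- scn$control_rate
    p1 <- stats::plogis(stats::qlogis(p0) + scn$true_effect)
    ctrl <- stats::rbinom(max_n, 1L, p0)
    trt <- stats::rbinom(max_n, 1L, p1)
  }

  log_rows <- list()
  stop_reason <- "max_n"; bf_at_stop <- NA_real_; n_at_stop <- max_n
  for (n in looks) {
    est <- if (continuous) {
      if (n < 2) next
      effect_estimate(mean(trt[1:n]) - mean(ctrl[1:n]),
                      se_md_from_groups(stats::sd(ctrl[1:n]), n,
                                        stats::sd(trt[1:n]), n))
    } else {
      a <- sum(trt[1:n]); b <- n - a; c_ <- sum(ctrl[1:n]); d <- n - c_
      if (any(c(a, b, c_, d) == 0)) next   # evidence undefined; keep recruiting
      effect_estimate(log((a / b) / (c_ / d)),
                      se_log_or_from_counts(a, b, c_, d))
    }
    oriented <- effect_estimate(abs(est$value), est$se, oriented = TRUE)
    bf <- bayes_factor(oriented, prior, method = method)$bf
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(n = n, estimate = est$value, se = est$se, bf = bf)
    if (bf > 3) { stop_reason <- "efficacy"; bf_at_stop <- bf; n_at_stop <- n; break }
    if (bf < 1/3) { stop_reason <- "futility"; bf_at_stop <- bf; n_at_stop <- n; break }
    bf_at_stop <- bf
  }
  out <- list(stop_reason = stop_reason, n_at_stop = n_at_stop,
              bf_at_stop = bf_at_stop,
              looks = if (length(log_rows)) do.call(rbind, log_rows)
                      else data.frame(n = integer(), estimate = numeric(),
                                      se = numeric(), bf = numeric()))
  class(out) <- "bfrct_stop"
  out
}

#' @export
print.bfrct_stop <- function(x, ...) {
  cat(sprintf("Sequential monitoring: stopped for %s at n = %d per arm (BF = %.3g)\n",
              x$stop_reason, x$n_at_stop, x$bf_at_stop))
  invisible(x)
}
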