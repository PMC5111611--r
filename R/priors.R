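#' Prior models for the alternative hypothesis
#'
#' Constructors for the prior placed on the intervention effect under the
#' alternative hypothesis H1. Three shapes are supported:
#'
#' * **half-normal** — a normal centred at 0 folded onto the predicted
#'   direction of benefit; its `sd` is set to the expected effect size. This
#'   encodes "some effect in the predicted direction, smaller values more
#'   likely" and is the conservative default for re-analysing trial effects.
#' * **normal** — a two-sided normal with arbitrary `mean` and `sd`.
#' * **uniform** — a flat prior between `lower` and `upper`, useful when a
#'   minimally clinically significant value and a plausible upper bound can
#'   be stated.
#'
#' @param sd Positive scale parameter. For the half-normal this is the SD of
#'   the underlying normal before folding (the expected effect size on the
#'   analysis scale).
#' @param mean Centre of the normal prior (the half-normal is pinned at 0).
#' @param lower,upper Support of the uniform prior, `lower < upper`.
#'
#' @return An object of class `bfrct_prior` with a `shape` field and exactly
#'   the parameters of that shape.
#' @examples
#' prior_halfnormal(4.65)
#' prior_uniform(0, 2)
#' @export
prior_halfnormal <- function(sd) {
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0)
    stop("half-normal prior requires a single finite sd > 0", call. = FALSE)
  structure(list(shape = "half_normal", sd = as.numeric(sd), mean = 0),
            class = "bfrct_prior")
}

#' @rdname prior_halfnormal
#' @export
prior_normal <- function(mean, sd) {
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0)
    stop("normal prior requires a single finite sd > 0", call. = FALSE)
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean))
    stop("normal prior requires a single finite mean", call. = FALSE)
  structure(list(shape = "normal", mean = as.numeric(mean), sd = as.numeric(sd)),
            class = "bfrct_prior")
}

#' @rdname prior_halfnormal
#' @export
prior_uniform <- function(lower, upper) {
  if (!is.numeric(lower) || !is.numeric(upper) || length(lower) != 1L ||
      length(upper) != 1L || !is.finite(lower) || !is.finite(upper))
    stop("uniform prior requires finite scalar bounds", call. = FALSE)
  if (upper <= lower)
    stop("uniform prior requires upper > lower", call. = FALSE)
  structure(list(shape = "uniform", lower = as.numeric(lower), upper = as.numeric(upper)),
            class = "bfrct_prior")
}

#' Prior density on the effect
#'
#' Evaluates the density of a `bfrct_prior` at effect values `theta`. The
#' half-normal density on `theta >= 0` is twice the underlying normal density
#' and zero below 0.
#'
#' @param prior A `bfrct_prior`.
#' @param theta Numeric vector of effect values.
#' @return Numeric vector of densities.
#' @export
prior_density <- function(prior, theta) {
  stopifnot(inherits(prior, "bfrct_prior"))
  switch(prior$shape,
    half_normal = ifelse(theta >= 0, 2 * stats::dnorm(theta, 0, prior$sd), 0),
    normal      = stats::dnorm(theta, prior$mean, prior$sd),
    uniform     = stats::dunif(theta, prior$lower, prior$upper)
  )
}

#' @export
print.bfrct_prior <- function(x, ...) {
  desc <- switch(x$shape,
    half_normal = sprintf("half-normal(sd = %g), peak at 0", x$sd),
    normal      = sprintf("normal(mean = %g, sd = %g)", x$mean, x$sd),
    uniform     = sprintf("uniform(%g, %g)", x$lower, x$upper))
  cat("H1 prior:", desc, "\n")
  invisible(x)
}

# support of the prior, for quadrature limits
prior_support <- function(prior) {
  switch(prior$shape,
    half_normal = c(0, Inf),
    normal      = c(-Inf, Inf),
    uniform     = c(prior$lower, prior$upper)
  )
}
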