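# Random (value, se, sd) triples for oracle-agreement properties.
# Scales span [0.01, 100]; the observed value is drawn on the combined
# scale sqrt(se^2 + sd^2) (its marginal scale under H1), which keeps both
# likelihoods well inside double range.
random_triples <- function(n, seed) {
  set.seed(seed)
  data.frame(
    se = exp(stats::runif(n, log(0.01), log(100))),
    sd = exp(stats::runif(n, log(0.01), log(100)))
  ) |> transform(value = abs(stats::rnorm(n)) * sqrt(se^2 + sd^2))
}
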