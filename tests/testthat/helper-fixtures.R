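# Shared fixtures, built in code. The small raw study is simulated once per
# test run and reused by the preprocessing/pipeline tests.

tiny_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_study(cohort_config(n_participants = 8, seed = 42),
                               n_trials = 12)
    cache
  }
})

tiny_preprocessed <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      s <- tiny_study()
      cache <<- preprocess_cohort(s$samples, s$trials)
    }
    cache
  }
})

# two vectors with an exactly specified Pearson correlation
make_correlated <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- as.numeric(scale(stats::rnorm(n)))
  z <- stats::rnorm(n)
  z <- stats::residuals(stats::lm(z ~ x))
  z <- as.numeric(scale(z))
  list(x = x, y = r * x + sqrt(1 - r^2) * z)
}
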