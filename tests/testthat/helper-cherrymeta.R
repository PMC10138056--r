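# helpers shared across test files

# random study set with controllable weights
rand_studies <- function(k, theta = 0, tau2 = 0, equal_var = FALSE) {
  v <- if (equal_var) rep(0.2, k) else stats::runif(k, 0.05, 0.5)
  studies(paste0("s", seq_len(k)),
          stats::rnorm(k, theta, sqrt(v + tau2)), variance = v)
}

# brute-force pooled one-sided p for a subset, independent of package kernels
brute_p <- function(y, v, tau2 = 0) {
  w <- 1 / (v + tau2)
  pnorm(-sum(w * y) / sqrt(sum(w)))
}

extdata <- function(f) system.file("extdata", f, package = "cherrymeta")
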