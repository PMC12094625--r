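# Shared fixtures, built in code.

# A small, well-behaved parameter set with strictly positive components.
toy_params <- function() {
  model_params(
    Ac = 0.5, Cc = 0.1,
    loadings = c(0.8, 0.7, 0.5, 0.4),
    As = c(0.05, 0.10, 0.15, 0.20),
    Cs = c(0.02, 0.03, 0.04, 0.05),
    thresholds = threshold_from_prevalence(c(0.3, 0.2, 0.1, 0.05))
  )
}

# Independence: no factor, no familial components, unit unique environment.
independence_params <- function(prev = c(0.3, 0.2, 0.1, 0.05)) {
  model_params(
    Ac = 0, Cc = 0, loadings = rep(0, 4), As = rep(0, 4), Cs = rep(0, 4),
    thresholds = threshold_from_prevalence(prev)
  )
}

# Noise-free pattern counts: expected counts at the given per-class sizes.
expected_counts <- function(params, n_per_class, gh_nodes = 20L) {
  cls <- names(n_per_class)
  counts <- list(classes = list(), disorders = params$disorders,
                 n_vars = 2L * length(params$disorders))
  for (cl in cls) {
    counts$classes[[cl]] <-
      n_per_class[[cl]] * pattern_probabilities(params, cl, gh_nodes = gh_nodes)
  }
  counts$n_pairs <- vapply(counts$classes, sum, numeric(1))
  class(counts) <- "pattern_counts"
  counts
}

# Exact 2x2 cell probabilities of a bivariate normal with thresholds (ta, tb)
# and correlation rho: c(p00, p01, p10, p11).
exact_cells <- function(ta, tb, rho) {
  p11 <- bvn_upper(ta, tb, rho)
  pa <- pnorm(ta, lower.tail = FALSE)
  pb <- pnorm(tb, lower.tail = FALSE)
  c(1 - pa - pb + p11, pb - p11, pa - p11, p11)
}
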