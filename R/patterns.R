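# Response-pattern aggregation and model-implied pattern probabilities.
#
# A pair of members, each with nd binary diagnoses, produces a 2*nd-bit
# response pattern. Aggregating a dataset to per-class pattern counts is a
# sufficient statistic for the likelihood, and makes likelihood cost
# independent of the number of pairs.

#' Bit matrix of all response patterns
#'
#' Row r (1-based) is the binary expansion of pattern r-1; bit k (column k)
#' is member 1's diagnosis k for k <= nd and member 2's diagnosis k - nd
#' otherwise.
#'
#' @param n_vars number of binary variables (2 * number of disorders)
#' @return `2^n_vars` x `n_vars` 0/1 matrix
#' @keywords internal
pattern_bits <- function(n_vars) {
  r <- 0:(2^n_vars - 1)
  sapply(seq_len(n_vars), function(k) bitwAnd(bitwShiftR(r, k - 1L), 1L))
}

#' Aggregate a pair dataset into per-class pattern counts
#'
#' @param data a `pair_dataset` (see [simulate_pairs()]), with `p1_*`/`p2_*`
#'   binary columns
#' @return object of class `pattern_counts`: per relative class, a vector of
#'   counts over all response patterns
#' @export
pattern_counts <- function(data) {
  p1 <- grep("^p1_", names(data), value = TRUE)
  disorders <- sub("^p1_", "", p1)
  p2 <- paste0("p2_", disorders)
  if (!all(p2 %in% names(data))) stop("missing member-2 phenotype columns")
  cols <- c(p1, p2)
  nv <- length(cols)
  Y <- as.matrix(data[cols])
  idx <- as.integer(Y %*% 2^(seq_len(nv) - 1L)) + 1L
  classes <- intersect(relative_classes()$label, unique(data$relative_class))
  counts <- lapply(classes, function(cl) {
    tabulate(idx[data$relative_class == cl], nbins = 2^nv)
  })
  names(counts) <- classes
  structure(
    list(classes = counts, disorders = disorders, n_vars = nv,
         n_pairs = vapply(counts, sum, numeric(1))),
    class = "pattern_counts"
  )
}

#' @export
print.pattern_counts <- function(x, ...) {
  cat("Pattern counts over", 2^x$n_vars, "patterns (",
      paste(x$disorders, collapse = ", "), ")\n")
  print(x$n_pairs)
  invisible(x)
}

#' Write pattern counts as TSV (class, pattern bitstring, count)
#'
#' Only patterns with positive counts are written.
#'
#' @param counts a [pattern_counts()] object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pattern_counts <- function(counts, path) {
  B <- pattern_bits(counts$n_vars)
  rows <- do.call(rbind, lapply(names(counts$classes), function(cl) {
    v <- counts$classes[[cl]]
    pos <- which(v > 0)
    data.frame(
      relative_class = cl,
      pattern = apply(B[pos, , drop = FALSE], 1, paste, collapse = ""),
      count = v[pos], stringsAsFactors = FALSE
    )
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pattern counts written by [write_pattern_counts()]
#'
#' @param path TSV path
#' @param disorders disorder labels (bit order)
#' @return a `pattern_counts` object
#' @export
read_pattern_counts <- function(path, disorders = DISORDERS) {
  rows <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = c("character", "character", "integer"))
  nv <- nchar(rows$pattern[1])
  bits <- t(sapply(strsplit(rows$pattern, ""), as.integer))
  idx <- as.integer(bits %*% 2^(seq_len(nv) - 1L)) + 1L
  classes <- intersect(relative_classes()$label, unique(rows$relative_class))
  counts <- lapply(classes, function(cl) {
    sel <- rows$relative_class == cl
    v <- numeric(2^nv)
    v[idx[sel]] <- rows$count[sel]
    v
  })
  names(counts) <- classes
  structure(
    list(classes = counts, disorders = disorders[seq_len(nv / 2L)], n_vars = nv,
         n_pairs = vapply(counts, sum, numeric(1))),
    class = "pattern_counts"
  )
}

#' Model-implied probabilities of all response patterns for one class
#'
#' Each entry is the probability of the multivariate-normal orthant defined
#' by the thresholds and the pattern. The default method integrates over
#' the common-factor pair by two-dimensional Gauss-Hermite quadrature:
#' conditional on the pair of factor scores, disorders are independent and
#' each contributes a closed-form bivariate rectangle over its specific
#' components. `method = "genz"` instead evaluates each of the 256
#' orthants of the assembled 8x8 covariance with randomized quasi-Monte
#' Carlo; it is much slower and serves as a cross-check.
#'
#' @param params a [model_params()] object
#' @param cls relative class label or row
#' @param method `"quadrature"` (fast, deterministic) or `"genz"`
#' @param gh_nodes Gauss-Hermite order per factor dimension
#' @param seed seed for the `"genz"` method
#' @return vector of `2^(2*nd)` probabilities (pattern-index order, bit 1 =
#'   member 1 disorder 1), summing to 1 up to quadrature accuracy
#' @export
pattern_probabilities <- function(params, cls,
                                  method = c("quadrature", "genz"),
                                  gh_nodes = 20L, seed = 20250428L) {
  method <- match.arg(method)
  if (is.character(cls)) cls <- relative_class(cls)
  nd <- length(params$loadings)
  tau <- thresholds_for_class(params, cls$label)
  if (method == "genz") {
    S <- suppressWarnings(pair_liability_covariance(params, cls))
    B <- pattern_bits(2L * nd)
    tauv <- c(tau, tau)
    p <- apply(B, 1, function(bits) {
      lower <- ifelse(bits == 1L, tauv, -Inf)
      upper <- ifelse(bits == 1L, Inf, tauv)
      mvn_rectangle_probability(S, lower, upper, seed = seed)
    })
    return(p)
  }
  cell_probs_quadrature(params, cls, tau, gh_nodes)$pattern
}

# Conditional-on-factor cell probabilities on a GH grid, and the implied
# pattern probabilities. Shared by pattern_probabilities() and the
# full-pattern log-likelihood.
#' @keywords internal
cell_probs_quadrature <- function(params, cls, tau, gh_nodes = 20L) {
  nd <- length(params$loadings)
  t <- as.numeric(cls$is_twin)
  rF <- max(min(factor_pair_correlation(params, cls), 0.999), -0.999)
  gh <- gauss_hermite_normal(gh_nodes)
  m <- gh_nodes
  z1 <- rep(gh$nodes, times = m)
  z2 <- rep(gh$nodes, each = m)
  w <- rep(gh$weights, times = m) * rep(gh$weights, each = m)
  # symmetric square root of the 2x2 factor correlation: swapping the grid
  # axes swaps (F1, F2), so pattern probabilities are exactly exchangeable
  sp <- sqrt(1 + rF); sm <- sqrt(1 - rF)
  F1 <- (sp + sm) / 2 * z1 + (sp - sm) / 2 * z2
  F2 <- (sp - sm) / 2 * z1 + (sp + sm) / 2 * z2
  G <- length(F1)
  cells <- vector("list", nd)          # each: G x 4 (cell = 1 + y1 + 2*y2)
  for (i in seq_len(nd)) {
    v <- 1 - params$loadings[i]^2
    cv <- cls$alpha * params$As[i] + cls$gamma * params$Cs[i] + t * params$Ts[i]
    if (v < 1e-10) v <- 1e-10
    rho <- max(min(cv / v, 0.999), -0.999)
    a <- (tau[i] - params$loadings[i] * F1) / sqrt(v)
    b <- (tau[i] - params$loadings[i] * F2) / sqrt(v)
    p11 <- bvn_upper(a, b, rho)
    pa <- stats::pnorm(a, lower.tail = FALSE)
    pb <- stats::pnorm(b, lower.tail = FALSE)
    p10 <- pmax(pa - p11, 0)
    p01 <- pmax(pb - p11, 0)
    p00 <- pmax(1 - pa - pb + p11, 0)
    cells[[i]] <- cbind(p00, p10, p01, p11)
  }
  B <- pattern_bits(2L * nd)
  P <- matrix(1, G, nrow(B))
  for (i in seq_len(nd)) {
    cell_idx <- 1L + B[, i] + 2L * B[, nd + i]
    P <- P * cells[[i]][, cell_idx, drop = FALSE]
  }
  list(pattern = as.numeric(w %*% P), weights = w, cells = cells)
}

#' Model-implied pattern probabilities for the bivariate model
#'
#' 16 orthant probabilities of the 4 x 4 covariance from
#' [bivariate_pair_covariance()], evaluated with seeded Genz-Bretz QMC.
#'
#' @param bparams a [bivariate_params()] object
#' @param cls relative class label or row
#' @param seed QMC seed
#' @return vector of 16 probabilities (bit order: p1 disorder 1, p1
#'   disorder 2, p2 disorder 1, p2 disorder 2)
#' @export
bivariate_pattern_probabilities <- function(bparams, cls, seed = 20250428L) {
  if (is.character(cls)) cls <- relative_class(cls)
  S <- suppressWarnings(bivariate_pair_covariance(bparams, cls))
  tau <- bparams$thresholds[, class_group(cls$label)]
  tauv <- c(tau[1], tau[2], tau[1], tau[2])  # (p1_d1, p1_d2, p2_d1, p2_d2)
  B <- pattern_bits(4L)
  apply(B, 1, function(bits) {
    lower <- ifelse(bits == 1L, tauv, -Inf)
    upper <- ifelse(bits == 1L, Inf, tauv)
    mvn_rectangle_probability(S, lower, upper, seed = seed)
  })
}
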