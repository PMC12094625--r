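# Bivariate / multivariate normal rectangle probabilities.
#
# The bivariate survival function is the kernel of the composite pairwise
# likelihood and of the tetrachoric estimator, so it is implemented here as a
# fully vectorized quadrature (Drezner-Wesolowsky form of the tetrachoric
# integral, Gauss-Legendre on the arcsine arc). Correlations beyond 0.925 in
# magnitude fall back to mvtnorm's exact bivariate code; they never occur in
# the hot fitting loops.

.quad_cache <- new.env(parent = emptyenv())

#' Gauss-Legendre nodes and weights on [-1, 1]
#'
#' Computed by the Golub-Welsch eigen decomposition of the Jacobi matrix of
#' the Legendre recurrence. Cached per order.
#'
#' @param n number of nodes
#' @return list with `nodes` and `weights` (weights sum to 2)
#' @keywords internal
gauss_legendre <- function(n) {
  key <- paste0("gl", n)
  if (!is.null(.quad_cache[[key]])) return(.quad_cache[[key]])
  if (n == 1L) {
    out <- list(nodes = 0, weights = 2)
  } else {
    j <- seq_len(n - 1L)
    b <- j / sqrt(4 * j^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(j, j + 1L)] <- b
    J[cbind(j + 1L, j)] <- b
    e <- eigen(J, symmetric = TRUE)
    ord <- order(e$values)
    out <- list(nodes = e$values[ord], weights = 2 * e$vectors[1, ord]^2)
  }
  .quad_cache[[key]] <- out
  out
}

#' Gauss-Hermite rule for expectations against the standard normal density
#'
#' Probabilists' Hermite rule: `sum(w * f(x))` approximates `E[f(Z)]` for
#' `Z ~ N(0,1)`. Weights sum to 1.
#'
#' @param n number of nodes
#' @return list with `nodes` and `weights`
#' @keywords internal
gauss_hermite_normal <- function(n) {
  key <- paste0("gh", n)
  if (!is.null(.quad_cache[[key]])) return(.quad_cache[[key]])
  j <- seq_len(n - 1L)
  b <- sqrt(j)
  J <- matrix(0, n, n)
  J[cbind(j, j + 1L)] <- b
  J[cbind(j + 1L, j)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  out <- list(nodes = e$values[ord], weights = e$vectors[1, ord]^2)
  .quad_cache[[key]] <- out
  out
}

#' Bivariate standard-normal upper-orthant probability
#'
#' `P(X > h, Y > k)` for standard bivariate normal variables with
#' correlation `rho`. Vectorized over all three arguments (recycled to a
#' common length). Infinite thresholds are allowed.
#'
#' @param h,k lower cut points (the probability is of exceeding both)
#' @param rho correlation(s) in `[-1, 1]`
#' @param nodes Gauss-Legendre order for the arcsine quadrature
#' @return vector of probabilities
#' @examples
#' bvn_upper(0, 0, 0.5)            # 1/4 + asin(0.5)/(2*pi) = 1/3
#' bvn_upper(qnorm(0.8), qnorm(0.8), 0)  # 0.04
#' @export
bvn_upper <- function(h, k, rho, nodes = 20L) {
  n <- max(length(h), length(k), length(rho))
  h <- rep_len(as.numeric(h), n)
  k <- rep_len(as.numeric(k), n)
  rho <- rep_len(as.numeric(rho), n)
  if (any(is.na(rho)) || any(rho < -1 | rho > 1)) {
    stop("rho must lie in [-1, 1]")
  }
  p <- numeric(n)

  sh <- stats::pnorm(h, lower.tail = FALSE)
  sk <- stats::pnorm(k, lower.tail = FALSE)

  # degenerate / infinite cases
  inf_hi <- (h == Inf) | (k == Inf)
  p[inf_hi] <- 0
  lo_h <- (h == -Inf) & !inf_hi
  lo_k <- (k == -Inf) & !inf_hi
  p[lo_h] <- sk[lo_h]
  p[lo_k & !lo_h] <- sh[lo_k & !lo_h]
  done <- inf_hi | lo_h | lo_k

  one <- !done & rho >= 1
  p[one] <- pmin(sh[one], sk[one])
  mone <- !done & rho <= -1
  p[mone] <- pmax(0, sh[mone] + sk[mone] - 1)
  done <- done | one | mone

  mid <- !done & abs(rho) <= 0.925
  if (any(mid)) {
    gl <- gauss_legendre(nodes)
    hs <- h[mid]; ks <- k[mid]; rs <- rho[mid]
    a <- asin(rs)                      # integrate theta over [0, asin(rho)]
    # node matrix: theta_ij = a_i * (x_j + 1) / 2
    theta <- outer(a / 2, gl$nodes + 1)
    sth <- sin(theta)
    cth2 <- 1 - sth^2
    f <- exp(-(hs^2 + ks^2 - 2 * outer(hs * ks, rep(1, nodes)) * sth) / (2 * cth2))
    integral <- (a / 2) * as.numeric(f %*% gl$weights)
    p[mid] <- pmin(pmax(sh[mid] * sk[mid] + integral / (2 * pi), 0), 1)
  }

  high <- !done & !mid
  if (any(high)) {
    idx <- which(high)
    for (i in idx) {
      p[i] <- mvtnorm::pmvnorm(
        lower = c(h[i], k[i]), upper = c(Inf, Inf),
        corr = matrix(c(1, rho[i], rho[i], 1), 2)
      )[1]
    }
  }
  # a joint exceedance can never exceed either marginal exceedance
  pmin(pmax(p, 0), pmin(sh, sk))
}

#' Bivariate standard-normal density
#'
#' @param h,k coordinates
#' @param rho correlation strictly inside `(-1, 1)`
#' @return density values (vectorized)
#' @keywords internal
dbvn <- function(h, k, rho) {
  om <- 1 - rho^2
  exp(-(h^2 - 2 * rho * h * k + k^2) / (2 * om)) / (2 * pi * sqrt(om))
}

#' Multivariate normal rectangle probability
#'
#' Probability that a multivariate normal vector with covariance `cov` falls
#' in the hyper-rectangle `[lower, upper]`. Dimensions 1 and 2 use closed
#' forms (the bivariate case through [bvn_upper()] by inclusion-exclusion);
#' dimensions 3 to 8 use Genz-Bretz randomized quasi-Monte Carlo from
#' \pkg{mvtnorm}, seeded so that the result is reproducible.
#'
#' @param cov covariance matrix (symmetric positive semidefinite, dim <= 8)
#' @param lower,upper bound vectors, `-Inf`/`Inf` allowed
#' @param seed integer seed controlling the QMC point set (dims >= 3)
#' @param abseps requested absolute accuracy for the QMC estimate
#' @return a single probability
#' @examples
#' S <- matrix(c(1, .5, .5, 1), 2)
#' mvn_rectangle_probability(S, c(0, 0), c(Inf, Inf))  # 1/3
#' @export
mvn_rectangle_probability <- function(cov, lower, upper, seed = 20250428L,
                                      abseps = 1e-6) {
  cov <- as.matrix(cov)
  d <- nrow(cov)
  if (d > 8L) stop("dimension > 8 is unsupported")
  if (!isTRUE(all.equal(cov, t(cov), tolerance = 1e-8))) {
    stop("covariance matrix must be symmetric")
  }
  if (length(lower) != d || length(upper) != d) {
    stop("bound lengths must match the covariance dimension")
  }
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("covariance matrix is not positive semidefinite")
  }
  if (any(upper < lower)) stop("upper bounds must be >= lower bounds")
  s <- sqrt(diag(cov))
  if (any(s <= 0)) stop("zero-variance coordinates are unsupported")
  lo <- (lower - 0) / s
  up <- (upper - 0) / s
  R <- cov / tcrossprod(s)
  if (d == 1L) {
    return(stats::pnorm(up) - stats::pnorm(lo))
  }
  if (d == 2L) {
    r <- R[1, 2]
    U <- function(a, b) bvn_upper(a, b, r)
    p <- U(lo[1], lo[2]) - U(lo[1], up[2]) - U(up[1], lo[2]) + U(up[1], up[2])
    return(min(max(p, 0), 1))
  }
  run <- function() {
    set.seed(as.integer(seed %% 2147483647))
    mvtnorm::pmvnorm(
      lower = lo, upper = up, corr = R,
      algorithm = mvtnorm::GenzBretz(abseps = abseps, releps = 0,
                                     maxpts = 8L * 8192L * d)
    )[1]
  }
  min(max(run(), 0), 1)
}
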