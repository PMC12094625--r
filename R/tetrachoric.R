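# Tetrachoric correlation: maximum likelihood on a 2x2 table.
#
# The three-parameter model (rho, tau_a, tau_b) is saturated on a 2x2
# table, so the joint MLE fixes the thresholds at the margin quantiles and
# solves the concordant-cell equation for rho; the standard error still
# comes from the full 3x3 observed information (delta method), which is
# what distinguishes the joint fit from a naive two-step estimate.

#' Tetrachoric correlation of a 2x2 table
#'
#' Estimates the correlation of the latent bivariate normal underlying two
#' binary variables, with thresholds implied by the margins. Counts need
#' not be integers (expected tables are accepted).
#'
#' @param table 2x2 matrix with `table[1,1]` the count of pairs negative on
#'   both variables and `table[2,2]` the doubly-positive count (rows: first
#'   variable 0/1, columns: second variable 0/1), or a length-4 vector
#'   `c(n00, n01, n10, n11)`
#' @param se compute the observed-information standard error (the costly
#'   part; disable when only the point estimate is needed)
#' @return list with `r` (estimate), `se` (observed-information standard
#'   error; `NA` unless status is `"ok"`), `status` (`"ok"`, `"boundary"`
#'   when the MLE is pinned at +/-1 or an identifying cell is empty,
#'   `"undefined"` when a margin is empty), and the implied thresholds
#' @examples
#' tetrachoric(matrix(c(25, 25, 25, 25), 2))$r   # 0
#' @export
tetrachoric <- function(table, se = TRUE) {
  if (is.matrix(table)) {
    n <- c(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
  } else {
    if (length(table) != 4L) stop("need a 2x2 table or c(n00, n01, n10, n11)")
    n <- as.numeric(table)
  }
  if (any(n < 0) || any(!is.finite(n))) stop("counts must be finite and non-negative")
  N <- sum(n)
  if (N <= 0) stop("table total must be positive")
  names(n) <- c("n00", "n01", "n10", "n11")
  pa <- (n["n10"] + n["n11"]) / N
  pb <- (n["n01"] + n["n11"]) / N
  out <- list(r = NA_real_, se = NA_real_, status = "undefined",
              tau_a = NA_real_, tau_b = NA_real_, n = n)
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1) return(out)

  tau_a <- stats::qnorm(unname(pa), lower.tail = FALSE)
  tau_b <- stats::qnorm(unname(pb), lower.tail = FALSE)
  out$tau_a <- tau_a; out$tau_b <- tau_b
  target <- unname(n["n11"] / N)
  lo <- max(0, unname(pa + pb - 1))        # P11 at rho = -1
  hi <- min(unname(pa), unname(pb))        # P11 at rho = +1

  if (n["n11"] == 0 || n["n00"] == 0 || target <= lo + 1e-12) {
    out$r <- -1; out$status <- "boundary"
    if (n["n11"] == 0 && unname(pa + pb) < 1) out$r <- -1
    return(out)
  }
  if (n["n01"] == 0 || n["n10"] == 0 || target >= hi - 1e-12) {
    out$r <- 1; out$status <- "boundary"
    return(out)
  }
  f <- function(r) bvn_upper(tau_a, tau_b, r) - target
  rhat <- stats::uniroot(f, c(-1 + 1e-9, 1 - 1e-9), tol = 1e-10)$root
  if (abs(rhat) > 1 - 1e-6) {
    out$r <- sign(rhat); out$status <- "boundary"
    return(out)
  }
  out$r <- rhat
  out$status <- "ok"
  if (!se) return(out)

  ll <- function(th) {
    p11 <- bvn_upper(th[2], th[3], th[1])
    sa <- stats::pnorm(th[2], lower.tail = FALSE)
    sb <- stats::pnorm(th[3], lower.tail = FALSE)
    p <- pmax(c(1 - sa - sb + p11, sb - p11, sa - p11, p11), 1e-12)
    sum(n * log(p))
  }
  H <- numDeriv::hessian(ll, c(rhat, tau_a, tau_b))
  V <- try(solve(-H), silent = TRUE)
  if (!inherits(V, "try-error") && is.finite(V[1, 1]) && V[1, 1] > 0) {
    out$se <- sqrt(V[1, 1])
  }
  out
}
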