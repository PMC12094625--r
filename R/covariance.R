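# Model-implied pair liability covariance matrices.

#' Expected correlation of the latent common factor within a pair
#' @keywords internal
factor_pair_correlation <- function(params, cls) {
  t <- as.numeric(cls$is_twin)
  cls$alpha * params$Ac + cls$gamma * params$Cc + t * params$Tc
}

#' Model-implied liability covariance of a relative pair
#'
#' Assembles the 8 x 8 covariance matrix of the liabilities
#' (member 1 disorders 1-4, member 2 disorders 1-4) implied by a
#' common-factor parameter set for one relative class. Within-person
#' blocks have unit diagonal and off-diagonals `lambda_i lambda_j`; the
#' cross-person block is
#' `lambda_i lambda_j (alpha Ac + gamma Cc + t Tc)` plus, on its diagonal,
#' the shared part of the residuals `alpha As_i + gamma Cs_i + t Ts_i`
#' (`t = 1` only for twin pairs).
#'
#' @param params a [model_params()] object
#' @param cls a relative class, as a label or a row of [relative_classes()]
#' @return 8 x 8 covariance matrix with attributes `psd` (logical) and
#'   `min_eigenvalue`; a warning is raised when the matrix is not positive
#'   semidefinite (allowed while fitting, fatal for simulation)
#' @export
pair_liability_covariance <- function(params, cls) {
  if (is.character(cls)) cls <- relative_class(cls)
  lam <- params$loadings
  nd <- length(lam)
  t <- as.numeric(cls$is_twin)
  g <- factor_pair_correlation(params, cls)
  W <- tcrossprod(lam)
  diag(W) <- 1
  B <- tcrossprod(lam) * g
  diag(B) <- diag(B) + cls$alpha * params$As + cls$gamma * params$Cs + t * params$Ts
  S <- rbind(cbind(W, B), cbind(t(B), W))
  nm <- c(paste0("p1_", params$disorders), paste0("p2_", params$disorders))
  dimnames(S) <- list(nm, nm)
  .flag_psd(S, cls$label)
}

.flag_psd <- function(S, label) {
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  mine <- min(ev)
  psd <- mine >= -1e-10 * max(abs(ev))
  if (!psd) {
    warning("implied pair covariance for class ", label,
            " is not positive semidefinite (min eigenvalue ",
            format(mine, digits = 3), ")")
  }
  structure(S, psd = psd, min_eigenvalue = mine)
}

#' Model-implied liability covariance of a pair under the bivariate model
#'
#' 4 x 4 covariance over (member 1 disorder i, member 1 disorder j,
#' member 2 disorder i, member 2 disorder j). Within-person cross-disorder
#' covariance is `covA + covC + covE` (the sum of the cross-disorder factor
#' covariances); cross-person same-disorder covariance is
#' `alpha a2 + gamma c2`; cross-person cross-disorder covariance is
#' `alpha covA + gamma covC`.
#'
#' @param bparams a [bivariate_params()] object
#' @param cls relative class label or row
#' @return 4 x 4 covariance matrix with PSD attributes as for
#'   [pair_liability_covariance()]
#' @export
bivariate_pair_covariance <- function(bparams, cls) {
  if (is.character(cls)) cls <- relative_class(cls)
  a <- cls$alpha; g <- cls$gamma
  w <- bparams$covA + bparams$covC + bparams$covE
  x <- a * bparams$covA + g * bparams$covC
  si <- a * bparams$a2[1] + g * bparams$c2[1]
  sj <- a * bparams$a2[2] + g * bparams$c2[2]
  S <- matrix(c(
    1,  w,  si, x,
    w,  1,  x,  sj,
    si, x,  1,  w,
    x,  sj, w,  1
  ), 4, 4, byrow = TRUE)
  nm <- c(paste0("p1_", bparams$labels), paste0("p2_", bparams$labels))
  dimnames(S) <- list(nm, nm)
  .flag_psd(S, cls$label)
}
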