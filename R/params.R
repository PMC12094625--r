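# Parameter containers for the common-factor and bivariate ACE models.
#
# The common-factor model decomposes one latent liability factor into
# additive-genetic (Ac), shared-environment (Cc) and unique-environment (Ec)
# variance components summing to 1; each disorder loads on the factor with a
# standardized path lambda_i and carries its own residual A/C/E components
# (As_i, Cs_i, Es_i) so that lambda_i^2 + As_i + Cs_i + Es_i = 1. Components
# are variances, not squared paths, and are allowed to be negative
# (Verhulst-style variance parameterization); only simulation insists on a
# positive-semidefinite pair covariance.

PARAMS_SCHEMA <- "famliab-params-1"

#' Construct common-factor model parameters
#'
#' @param Ac,Cc additive-genetic and shared-environment variance of the
#'   latent common factor; `Ec` is derived as `1 - Ac - Cc`
#' @param loadings standardized factor loadings, one per disorder,
#'   non-negative (sign convention fixing the factor direction)
#' @param As,Cs disorder-specific additive-genetic and shared-environment
#'   residual variances; `Es` is derived from the unit-variance constraint
#' @param thresholds liability thresholds: either a length-4 vector (one
#'   threshold per disorder, shared by all relative classes) or a 4 x 2
#'   matrix with columns `twin_full` and `half_sib` when prevalences differ
#'   by family type
#' @param Tc,Ts optional twin-specific extra covariance for the factor and
#'   the residuals (active only in MZ/DZ pairs; default 0 = disabled)
#' @param disorders disorder labels
#' @return an object of class `model_params`
#' @examples
#' p <- reference_params()
#' p$Ac + p$Cc + p$Ec  # 1
#' @export
model_params <- function(Ac, Cc, loadings, As, Cs, thresholds,
                         Tc = 0, Ts = rep(0, length(loadings)),
                         disorders = DISORDERS) {
  nd <- length(disorders)
  stopifnot(length(loadings) == nd, length(As) == nd, length(Cs) == nd,
            length(Ts) == nd, length(Tc) == 1L)
  if (any(loadings < 0)) stop("loadings must be non-negative")
  if (any(loadings^2 > 1)) stop("loadings must not exceed 1 in magnitude")
  Ec <- 1 - Ac - Cc
  Es <- 1 - loadings^2 - As - Cs
  th <- .as_threshold_matrix(thresholds, disorders)
  out <- list(
    disorders = as.character(disorders),
    Ac = as.numeric(Ac), Cc = as.numeric(Cc), Ec = as.numeric(Ec),
    loadings = stats::setNames(as.numeric(loadings), disorders),
    As = stats::setNames(as.numeric(As), disorders),
    Cs = stats::setNames(as.numeric(Cs), disorders),
    Es = stats::setNames(as.numeric(Es), disorders),
    thresholds = th,
    Tc = as.numeric(Tc),
    Ts = stats::setNames(as.numeric(Ts), disorders)
  )
  class(out) <- "model_params"
  validate_model_params(out)
  out
}

.as_threshold_matrix <- function(thresholds, disorders) {
  nd <- length(disorders)
  if (is.matrix(thresholds)) {
    if (nrow(thresholds) != nd || ncol(thresholds) != 2L) {
      stop("threshold matrix must be ", nd, " x 2")
    }
    th <- thresholds
  } else {
    if (length(thresholds) != nd) stop("need one threshold per disorder")
    th <- cbind(thresholds, thresholds)
  }
  dimnames(th) <- list(disorders, c("twin_full", "half_sib"))
  th
}

#' @keywords internal
validate_model_params <- function(p, tol = 1e-8) {
  if (abs(p$Ac + p$Cc + p$Ec - 1) > tol) {
    stop("latent variance components must sum to 1")
  }
  tot <- p$loadings^2 + p$As + p$Cs + p$Es
  if (any(abs(tot - 1) > tol)) {
    stop("per-disorder liability variance must equal 1")
  }
  invisible(p)
}

#' Thresholds applying to one relative class
#' @keywords internal
thresholds_for_class <- function(params, label) {
  params$thresholds[, class_group(label)]
}

#' Reconstructed reference parameter set
#'
#' A complete common-factor parameter set consistent with the published
#' point estimates of the source study: latent components Ac = 0.49,
#' Cc = 0.04, Ec = 0.47; loadings ~0.82-0.84 for the internalizing
#' disorders (MD, AD) and ~0.38-0.40 for the functional somatic disorders
#' (IBS, FM); disorder-specific components chosen so the implied total
#' heritabilities are 34% (MD), 40% (AD), 21% (IBS) and 43% (FM), with a
#' small negative shared-environment residual for IBS. The exact
#' per-disorder loadings and specific components were not published; this
#' set is a reconstruction consistent with the printed ranges and totals,
#' not the original estimates.
#'
#' @return a [model_params()] object
#' @export
reference_params <- function() {
  model_params(
    Ac = 0.49, Cc = 0.04,
    loadings = c(0.82, 0.84, 0.38, 0.40),
    As = c(0.010, 0.050, 0.139244, 0.3516),
    Cs = c(0.0176, 0.012, -0.030, 0.0736),
    thresholds = threshold_from_prevalence(c(0.20, 0.20, 0.06, 0.01))
  )
}

#' Published bivariate genetic correlations between the four disorders
#'
#' Point estimates from bivariate model fits: high for MD-AD (+0.91),
#' moderate for IBS with either internalizing disorder (+0.62),
#' intermediate for FM-MD (+0.54) and FM-AD (+0.28), and modest for
#' IBS-FM (+0.38).
#'
#' @return symmetric 4 x 4 matrix of genetic correlations (unit diagonal)
#' @export
reference_genetic_correlations <- function() {
  rA <- diag(4)
  dimnames(rA) <- list(DISORDERS, DISORDERS)
  rA["MD", "AD"] <- rA["AD", "MD"] <- 0.91
  rA["MD", "IBS"] <- rA["IBS", "MD"] <- 0.62
  rA["AD", "IBS"] <- rA["IBS", "AD"] <- 0.62
  rA["MD", "FM"] <- rA["FM", "MD"] <- 0.54
  rA["AD", "FM"] <- rA["FM", "AD"] <- 0.28
  rA["IBS", "FM"] <- rA["FM", "IBS"] <- 0.38
  rA
}

#' Variance decomposition implied by common-factor parameters
#'
#' Total liability variance components per disorder (a2 = lambda^2*Ac + As,
#' analogously c2 and e2) together with the split into common-factor and
#' disorder-specific parts and the common-factor share of each source.
#' Shares are reported as `NA` (undefined) when a negative component makes
#' the proportion fall outside `[0, 1]`, mirroring the convention of
#' printing a dash in that situation.
#'
#' @param params a [model_params()] object
#' @return data frame, one row per disorder
#' @export
implied_components <- function(params) {
  l2 <- params$loadings^2
  comp <- function(common, specific) {
    tot <- common + specific
    share <- common / tot
    share[!(tot > 0) | share < 0 | share > 1] <- NA_real_
    list(total = tot, common = common, specific = specific, share = share)
  }
  a <- comp(l2 * params$Ac, params$As)
  c_ <- comp(l2 * params$Cc, params$Cs)
  e <- comp(l2 * params$Ec, params$Es)
  data.frame(
    disorder = params$disorders,
    a2 = a$total, c2 = c_$total, e2 = e$total,
    a2_common = a$common, a2_specific = a$specific, a2_share_common = a$share,
    c2_common = c_$common, c2_specific = c_$specific, c2_share_common = c_$share,
    e2_common = e$common, e2_specific = e$specific, e2_share_common = e$share,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Genetic correlation implied by the common-factor model
#'
#' `rG = lambda_i lambda_j Ac / sqrt(a2_i a2_j)` where `a2` are the total
#' additive-genetic variances. Defined only when both totals are positive.
#'
#' @param params a [model_params()] object
#' @param i,j disorder labels or indices
#' @return genetic correlation in `[-1, 1]`
#' @export
implied_genetic_correlation <- function(params, i, j) {
  i <- .disorder_index(params$disorders, i)
  j <- .disorder_index(params$disorders, j)
  a2 <- params$loadings^2 * params$Ac + params$As
  if (a2[i] <= 0 || a2[j] <= 0) {
    stop("genetic correlation undefined: non-positive total genetic variance")
  }
  if (i == j) return(1)
  unname(params$loadings[i] * params$loadings[j] * params$Ac /
           sqrt(a2[i] * a2[j]))
}

.disorder_index <- function(labels, x) {
  if (is.character(x)) {
    i <- match(x, labels)
    if (is.na(i)) stop("unknown disorder: ", x)
    return(i)
  }
  xi <- as.integer(x)
  if (xi < 1L || xi > length(labels)) stop("disorder index out of range")
  xi
}

#' Construct bivariate correlated-factors ACE parameters
#'
#' Two disorders, each with liability variance components `a2`, `c2`, `e2`
#' (`e2` derived so components sum to 1), connected by cross-disorder
#' correlations of their A, C and E factors. When a shared-environment
#' component is negative the C correlation is undefined; `rC` must then be
#' 0 (no cross-disorder C covariance) and is stored as `NA`.
#'
#' @param labels two disorder labels
#' @param a2,c2 per-disorder variance components (length 2); `e2` derived
#' @param rA,rC,rE cross-disorder factor correlations in `[-1, 1]`
#' @param thresholds liability thresholds, length-2 vector or 2 x 2 matrix
#'   (columns `twin_full`, `half_sib`)
#' @return object of class `bivariate_params`
#' @export
bivariate_params <- function(labels, a2, c2, rA, rC, rE, thresholds) {
  stopifnot(length(labels) == 2L, length(a2) == 2L, length(c2) == 2L)
  e2 <- 1 - a2 - c2
  for (r in c(rA, rE)) {
    if (!is.finite(r) || abs(r) > 1) stop("factor correlations must lie in [-1, 1]")
  }
  if (any(a2 < 0)) stop("a2 must be non-negative in the bivariate model")
  cprod <- c2[1] * c2[2]
  if (cprod < 0) {
    if (!is.na(rC) && rC != 0) {
      stop("rC is undefined when a c2 component is negative; use rC = 0")
    }
    covC <- 0
    rC <- NA_real_
  } else {
    if (!is.finite(rC) || abs(rC) > 1) stop("factor correlations must lie in [-1, 1]")
    covC <- rC * sqrt(cprod)
  }
  eprod <- e2[1] * e2[2]
  if (eprod < 0) stop("e2 components must be non-negative")
  out <- list(
    labels = as.character(labels),
    a2 = stats::setNames(as.numeric(a2), labels),
    c2 = stats::setNames(as.numeric(c2), labels),
    e2 = stats::setNames(as.numeric(e2), labels),
    rA = as.numeric(rA), rC = rC, rE = as.numeric(rE),
    covA = rA * sqrt(a2[1] * a2[2]),
    covC = covC,
    covE = rE * sqrt(eprod),
    thresholds = .as_threshold_matrix(thresholds, labels)
  )
  class(out) <- "bivariate_params"
  out
}

#' Reconstructed bivariate generating parameters for a disorder pair
#'
#' Per-disorder totals at the published values (a2 = 0.34/0.40/0.21/0.43
#' for MD/AD/IBS/FM, shared-environment totals from the reconstructed
#' reference set, including the small negative value for IBS) and the
#' published genetic correlation for the pair. The C and E factor
#' correlations were not published; they are reconstructed as the values
#' implied by the common-factor reference set (0 for the C correlation of
#' pairs involving IBS, whose c2 is negative).
#'
#' @param d1,d2 disorder labels
#' @return a [bivariate_params()] object
#' @export
default_bivariate_params <- function(d1, d2) {
  ref <- reference_params()
  ic <- implied_components(ref)
  rownames(ic) <- ic$disorder
  a2_pub <- c(MD = 0.34, AD = 0.40, IBS = 0.21, FM = 0.43)
  i <- .disorder_index(DISORDERS, d1)
  j <- .disorder_index(DISORDERS, d2)
  d1 <- DISORDERS[i]; d2 <- DISORDERS[j]
  if (d1 == d2) stop("need two distinct disorders")
  a2 <- a2_pub[c(d1, d2)]
  c2 <- ic[c(d1, d2), "c2"]
  e2 <- 1 - a2 - c2
  lam <- ref$loadings[c(d1, d2)]
  rA <- reference_genetic_correlations()[d1, d2]
  rE <- unname(lam[1] * lam[2] * ref$Ec / sqrt(e2[1] * e2[2]))
  if (c2[1] > 0 && c2[2] > 0) {
    rC <- unname(lam[1] * lam[2] * ref$Cc / sqrt(c2[1] * c2[2]))
  } else {
    rC <- 0
  }
  bivariate_params(
    labels = c(d1, d2), a2 = a2, c2 = c2,
    rA = rA, rC = rC, rE = rE,
    thresholds = ref$thresholds[c(d1, d2), 1]
  )
}

#' Serialize model parameters to JSON
#'
#' Writes an explicit-field JSON document with a schema-version key;
#' the inverse of [params_from_json()].
#'
#' @param params a `model_params` or `bivariate_params` object
#' @param path optional file path; if `NULL` the JSON string is returned
#' @return JSON string (invisibly, when written to a file)
#' @export
params_to_json <- function(params, path = NULL) {
  if (inherits(params, "model_params")) {
    doc <- list(
      schema_version = PARAMS_SCHEMA, type = "common_factor",
      disorders = params$disorders,
      Ac = params$Ac, Cc = params$Cc, Ec = params$Ec,
      loadings = unname(params$loadings),
      As = unname(params$As), Cs = unname(params$Cs), Es = unname(params$Es),
      thresholds_twin_full = unname(params$thresholds[, "twin_full"]),
      thresholds_half_sib = unname(params$thresholds[, "half_sib"]),
      Tc = params$Tc, Ts = unname(params$Ts)
    )
  } else if (inherits(params, "bivariate_params")) {
    doc <- list(
      schema_version = PARAMS_SCHEMA, type = "bivariate",
      disorders = params$labels,
      a2 = unname(params$a2), c2 = unname(params$c2), e2 = unname(params$e2),
      rA = params$rA, rC = params$rC, rE = params$rE,
      thresholds_twin_full = unname(params$thresholds[, "twin_full"]),
      thresholds_half_sib = unname(params$thresholds[, "half_sib"])
    )
  } else {
    stop("unsupported parameter object")
  }
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Deserialize model parameters from JSON
#'
#' @param x JSON string or path to a JSON file written by [params_to_json()]
#' @return a `model_params` or `bivariate_params` object
#' @export
params_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x)
  if (!identical(doc$schema_version, PARAMS_SCHEMA)) {
    stop("unrecognized schema version: ", doc$schema_version)
  }
  th <- cbind(doc$thresholds_twin_full, doc$thresholds_half_sib)
  if (identical(doc$type, "common_factor")) {
    model_params(
      Ac = doc$Ac, Cc = doc$Cc, loadings = doc$loadings,
      As = doc$As, Cs = doc$Cs, thresholds = th,
      Tc = doc$Tc, Ts = doc$Ts, disorders = doc$disorders
    )
  } else if (identical(doc$type, "bivariate")) {
    bivariate_params(
      labels = doc$disorders, a2 = doc$a2, c2 = doc$c2,
      rA = doc$rA, rC = if (is.null(doc$rC)) NA_real_ else doc$rC,
      rE = doc$rE, thresholds = th
    )
  } else {
    stop("unrecognized parameter type: ", doc$type)
  }
}

#' @export
print.model_params <- function(x, ...) {
  cat("Common-factor liability model parameters\n")
  cat(sprintf("  latent: Ac = %.4f, Cc = %.4f, Ec = %.4f\n", x$Ac, x$Cc, x$Ec))
  tab <- data.frame(
    loading = x$loadings, As = x$As, Cs = x$Cs, Es = x$Es,
    threshold = x$thresholds[, "twin_full"]
  )
  print(round(tab, 4))
  if (x$Tc != 0 || any(x$Ts != 0)) {
    cat(sprintf("  twin-specific: Tc = %.4f, Ts = %s\n", x$Tc,
                paste(round(x$Ts, 4), collapse = ", ")))
  }
  invisible(x)
}

#' @export
print.bivariate_params <- function(x, ...) {
  cat("Bivariate correlated-factors ACE parameters (",
      paste(x$labels, collapse = "-"), ")\n", sep = "")
  tab <- data.frame(a2 = x$a2, c2 = x$c2, e2 = x$e2,
                    threshold = x$thresholds[, "twin_full"])
  print(round(tab, 4))
  cat(sprintf("  rA = %.3f, rC = %s, rE = %.3f\n", x$rA,
              ifelse(is.na(x$rC), "undefined", sprintf("%.3f", x$rC)), x$rE))
  invisible(x)
}
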