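# Confidence intervals for fitted models.
#
# Bootstrap: multinomial resampling of the per-class pattern counts (which
# is exactly resampling pairs within class), warm-started refits, percentile
# intervals. Profile: inversion of the likelihood ratio at the 95%
# chi-square cutoff. Both operate on the composite objective, whose optimum
# coincides with the full-pattern optimum up to small-sample noise.

#' @keywords internal
resample_counts <- function(counts) {
  out <- counts
  for (cl in names(counts$classes)) {
    v <- counts$classes[[cl]]
    N <- sum(v)
    if (N == 0) next
    out$classes[[cl]] <- as.numeric(stats::rmultinom(1, N, v / N))
  }
  out$n_pairs <- vapply(out$classes, sum, numeric(1))
  out
}

#' @keywords internal
refit_warm <- function(theta0, counts, map, kind, max_iter = 300L) {
  cd <- composite_data(counts)
  obj <- make_composite_objective(cd, map, kind)
  optim_restarts(theta0, obj$fn, obj$gr, map$lower, map$upper,
                 maxit = max_iter, restarts = 3L)
}

#' Per-parameter 95% confidence intervals for a fitted model
#'
#' @param fit a `famliab_fit`
#' @param counts the [pattern_counts()] the model was fitted to
#' @param method `"bootstrap"` (percentile, pairs resampled within class)
#'   or `"profile"` (likelihood-ratio inversion)
#' @param reps bootstrap replicate count; below 50 a warning is recorded in
#'   the result's `warning` attribute
#' @param seed RNG seed; results are deterministic given the seed
#' @param parameters optional subset of parameter names (profile method can
#'   be slow over all parameters)
#' @return data frame with columns `parameter`, `estimate`, `lower`,
#'   `upper` (and `method`)
#' @export
confidence_intervals <- function(fit, counts, method = c("bootstrap", "profile"),
                                 reps = 200L, seed = 20250428L,
                                 parameters = NULL) {
  method <- match.arg(method)
  if (inherits(counts, "pair_dataset")) counts <- pattern_counts(counts)
  if (!identical(counts_fingerprint(counts), fit$counts_hash)) {
    stop("counts do not match the data the model was fitted to")
  }
  kind <- if (fit$variant == "bivariate") "biv" else "cf"
  map <- fit$map
  theta0 <- fit$estimates
  warn <- NULL
  if (method == "bootstrap") {
    if (reps < 50L) {
      warn <- paste0("bootstrap with ", reps,
                     " replicates; intervals are unstable below 50")
      warning(warn)
    }
    # Hessian-preconditioned refits: the composite surface has nearly flat
    # ridges on which box-constrained quasi-Newton restarts are slow; in
    # coordinates whitened by the curvature at the point estimate each
    # bootstrap refit converges in a handful of steps.
    obj0 <- make_composite_objective(composite_data(counts), map, kind)
    H <- numDeriv::jacobian(obj0$gr, theta0)
    H <- (H + t(H)) / 2
    ev <- eigen(H, symmetric = TRUE)
    lam_floor <- max(ev$values) * 1e-8
    A <- ev$vectors %*% diag(1 / sqrt(pmax(ev$values, lam_floor))) %*% t(ev$vectors)
    set.seed(as.integer(seed))
    draws <- matrix(NA_real_, reps, length(theta0),
                    dimnames = list(NULL, names(theta0)))
    for (r in seq_len(reps)) {
      cr <- resample_counts(counts)
      objr <- make_composite_objective(composite_data(cr), map, kind)
      fn <- function(phi) objr$fn(theta0 + as.vector(A %*% phi))
      grf <- function(phi) as.vector(crossprod(A, objr$gr(theta0 + as.vector(A %*% phi))))
      o <- stats::optim(numeric(length(theta0)), fn, grf, method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-12))
      draws[r, ] <- pmin(pmax(theta0 + as.vector(A %*% o$par), map$lower),
                         map$upper)
    }
    qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
    out <- data.frame(
      parameter = names(theta0), estimate = unname(theta0),
      lower = qs[1, ], upper = qs[2, ], method = "bootstrap",
      row.names = NULL, stringsAsFactors = FALSE
    )
    attr(out, "draws") <- draws
  } else {
    if (is.null(parameters)) parameters <- names(theta0)
    cd <- composite_data(counts)
    obj <- make_composite_objective(cd, map, kind)
    f0 <- obj$fn(theta0)
    cut <- stats::qchisq(0.95, 1) / 2          # on the -lnL scale
    prof_bound <- function(pn, dir) {
      i <- match(pn, names(theta0))
      bound <- if (dir < 0) map$lower[i] else map$upper[i]
      dev <- function(val) {
        mapc <- map
        mapc$lower[i] <- mapc$upper[i] <- val
        th <- theta0; th[i] <- val
        refit_warm(th, counts, mapc, kind)$value - f0
      }
      if (dev(bound) < cut) return(unname(bound))
      lo <- theta0[i]; hi <- bound
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        if (dev(mid) < cut) lo <- mid else hi <- mid
        if (abs(hi - lo) < 1e-4) break
      }
      unname((lo + hi) / 2)
    }
    rows <- lapply(parameters, function(pn) {
      data.frame(parameter = pn, estimate = unname(theta0[match(pn, names(theta0))]),
                 lower = prof_bound(pn, -1), upper = prof_bound(pn, +1),
                 method = "profile", stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  }
  attr(out, "warning") <- warn
  attr(out, "seed") <- as.integer(seed)
  out
}
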