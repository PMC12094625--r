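# Maximum-likelihood fitting of the common-factor and bivariate models.
#
# The optimizer works on an unconstrained-ish box: Ac and Cc are free (Ec is
# eliminated by the sum-to-one constraint, likewise the Es residuals), and
# variance components may go negative. The composite pairwise likelihood
# with its analytic gradient is the default engine; "full_pattern" mode
# warm-starts from the composite optimum and maximizes the multinomial
# pattern likelihood. The AIC is always based on the full-pattern
# log-likelihood evaluated at the estimate (a composite pseudo-likelihood
# has no comparable AIC), with k counting free parameters only.

#' Fitting specification
#'
#' @param variant model variant: full common-factor model, the all-C-zero
#'   constrained model, the twin-specific extension, or a bivariate model
#'   for a pair of disorders
#' @param likelihood `"composite"` (default) or `"full_pattern"`
#' @param disorders for `variant = "bivariate"`: the two disorder labels
#' @param threshold_groups one threshold per disorder (`"single"`) or
#'   separate thresholds for twin/full-sib and half-sib families
#' @param max_iter optimizer iteration cap
#' @param multistart number of jittered starts (>= 1)
#' @param seed seed for start jitter (and CI resampling)
#' @param ci `"none"`, `"bootstrap"` or `"profile"`
#' @param ci_reps bootstrap replicate count when `ci = "bootstrap"`
#' @param gh_nodes Gauss-Hermite order for full-pattern probabilities
#' @return a `fit_spec` list
#' @export
fit_spec <- function(variant = c("full", "noC", "twin_specific", "bivariate"),
                     likelihood = c("composite", "full_pattern"),
                     disorders = NULL,
                     threshold_groups = c("single", "by_family_type"),
                     max_iter = 500L, multistart = 5L, seed = 20250428L,
                     ci = c("none", "bootstrap", "profile"), ci_reps = 200L,
                     gh_nodes = 20L) {
  variant <- match.arg(variant)
  ci <- match.arg(ci)
  if (ci != "none" && ci_reps < 1L) stop("replication count must be >= 1")
  structure(list(
    variant = variant, likelihood = match.arg(likelihood),
    disorders = disorders, threshold_groups = match.arg(threshold_groups),
    max_iter = as.integer(max_iter), multistart = as.integer(multistart),
    seed = as.integer(seed), ci = ci, ci_reps = as.integer(ci_reps),
    gh_nodes = as.integer(gh_nodes)
  ), class = "fit_spec")
}

# ---- parameter maps --------------------------------------------------------

#' @keywords internal
cf_param_map <- function(variant, threshold_groups, disorders) {
  nd <- length(disorders)
  has_C <- variant != "noC"
  has_T <- variant == "twin_specific"
  nm <- c("Ac", if (has_C) "Cc",
          paste0("lam_", disorders),
          paste0("As_", disorders),
          if (has_C) paste0("Cs_", disorders),
          if (has_T) c("Tc", paste0("Ts_", disorders)))
  if (threshold_groups == "single") {
    nm <- c(nm, paste0("tau_", disorders))
  } else {
    nm <- c(nm, paste0("tau_", disorders, "_twin_full"),
            paste0("tau_", disorders, "_half_sib"))
  }
  lower <- upper <- stats::setNames(numeric(length(nm)), nm)
  lower[] <- -0.9; upper[] <- 1.5
  lower[grep("^lam_", nm)] <- 0; upper[grep("^lam_", nm)] <- 0.999
  lower[grep("^tau_", nm)] <- -5; upper[grep("^tau_", nm)] <- 5
  if (has_T) { lower[c("Tc", paste0("Ts_", disorders))] <- -0.5
               upper[c("Tc", paste0("Ts_", disorders))] <- 0.5 }
  list(variant = variant, groups = threshold_groups, disorders = disorders,
       nd = nd, names = nm, lower = lower, upper = upper,
       has_C = has_C, has_T = has_T)
}

#' @keywords internal
cf_unpack <- function(theta, map) {
  nd <- map$nd
  i <- 1L
  Ac <- theta[i]; i <- i + 1L
  Cc <- 0
  if (map$has_C) { Cc <- theta[i]; i <- i + 1L }
  lam <- theta[i:(i + nd - 1L)]; i <- i + nd
  As <- theta[i:(i + nd - 1L)]; i <- i + nd
  Cs <- rep(0, nd)
  if (map$has_C) { Cs <- theta[i:(i + nd - 1L)]; i <- i + nd }
  Tc <- 0; Ts <- rep(0, nd)
  if (map$has_T) {
    Tc <- theta[i]; i <- i + 1L
    Ts <- theta[i:(i + nd - 1L)]; i <- i + nd
  }
  if (map$groups == "single") {
    tau <- cbind(theta[i:(i + nd - 1L)], theta[i:(i + nd - 1L)])
  } else {
    tau <- cbind(theta[i:(i + nd - 1L)], theta[(i + nd):(i + 2L * nd - 1L)])
  }
  colnames(tau) <- c("twin_full", "half_sib")
  list(Ac = Ac, Cc = Cc, Tc = Tc, loadings = lam, As = As, Cs = Cs, Ts = Ts,
       tau = tau)
}

#' @keywords internal
cf_pack_grad <- function(gr, map) {
  out <- c(gr$Ac, if (map$has_C) gr$Cc, gr$loadings, gr$As,
           if (map$has_C) gr$Cs,
           if (map$has_T) c(gr$Tc, gr$Ts))
  if (map$groups == "single") {
    out <- c(out, gr$tau[, 1] + gr$tau[, 2])
  } else {
    out <- c(out, gr$tau[, 1], gr$tau[, 2])
  }
  out
}

#' @keywords internal
biv_param_map <- function(threshold_groups, disorders) {
  nm <- c(paste0("a2_", disorders), paste0("c2_", disorders),
          "covA", "covC", "covE")
  if (threshold_groups == "single") {
    nm <- c(nm, paste0("tau_", disorders))
  } else {
    nm <- c(nm, paste0("tau_", disorders, "_twin_full"),
            paste0("tau_", disorders, "_half_sib"))
  }
  lower <- upper <- stats::setNames(numeric(length(nm)), nm)
  lower[1:2] <- 0; upper[1:2] <- 1            # a2 >= 0 (reported rA needs it)
  lower[3:4] <- -0.9; upper[3:4] <- 1
  lower[5:7] <- -1; upper[5:7] <- 1
  lower[grep("^tau_", nm)] <- -5; upper[grep("^tau_", nm)] <- 5
  list(groups = threshold_groups, disorders = disorders, names = nm,
       lower = lower, upper = upper)
}

#' @keywords internal
biv_unpack <- function(theta, map) {
  if (map$groups == "single") {
    tau <- cbind(theta[8:9], theta[8:9])
  } else {
    tau <- cbind(theta[8:9], theta[10:11])
  }
  colnames(tau) <- c("twin_full", "half_sib")
  list(a2 = theta[1:2], c2 = theta[3:4], covA = theta[5], covC = theta[6],
       covE = theta[7], tau = tau)
}

#' @keywords internal
biv_pack_grad <- function(gr, map) {
  out <- c(gr$a2, gr$c2, gr$covA, gr$covC, gr$covE)
  if (map$groups == "single") {
    c(out, gr$tau[, 1] + gr$tau[, 2])
  } else {
    c(out, gr$tau[, 1], gr$tau[, 2])
  }
}

# ---- objective builders ----------------------------------------------------

# Cached value+gradient objective for optim (fn and gr share one evaluation).
#' @keywords internal
make_composite_objective <- function(cd, map, kind = c("cf", "biv")) {
  kind <- match.arg(kind)
  cache <- new.env(parent = emptyenv())
  evalf <- function(theta) {
    key <- paste(theta, collapse = ",")
    if (identical(cache$key, key)) return(cache$res)
    if (kind == "cf") {
      p <- cf_unpack(theta, map)
      r <- composite_ll_cf(p, cd, grad = TRUE)
      g <- cf_pack_grad(r$gr, map)
    } else {
      p <- biv_unpack(theta, map)
      r <- composite_ll_biv(p, cd, grad = TRUE)
      g <- biv_pack_grad(r$gr, map)
    }
    res <- list(value = -r$ll, gradient = -g)
    cache$key <- key; cache$res <- res
    res
  }
  list(fn = function(theta) evalf(theta)$value,
       gr = function(theta) evalf(theta)$gradient)
}

# Cached value+gradient objective for the full-pattern likelihood.
#' @keywords internal
make_full_pattern_objective <- function(counts, map, gh_nodes) {
  cache <- new.env(parent = emptyenv())
  evalf <- function(theta) {
    key <- paste(theta, collapse = ",")
    if (identical(cache$key, key)) return(cache$res)
    p <- cf_unpack(theta, map)
    r <- full_pattern_ll_cf(p, counts, gh_nodes = gh_nodes, grad = TRUE)
    res <- list(value = -r$ll, gradient = -cf_pack_grad(r$gr, map))
    cache$key <- key; cache$res <- res
    res
  }
  list(fn = function(theta) evalf(theta)$value,
       gr = function(theta) evalf(theta)$gradient)
}

# L-BFGS-B with restarts: the composite surface has nearly flat ridges on
# which a single L-BFGS-B run can terminate early; restarting from the
# endpoint (resetting the Hessian approximation) until the objective stops
# improving reliably reaches the optimum at negligible cost.
#' @keywords internal
optim_restarts <- function(th, fn, gr, lower, upper, maxit = 500L,
                           restarts = 20L, tol = 1e-7) {
  val <- Inf
  best <- NULL
  for (r in seq_len(restarts)) {
    o <- stats::optim(th, fn, gr, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = maxit, factr = 1e3))
    th <- o$par
    best <- o
    if (val - o$value < tol) break
    val <- o$value
  }
  best
}

# ---- starting values -------------------------------------------------------

#' @keywords internal
observed_thresholds <- function(counts) {
  B <- pattern_bits(counts$n_vars)
  nd <- counts$n_vars / 2L
  grp_of <- class_group(names(counts$classes))
  tau <- matrix(NA_real_, nd, 2, dimnames = list(NULL, c("twin_full", "half_sib")))
  for (grp in c("twin_full", "half_sib")) {
    cls <- names(counts$classes)[grp_of == grp]
    if (!length(cls)) next
    tot <- 0; aff <- numeric(nd)
    for (cl in cls) {
      v <- counts$classes[[cl]]
      tot <- tot + 2 * sum(v)
      aff <- aff + colSums(v * B)[1:nd] + colSums(v * B)[(nd + 1):(2 * nd)]
    }
    pr <- pmin(pmax(aff / tot, 1 / (tot + 2)), 1 - 1 / (tot + 2))
    tau[, grp] <- stats::qnorm(pr, lower.tail = FALSE)
  }
  # fall back to the other group when one family type is absent
  if (anyNA(tau[, 1])) tau[, 1] <- tau[, 2]
  if (anyNA(tau[, 2])) tau[, 2] <- tau[, 1]
  tau
}

#' @keywords internal
cf_start <- function(counts, map) {
  tau <- observed_thresholds(counts)
  nd <- map$nd
  th <- c(Ac = 0.35, if (map$has_C) c(Cc = 0.05),
          stats::setNames(rep(0.5, nd), paste0("lam_", map$disorders)),
          stats::setNames(rep(0.10, nd), paste0("As_", map$disorders)),
          if (map$has_C) stats::setNames(rep(0.02, nd), paste0("Cs_", map$disorders)),
          if (map$has_T) c(Tc = 0.01, stats::setNames(rep(0.01, nd), paste0("Ts_", map$disorders))))
  if (map$groups == "single") {
    th <- c(th, stats::setNames(rowMeans(tau), paste0("tau_", map$disorders)))
  } else {
    th <- c(th, stats::setNames(tau[, 1], paste0("tau_", map$disorders, "_twin_full")),
            stats::setNames(tau[, 2], paste0("tau_", map$disorders, "_half_sib")))
  }
  th[map$names]
}

#' @keywords internal
biv_start <- function(counts, map) {
  tau <- observed_thresholds(counts)
  th <- c(stats::setNames(c(0.3, 0.3), paste0("a2_", map$disorders)),
          stats::setNames(c(0.05, 0.05), paste0("c2_", map$disorders)),
          covA = 0.15, covC = 0.02, covE = 0.2)
  if (map$groups == "single") {
    th <- c(th, stats::setNames(rowMeans(tau), paste0("tau_", map$disorders)))
  } else {
    th <- c(th, stats::setNames(tau[, 1], paste0("tau_", map$disorders, "_twin_full")),
            stats::setNames(tau[, 2], paste0("tau_", map$disorders, "_half_sib")))
  }
  th[map$names]
}

# ---- moment (tetrachoric) starting values ---------------------------------
#
# The composite surface has nearly flat ridges trading disorder-specific A
# against C, so cold generic starts can stall far from the optimum. A
# method-of-moments start solves the class structure in closed form from
# tetrachoric correlations of the pooled tables: loadings by the triad
# method on within-person correlations, the factor-pair correlation g per
# class from cross-person cross-disorder tables, (Ac, Cc) and the specific
# components by weighted least squares on the (alpha, gamma) design.

#' @keywords internal
.table_tetra <- function(n) {
  tc <- tetrachoric(c(n[1, "n00"], n[1, "n01"], n[1, "n10"], n[1, "n11"]),
                    se = FALSE)
  if (tc$status == "ok") tc$r else NA_real_
}

#' @keywords internal
cf_moment_start <- function(cd, map, base) {
  out <- try({
    nd <- length(map$disorders)
    lay <- cd$layout
    nw <- length(lay$wi)
    K <- length(cd$classes)
    Ns <- vapply(cd$classes, `[[`, 0, "N")
    # tetrachoric of every pooled table, per class
    R <- lapply(cd$classes, function(cc) {
      vapply(seq_len(nrow(cc$n)), function(r) .table_tetra(cc$n[r, , drop = FALSE]),
             0)
    })
    # within-person correlations pooled over classes (weighted mean)
    rw <- vapply(seq_len(nw), function(w) {
      v <- vapply(R, `[`, 0, w)
      stats::weighted.mean(v, Ns, na.rm = TRUE)
    }, 0)
    RW <- diag(nd)
    RW[cbind(lay$wi, lay$wj)] <- RW[cbind(lay$wj, lay$wi)] <- rw
    lam <- vapply(seq_len(nd), function(i) {
      others <- setdiff(seq_len(nd), i)
      prs <- utils::combn(others, 2)
      v <- apply(prs, 2, function(jk) {
        RW[i, jk[1]] * RW[i, jk[2]] / RW[jk[1], jk[2]]
      })
      sqrt(stats::median(pmax(v, 1e-4), na.rm = TRUE))
    }, 0)
    lam <- pmin(pmax(lam, 0.05), 0.95)
    # factor-pair correlation per class from cross-person cross-disorder
    ghat <- vapply(seq_len(K), function(k) {
      v <- R[[k]][nw + nd + seq_len(nw)] / (lam[lay$xi] * lam[lay$xj])
      stats::median(v, na.rm = TRUE)
    }, 0)
    A <- vapply(cd$classes, `[[`, 0, "alpha")
    G <- vapply(cd$classes, `[[`, 0, "gamma")
    ok <- is.finite(ghat)
    X <- cbind(A, G)[ok, , drop = FALSE]
    fitAC <- stats::lm.wfit(X, ghat[ok], w = Ns[ok])$coefficients
    Ac <- fitAC[1]; Cc <- if (map$has_C) fitAC[2] else 0
    gfit <- A * Ac + G * Cc
    # disorder-specific components from cross-person same-disorder tables
    As <- Cs <- numeric(nd)
    for (i in seq_len(nd)) {
      y <- vapply(seq_len(K), function(k) R[[k]][nw + i], 0) - lam[i]^2 * gfit
      ok <- is.finite(y)
      co <- stats::lm.wfit(cbind(A, G)[ok, , drop = FALSE], y[ok],
                           w = Ns[ok])$coefficients
      As[i] <- co[1]; Cs[i] <- if (map$has_C) co[2] else 0
    }
    th <- base
    th["Ac"] <- Ac
    if (map$has_C) th["Cc"] <- Cc
    th[paste0("lam_", map$disorders)] <- lam
    th[paste0("As_", map$disorders)] <- As
    if (map$has_C) th[paste0("Cs_", map$disorders)] <- Cs
    pmin(pmax(th, map$lower), map$upper)
  }, silent = TRUE)
  if (inherits(out, "try-error") || anyNA(out)) base else out
}

#' @keywords internal
biv_moment_start <- function(cd, map, base) {
  out <- try({
    K <- length(cd$classes)
    Ns <- vapply(cd$classes, `[[`, 0, "N")
    R <- lapply(cd$classes, function(cc) {
      vapply(seq_len(nrow(cc$n)), function(r) .table_tetra(cc$n[r, , drop = FALSE]),
             0)
    })
    A <- vapply(cd$classes, `[[`, 0, "alpha")
    G <- vapply(cd$classes, `[[`, 0, "gamma")
    lsq <- function(y) {
      ok <- is.finite(y)
      stats::lm.wfit(cbind(A, G)[ok, , drop = FALSE], y[ok], w = Ns[ok])$coefficients
    }
    co1 <- lsq(vapply(seq_len(K), function(k) R[[k]][2], 0))
    co2 <- lsq(vapply(seq_len(K), function(k) R[[k]][3], 0))
    cox <- lsq(vapply(seq_len(K), function(k) R[[k]][4], 0))
    covW <- stats::weighted.mean(vapply(seq_len(K), function(k) R[[k]][1], 0),
                                 Ns, na.rm = TRUE)
    th <- base
    th[paste0("a2_", map$disorders)] <- c(co1[1], co2[1])
    th[paste0("c2_", map$disorders)] <- c(co1[2], co2[2])
    th["covA"] <- cox[1]; th["covC"] <- cox[2]
    th["covE"] <- covW - cox[1] - cox[2]
    pmin(pmax(th, map$lower), map$upper)
  }, silent = TRUE)
  if (inherits(out, "try-error") || anyNA(out)) base else out
}

#' @keywords internal
jitter_start <- function(start, map, amount = 0.12) {
  x <- start + stats::runif(length(start), -amount, amount)
  pmin(pmax(x, map$lower), map$upper)
}

# ---- main fitting entry points ---------------------------------------------

#' @keywords internal
check_identifiable <- function(counts) {
  rc <- relative_classes()
  present <- names(counts$classes)[vapply(counts$classes, sum, 0) > 0]
  sig <- unique(paste(rc$alpha[match(present, rc$label)],
                      rc$gamma[match(present, rc$label)]))
  if (length(sig) < 2L) {
    stop("unidentifiable design: need pairs in at least two relative classes ",
         "differing in genetic sharing or shared-environment exposure")
  }
  invisible(TRUE)
}

#' Fit a liability model to pair data
#'
#' Maximizes the selected likelihood over the free parameters, with the
#' sum-to-one constraints eliminated by substitution (Ec and the residual
#' Es components are derived). Uses seeded multistart L-BFGS-B; in
#' `"full_pattern"` mode the composite optimum is used as the starting
#' point for the pattern likelihood.
#'
#' @param data a `pair_dataset` or [pattern_counts()] object
#' @param spec a [fit_spec()]
#' @return a `famliab_fit` object: estimated parameters, -2 log-likelihood
#'   (full-pattern, at the estimate), free-parameter count `k`,
#'   `AIC = -2lnL + 2k`, convergence diagnostics, and optional CIs
#' @export
fit <- function(data, spec = fit_spec()) {
  if (identical(spec$variant, "bivariate")) {
    return(fit_bivariate(data, disorders = spec$disorders, spec = spec))
  }
  fit_common_factor(data, spec)
}

#' @rdname fit
#' @export
fit_common_factor <- function(data, spec = fit_spec()) {
  counts <- if (inherits(data, "pattern_counts")) data else pattern_counts(data)
  check_identifiable(counts)
  if (counts$n_vars != 8L) stop("common-factor fitting expects four disorders")
  map <- cf_param_map(spec$variant, spec$threshold_groups, counts$disorders)
  cd <- composite_data(counts)
  obj <- make_composite_objective(cd, map, "cf")
  base_start <- cf_moment_start(cd, map, cf_start(counts, map))

  best <- NULL
  set.seed(spec$seed)
  for (s in seq_len(spec$multistart)) {
    st <- if (s == 1L) base_start else jitter_start(base_start, map)
    o <- optim_restarts(st, obj$fn, obj$gr, map$lower, map$upper,
                        maxit = spec$max_iter,
                        restarts = if (s == 1L) 20L else 5L)
    if (is.null(best) || o$value < best$value) best <- o
  }
  comp_ll <- -best$value
  theta <- best$par
  conv <- best$convergence == 0L
  msg <- if (conv) "converged" else paste0("optim code ", best$convergence,
                                           ": ", best$message)
  if (spec$likelihood == "full_pattern") {
    fobj <- make_full_pattern_objective(counts, map, spec$gh_nodes)
    o2 <- optim_restarts(theta, fobj$fn, fobj$gr, map$lower, map$upper,
                         maxit = spec$max_iter, restarts = 10L)
    theta <- o2$par
    conv <- conv && o2$convergence == 0L
    if (o2$convergence != 0L) msg <- paste0("full-pattern optim code ",
                                            o2$convergence, ": ", o2$message)
  }

  p <- cf_unpack(theta, map)
  params <- model_params(Ac = p$Ac, Cc = p$Cc, loadings = p$loadings,
                         As = p$As, Cs = p$Cs, thresholds = p$tau,
                         Tc = p$Tc, Ts = p$Ts, disorders = counts$disorders)
  ll_full <- as.numeric(loglik(params, counts, gh_nodes = spec$gh_nodes))
  k <- length(theta)
  out <- structure(list(
    params = params, estimates = stats::setNames(theta, map$names),
    variant = spec$variant, likelihood = spec$likelihood,
    loglik = ll_full, composite_loglik = comp_ll,
    minus2LL = -2 * ll_full, k = k, AIC = -2 * ll_full + 2 * k,
    converged = conv, message = msg, seed = spec$seed, spec = spec,
    map = map, counts_hash = counts_fingerprint(counts), ci = NULL
  ), class = "famliab_fit")
  if (spec$ci != "none") {
    out$ci <- confidence_intervals(out, counts, method = spec$ci,
                                   reps = spec$ci_reps, seed = spec$seed)
  }
  out
}

#' Fit a bivariate correlated-factors ACE model
#'
#' Internally parameterized by per-disorder a2/c2 components and free
#' cross-disorder covariances (covA, covC, covE), which remain defined when
#' a shared-environment component is negative; the genetic correlation
#' `rA = covA / sqrt(a2_1 a2_2)` is derived at reporting time.
#'
#' @param data a `pair_dataset` or [pattern_counts()] object; when it holds
#'   four disorders it is restricted to `disorders` first
#' @param disorders the two disorder labels
#' @param spec a [fit_spec()]
#' @return a `famliab_fit` with a `bivariate_params`-like parameter object
#'   and derived `rA`, `rC`, `rE`
#' @export
fit_bivariate <- function(data, disorders, spec = fit_spec(variant = "bivariate")) {
  if (length(disorders) != 2L) stop("need exactly two disorders")
  if (inherits(data, "pattern_counts")) {
    counts <- data
    if (counts$n_vars != 4L) stop("pattern counts must hold two disorders")
  } else {
    keep <- c("pair_id", "relative_class",
              paste0("p1_", disorders), paste0("p2_", disorders))
    counts <- pattern_counts(as.data.frame(data)[keep])
  }
  if (!identical(counts$disorders, as.character(disorders))) {
    stop("pattern counts disorders do not match the requested pair")
  }
  check_identifiable(counts)
  map <- biv_param_map(spec$threshold_groups, disorders)
  cd <- composite_data(counts)
  obj <- make_composite_objective(cd, map, "biv")
  base_start <- biv_moment_start(cd, map, biv_start(counts, map))

  best <- NULL
  set.seed(spec$seed)
  for (s in seq_len(spec$multistart)) {
    st <- if (s == 1L) base_start else jitter_start(base_start, map)
    o <- optim_restarts(st, obj$fn, obj$gr, map$lower, map$upper,
                        maxit = spec$max_iter,
                        restarts = if (s == 1L) 20L else 5L)
    if (is.null(best) || o$value < best$value) best <- o
  }
  theta <- best$par
  p <- biv_unpack(theta, map)
  e2 <- 1 - p$a2 - p$c2
  rA <- if (all(p$a2 > 0)) unname(p$covA / sqrt(p$a2[1] * p$a2[2])) else NA_real_
  rC <- if (all(p$c2 > 0)) unname(p$covC / sqrt(p$c2[1] * p$c2[2])) else NA_real_
  rE <- if (all(e2 > 0)) unname(p$covE / sqrt(e2[1] * e2[2])) else NA_real_
  params <- structure(list(
    labels = as.character(disorders),
    a2 = stats::setNames(p$a2, disorders), c2 = stats::setNames(p$c2, disorders),
    e2 = stats::setNames(e2, disorders),
    rA = rA, rC = rC, rE = rE,
    covA = p$covA, covC = p$covC, covE = p$covE,
    thresholds = .as_threshold_matrix(p$tau, disorders)
  ), class = "bivariate_params")
  ll_full <- as.numeric(loglik(params, counts))
  k <- length(theta)
  conv <- best$convergence == 0L
  out <- structure(list(
    params = params, estimates = stats::setNames(theta, map$names),
    variant = "bivariate", likelihood = "composite",
    loglik = ll_full, composite_loglik = -best$value,
    minus2LL = -2 * ll_full, k = k, AIC = -2 * ll_full + 2 * k,
    converged = conv,
    message = if (conv) "converged" else paste0("optim code ", best$convergence),
    seed = spec$seed, spec = spec, map = map,
    counts_hash = counts_fingerprint(counts), ci = NULL
  ), class = "famliab_fit")
  if (spec$ci != "none") {
    out$ci <- confidence_intervals(out, counts, method = spec$ci,
                                   reps = spec$ci_reps, seed = spec$seed)
  }
  out
}

#' @keywords internal
counts_fingerprint <- function(counts) {
  fnv1a(paste(
    paste(names(counts$classes), collapse = ","),
    paste(unlist(counts$classes), collapse = ","),
    sep = "|"
  ))
}

#' Compare two fitted models by AIC
#'
#' @param full,constrained two `famliab_fit` objects fitted to the same data
#' @return list with the preferred fit's label (`"full"`/`"constrained"`),
#'   `delta_aic` (constrained minus full) and a tie flag; ties prefer the
#'   model with fewer parameters
#' @export
compare_models <- function(full, constrained) {
  if (!identical(full$counts_hash, constrained$counts_hash)) {
    stop("fits were produced from different datasets")
  }
  d <- constrained$AIC - full$AIC
  if (d == 0) {
    preferred <- if (constrained$k <= full$k) "constrained" else "full"
    tie <- TRUE
  } else {
    preferred <- if (d > 0) "full" else "constrained"
    tie <- FALSE
  }
  list(preferred = preferred, delta_aic = d, tie = tie,
       aic_full = full$AIC, aic_constrained = constrained$AIC)
}

#' @export
print.famliab_fit <- function(x, ...) {
  cat("famliab fit (", x$variant, ", ", x$likelihood, " likelihood)\n", sep = "")
  cat(sprintf("  -2lnL = %.2f, k = %d, AIC = %.2f, %s\n",
              x$minus2LL, x$k, x$AIC, x$message))
  print(round(x$estimates, 4))
  if (!is.null(x$ci)) {
    cat("95% confidence intervals:\n")
    print(x$ci)
  }
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' @param fit a `famliab_fit`
#' @param path optional output path
#' @return JSON string (invisibly when written)
#' @export
fit_to_json <- function(fit, path = NULL) {
  doc <- list(
    schema_version = "famliab-fit-1",
    variant = fit$variant, likelihood = fit$likelihood,
    estimates = as.list(fit$estimates),
    minus2LL = fit$minus2LL, k = fit$k, AIC = fit$AIC,
    converged = fit$converged, message = fit$message,
    seed = fit$seed, counts_hash = fit$counts_hash
  )
  if (!is.null(fit$ci)) {
    doc$ci <- list(parameter = fit$ci$parameter, lower = fit$ci$lower,
                   upper = fit$ci$upper)
  }
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
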