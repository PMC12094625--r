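# Synthetic relative-pair data with the exact statistical structure the
# analysis assumes.
#
# Liabilities are drawn via the factor construction (common factor pair plus
# per-disorder specific pairs), not by Cholesky of the assembled 8x8 matrix;
# the assembled matrix then serves as an independent oracle in tests.

#' Published per-class pair counts of the registry design
#' @keywords internal
DESIGN_COUNTS <- c(MZ = 8052, DZ = 7216, FS = 712762, HST = 23623, HSA = 53873)

#' Define a simulation scenario
#'
#' @param params generating [model_params()]
#' @param counts named vector of pair counts per relative class
#'   (names among MZ, DZ, FS, HST, HSA)
#' @param scale factor applied to `counts` (counts are rounded after
#'   scaling)
#' @param seed master seed; per-class random streams are derived from it
#' @return object of class `simulation_scenario`
#' @export
simulation_scenario <- function(params, counts = DESIGN_COUNTS, scale = 1,
                                seed = 20250428L) {
  stopifnot(scale > 0, all(counts >= 0))
  if (is.null(names(counts)) || !all(names(counts) %in% relative_classes()$label)) {
    stop("counts must be named by relative class")
  }
  out <- list(
    params = params,
    counts = round(counts * scale),
    scale = scale,
    seed = as.integer(seed)
  )
  class(out) <- "simulation_scenario"
  out
}

#' The default registry-design scenario
#'
#' Pair counts at the published design sizes (8,052 MZ / 7,216 DZ /
#' 712,762 FS / 23,623 HST / 53,873 HSA pairs, multiplied by `scale`) under
#' the reconstructed reference parameters ([reference_params()]).
#'
#' @param scale positive scale factor on the pair counts
#' @param seed master seed
#' @return a [simulation_scenario()]
#' @export
default_scenario <- function(scale = 1, seed = 20250428L) {
  simulation_scenario(reference_params(), DESIGN_COUNTS, scale, seed)
}

#' FNV-1a hash of a string (scenario fingerprinting)
#' @keywords internal
fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 216613626                      # 31-bit variant (R integers are 32-bit)
  for (b in bytes) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483648
  }
  sprintf("%08x", as.integer(h))
}

#' @keywords internal
scenario_hash <- function(scenario) {
  fnv1a(paste(
    params_to_json(scenario$params),
    paste(names(scenario$counts), scenario$counts, collapse = ";"),
    scenario$scale, scenario$seed,
    sep = "|"
  ))
}

.class_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) + 1000003 * idx) %% 2147483647)
}

#' Draw liability pairs for one relative class
#'
#' Returns raw (pre-threshold) liabilities, mainly for covariance-oracle
#' checks: the empirical covariance of the returned matrix converges to
#' [pair_liability_covariance()].
#'
#' @param params a [model_params()] object
#' @param cls relative class label or row
#' @param n number of pairs
#' @param seed RNG seed
#' @return n x 8 matrix (member 1 disorders, then member 2 disorders)
#' @export
simulate_liability_pairs <- function(params, cls, n, seed = 1L) {
  if (is.character(cls)) cls <- relative_class(cls)
  nd <- length(params$loadings)
  t <- as.numeric(cls$is_twin)
  rF <- factor_pair_correlation(params, cls)
  if (abs(rF) > 1) stop("factor pair correlation outside [-1, 1] for class ", cls$label)
  set.seed(seed)
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  F1 <- z1
  F2 <- rF * z1 + sqrt(1 - rF^2) * z2
  L <- matrix(0, n, 2 * nd)
  for (i in seq_len(nd)) {
    v <- 1 - params$loadings[i]^2          # total specific variance
    cv <- cls$alpha * params$As[i] + cls$gamma * params$Cs[i] + t * params$Ts[i]
    if (v < -1e-12 || abs(cv) > v + 1e-12) {
      stop("specific-component covariance not positive semidefinite for class ",
           cls$label, ", disorder ", params$disorders[i])
    }
    u1 <- stats::rnorm(n); u2 <- stats::rnorm(n)
    if (v > 0) {
      s1 <- sqrt(v) * u1
      s2 <- (cv / sqrt(v)) * u1 + sqrt(max(v - cv^2 / v, 0)) * u2
    } else {
      s1 <- s2 <- numeric(n)
    }
    L[, i] <- params$loadings[i] * F1 + s1
    L[, nd + i] <- params$loadings[i] * F2 + s2
  }
  colnames(L) <- c(paste0("p1_", params$disorders), paste0("p2_", params$disorders))
  L
}

#' Simulate a relative-pair binary phenotype dataset
#'
#' For each relative class, draws the common-factor pair from a bivariate
#' normal with correlation `alpha*Ac + gamma*Cc (+ Tc for twins)`, adds
#' per-disorder specific components with the class-appropriate cross-pair
#' covariance, and thresholds the resulting liabilities. Each class uses
#' its own seeded random stream, so the dataset is bit-for-bit reproducible
#' from the scenario alone.
#'
#' @param scenario a [simulation_scenario()]
#' @return a `pair_dataset` data frame with columns `pair_id`,
#'   `relative_class`, and `p1_<disorder>`/`p2_<disorder>` binary columns;
#'   the scenario hash and seed are attached as attributes
#' @export
simulate_pairs <- function(scenario) {
  params <- scenario$params
  rc <- relative_classes()
  keep <- rc$label %in% names(scenario$counts)
  rc <- rc[keep, , drop = FALSE]
  blocks <- vector("list", nrow(rc))
  for (k in seq_len(nrow(rc))) {
    cls <- rc[k, , drop = FALSE]
    n <- as.integer(scenario$counts[[cls$label]])
    if (n == 0L) next
    S <- withCallingHandlers(
      pair_liability_covariance(params, cls),
      warning = function(w) stop("non-PSD pair covariance for class ", cls$label)
    )
    L <- simulate_liability_pairs(params, cls, n,
                                  seed = .class_seed(scenario$seed, match(cls$label, relative_classes()$label)))
    tau <- thresholds_for_class(params, cls$label)
    Y <- matrix(0L, n, ncol(L))
    nd <- length(tau)
    for (i in seq_len(nd)) {
      Y[, i] <- as.integer(L[, i] > tau[i])
      Y[, nd + i] <- as.integer(L[, nd + i] > tau[i])
    }
    df <- data.frame(
      pair_id = paste0(cls$label, "_", seq_len(n)),
      relative_class = cls$label,
      Y, stringsAsFactors = FALSE
    )
    names(df)[-(1:2)] <- colnames(L)
    blocks[[k]] <- df
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  attr(out, "scenario_hash") <- scenario_hash(scenario)
  attr(out, "seed") <- scenario$seed
  attr(out, "disorders") <- params$disorders
  class(out) <- c("pair_dataset", "data.frame")
  out
}

#' Simulate pair data from a bivariate correlated-factors ACE model
#'
#' Draws 4-dimensional liability vectors from the covariance assembled by
#' [bivariate_pair_covariance()] and thresholds them.
#'
#' @param bparams a [bivariate_params()] object
#' @param counts named per-class pair counts
#' @param seed master seed (per-class streams derived from it)
#' @return a `pair_dataset` restricted to the two disorders
#' @export
simulate_bivariate <- function(bparams, counts = DESIGN_COUNTS, seed = 20250428L) {
  rc <- relative_classes()
  rc <- rc[rc$label %in% names(counts), , drop = FALSE]
  blocks <- vector("list", nrow(rc))
  for (k in seq_len(nrow(rc))) {
    cls <- rc[k, , drop = FALSE]
    n <- as.integer(counts[[cls$label]])
    if (n == 0L) next
    S <- withCallingHandlers(
      bivariate_pair_covariance(bparams, cls),
      warning = function(w) stop("non-PSD bivariate covariance for class ", cls$label)
    )
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    rt <- e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
    set.seed(.class_seed(seed, match(cls$label, relative_classes()$label)))
    Z <- matrix(stats::rnorm(4L * n), n, 4L)
    L <- Z %*% rt
    tau <- bparams$thresholds[, class_group(cls$label)]
    tauv <- c(tau, tau)                  # p1_d1, p1_d2, p2_d1, p2_d2
    Y <- matrix(0L, n, 4L)
    for (i in 1:4) Y[, i] <- as.integer(L[, i] > tauv[i])
    df <- data.frame(
      pair_id = paste0(cls$label, "_", seq_len(n)),
      relative_class = cls$label,
      Y, stringsAsFactors = FALSE
    )
    names(df)[-(1:2)] <- c(paste0("p1_", bparams$labels), paste0("p2_", bparams$labels))
    blocks[[k]] <- df
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  attr(out, "seed") <- as.integer(seed)
  attr(out, "disorders") <- bparams$labels
  class(out) <- c("pair_dataset", "data.frame")
  out
}

#' Write a pair dataset as TSV (plus a scenario sidecar)
#'
#' @param data a `pair_dataset`
#' @param path output TSV path
#' @param scenario optional [simulation_scenario()]; when given, a JSON
#'   sidecar `<path>.scenario.json` with seed and scenario hash is written
#' @return `path`, invisibly
#' @export
write_pair_dataset <- function(data, path, scenario = NULL) {
  utils::write.table(as.data.frame(data), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(scenario)) {
    side <- list(
      schema_version = "famliab-scenario-1",
      seed = scenario$seed,
      scale = scenario$scale,
      counts = as.list(scenario$counts),
      scenario_hash = scenario_hash(scenario),
      params = jsonlite::fromJSON(params_to_json(scenario$params))
    )
    jsonlite::write_json(side, paste0(path, ".scenario.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a pair dataset written by [write_pair_dataset()]
#'
#' @param path TSV path
#' @return a `pair_dataset` data frame
#' @export
read_pair_dataset <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("pair_id", "relative_class")
  if (!all(need %in% names(out))) {
    stop("not a pair dataset: missing ", paste(setdiff(need, names(out)), collapse = ", "))
  }
  pcols <- grep("^p[12]_", names(out), value = TRUE)
  if (!all(unlist(out[pcols]) %in% c(0L, 1L))) {
    stop("phenotype columns must be binary")
  }
  bad <- setdiff(unique(out$relative_class), relative_classes()$label)
  if (length(bad)) stop("unknown relative classes: ", paste(bad, collapse = ", "))
  attr(out, "disorders") <- unique(sub("^p[12]_", "", pcols))
  class(out) <- c("pair_dataset", "data.frame")
  out
}
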