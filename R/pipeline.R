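# Orchestration: simulate / describe / fit / report with machine-readable
# outputs. Every reported number traces back to a fit result or a
# correlation summary recorded in the run manifest.

#' Read a run configuration
#'
#' JSON with any of: `out_dir`, `input`, `scale`, `seed`, `counts`,
#' `params` (inline parameter document as written by [params_to_json()]),
#' `likelihood`, `threshold_groups`, `ci`, `ci_reps`, `multistart`,
#' `verbose`. Missing fields take the defaults below.
#'
#' @param path JSON path, or `NULL` for an all-default config
#' @param ... overrides applied after reading
#' @return a `run_config` list
#' @export
read_run_config <- function(path = NULL, ...) {
  cfg <- list(
    out_dir = ".", input = NULL, scale = 1, seed = 20250428L, counts = NULL,
    params = NULL, likelihood = "composite", threshold_groups = "single",
    ci = "none", ci_reps = 200L, multistart = 5L, verbose = TRUE
  )
  if (!is.null(path)) {
    user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    cfg[names(user)] <- user
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

.log <- function(cfg, ...) {
  if (isTRUE(cfg$verbose)) message("[famliab] ", ...)
}

.cfg_scenario <- function(cfg) {
  params <- if (is.null(cfg$params)) {
    reference_params()
  } else {
    params_from_json(jsonlite::toJSON(cfg$params, auto_unbox = TRUE, digits = NA))
  }
  counts <- if (is.null(cfg$counts)) DESIGN_COUNTS else unlist(cfg$counts)
  simulation_scenario(params, counts, scale = cfg$scale, seed = cfg$seed)
}

#' Simulate a dataset to disk
#'
#' Writes `pairs.tsv` and its scenario sidecar into `out_dir`. Rerunning
#' the same config produces byte-identical output.
#'
#' @param config a [read_run_config()] result
#' @return path of the written TSV, invisibly
#' @export
run_simulate <- function(config) {
  scenario <- .cfg_scenario(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  data <- simulate_pairs(scenario)
  path <- file.path(config$out_dir, "pairs.tsv")
  write_pair_dataset(data, path, scenario = scenario)
  .log(config, "simulated ", nrow(data), " pairs (seed ", scenario$seed,
       ", scale ", scenario$scale, ") -> ", path)
  invisible(path)
}

#' Tetrachoric descriptives to disk
#'
#' @param config config with `input` (pair TSV) and `out_dir`
#' @return path of the written table, invisibly
#' @export
run_describe <- function(config) {
  data <- read_pair_dataset(config$input)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cs <- correlation_summary(data)
  path <- file.path(config$out_dir, "table1_correlations.tsv")
  write_correlation_summary(cs, path)
  .log(config, "wrote ", path)
  invisible(path)
}

#' @keywords internal
.table2_rows <- function(ic, ci_tab = NULL) {
  fmt_share <- function(s) ifelse(is.na(s), "-", sprintf("%.3f", s))
  data.frame(
    disorder = rep(ic$disorder, each = 3L),
    source = rep(c("A", "C", "E"), times = nrow(ic)),
    total = as.numeric(t(as.matrix(ic[, c("a2", "c2", "e2")]))),
    common = as.numeric(t(as.matrix(ic[, c("a2_common", "c2_common", "e2_common")]))),
    specific = as.numeric(t(as.matrix(ic[, c("a2_specific", "c2_specific", "e2_specific")]))),
    share_common = fmt_share(as.numeric(t(as.matrix(
      ic[, c("a2_share_common", "c2_share_common", "e2_share_common")])))),
    stringsAsFactors = FALSE
  )
}

#' Fit the models and emit the report bundle
#'
#' Fits the full common-factor model and the all-C-zero alternative,
#' compares them by AIC, fits all six bivariate models, and writes:
#' `table1_correlations.tsv`, `table2_variance_components.tsv`,
#' `table3_genetic_correlations.tsv` (bivariate estimates alongside the
#' common-factor-implied values), `figure1_model.json` and
#' `manifest.json`.
#'
#' @param config config with `input` (pair TSV) and `out_dir`
#' @return the manifest list, invisibly
#' @export
run_fit_and_report <- function(config) {
  t_start <- Sys.time()
  data <- read_pair_dataset(config$input)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- pattern_counts(data)
  disorders <- counts$disorders

  mk_spec <- function(variant) {
    fit_spec(variant = variant, likelihood = config$likelihood,
             threshold_groups = config$threshold_groups,
             multistart = config$multistart, seed = config$seed,
             ci = if (variant == "full") config$ci else "none",
             ci_reps = config$ci_reps)
  }
  .log(config, "fitting full common-factor model")
  fit_full <- fit_common_factor(counts, mk_spec("full"))
  .log(config, "fitting all-C-zero model")
  fit_noC <- fit_common_factor(counts, mk_spec("noC"))
  cmp <- compare_models(fit_full, fit_noC)

  # descriptives
  cs <- correlation_summary(data)
  p1 <- file.path(config$out_dir, "table1_correlations.tsv")
  write_correlation_summary(cs, p1)

  # variance components
  ic <- implied_components(fit_full$params)
  t2 <- .table2_rows(ic)
  if (!is.null(fit_full$ci)) {
    t2$note <- "CIs for free parameters in manifest"
  }
  p2 <- file.path(config$out_dir, "table2_variance_components.tsv")
  utils::write.table(t2, p2, sep = "\t", quote = FALSE, row.names = FALSE)

  # bivariate genetic correlations
  prs <- utils::combn(disorders, 2)
  biv <- vector("list", ncol(prs))
  for (k in seq_len(ncol(prs))) {
    d1 <- prs[1, k]; d2 <- prs[2, k]
    .log(config, "fitting bivariate model ", d1, "-", d2)
    bf <- fit_bivariate(data, c(d1, d2),
                        fit_spec(variant = "bivariate", seed = config$seed,
                                 multistart = config$multistart,
                                 threshold_groups = config$threshold_groups))
    biv[[k]] <- list(pair = c(d1, d2), fit = bf)
  }
  t3 <- do.call(rbind, lapply(biv, function(b) {
    data.frame(
      disorder_a = b$pair[1], disorder_b = b$pair[2],
      rA_bivariate = b$fit$params$rA,
      rA_common_factor = tryCatch(
        implied_genetic_correlation(fit_full$params, b$pair[1], b$pair[2]),
        error = function(e) NA_real_
      ),
      converged = b$fit$converged, stringsAsFactors = FALSE
    )
  }))
  p3 <- file.path(config$out_dir, "table3_genetic_correlations.tsv")
  utils::write.table(t3, p3, sep = "\t", quote = FALSE, row.names = FALSE)

  # figure-1-style model summary
  pf <- fit_full$params
  fig <- list(
    latent = list(Ac = pf$Ac, Cc = pf$Cc, Ec = pf$Ec),
    loadings = as.list(pf$loadings),
    specific = list(As = as.list(pf$As), Cs = as.list(pf$Cs),
                    Es = as.list(pf$Es)),
    thresholds = as.list(pf$thresholds[, "twin_full"])
  )
  if (!is.null(fit_full$ci)) {
    fig$ci <- list(parameter = fit_full$ci$parameter,
                   lower = fit_full$ci$lower, upper = fit_full$ci$upper)
  }
  p4 <- file.path(config$out_dir, "figure1_model.json")
  jsonlite::write_json(fig, p4, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("famliab")),
    seed = config$seed,
    counts_hash = fit_full$counts_hash,
    n_pairs = as.list(counts$n_pairs),
    model_comparison = list(
      preferred = cmp$preferred, delta_aic = cmp$delta_aic,
      aic_full = cmp$aic_full, aic_no_C = cmp$aic_constrained,
      k_full = fit_full$k, k_no_C = fit_noC$k,
      converged_full = fit_full$converged, converged_no_C = fit_noC$converged
    ),
    fits = list(
      full = jsonlite::fromJSON(fit_to_json(fit_full)),
      no_C = jsonlite::fromJSON(fit_to_json(fit_noC)),
      bivariate = lapply(biv, function(b) jsonlite::fromJSON(fit_to_json(b$fit)))
    ),
    outputs = c(table1 = p1, table2 = p2, table3 = p3, figure1 = p4),
    elapsed_seconds = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log(config, "report bundle written to ", config$out_dir,
       " (AIC full ", round(cmp$aic_full, 1), " vs no-C ",
       round(cmp$aic_constrained, 1), ", preferred: ",
       ifelse(cmp$preferred == "full", "full", "no-C"), ")")
  invisible(manifest)
}
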