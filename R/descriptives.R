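# Descriptive tetrachoric correlation families for relative-pair data.
#
# Three families per relative class: cross-relative within-disorder (the
# classical twin correlations), within-individual cross-disorder
# (comorbidity on the liability scale) and cross-relative cross-disorder.
# Cross-relative tables are symmetrized (each unordered pair counted in
# both orientations, the double-entry convention used for descriptives);
# model fitting does not double enter.

#' Build a 2x2 contingency table from pair data
#'
#' @param data a `pair_dataset`
#' @param cls relative class label
#' @param disorder_a disorder observed on the first member (rows)
#' @param disorder_b disorder observed on the second member (columns); for
#'   `type = "within_individual"` both disorders are read from `member`
#' @param type `"cross_relative"` (member 1 vs member 2, symmetrized by
#'   default) or `"within_individual"`
#' @param symmetrize count each unordered pair in both orientations
#'   (cross-relative tables only)
#' @param member which member carries both disorders for
#'   within-individual tables (1 or 2)
#' @return 2x2 matrix of counts (rows `disorder_a` 0/1, columns
#'   `disorder_b` 0/1)
#' @export
build_crosstab <- function(data, cls, disorder_a, disorder_b,
                           type = c("cross_relative", "within_individual"),
                           symmetrize = TRUE, member = 1L) {
  type <- match.arg(type)
  if (!cls %in% data$relative_class) stop("class not present in data: ", cls)
  d <- data[data$relative_class == cls, , drop = FALSE]
  col <- function(m, dis) {
    nm <- paste0("p", m, "_", dis)
    if (!nm %in% names(d)) stop("unknown disorder: ", dis)
    d[[nm]]
  }
  tab <- function(a, b) {
    m <- matrix(0, 2, 2, dimnames = list(c("0", "1"), c("0", "1")))
    m[1, 1] <- sum(a == 0 & b == 0); m[1, 2] <- sum(a == 0 & b == 1)
    m[2, 1] <- sum(a == 1 & b == 0); m[2, 2] <- sum(a == 1 & b == 1)
    m
  }
  if (type == "within_individual") {
    return(tab(col(member, disorder_a), col(member, disorder_b)))
  }
  out <- tab(col(1L, disorder_a), col(2L, disorder_b))
  if (symmetrize) out <- out + tab(col(2L, disorder_a), col(1L, disorder_b))
  out
}

#' Tetrachoric correlation summary of a pair dataset
#'
#' For every relative class present in the data (in the fixed order MZ, DZ,
#' FS, HST, HSA; absent classes are omitted) computes tetrachoric
#' correlations with standard errors and status flags for the three
#' correlation families: within-disorder cross-relative, within-individual
#' cross-disorder (pooled over the two members, so the summary is invariant
#' to member order), and cross-relative cross-disorder (all ordered
#' disorder pairs of the symmetrized tables).
#'
#' @param data a `pair_dataset`
#' @return a `correlation_summary` data frame with columns `class`,
#'   `family`, `disorder_a`, `disorder_b`, `r`, `se`, `status`, `n_pairs`
#' @export
correlation_summary <- function(data) {
  disorders <- attr(data, "disorders")
  if (is.null(disorders)) {
    disorders <- sub("^p1_", "", grep("^p1_", names(data), value = TRUE))
  }
  classes <- intersect(relative_classes()$label, unique(data$relative_class))
  if (!length(classes)) stop("no relative classes present")
  rows <- list()
  add <- function(cl, fam, da, db, tab, n_pairs) {
    tc <- tetrachoric(tab)
    rows[[length(rows) + 1L]] <<- data.frame(
      class = cl, family = fam, disorder_a = da, disorder_b = db,
      r = tc$r, se = tc$se, status = tc$status, n_pairs = n_pairs,
      stringsAsFactors = FALSE
    )
  }
  for (cl in classes) {
    np <- sum(data$relative_class == cl)
    for (d in disorders) {
      add(cl, "cross_relative_within_disorder", d, d,
          build_crosstab(data, cl, d, d), np)
    }
    nd <- length(disorders)
    for (i in seq_len(nd - 1L)) for (j in (i + 1L):nd) {
      tab <- build_crosstab(data, cl, disorders[i], disorders[j],
                            type = "within_individual", member = 1L) +
        build_crosstab(data, cl, disorders[i], disorders[j],
                       type = "within_individual", member = 2L)
      add(cl, "within_individual", disorders[i], disorders[j], tab, np)
    }
    for (da in disorders) for (db in disorders) {
      if (da == db) next
      add(cl, "cross_relative_cross_disorder", da, db,
          build_crosstab(data, cl, da, db), np)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("correlation_summary", class(out))
  out
}

#' Write a correlation summary as a wide TSV
#'
#' One row per correlation family and disorder pair, one column per
#' relative class, cells formatted `"r (se)"`; correlations that cannot be
#' estimated (empty margins or boundary solutions) print as `"-"`.
#'
#' @param x a [correlation_summary()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_correlation_summary <- function(x, path) {
  cell <- ifelse(
    x$status == "ok",
    sprintf("%.3f (%.3f)", x$r, x$se),
    "-"
  )
  key <- paste(x$family, x$disorder_a, x$disorder_b, sep = "|")
  classes <- intersect(relative_classes()$label, unique(x$class))
  keys <- unique(key)
  wide <- data.frame(
    family = x$family[match(keys, key)],
    disorder_a = x$disorder_a[match(keys, key)],
    disorder_b = x$disorder_b[match(keys, key)],
    stringsAsFactors = FALSE
  )
  for (cl in classes) {
    wide[[cl]] <- "-"
    sel <- x$class == cl
    wide[[cl]][match(key[sel], keys)] <- cell[sel]
  }
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
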