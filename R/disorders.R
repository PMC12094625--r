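# Disorder sets and relative-class definitions.

#' Default disorder labels
#' @keywords internal
DISORDERS <- c("MD", "AD", "IBS", "FM")

#' Define the set of disorders under study
#'
#' A disorder set couples labels with lifetime prevalences. The default is
#' the four-disorder design analysed throughout the package: major
#' depression (MD) and anxiety disorders (AD) at ~20% lifetime prevalence,
#' irritable bowel syndrome (IBS) at ~6% and fibromyalgia (FM) at ~1%.
#'
#' @param labels character vector of unique disorder identifiers
#' @param prevalence lifetime prevalences, strictly inside (0, 1)
#' @return a `disorder_set` data frame with columns `label`, `prevalence`
#'   and `threshold` (the standard-normal liability threshold implied by the
#'   prevalence)
#' @export
disorder_set <- function(labels = DISORDERS,
                         prevalence = c(0.20, 0.20, 0.06, 0.01)) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("disorder labels must be unique")
  if (length(prevalence) != length(labels)) {
    stop("prevalence must have one entry per label")
  }
  if (any(prevalence <= 0 | prevalence >= 1)) {
    stop("prevalences must lie strictly inside (0, 1)")
  }
  out <- data.frame(
    label = labels,
    prevalence = as.numeric(prevalence),
    threshold = threshold_from_prevalence(prevalence),
    stringsAsFactors = FALSE
  )
  class(out) <- c("disorder_set", class(out))
  out
}

#' Liability threshold implied by a lifetime prevalence
#'
#' Under the liability-threshold model a binary diagnosis is present iff a
#' standard-normal liability exceeds the threshold, so the threshold is the
#' upper-tail normal quantile of the prevalence.
#'
#' @param K prevalence(s) in (0, 1)
#' @return threshold(s) in standard-normal units
#' @examples
#' threshold_from_prevalence(0.5)    # 0
#' threshold_from_prevalence(0.20)   # 0.8416
#' @export
threshold_from_prevalence <- function(K) {
  if (any(!is.finite(K)) || any(K <= 0 | K >= 1)) {
    stop("prevalence must lie strictly inside (0, 1)")
  }
  stats::qnorm(K, lower.tail = FALSE)
}

#' The five relative classes of the extended twin-sibling design
#'
#' Each class carries its additive-genetic sharing coefficient `alpha`
#' (1 for MZ twins, 0.5 for DZ twins and full siblings, 0.25 for
#' half-siblings), its shared-environment indicator `gamma` (1 for pairs
#' reared together, 0 for half-siblings reared apart) and a twin flag that
#' activates optional twin-specific components.
#'
#' @return data frame with columns `label`, `alpha`, `gamma`, `is_twin`
#' @export
relative_classes <- function() {
  data.frame(
    label   = c("MZ", "DZ", "FS", "HST", "HSA"),
    alpha   = c(1.0, 0.5, 0.5, 0.25, 0.25),
    gamma   = c(1, 1, 1, 1, 0),
    is_twin = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Look up a single relative class
#'
#' @param label one of `"MZ"`, `"DZ"`, `"FS"`, `"HST"`, `"HSA"`
#' @return one-row data frame (see [relative_classes()])
#' @export
relative_class <- function(label) {
  rc <- relative_classes()
  i <- match(label, rc$label)
  if (is.na(i)) stop("unknown relative class: ", label)
  rc[i, , drop = FALSE]
}

#' Family-type group of a relative class
#'
#' Twin and full-sibling pairs come from intact families; half-sibling pairs
#' from half-sibling families, where prevalences can run moderately higher.
#' Used when thresholds are allowed to differ by family type.
#'
#' @param label relative-class label(s)
#' @return `"twin_full"` or `"half_sib"` per label
#' @keywords internal
class_group <- function(label) {
  ifelse(label %in% c("MZ", "DZ", "FS"), "twin_full", "half_sib")
}
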