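#' Construct and validate a scan manifest
#'
#' The scan manifest is the cohort roster: one row per imaging scan, linking
#' the scan to its subject and class label. All population graphs, feature
#' matrices and split plans follow the manifest's row order; nothing is ever
#' implicitly sorted.
#'
#' @param x A data frame with columns `scan_id`, `subject_id`, `label`
#'   (class index, 0 = healthy control, 1 = disease) and optionally
#'   `is_augmented` (logical, defaults to `FALSE`).
#' @param require_both_classes Require both classes to be present (needed
#'   whenever a model is to be trained). Default `FALSE`.
#'
#' @return A tibble of class `scan_manifest` with columns `scan_id`,
#'   `subject_id`, `label`, `is_augmented`, in the input row order.
#' @export
#' @examples
#' as_scan_manifest(data.frame(
#'   scan_id = c("s1", "s2"), subject_id = c("a", "a"), label = c(1, 1)
#' ))
as_scan_manifest <- function(x, require_both_classes = FALSE) {
  stopifnot(is.data.frame(x))
  needed <- c("scan_id", "subject_id", "label")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  out <- tibble::as_tibble(x)
  out$scan_id <- as.character(out$scan_id)
  out$subject_id <- as.character(out$subject_id)
  out$label <- as.integer(out$label)
  if (!"is_augmented" %in% names(out)) out$is_augmented <- FALSE
  out$is_augmented <- as.logical(out$is_augmented)
  out <- out[, c("scan_id", "subject_id", "label", "is_augmented",
                 setdiff(names(out), c("scan_id", "subject_id", "label", "is_augmented")))]

  if (anyDuplicated(out$scan_id)) {
    dup <- unique(out$scan_id[duplicated(out$scan_id)])
    stop("duplicate scan_id in manifest: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (any(is.na(out$scan_id)) || any(is.na(out$subject_id)) || any(is.na(out$label))) {
    stop("manifest contains missing scan_id, subject_id or label values")
  }
  if (!all(out$label %in% c(0L, 1L))) {
    stop("labels must be class indices in {0, 1}")
  }
  # a subject must carry a single label across its scans
  lab_per_subj <- tapply(out$label, out$subject_id, function(l) length(unique(l)))
  if (any(lab_per_subj > 1)) {
    stop("subjects with conflicting labels across scans: ",
         paste(names(lab_per_subj)[lab_per_subj > 1], collapse = ", "))
  }
  if (require_both_classes && length(unique(out$label)) < 2) {
    stop("both classes must be present to train a model; got only class ",
         unique(out$label))
  }
  class(out) <- c("scan_manifest", class(out))
  out
}

#' Per-class counts and the majority-class fraction of a cohort
#'
#' @param manifest A scan manifest (or any data frame with a `label` column).
#' @return A tibble with one row per class: `label`, `n_scans`,
#'   `fraction` (of scans) and `majority` flag.
#' @export
class_balance <- function(manifest) {
  lab <- manifest$label
  tab <- table(factor(lab, levels = sort(unique(lab))))
  out <- tibble::tibble(
    label = as.integer(names(tab)),
    n_scans = as.integer(tab),
    fraction = as.numeric(tab) / length(lab)
  )
  out$majority <- out$n_scans == max(out$n_scans)
  out
}
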