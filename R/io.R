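# Delimited-text readers/writers shared by all modules. Everything is
# plain TSV for diffability; numeric values are written with 10 significant
# digits, which bounds the round-trip error of every artifact.

fmt_num <- function(x) sprintf("%.10g", x)

write_matrix_tsv <- function(m, path) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  chr <- matrix(fmt_num(m), nrow(m), ncol(m))
  lines <- c(paste(c("id", colnames(m)), collapse = "\t"),
             paste(rownames(m), apply(chr, 1, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric or missing cells in ", path)
  rownames(m) <- ids
  m
}

#' Read a square connectivity matrix
#'
#' Expects delimited text with a header row and a first column of region
#' labels. The matrix must be square and symmetric within `tolerance`;
#' asymmetry is reported with the offending region pair.
#'
#' @param path File path.
#' @param tolerance Symmetry tolerance (default 1e-6).
#' @return A named R x R numeric matrix with a `region_labels` attribute.
#' @export
read_connectivity_matrix <- function(path, tolerance = 1e-6) {
  m <- read_matrix_tsv(path)
  if (nrow(m) != ncol(m)) {
    stop(sprintf("%s: matrix is not square (%d x %d)", path, nrow(m), ncol(m)))
  }
  if (!identical(rownames(m), colnames(m))) {
    stop(path, ": row and column region labels disagree")
  }
  asym <- abs(m - t(m))
  if (max(asym) > tolerance) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("%s: asymmetric beyond tolerance at regions (%s, %s): |%g - %g|",
                 path, rownames(m)[ij[1]], colnames(m)[ij[2]],
                 m[ij[1], ij[2]], m[ij[2], ij[1]]))
  }
  attr(m, "region_labels") <- rownames(m)
  m
}

#' Vectorise the strict upper triangle of a square matrix
#'
#' Row-major over region pairs (i < j) with 0-based region indexing — the
#' package-wide vectorisation convention for connectivity matrices.
#'
#' @param m Square matrix.
#' @return Numeric vector of length R(R-1)/2, named `i_j` by pair.
#' @export
upper_triangle_vector <- function(m) {
  R <- nrow(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]  # row-major pair order
  v <- m[idx]
  names(v) <- sprintf("%d_%d", idx[, 1] - 1L, idx[, 2] - 1L)
  v
}

#' Read a subject-level omics table
#'
#' Delimited text with a header row; first column is `subject_id`, the
#' remaining columns are numeric features. Duplicate subjects or missing
#' cells are errors.
#'
#' @param path File path.
#' @param omics_type Name for the omics type (default: file stem).
#' @return An [omics_table()].
#' @export
read_omics_table <- function(path, omics_type = NULL) {
  if (is.null(omics_type)) {
    omics_type <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- utils::read.delim(path, check.names = FALSE)
  if (names(df)[1] != "subject_id") {
    stop(path, ": first column must be subject_id, got ", names(df)[1])
  }
  ids <- as.character(df$subject_id)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("%s: missing or non-numeric cell at subject %s, feature %s",
                 path, ids[bad[1]], colnames(m)[bad[2]]))
  }
  omics_table(m, omics_type, subject_ids = ids)
}

#' Write a population graph as delimited text
#'
#' @param graph A `population_graph`.
#' @param path Output path.
#' @export
write_population_graph <- function(graph, path) {
  write_matrix_tsv(graph$adjacency, path)
  invisible(path)
}

#' Read a population graph written by [write_population_graph()]
#'
#' @param path File path.
#' @param kind `"PSG"` or `"POG"`.
#' @return A `population_graph`.
#' @export
read_population_graph <- function(path, kind = "PSG") {
  m <- read_matrix_tsv(path)
  colnames(m) <- rownames(m)
  new_population_graph(kind, m, rownames(m), sprintf("read from %s", path))
}

#' Write a cohort as the on-disk file tree
#'
#' Emits exactly the external formats the readers consume: a scan manifest
#' (`manifest.tsv`), one square connectivity matrix per scan per modality
#' (`connectivity/<modality>/<scan_id>.tsv`), and one subject-level omics
#' table per omics type (`omics/<type>.tsv`). Values round-trip through the
#' readers to 10 significant digits.
#'
#' @param cohort A cohort (e.g. from [simulate_cohort()]).
#' @param directory Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  utils::write.table(
    data.frame(scan_id = man$scan_id, subject_id = man$subject_id,
               label = man$label, is_augmented = man$is_augmented),
    file.path(directory, "manifest.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  for (mod in names(cohort$connectivity)) {
    f <- cohort$connectivity[[mod]]
    mod_dir <- file.path(directory, "connectivity", mod)
    dir.create(mod_dir, recursive = TRUE, showWarnings = FALSE)
    R <- f$atlas_size
    labels <- sprintf("r%03d", seq_len(R) - 1L)  # 0-based region labels
    for (p in seq_len(nrow(f$matrix))) {
      m <- matrix(0, R, R, dimnames = list(labels, labels))
      m[upper.tri(m)] <- 0  # filled below in row-major pair order
      idx <- which(upper.tri(m), arr.ind = TRUE)
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      m[idx] <- f$matrix[p, ]
      m <- m + t(m)
      diag(m) <- 1
      write_matrix_tsv(m, file.path(mod_dir, paste0(man$scan_id[p], ".tsv")))
    }
  }

  om_dir <- file.path(directory, "omics")
  dir.create(om_dir, recursive = TRUE, showWarnings = FALSE)
  for (tp in names(cohort$omics)) {
    o <- cohort$omics[[tp]]
    chr <- matrix(fmt_num(o$matrix), nrow(o$matrix), ncol(o$matrix))
    lines <- c(paste(c("subject_id", colnames(o$matrix)), collapse = "\t"),
               paste(o$subject_ids, apply(chr, 1, paste, collapse = "\t"),
                     sep = "\t"))
    writeLines(lines, file.path(om_dir, paste0(tp, ".tsv")))
  }
  invisible(directory)
}

#' Read a cohort file tree written by [write_cohort()]
#'
#' @param directory Cohort directory.
#' @param symmetry_tolerance Tolerance passed to
#'   [read_connectivity_matrix()].
#' @return A list with `manifest`, `connectivity`, `omics` (no `truth`).
#' @export
read_cohort <- function(directory, symmetry_tolerance = 1e-6) {
  man <- as_scan_manifest(
    utils::read.delim(file.path(directory, "manifest.tsv")))
  conn_dir <- file.path(directory, "connectivity")
  connectivity <- list()
  for (mod in list.dirs(conn_dir, recursive = FALSE, full.names = FALSE)) {
    rows <- lapply(man$scan_id, function(sid) {
      m <- read_connectivity_matrix(
        file.path(conn_dir, mod, paste0(sid, ".tsv")), symmetry_tolerance)
      upper_triangle_vector(m)
    })
    X <- do.call(rbind, rows)
    rownames(X) <- man$scan_id
    R <- (1 + sqrt(1 + 8 * ncol(X))) / 2
    connectivity[[mod]] <- connectivity_features(X, mod, as.integer(round(R)))
  }
  om_dir <- file.path(directory, "omics")
  omics <- list()
  for (f in list.files(om_dir, pattern = "\\.tsv$")) {
    tp <- sub("\\.tsv$", "", f)
    omics[[tp]] <- read_omics_table(file.path(om_dir, f), tp)
  }
  structure(list(manifest = man, connectivity = connectivity, omics = omics),
            class = "synthetic_cohort")
}
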