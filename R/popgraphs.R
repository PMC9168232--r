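#' Pearson similarity between two feature vectors
#'
#' The similarity measure underlying both population graph flavours. A vector
#' with zero variance yields similarity 0 (rather than an error): degenerate
#' scans must not abort cohort-graph construction. Callers that need to know
#' whether the degenerate branch was taken can inspect the `"degenerate"`
#' attribute.
#'
#' @param x_u,x_v Numeric vectors of equal length >= 2.
#' @return The sample Pearson correlation in \[-1, 1\]; 0 if either vector is
#'   constant, with attribute `degenerate = TRUE` in that case.
#' @export
#' @examples
#' pearson_similarity(c(1, 2, 3), c(3, 2, 1))
pearson_similarity <- function(x_u, x_v) {
  stopifnot(length(x_u) == length(x_v), length(x_u) >= 2)
  su <- stats::sd(x_u)
  sv <- stats::sd(x_v)
  if (!is.finite(su) || !is.finite(sv) || su == 0 || sv == 0) {
    return(structure(0, degenerate = TRUE))
  }
  stats::cor(x_u, x_v)
}

# Pairwise Pearson correlations between the rows of a matrix.
# Zero-variance rows get similarity 0 against everything (including
# themselves); the degenerate-row indices are returned as an attribute.
row_correlations <- function(x) {
  stopifnot(is.matrix(x), ncol(x) >= 2)
  sds <- apply(x, 1, stats::sd)
  degen <- which(!is.finite(sds) | sds == 0)
  cc <- suppressWarnings(stats::cor(t(x)))
  if (length(degen) > 0) {
    cc[degen, ] <- 0
    cc[, degen] <- 0
  }
  cc[!is.finite(cc)] <- 0
  # cor() is symmetric up to representation; enforce exactly
  cc <- (cc + t(cc)) / 2
  attr(cc, "degenerate_rows") <- degen
  cc
}

new_population_graph <- function(kind, adjacency, scan_ids, provenance) {
  stopifnot(kind %in% c("PSG", "POG"), is.matrix(adjacency),
            nrow(adjacency) == ncol(adjacency))
  dimnames(adjacency) <- list(scan_ids, scan_ids)
  structure(
    list(kind = kind, adjacency = adjacency, scan_ids = scan_ids,
         provenance = provenance),
    class = "population_graph"
  )
}

#' @export
print.population_graph <- function(x, ...) {
  off <- x$adjacency[upper.tri(x$adjacency)]
  cat(sprintf("<population_graph> %s over %d scans\n", x$kind, nrow(x$adjacency)))
  cat(sprintf("  off-diagonal range [%.4f, %.4f], mean %.4f\n",
              min(off), max(off), mean(off)))
  cat("  provenance:", paste(x$provenance, collapse = " | "), "\n")
  invisible(x)
}

#' Build the population scan graph (PSG) from connectivity features
#'
#' For each imaging modality the pairwise Pearson similarities between scans
#' are computed, the full P x P similarity matrix is min-max normalised to
#' \[0, 1\] (over all entries, diagonal included), incremented by 1 so its
#' minimum is 1, and multiplied elementwise into the running PSG, which
#' starts as a matrix of ones. With M modalities every entry of the fused
#' PSG lies in \[1, 2^M\].
#'
#' A constant similarity matrix (max equals min) min-max-normalises to all
#' zeros, hence contributes the all-ones factor after the +1 — the fusion
#' identity, so an information-free modality leaves the PSG unchanged.
#'
#' @param features A list of connectivity feature sets as produced by
#'   [connectivity_features()]: each element has a `matrix` (P x J_m, scans
#'   in manifest order) and a `modality` name. All must share the same P.
#' @param scan_ids Optional scan identifiers (length P) used to label the
#'   adjacency matrix.
#' @return A `population_graph` of kind `"PSG"`.
#' @export
build_psg <- function(features, scan_ids = NULL) {
  stopifnot(is.list(features), length(features) >= 1)
  if (!is.null(features$matrix)) features <- list(features)
  P <- nrow(features[[1]]$matrix)
  prov <- character(0)
  A <- matrix(1, P, P)
  for (f in features) {
    X <- f$matrix
    if (!is.matrix(X) || nrow(X) != P) {
      stop("connectivity feature matrices disagree on the number of scans (",
           nrow(X), " vs ", P, ")")
    }
    Am <- row_correlations(X)
    degen <- attr(Am, "degenerate_rows")
    attr(Am, "degenerate_rows") <- NULL
    rng <- range(Am)
    if (rng[2] > rng[1]) {
      Am <- (Am - rng[1]) / (rng[2] - rng[1])
    } else {
      Am[] <- 0  # constant similarity: information-free, becomes the fusion identity
    }
    Am <- Am + 1
    A <- A * Am
    prov <- c(prov, sprintf("%s: pearson -> minmax -> +1%s",
                            f$modality %||% "modality",
                            if (length(degen) > 0) sprintf(" [%d zero-variance scans]", length(degen)) else ""))
  }
  A <- (A + t(A)) / 2
  if (is.null(scan_ids)) scan_ids <- rownames(features[[1]]$matrix)
  new_population_graph("PSG", A, scan_ids,
                       c(prov, sprintf("product fusion of %d modalities", length(features))))
}

#' WGCNA soft-threshold power scaling
#'
#' Re-scales a similarity matrix so the implied weighted network's degree
#' distribution approaches a power law: the unsigned weighted-network
#' adjacency `|s|^beta`. Order-preserving on the similarity magnitude and
#' symmetric whenever the input is.
#'
#' @param similarity A square matrix with entries in \[-1, 1\].
#' @param beta Positive soft-threshold power.
#' @return A matrix of the same dimensions with entries in \[0, 1\].
#' @export
wgcna_power_scale <- function(similarity, beta) {
  stopifnot(is.matrix(similarity), nrow(similarity) == ncol(similarity))
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta) || beta <= 0) {
    stop("beta must be a single positive number, got: ", format(beta))
  }
  abs(similarity)^beta
}

#' Choose a WGCNA soft-threshold power by scale-free fit
#'
#' Scans the candidate powers in increasing order and returns the smallest
#' one whose scaled network achieves a scale-free-topology fit R^2 >= `rsq_cut`
#' (log-log regression of binned degree frequency on degree, over at least 5
#' occupied bins). If no candidate qualifies, the candidate with the highest
#' fit is returned. With fewer than 10 nodes (or a degenerate fit everywhere)
#' the fixed default power 6 is returned with a warning.
#'
#' @param similarity Square similarity matrix in \[-1, 1\].
#' @param candidate_betas Numeric vector of candidate powers (default 1:10).
#' @param rsq_cut Scale-free fit threshold (default 0.8).
#' @return The selected power (a single number).
#' @export
pick_soft_threshold <- function(similarity, candidate_betas = 1:10, rsq_cut = 0.8) {
  stopifnot(length(candidate_betas) >= 1)
  candidate_betas <- sort(candidate_betas)
  P <- nrow(similarity)
  if (P < 10) {
    warning("fewer than 10 nodes: falling back to fixed default beta = 6")
    return(6)
  }
  if (length(candidate_betas) == 1) return(candidate_betas[1])
  fits <- vapply(candidate_betas, function(b) {
    a <- wgcna_power_scale(similarity, b)
    diag(a) <- 0
    scale_free_fit(rowSums(a))
  }, numeric(1))
  if (all(is.na(fits))) {
    warning("scale-free fit undefined for every candidate: falling back to beta = 6")
    return(6)
  }
  ok <- which(!is.na(fits) & fits >= rsq_cut)
  if (length(ok) > 0) candidate_betas[ok[1]] else candidate_betas[which.max(fits)]
}

# R^2 of the log10(frequency) ~ log10(degree) regression over >= 5 occupied
# equal-width degree bins; NA when the fit is undefined (degenerate degrees).
scale_free_fit <- function(degrees, n_bins = 10) {
  degrees <- degrees[is.finite(degrees) & degrees > 0]
  if (length(degrees) < 10 || diff(range(degrees)) == 0) return(NA_real_)
  cuts <- seq(min(degrees), max(degrees), length.out = n_bins + 1)
  bin <- cut(degrees, cuts, include.lowest = TRUE)
  freq <- tapply(degrees, bin, length)
  mid <- tapply(degrees, bin, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 5) return(NA_real_)
  x <- log10(mid[keep])
  y <- log10(freq[keep] / sum(freq[keep]))
  if (diff(range(x)) == 0) return(NA_real_)
  summary(stats::lm(y ~ x))$r.squared
}

#' Expand a subject-level graph to scan level
#'
#' Entry (p, q) of the result equals entry (subject(p), subject(q)) of the
#' input, so a subject with k scans induces a constant k x k block. The
#' output follows the manifest's scan order.
#'
#' @param subject_graph S x S matrix with subject ids as dimnames.
#' @param manifest A scan manifest; every subject in it must appear in
#'   `subject_graph`.
#' @return A P x P matrix with scan ids as dimnames.
#' @export
duplicate_scans <- function(subject_graph, manifest) {
  stopifnot(is.matrix(subject_graph), !is.null(rownames(subject_graph)))
  missing_subj <- setdiff(unique(manifest$subject_id), rownames(subject_graph))
  if (length(missing_subj) > 0) {
    offending <- manifest$scan_id[manifest$subject_id %in% missing_subj]
    stop("scans whose subject lacks omics data: ",
         paste(utils::head(offending, 5), collapse = ", "),
         " (subjects: ", paste(utils::head(missing_subj, 5), collapse = ", "), ")")
  }
  idx <- match(manifest$subject_id, rownames(subject_graph))
  out <- subject_graph[idx, idx, drop = FALSE]
  dimnames(out) <- list(manifest$scan_id, manifest$scan_id)
  out
}

#' Build a population omics graph (POG)
#'
#' Subject-level Pearson correlations between omics feature vectors, with the
#' diagonal forced to 1 (self-loops), WGCNA power scaling, and duplication to
#' scan level for subjects with more than one imaging scan. Entries of the
#' result lie in \[0, 1\] with a unit diagonal.
#'
#' @param omics An omics table as produced by [omics_table()]: a list with a
#'   subjects x features `matrix` (rownames are subject ids) and an
#'   `omics_type` name.
#' @param manifest A scan manifest; all its subjects must be present.
#' @param beta_policy Either a fixed positive power (default 6, the unsigned
#'   WGCNA convention) or the string `"scale_free"` to select the power with
#'   [pick_soft_threshold()].
#' @return A `population_graph` of kind `"POG"`.
#' @export
build_pog <- function(omics, manifest, beta_policy = 6) {
  O <- omics$matrix
  stopifnot(is.matrix(O), !is.null(rownames(O)))
  B <- row_correlations(O)
  degen <- attr(B, "degenerate_rows")
  attr(B, "degenerate_rows") <- NULL
  diag(B) <- 1
  if (identical(beta_policy, "scale_free")) {
    beta <- pick_soft_threshold(B)
  } else {
    beta <- beta_policy
  }
  B <- wgcna_power_scale(B, beta)
  diag(B) <- 1
  dimnames(B) <- list(rownames(O), rownames(O))
  A <- duplicate_scans(B, manifest)
  new_population_graph(
    "POG", A, manifest$scan_id,
    c(sprintf("%s: subject pearson -> self-loops -> |r|^%g -> scan duplication",
              omics$omics_type %||% "omics", beta),
      if (length(degen) > 0) sprintf("%d zero-variance subjects", length(degen)))
  )
}

#' Bundle vectorised connectivity features for one modality
#'
#' @param matrix P x J_m matrix of vectorised strict-upper-triangle
#'   connectivity features, scans as rows in manifest order.
#' @param modality Modality name.
#' @param atlas_size Number of atlas regions R; J_m must equal R(R-1)/2.
#' @return A list of class `connectivity_features`.
#' @export
connectivity_features <- function(matrix, modality, atlas_size) {
  stopifnot(is.matrix(matrix))
  J <- atlas_size * (atlas_size - 1) / 2
  if (ncol(matrix) != J) {
    stop(sprintf("modality %s: expected J = R(R-1)/2 = %d features for R = %d, got %d",
                 modality, J, atlas_size, ncol(matrix)))
  }
  structure(list(matrix = matrix, modality = modality, atlas_size = atlas_size),
            class = "connectivity_features")
}

#' Bundle a subject-level omics feature table
#'
#' @param matrix S x K_n numeric matrix, subjects as rows.
#' @param omics_type Name of the omics type.
#' @param subject_ids Subject identifiers (defaults to rownames).
#' @return A list of class `omics_table`.
#' @export
omics_table <- function(matrix, omics_type, subject_ids = rownames(matrix)) {
  stopifnot(is.matrix(matrix), ncol(matrix) >= 1)
  if (is.null(subject_ids)) stop("omics table needs subject ids")
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids in omics table")
  if (anyNA(matrix)) stop("omics table ", omics_type, " contains missing values")
  rownames(matrix) <- subject_ids
  structure(list(matrix = matrix, omics_type = omics_type,
                 subject_ids = subject_ids, feature_ids = colnames(matrix)),
            class = "omics_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
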