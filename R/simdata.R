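#' Synthetic-cohort simulation recipe
#'
#' Defines the generative model for a synthetic multi-modal imaging and
#' multi-omics cohort with known ground truth: subjects carry a class label
#' (drawn Bernoulli with minority probability `1 - imbalance`) and a latent
#' factor vector; each subject contributes one or more scans; per-scan
#' connectivity matrices are a shared template plus a class component
#' (scaled by the modality's `class_effect_size`), a subject component
#' driven by the latent factors, and scan noise; omics feature tables get a
#' class mean shift of `effect_size` noise-sd units on a random 10% feature
#' subset when `informative`, on top of a feature baseline profile and
#' subject-correlated (latent-driven) structure, so population omics graphs
#' carry subject similarity even for uninformative omics types.
#'
#' The desk-scale defaults (120 subjects, 20 regions, two modalities, three
#' omics types of very different width, 75% majority class, 1.5 scans per
#' subject) keep every protocol run in minutes while preserving the
#' structural features of a real paired imaging/omics cohort.
#'
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param n_subjects Number of subjects.
#' @param imbalance Majority-class fraction pi in (0, 1); labels are drawn
#'   Bernoulli(1 - pi), so class 0 is the majority in expectation.
#' @param atlas_size Number of atlas regions R (>= 4).
#' @param modalities Data frame with columns `name`, `noise_sd`,
#'   `class_effect_size`.
#' @param omics_types Data frame with columns `name`, `k`, `informative`,
#'   `effect_size`, `noise_sd`.
#' @param scans_per_subject Mean of the 1-shifted Poisson scan count.
#' @param latent_dim Dimension of the per-subject latent factors.
#' @param baseline_sd Fallback spread of the shared per-feature omics
#'   baseline profile, used when `omics_types` carries no `baseline_sd`
#'   column. The per-type values control the background correlation between
#'   subjects: types with a strong shared profile (expression-like) give
#'   population omics graphs with uniformly high similarities, while a weak
#'   shared profile (genotype-like) gives low background similarity.
#' @param latent_loading_sd Scale of the latent-factor loadings in the
#'   omics tables.
#' @param subject_effect_sd Scale of the subject-specific connectivity
#'   component (total sd across latent dimensions); controls how strongly
#'   between-subject connectome similarity varies, i.e. how peaked the PSG
#'   similarity profiles are.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1,
    n_subjects = 120,
    imbalance = 0.75,
    atlas_size = 20,
    modalities = data.frame(name = c("dti", "fmri"),
                            noise_sd = c(0.3, 0.3),
                            class_effect_size = c(0, 0)),
    omics_types = data.frame(name = c("omA", "omB", "omC"),
                             k = c(50, 200, 500),
                             informative = c(FALSE, FALSE, FALSE),
                             effect_size = c(0, 0, 0),
                             noise_sd = c(1, 1, 1),
                             baseline_sd = c(2.5, 1.6, 0.5)),
    scans_per_subject = 1.5,
    latent_dim = 8,
    baseline_sd = 1.6,
    latent_loading_sd = 0.12,
    subject_effect_sd = 1) {
  stopifnot(imbalance > 0, imbalance < 1, atlas_size >= 4,
            n_subjects >= 2, scans_per_subject >= 1, latent_dim >= 1,
            all(omics_types$k >= 2), all(omics_types$effect_size >= 0),
            all(modalities$class_effect_size >= 0))
  structure(list(
    seed = seed, n_subjects = n_subjects, imbalance = imbalance,
    atlas_size = atlas_size, modalities = modalities,
    omics_types = omics_types, scans_per_subject = scans_per_subject,
    latent_dim = latent_dim, baseline_sd = baseline_sd,
    latent_loading_sd = latent_loading_sd,
    subject_effect_sd = subject_effect_sd
  ), class = "simulation_config")
}

#' Desk-scale recovery preset: one informative omics type
#'
#' The default simulation recipe with the class signal confined to the
#' widest omics type (effect 2 noise-sd units on 10% of its features) —
#' the standard test bed for end-to-end signal recovery.
#'
#' @param seed Integer seed.
#' @param effect_size Class shift in noise-sd units (default 2).
#' @return A `simulation_config`.
#' @export
preset_one_informative_omics <- function(seed = 1, effect_size = 2) {
  cfg <- simulation_config(seed = seed)
  cfg$omics_types$informative <- c(FALSE, FALSE, TRUE)
  cfg$omics_types$effect_size <- c(0, 0, effect_size)
  cfg
}

#' Desk-scale null preset: no class signal anywhere
#'
#' @param seed Integer seed.
#' @return A `simulation_config` with all effect sizes zero.
#' @export
preset_null <- function(seed = 1) {
  simulation_config(seed = seed)
}

sym_noise <- function(R, sd) {
  m <- matrix(stats::rnorm(R * R, 0, sd), R, R)
  (m + t(m)) / sqrt(2)
}

upper_vec <- function(m) m[upper.tri(m)]

#' Simulate a synthetic cohort
#'
#' Draws subjects, labels, latent factors and scan counts, then generates
#' per-scan symmetric unit-diagonal connectivity matrices (vectorised to
#' strict-upper-triangle features in row-major pair order) and subject-level
#' omics tables according to the recipe. Bitwise reproducible from the
#' config seed.
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_cohort`: `manifest` (scan manifest),
#'   `connectivity` (named list of [connectivity_features()]), `omics`
#'   (named list of [omics_table()]), and `truth` (subject labels, latent
#'   factors, informative flags, per-omics shifted feature indices).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, {
    S <- config$n_subjects
    labels <- stats::rbinom(S, 1, 1 - config$imbalance)
    if (length(unique(labels)) < 2) {
      stop(sprintf(
        "degenerate draw: class counts %d/%d — increase n_subjects or soften imbalance",
        sum(labels == 0), sum(labels == 1)))
    }
    subject_ids <- sprintf("subj%03d", seq_len(S))
    z <- matrix(stats::rnorm(S * config$latent_dim), S, config$latent_dim)
    n_scans <- 1 + stats::rpois(S, config$scans_per_subject - 1)

    manifest <- as_scan_manifest(tibble::tibble(
      scan_id = sprintf("%s.scan%d", rep(subject_ids, n_scans),
                        unlist(lapply(n_scans, seq_len))),
      subject_id = rep(subject_ids, n_scans),
      label = rep(labels, n_scans),
      is_augmented = FALSE
    ))
    scan_subj <- match(manifest$subject_id, subject_ids)
    R <- config$atlas_size

    connectivity <- list()
    for (i in seq_len(nrow(config$modalities))) {
      mod <- config$modalities[i, ]
      base <- sym_noise(R, 1)
      class_dir <- stats::rnorm(R)
      class_comp <- tcrossprod(class_dir) / sqrt(R)
      subj_loadings <- lapply(seq_len(config$latent_dim), function(k) {
        sym_noise(R, config$subject_effect_sd / sqrt(config$latent_dim))
      })
      X <- matrix(NA_real_, nrow(manifest), R * (R - 1) / 2)
      for (p in seq_len(nrow(manifest))) {
        s <- scan_subj[p]
        W <- base +
          mod$class_effect_size * manifest$label[p] * class_comp +
          Reduce(`+`, Map(function(k, L) z[s, k] * L,
                          seq_len(config$latent_dim), subj_loadings)) +
          sym_noise(R, mod$noise_sd)
        diag(W) <- 1
        X[p, ] <- upper_vec(W)
      }
      rownames(X) <- manifest$scan_id
      connectivity[[mod$name]] <- connectivity_features(X, mod$name, R)
    }

    omics <- list()
    truth_shift <- list()
    for (i in seq_len(nrow(config$omics_types))) {
      ot <- config$omics_types[i, ]
      K <- ot$k
      bsd <- if (!is.null(ot$baseline_sd)) ot$baseline_sd else config$baseline_sd
      baseline <- stats::rnorm(K, 0, bsd)
      G <- matrix(stats::rnorm(K * config$latent_dim, 0, config$latent_loading_sd),
                  K, config$latent_dim)
      shift <- rep(0, K)
      shifted_idx <- integer(0)
      if (isTRUE(ot$informative) && ot$effect_size > 0) {
        shifted_idx <- sample(K, max(1, round(0.1 * K)))
        shift[shifted_idx] <- sample(c(-1, 1), length(shifted_idx), replace = TRUE) *
          ot$effect_size * ot$noise_sd
      }
      O <- matrix(stats::rnorm(S * K, 0, ot$noise_sd), S, K)
      O <- O + rep(baseline, each = S) + z %*% t(G) +
        outer(labels, shift)
      rownames(O) <- subject_ids
      colnames(O) <- sprintf("%s_f%d", ot$name, seq_len(K))
      omics[[ot$name]] <- omics_table(O, ot$name)
      truth_shift[[ot$name]] <- shifted_idx
    }

    structure(list(
      manifest = manifest,
      connectivity = connectivity,
      omics = omics,
      truth = list(
        subject_ids = subject_ids, labels = labels, latent = z,
        informative = stats::setNames(as.logical(config$omics_types$informative),
                                      config$omics_types$name),
        shifted_features = truth_shift,
        config = config
      )
    ), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cb <- class_balance(x$manifest)
  cat(sprintf("<synthetic_cohort> %d subjects, %d scans\n",
              length(x$truth$subject_ids), nrow(x$manifest)))
  cat(sprintf("  scans per class: %s\n",
              paste(sprintf("class %d: %d (%.1f%%)", cb$label, cb$n_scans,
                            100 * cb$fraction), collapse = ", ")))
  cat(sprintf("  modalities: %s\n", paste(names(x$connectivity), collapse = ", ")))
  inf <- names(x$truth$informative)[x$truth$informative]
  cat(sprintf("  omics: %s (informative: %s)\n",
              paste(names(x$omics), collapse = ", "),
              if (length(inf) > 0) paste(inf, collapse = ", ") else "none"))
  invisible(x)
}
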