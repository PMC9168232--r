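#' Backward elimination over omics types
#'
#' Starting from the full set, every leave-one-out subset is scored; if the
#' best of them scores strictly higher than the current best model, it is
#' accepted and the procedure recurses, terminating when no strict
#' improvement is found or no omics type remains. Ties among equally
#' scoring subsets are broken by the lexicographic order of the removed
#' omics name. A failing score function marks the subset with `-Inf` and
#' the search continues.
#'
#' @param omics_names Character vector of omics type names (>= 1).
#' @param score_fn Function mapping a character vector (subset) to a single
#'   numeric score (in production an MCC from [run_protocol()]; in tests a
#'   lookup table).
#' @return A list of class `elimination_trace`: `trace` (tibble with
#'   `round`, `subset`, `removed`, `score`, `accepted`), `final_subset`,
#'   `final_score`, `termination` (`"no_improvement"` or `"exhausted"`).
#' @export
backward_eliminate <- function(omics_names, score_fn) {
  stopifnot(length(omics_names) >= 1, is.function(score_fn))
  safe_score <- function(subset) {
    v <- tryCatch(as.numeric(score_fn(subset)), error = function(e) -Inf)
    if (length(v) != 1 || is.na(v)) -Inf else v
  }
  current <- omics_names
  best_score <- safe_score(current)
  rows <- list(tibble::tibble(
    round = 0L, subset = paste(current, collapse = "-"),
    removed = NA_character_, score = best_score, accepted = TRUE
  ))
  round <- 0L
  termination <- "no_improvement"
  while (length(current) > 0) {
    round <- round + 1L
    removed_order <- sort(current, method = "radix")  # locale-independent tie-break
    cand <- lapply(removed_order, function(r) {
      subset <- setdiff(current, r)
      list(removed = r, subset = subset, score = safe_score(subset))
    })
    scores <- vapply(cand, `[[`, numeric(1), "score")
    rows[[length(rows) + 1]] <- tibble::tibble(
      round = round,
      subset = vapply(cand, function(c) paste(c$subset, collapse = "-"), character(1)),
      removed = removed_order, score = scores,
      accepted = FALSE
    )
    best_i <- which.max(scores)  # first max = lexicographically smallest removal
    if (scores[best_i] > best_score) {
      current <- cand[[best_i]]$subset
      best_score <- scores[best_i]
      last <- rows[[length(rows)]]
      last$accepted[best_i] <- TRUE
      rows[[length(rows)]] <- last
      if (length(current) == 0) {
        termination <- "exhausted"
        break
      }
    } else {
      break
    }
  }
  structure(list(
    trace = dplyr::bind_rows(rows),
    final_subset = current,
    final_score = best_score,
    termination = termination
  ), class = "elimination_trace")
}

#' @export
print.elimination_trace <- function(x, ...) {
  cat(sprintf("<elimination_trace> final subset: {%s}, score %.4g (%s)\n",
              paste(x$final_subset, collapse = ", "), x$final_score,
              x$termination))
  print(x$trace)
  invisible(x)
}

#' Reduced architectures: zero or one omics network
#'
#' Runs the evaluation protocol with the attention layer removed: with one
#' omics type the single omics network's head feeds the softmax directly;
#' with none, the connectome encoder feeds a linear output head.
#'
#' @param cohort A cohort.
#' @param config A [train_config()].
#' @param omics Character vector of length 0 or 1 naming the omics type to
#'   keep.
#' @param modalities Imaging modalities to use (default: all).
#' @return A `protocol_result` tibble (one row).
#' @export
reduced_architecture <- function(cohort, config = train_config(), omics = character(0),
                                 modalities = names(cohort$connectivity)) {
  if (length(omics) > 1) {
    stop("reduced_architecture is for 0 or 1 omics types; use run_protocol for more")
  }
  run_protocol(cohort, config,
               combinations = list(list(modalities = modalities, omics = omics)))
}

#' Attention-layer ablation: query/key/value fusion vs self-attention
#'
#' Runs the identical pipeline twice with the fusion operator swapped,
#' sharing seeds across variants for a paired comparison.
#'
#' @param cohort A cohort.
#' @param config A [train_config()].
#' @param omics Omics types to use (>= 2).
#' @param modalities Imaging modalities to use (default: all).
#' @return A tibble with one row per variant (`variant`, accuracy and MCC
#'   summaries, per-seed metrics).
#' @export
attention_ablation <- function(cohort, config = train_config(),
                               omics = names(cohort$omics),
                               modalities = names(cohort$connectivity)) {
  if (length(omics) < 2) stop("attention ablation requires >= 2 omics types")
  rows <- lapply(c("joingcla", "self_attention"), function(v) {
    cfg <- config
    cfg$attention <- v
    res <- run_protocol(cohort, cfg,
                        combinations = list(list(modalities = modalities,
                                                 omics = omics)))
    dplyr::mutate(res, variant = v, .before = 1)
  })
  dplyr::bind_rows(rows)
}
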