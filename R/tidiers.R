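#' Tidy a fitted model's training history
#'
#' Broom-style accessor: one row per epoch with loss, training accuracy and
#' MCC, and validation MCC where monitored.
#'
#' @param x A `joingcla_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.joingcla_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a fitted model
#'
#' @param x A `joingcla_fit`.
#' @param ... Unused.
#' @return A tibble with the seed, epochs run, best epoch, best validation
#'   MCC, final training loss and the number of omics networks.
#' @export
glance.joingcla_fit <- function(x, ...) {
  tibble::tibble(
    seed = x$seed,
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_mcc = x$best_val_mcc,
    final_loss = x$history$loss[nrow(x$history)],
    n_omics = length(x$omics_types),
    attention = x$config$attention
  )
}

#' @export
print.joingcla_fit <- function(x, ...) {
  cat(sprintf("<joingcla_fit> seed %d, %d omics networks (%s fusion)\n",
              x$seed, length(x$omics_types), x$config$attention))
  cat(sprintf("  %d epochs, best epoch %d", nrow(x$history), x$best_epoch))
  if (is.finite(x$best_val_mcc %||% NA)) {
    cat(sprintf(", best validation MCC %.3f", x$best_val_mcc))
  }
  cat("\n")
  invisible(x)
}

#' Tidy a protocol result
#'
#' @param x A `protocol_result`.
#' @param ... Unused.
#' @return Per-seed metrics in long form: one row per combination and seed.
#' @export
tidy.protocol_result <- function(x, ...) {
  tidyr::unnest(
    dplyr::select(tibble::as_tibble(x), "combination", "per_seed"),
    "per_seed")
}

#' One-row-per-combination summary of a protocol result
#'
#' @param x A `protocol_result`.
#' @param ... Unused.
#' @return A tibble in the reporting format: combination, `accuracy` and
#'   `mcc` as "mean ± sd" strings, plus the numeric summaries.
#' @export
glance.protocol_result <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), "combination", "accuracy", "mcc",
                "accuracy_mean", "accuracy_sd", "mcc_mean", "mcc_sd")
}

#' Generic tidiers
#'
#' Broom-style generics re-exported for the package's fit and result
#' classes.
#' @param x Object to tidy or summarise.
#' @param ... Method-specific arguments.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")
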