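# Independent scalar-loop oracles used across the suite. These deliberately
# avoid the package's vectorised code paths: everything is explicit loops
# over indices, so agreement is evidence, not tautology.

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sx <- sqrt(sum((x - mx)^2))
  sy <- sqrt(sum((y - my)^2))
  if (sx == 0 || sy == 0) return(0)
  sxy / (sx * sy)
}

oracle_pairwise_similarity <- function(X) {
  P <- nrow(X)
  out <- matrix(NA_real_, P, P)
  for (u in seq_len(P)) {
    for (v in seq_len(P)) {
      out[u, v] <- oracle_pearson(X[u, ], X[v, ])
    }
  }
  out
}

oracle_psg <- function(feature_list) {
  P <- nrow(feature_list[[1]])
  A <- matrix(1, P, P)
  for (X in feature_list) {
    Am <- oracle_pairwise_similarity(X)
    lo <- min(Am); hi <- max(Am)
    if (hi > lo) {
      for (u in 1:P) for (v in 1:P) Am[u, v] <- (Am[u, v] - lo) / (hi - lo)
    } else {
      Am[, ] <- 0
    }
    A <- A * (Am + 1)
  }
  A
}

oracle_gcn <- function(H, A, W, relu = FALSE) {
  P <- nrow(A)
  Ahat <- A
  for (i in 1:P) Ahat[i, i] <- Ahat[i, i] + 1
  d <- numeric(P)
  for (i in 1:P) d[i] <- sum(Ahat[i, ])
  S <- matrix(0, P, P)
  for (i in 1:P) for (j in 1:P) S[i, j] <- Ahat[i, j] / sqrt(d[i] * d[j])
  Z <- S %*% H %*% W
  if (relu) Z[Z < 0] <- 0
  Z
}

oracle_attention <- function(H3_list, H4_list, W3c, W4c) {
  N <- length(H4_list)
  P <- nrow(H4_list[[1]])
  L4 <- ncol(H4_list[[1]])
  H5 <- matrix(0, P, L4)
  scores <- array(0, c(P, L4, N))
  for (i in 1:P) {
    q <- numeric(L4)
    for (l in 1:L4) for (n in 1:N) q[l] <- q[l] + H4_list[[n]][i, l] / N
    k <- numeric(N); v <- numeric(N)
    for (n in 1:N) {
      k[n] <- sum(H3_list[[n]][i, ] * W3c[, 1])
      v[n] <- sum(H4_list[[n]][i, ] * W4c[, 1])
    }
    for (l in 1:L4) {
      raw <- q[l] * k
      e <- exp(raw - max(raw))
      al <- e / sum(e)
      scores[i, l, ] <- al
      H5[i, l] <- sum(al * v)
    }
  }
  list(H5 = H5, scores = scores)
}

oracle_self_attention <- function(H4_list) {
  N <- length(H4_list)
  P <- nrow(H4_list[[1]])
  L4 <- ncol(H4_list[[1]])
  H5 <- matrix(0, P, L4)
  for (i in 1:P) {
    X <- matrix(0, N, L4)
    for (n in 1:N) X[n, ] <- H4_list[[n]][i, ]
    out <- matrix(0, N, L4)
    for (r in 1:N) {
      raw <- numeric(N)
      for (c in 1:N) raw[c] <- sum(X[r, ] * X[c, ]) / sqrt(L4)
      e <- exp(raw - max(raw))
      al <- e / sum(e)
      for (c in 1:N) out[r, ] <- out[r, ] + al[c] * X[c, ]
    }
    for (l in 1:L4) H5[i, l] <- mean(out[, l])
  }
  H5
}

oracle_mcc <- function(pred, lab) {
  # covariance-form expression, distinct from the confusion-table route
  n <- length(pred)
  cov_xy <- sum((pred - mean(pred)) * (lab - mean(lab)))
  cov_xx <- sum((pred - mean(pred))^2)
  cov_yy <- sum((lab - mean(lab))^2)
  if (cov_xx == 0 || cov_yy == 0) return(0)
  cov_xy / sqrt(cov_xx * cov_yy)
}

oracle_weighted_ce <- function(y, lab, w) {
  tot <- 0
  for (i in seq_along(y)) {
    yi <- min(max(y[i], 1e-12), 1 - 1e-12)
    wi <- w[[as.character(lab[i])]]
    tot <- tot - wi * lab[i] * log(yi) - (1 - wi) * (1 - lab[i]) * log(1 - yi)
  }
  tot / length(y)
}

# Backward-elimination replay: exhaustive recursive descent following the
# same strict-improvement rule, used to validate the iterative search.
oracle_eliminate <- function(names, score_fn) {
  best <- sort(names, method = "radix")
  best_score <- score_fn(best)
  repeat {
    if (length(best) == 0) break
    cand_scores <- sapply(sort(best, method = "radix"),
                          function(r) score_fn(setdiff(best, r)))
    cand_scores[is.na(cand_scores)] <- -Inf
    if (max(cand_scores) > best_score) {
      rm_name <- names(cand_scores)[which.max(cand_scores)]
      best <- setdiff(best, rm_name)
      best_score <- max(cand_scores)
    } else break
  }
  list(subset = best, score = best_score)
}

tiny_manifest <- function(n_subjects = 6, scans = NULL, labels = NULL, seed = 42) {
  withr::with_seed(seed, {
    if (is.null(scans)) scans <- sample(1:3, n_subjects, replace = TRUE)
    if (is.null(labels)) labels <- rep_len(c(0, 1), n_subjects)
    sid <- sprintf("s%02d", seq_len(n_subjects))
    as_scan_manifest(tibble::tibble(
      scan_id = sprintf("%s.%d", rep(sid, scans), unlist(lapply(scans, seq_len))),
      subject_id = rep(sid, scans),
      label = rep(labels, scans)
    ))
  })
}

# Minimal random model inputs for layer-level tests.
tiny_model_inputs <- function(P = 5, J = 6, N = 2, shapes = layer_shapes(3, 3, 3, 2),
                              seed = 7) {
  withr::with_seed(seed, {
    Xc <- matrix(rnorm(P * J), P, J)
    rand_adj <- function() {
      m <- matrix(runif(P * P), P, P)
      m <- (m + t(m)) / 2
      diag(m) <- 0
      m
    }
    psg <- rand_adj() + 1  # PSG-like: positive weights
    pogs <- replicate(N, rand_adj(), simplify = FALSE)
    params <- init_model_parameters(J, N, shapes)
    list(Xc = Xc, psg = psg, pogs = pogs, params = params, shapes = shapes)
  })
}
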