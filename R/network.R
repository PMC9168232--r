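#' Layer widths of the JOIN-GCLA model
#'
#' @param L1 Hidden width of the encoder linear layer.
#' @param L2 Width of the encoder graph convolution.
#' @param L3 Width of each omics graph convolution.
#' @param L4 Number of classes (2 for the HC-vs-disease task).
#' @return A named list of validated layer sizes.
#' @export
layer_shapes <- function(L1 = 16, L2 = 16, L3 = 16, L4 = 2) {
  sizes <- c(L1 = L1, L2 = L2, L3 = L3, L4 = L4)
  if (any(sizes < 1)) stop("all layer sizes must be >= 1")
  as.list(sizes)
}

glorot_uniform <- function(n_in, n_out) {
  limit <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -limit, limit), n_in, n_out)
}

#' Initialise model parameters
#'
#' Weights are Glorot-uniform; biases start at a small positive value (0.1)
#' so that every rectified unit is initially active (the double-rectified
#' omics heads can otherwise die permanently at initialisation). Fully
#' determined by the R RNG state (seed the session or use
#' [withr::with_seed()] for reproducibility).
#'
#' @param J Total number of connectivity features (columns of the
#'   modality-wise concatenation).
#' @param n_omics Number of omics networks N (0, 1, or more).
#' @param shapes A [layer_shapes()] list.
#' @return A named list of weight matrices and bias vectors: encoder
#'   (`W1`, `b1`, `W2`), per-omics blocks (`W3`, `W4`, `b4`), attention
#'   projections (`W3c`, `W4c`) when N >= 2, or a direct output head
#'   (`W_out`, `b_out`) when N = 0.
#' @export
init_model_parameters <- function(J, n_omics, shapes = layer_shapes()) {
  p <- list(
    W1 = glorot_uniform(J, shapes$L1),
    b1 = rep(0.1, shapes$L1),
    W2 = glorot_uniform(shapes$L1, shapes$L2)
  )
  if (n_omics == 0) {
    p$W_out <- glorot_uniform(shapes$L2, shapes$L4)
    p$b_out <- rep(0, shapes$L4)
  } else {
    p$omics <- lapply(seq_len(n_omics), function(n) {
      list(W3 = glorot_uniform(shapes$L2, shapes$L3),
           W4 = glorot_uniform(shapes$L3, shapes$L4),
           b4 = rep(0.1, shapes$L4))
    })
    if (n_omics >= 2) {
      p$W3c <- glorot_uniform(shapes$L3, 1)
      p$W4c <- glorot_uniform(shapes$L4, 1)
    }
  }
  p$shapes <- shapes
  p$n_omics <- n_omics
  p
}

#' Encoder linear layer
#'
#' `H1 = ReLU(Xc W1 + b1)`: reduces the concatenated connectivity features
#' to the encoder width.
#'
#' @param Xc P x J matrix of concatenated connectivity features.
#' @param W1 J x L1 weight matrix.
#' @param b1 Length-L1 bias.
#' @return P x L1 rectified activations.
#' @export
encoder_linear <- function(Xc, W1, b1) {
  if (ncol(Xc) != nrow(W1)) {
    stop(sprintf("encoder shape mismatch: Xc has %d features, W1 expects %d",
                 ncol(Xc), nrow(W1)))
  }
  pmax(sweep(Xc %*% W1, 2, -b1, "-"), 0)
}

# Symmetrically normalised adjacency with self-loops (Kipf-Welling):
# S = Dhat^(-1/2) (A + I) Dhat^(-1/2), Dhat the degree matrix of A + I.
gcn_normalize <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (any(A < 0)) stop("graph convolution requires a nonnegative adjacency")
  Ahat <- A + diag(nrow(A))
  d <- rowSums(Ahat)
  if (any(d <= 0)) stop("internal: zero-degree row after adding self-loops")
  inv_sqrt <- 1 / sqrt(d)
  Ahat * outer(inv_sqrt, inv_sqrt)
}

#' Spectral graph convolution layer
#'
#' `act(Dhat^(-1/2) (A + I) Dhat^(-1/2) H W)` with `Dhat` the degree matrix
#' of `A + I`. The rectifier is used in the connectome encoder; the omics
#' layers are linear.
#'
#' @param H P x d_in input activations.
#' @param A P x P symmetric nonnegative adjacency (self-loops are added
#'   internally).
#' @param W d_in x d_out weight matrix.
#' @param activation `"relu"` or `"identity"`.
#' @return P x d_out activations.
#' @export
gcn_propagate <- function(H, A, W, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  S <- gcn_normalize(A)
  Z <- S %*% H %*% W
  if (activation == "relu") pmax(Z, 0) else Z
}

#' Omics-network output head
#'
#' `H4 = ReLU(ReLU(H3) W4 + b4)` — the double rectification is part of the
#' model definition and is applied exactly as stated.
#'
#' @param H3 P x L3 omics graph-convolution output.
#' @param W4 L3 x L4 weights.
#' @param b4 Length-L4 bias.
#' @return P x L4 nonnegative logits.
#' @export
omics_head <- function(H3, W4, b4) {
  stopifnot(ncol(H3) == nrow(W4))
  pmax(sweep(pmax(H3, 0) %*% W4, 2, -b4, "-"), 0)
}

#' Query/key/value attention fusion over omics networks
#'
#' Per sample, the query is the mean of the omics-network logits (length
#' L4); the key for omics network n is the scalar projection `H3_n W3c`; the
#' raw score matrix is the outer product query x keys (L4 x N), normalised by
#' a softmax over the omics axis; the value for network n is the scalar
#' projection `H4_n W4c`. The fused logits are `scores %*% values`. No
#' sqrt(d) scaling is applied.
#'
#' @param H3_list,H4_list Lists (length N >= 2) of P x L3 and P x L4
#'   matrices from the omics networks.
#' @param W3c L3 x 1 key projection.
#' @param W4c L4 x 1 value projection.
#' @return A list with `H5` (P x L4 fused logits) and `scores`
#'   (P x L4 x N array; each `scores[i, l, ]` sums to 1).
#' @export
attention_fuse <- function(H3_list, H4_list, W3c, W4c) {
  N <- length(H4_list)
  if (N < 2) {
    stop("attention fusion needs N >= 2 omics networks; ",
         "use the reduced architecture for N <= 1")
  }
  P <- nrow(H4_list[[1]])
  L4 <- ncol(H4_list[[1]])
  q <- Reduce(`+`, H4_list) / N                          # P x L4
  K <- vapply(H3_list, function(h) drop(h %*% W3c), numeric(P))  # P x N
  V <- vapply(H4_list, function(h) drop(h %*% W4c), numeric(P))  # P x N
  if (P == 1) { K <- matrix(K, 1); V <- matrix(V, 1) }
  scores <- array(NA_real_, c(P, L4, N))
  H5 <- matrix(0, P, L4)
  for (l in seq_len(L4)) {
    raw <- q[, l] * K                                    # P x N
    raw <- raw - apply(raw, 1, max)
    e <- exp(raw)
    al <- e / rowSums(e)
    scores[, l, ] <- al
    H5[, l] <- rowSums(al * V)
  }
  list(H5 = H5, scores = scores, q = q, K = K, V = V)
}

#' Scaled dot-product self-attention fusion (ablation baseline)
#'
#' Standard self-attention over the N stacked omics-network logit vectors
#' (query = key = value, scale 1/sqrt(L4)), mean-pooled over the omics axis.
#'
#' @inheritParams attention_fuse
#' @return A list with `H5` (P x L4) and `scores` (P x N x N array of
#'   row-stochastic attention matrices).
#' @export
self_attention_fuse <- function(H4_list) {
  N <- length(H4_list)
  if (N < 2) stop("self-attention fusion needs N >= 2 omics networks")
  P <- nrow(H4_list[[1]])
  L4 <- ncol(H4_list[[1]])
  s <- sqrt(L4)
  H5 <- matrix(0, P, L4)
  scores <- array(NA_real_, c(P, N, N))
  for (i in seq_len(P)) {
    Xi <- do.call(rbind, lapply(H4_list, function(h) h[i, ]))  # N x L4
    raw <- Xi %*% t(Xi) / s
    raw <- raw - apply(raw, 1, max)
    e <- exp(raw)
    al <- e / rowSums(e)
    scores[i, , ] <- al
    H5[i, ] <- colMeans(al %*% Xi)
  }
  list(H5 = H5, scores = scores)
}

#' Row-wise softmax class probabilities
#'
#' @param H5 P x L4 matrix of logits.
#' @return P x L4 matrix whose rows are probability vectors; the argmax is
#'   the predicted label.
#' @export
output_probabilities <- function(H5) {
  stopifnot(all(is.finite(H5)))
  z <- H5 - apply(H5, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Class weights for the imbalance-aware loss
#'
#' `w_c = 1 - P_c / P` where `P_c` counts the training samples of class c.
#' For binary labels the two weights sum to 1, so the minority class gets
#' the larger weight.
#'
#' @param labels Integer class labels (0/1) of the training samples.
#' @return Named numeric vector of per-class weights (names are the class
#'   indices).
#' @export
class_weights <- function(labels) {
  tab <- table(factor(labels, levels = sort(unique(labels))))
  if (length(tab) < 2) {
    stop("class weights undefined for a single-class training set (class ",
         names(tab), " only)")
  }
  w <- 1 - as.numeric(tab) / length(labels)
  names(w) <- names(tab)
  w
}

#' Class-weighted binary cross-entropy
#'
#' Mean over samples of
#' `-w_{yd} yd log(y) - (1 - w_{yd}) (1 - yd) log(1 - y)`,
#' with `y` the predicted probability of class 1 clamped to
#' `[eps, 1 - eps]` and `w_{yd}` the weight of the sample's own class.
#'
#' @param prob_positive Predicted probability of class 1 per sample.
#' @param labels 0/1 labels.
#' @param weights Named per-class weights from [class_weights()] (or any
#'   vector with names `"0"` and `"1"`).
#' @param eps Clamping epsilon (default 1e-12).
#' @return A nonnegative scalar loss.
#' @export
weighted_cross_entropy <- function(prob_positive, labels, weights, eps = 1e-12) {
  stopifnot(length(prob_positive) == length(labels))
  y <- pmin(pmax(prob_positive, eps), 1 - eps)
  w_own <- weights[as.character(labels)]
  term <- -w_own * labels * log(y) - (1 - w_own) * (1 - labels) * log(1 - y)
  mean(term)
}

as_adjacency <- function(g) {
  if (inherits(g, "population_graph")) g$adjacency else g
}

dropout_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

apply_mask <- function(H, mask) if (is.null(mask)) H else H * mask

#' Full forward pass of the JOIN-GCLA model
#'
#' Composes the connectome encoder (linear layer, graph convolution over the
#' PSG), the omics networks (one linear graph convolution per POG plus its
#' head), the attention fusion (bypassed for N <= 1: with one omics network
#' its head feeds the softmax directly; with none, the encoder output feeds
#' a linear head), and the output softmax. Dropout (when `training = TRUE`
#' and `dropout_rate > 0`) is applied after the graph convolution layer in
#' the encoder and in each omics network; in evaluation mode the pass is
#' deterministic.
#'
#' @param Xc P x J concatenated connectivity features.
#' @param psg PSG adjacency (matrix or `population_graph`).
#' @param pogs List of N POG adjacencies (matrices or `population_graph`s).
#' @param params Parameters from [init_model_parameters()].
#' @param dropout_rate Dropout probability in \[0, 1).
#' @param training Logical; enables dropout (draws from the R RNG).
#' @param attention `"joingcla"` (the query/key/value layer) or
#'   `"self_attention"` (the ablation baseline).
#' @return A forward trace: activations `H1`..`H5`, per-omics `H3`/`H4`
#'   lists, `scores`, class `probs`, and the caches needed for
#'   backpropagation.
#' @export
model_forward <- function(Xc, psg, pogs, params, dropout_rate = 0,
                          training = FALSE, attention = c("joingcla", "self_attention")) {
  attention <- match.arg(attention)
  A <- as_adjacency(psg)
  pogs <- lapply(pogs, as_adjacency)
  N <- params$n_omics
  stopifnot(length(pogs) == N, nrow(Xc) == nrow(A))
  P <- nrow(Xc)

  Sp <- gcn_normalize(A)
  H1 <- encoder_linear(Xc, params$W1, params$b1)
  Z2 <- Sp %*% H1 %*% params$W2
  H2 <- pmax(Z2, 0)
  m2 <- if (training) dropout_mask(P, ncol(H2), dropout_rate) else NULL
  H2d <- apply_mask(H2, m2)

  tr <- list(H1 = H1, Z2 = Z2, H2 = H2, H2d = H2d, mask2 = m2, Sp = Sp,
             attention = attention)

  if (N == 0) {
    H5 <- sweep(H2d %*% params$W_out, 2, -params$b_out, "-")
    tr$H5 <- H5
    tr$probs <- output_probabilities(H5)
    return(tr)
  }

  Sn <- lapply(pogs, gcn_normalize)
  H3 <- vector("list", N); H3d <- vector("list", N)
  H4 <- vector("list", N); Z4 <- vector("list", N); m3 <- vector("list", N)
  for (n in seq_len(N)) {
    H3[[n]] <- Sn[[n]] %*% H2d %*% params$omics[[n]]$W3
    m3[n] <- list(if (training) dropout_mask(P, ncol(H3[[n]]), dropout_rate))
    H3d[[n]] <- apply_mask(H3[[n]], m3[[n]])
    Z4[[n]] <- sweep(pmax(H3d[[n]], 0) %*% params$omics[[n]]$W4, 2,
                     -params$omics[[n]]$b4, "-")
    H4[[n]] <- pmax(Z4[[n]], 0)
  }
  tr <- c(tr, list(Sn = Sn, H3 = H3, H3d = H3d, Z4 = Z4, H4 = H4, mask3 = m3))

  if (N == 1) {
    tr$H5 <- H4[[1]]
  } else if (attention == "joingcla") {
    att <- attention_fuse(H3d, H4, params$W3c, params$W4c)
    tr$H5 <- att$H5
    tr$scores <- att$scores
    tr$att_cache <- att[c("q", "K", "V")]
  } else {
    att <- self_attention_fuse(H4)
    tr$H5 <- att$H5
    tr$scores <- att$scores
  }
  tr$probs <- output_probabilities(tr$H5)
  tr
}

# Gradient of the class-weighted binary cross-entropy with respect to the
# output logits H5, restricted to the rows in train_idx (others zero).
# The mean is taken over the training rows only.
loss_grad_logits <- function(probs, labels, weights, train_idx) {
  P <- nrow(probs)
  G <- matrix(0, P, ncol(probs))
  n <- length(train_idx)
  for (i in train_idx) {
    yd <- labels[i]
    coef <- if (yd == 1) weights[["1"]] else (1 - weights[["0"]])
    onehot <- c(1 - yd, yd)
    G[i, ] <- coef * (probs[i, ] - onehot) / n
  }
  G
}

# Analytic backpropagation through the full model. `tr` is a training-mode
# forward trace; returns gradients in the same nested structure as params.
model_backward <- function(Xc, params, tr, dH5) {
  N <- params$n_omics
  g <- list()

  if (N == 0) {
    g$W_out <- t(tr$H2d) %*% dH5
    g$b_out <- colSums(dH5)
    dH2d <- dH5 %*% t(params$W_out)
  } else {
    P <- nrow(dH5); L4 <- ncol(dH5)
    dH4 <- lapply(seq_len(N), function(n) matrix(0, P, L4))
    dH3d_att <- lapply(seq_len(N), function(n) NULL)

    if (N == 1) {
      dH4[[1]] <- dH5
    } else if (tr$attention == "joingcla") {
      K <- tr$att_cache$K; V <- tr$att_cache$V; q <- tr$att_cache$q
      dV <- matrix(0, P, N); dK <- matrix(0, P, N); dq <- matrix(0, P, L4)
      for (l in seq_len(L4)) {
        al <- matrix(tr$scores[, l, ], P, N)
        dV <- dV + al * dH5[, l]
        dal <- dH5[, l] * V
        draw <- al * (dal - rowSums(al * dal))
        dq[, l] <- rowSums(draw * K)
        dK <- dK + draw * q[, l]
      }
      g$W3c <- matrix(0, nrow(params$W3c), 1)
      g$W4c <- matrix(0, nrow(params$W4c), 1)
      for (n in seq_len(N)) {
        dH4[[n]] <- dq / N + dV[, n] %*% t(params$W4c[, 1, drop = FALSE])
        dH3d_att[[n]] <- dK[, n] %*% t(params$W3c[, 1, drop = FALSE])
        g$W4c <- g$W4c + t(tr$H4[[n]]) %*% dV[, n, drop = FALSE]
        g$W3c <- g$W3c + t(tr$H3d[[n]]) %*% dK[, n, drop = FALSE]
      }
    } else {
      # self-attention baseline
      s <- sqrt(L4)
      for (i in seq_len(P)) {
        Xi <- do.call(rbind, lapply(tr$H4, function(h) h[i, ]))
        al <- matrix(tr$scores[i, , ], N, N)
        dO <- matrix(rep(dH5[i, ] / N, each = N), N, L4)
        dal <- dO %*% t(Xi)
        dXi <- t(al) %*% dO
        draw <- al * (dal - rowSums(al * dal))
        dXi <- dXi + (draw %*% Xi + t(draw) %*% Xi) / s
        for (n in seq_len(N)) dH4[[n]][i, ] <- dXi[n, ]
      }
    }

    g$omics <- vector("list", N)
    dH2d <- matrix(0, nrow(dH5), ncol(tr$H2d))
    for (n in seq_len(N)) {
      dZ4 <- dH4[[n]] * (tr$Z4[[n]] > 0)
      gW4 <- t(pmax(tr$H3d[[n]], 0)) %*% dZ4
      gb4 <- colSums(dZ4)
      dH3d <- (dZ4 %*% t(params$omics[[n]]$W4)) * (tr$H3d[[n]] > 0)
      if (!is.null(dH3d_att[[n]])) dH3d <- dH3d + dH3d_att[[n]]
      dH3 <- apply_mask(dH3d, tr$mask3[[n]])
      SH2 <- tr$Sn[[n]] %*% tr$H2d
      g$omics[[n]] <- list(W3 = t(SH2) %*% dH3, W4 = gW4, b4 = gb4)
      dH2d <- dH2d + t(tr$Sn[[n]]) %*% dH3 %*% t(params$omics[[n]]$W3)
    }
  }

  dH2 <- apply_mask(dH2d, tr$mask2)
  dZ2 <- dH2 * (tr$Z2 > 0)
  SH1 <- tr$Sp %*% tr$H1
  g$W2 <- t(SH1) %*% dZ2
  dH1 <- (t(tr$Sp) %*% dZ2 %*% t(params$W2)) * (tr$H1 > 0)
  g$W1 <- t(Xc) %*% dH1
  g$b1 <- colSums(dH1)
  g
}

# ---- Adam optimiser over the nested parameter list ----------------------

param_names <- c("W1", "b1", "W2", "W_out", "b_out", "W3c", "W4c")

map_params <- function(p, f) {
  out <- p
  for (nm in intersect(param_names, names(p))) out[[nm]] <- f(p[[nm]], nm)
  if (!is.null(p$omics)) {
    out$omics <- lapply(seq_along(p$omics), function(n) {
      lapply(stats::setNames(nm = names(p$omics[[n]])), function(k) {
        f(p$omics[[n]][[k]], paste0("omics", n, ".", k))
      })
    })
  }
  out
}

map2_params <- function(p, q, f) {
  out <- p
  for (nm in intersect(param_names, names(p))) out[[nm]] <- f(p[[nm]], q[[nm]])
  if (!is.null(p$omics)) {
    out$omics <- lapply(seq_along(p$omics), function(n) {
      lapply(stats::setNames(nm = names(p$omics[[n]])), function(k) {
        f(p$omics[[n]][[k]], q$omics[[n]][[k]])
      })
    })
  }
  out
}

adam_init <- function(params) {
  zero <- function(x, nm) x * 0
  list(m = map_params(params, zero), v = map_params(params, zero), t = 0)
}

adam_step <- function(params, grads, state, lr = 0.001,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- map2_params(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map2_params(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- map2_params(state$m, state$v, function(m, v) {
    lr * (m / bc1) / (sqrt(v / bc2) + eps)
  })
  params <- map2_params(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}
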