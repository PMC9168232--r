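test_that("encoder_linear is a rectified affine map", {
  Xc <- matrix(c(1, 2, 0.5, 3), 2, 2)
  expect_equal(encoder_linear(Xc, diag(2), c(0, 0)), Xc)
  expect_equal(encoder_linear(Xc, -diag(2), c(0, 0)), matrix(0, 2, 2))
  withr::with_seed(2, {
    X <- matrix(rnorm(12), 3, 4)
    W <- matrix(rnorm(8), 4, 2)
    b <- rnorm(2)
  })
  out <- encoder_linear(X, W, b)
  for (i in 1:3) for (j in 1:2) {
    z <- sum(X[i, ] * W[, j]) + b[j]
    expect_equal(out[i, j], max(0, z), tolerance = 1e-12)
  }
  expect_error(encoder_linear(X, matrix(0, 3, 2), b), "mismatch")
})

test_that("gcn_propagate implements the normalised graph convolution", {
  # graphless limit: A = 0 reduces to act(H W)
  H <- matrix(c(1, -2, 3, 4), 2, 2)
  W <- diag(2)
  expect_equal(gcn_propagate(H, matrix(0, 2, 2), W, "identity"), H)
  expect_equal(gcn_propagate(H, matrix(0, 2, 2), W, "relu"), pmax(H, 0))

  # two-node hand computation: A = [[0,1],[1,0]], H = (1,3), W = 1
  out <- gcn_propagate(matrix(c(1, 3), 2, 1), matrix(c(0, 1, 1, 0), 2, 2),
                       matrix(1), "identity")
  expect_equal(out, matrix(c(2, 2), 2, 1))

  # dense random graphs against the explicit loop oracle
  withr::with_seed(13, {
    for (rep in 1:10) {
      P <- sample(3:6, 1)
      A <- matrix(runif(P * P), P, P); A <- (A + t(A)) / 2; diag(A) <- 0
      H2 <- matrix(rnorm(P * 3), P, 3)
      W2 <- matrix(rnorm(6), 3, 2)
      expect_equal(gcn_propagate(H2, A, W2, "identity"),
                   oracle_gcn(H2, A, W2, relu = FALSE), tolerance = 1e-9)
      expect_equal(gcn_propagate(H2, A, W2, "relu"),
                   oracle_gcn(H2, A, W2, relu = TRUE), tolerance = 1e-9)
    }
  })
  expect_error(gcn_propagate(H, matrix(-1, 2, 2), W), "nonnegative")
})

test_that("omics_head applies the double rectification as written", {
  W4 <- diag(2); b4 <- c(0, 0)
  H3_neg <- matrix(-abs(rnorm(6)), 3, 2)
  expect_equal(omics_head(H3_neg, W4, b4), matrix(0, 3, 2))
  H3_pos <- matrix(abs(rnorm(6)), 3, 2)
  expect_equal(omics_head(H3_pos, W4, b4), H3_pos)
  withr::with_seed(4, {
    H3 <- matrix(rnorm(12), 4, 3)
    W <- matrix(rnorm(6), 3, 2)
    b <- rnorm(2)
  })
  out <- omics_head(H3, W, b)
  for (i in 1:4) for (j in 1:2) {
    inner <- pmax(H3[i, ], 0)
    expect_equal(out[i, j], max(0, sum(inner * W[, j]) + b[j]), tolerance = 1e-12)
  }
  expect_true(all(out >= 0))
})

test_that("attention_fuse matches the scalar-loop oracle and its symmetries", {
  withr::with_seed(6, {
    P <- 2; L3 <- 2; L4 <- 2
    H3 <- replicate(2, matrix(rnorm(P * L3), P, L3), simplify = FALSE)
    H4 <- replicate(2, matrix(abs(rnorm(P * L4)), P, L4), simplify = FALSE)
    W3c <- matrix(rnorm(L3), L3, 1)
    W4c <- matrix(rnorm(L4), L4, 1)
  })
  got <- attention_fuse(H3, H4, W3c, W4c)
  want <- oracle_attention(H3, H4, W3c, W4c)
  expect_equal(got$H5, want$H5, tolerance = 1e-9)
  expect_equal(got$scores, want$scores, tolerance = 1e-9)

  # identical omics networks: all weights exactly 1/2, H5 = either value
  H3s <- list(H3[[1]], H3[[1]]); H4s <- list(H4[[1]], H4[[1]])
  sym <- attention_fuse(H3s, H4s, W3c, W4c)
  expect_equal(as.vector(sym$scores), rep(0.5, length(sym$scores)))
  expect_equal(sym$H5,
               matrix(rep(drop(H4[[1]] %*% W4c), 2), P, L4), tolerance = 1e-12)

  # softmax saturation: a dominating key gets weight -> 1
  H3dom <- H3
  H3dom[[2]] <- H3[[2]] + 1e4 * matrix(rep(sign(W3c[, 1]), each = P), P, L3)
  qpos <- lapply(H4, function(h) h + 1)  # strictly positive query
  sat <- attention_fuse(H3dom, qpos, W3c, W4c)
  expect_true(all(sat$scores[, , 2] > 1 - 1e-6))

  # larger random instances against the oracle
  withr::with_seed(61, {
    for (rep in 1:5) {
      P <- sample(2:5, 1); N <- sample(2:4, 1)
      H3r <- replicate(N, matrix(rnorm(P * 3), P, 3), simplify = FALSE)
      H4r <- replicate(N, matrix(abs(rnorm(P * 2)), P, 2), simplify = FALSE)
      a <- matrix(rnorm(3), 3, 1); b <- matrix(rnorm(2), 2, 1)
      got_r <- attention_fuse(H3r, H4r, a, b)
      want_r <- oracle_attention(H3r, H4r, a, b)
      expect_equal(got_r$H5, want_r$H5, tolerance = 1e-9)
      expect_equal(got_r$scores, want_r$scores, tolerance = 1e-9)
    }
  })
  expect_error(attention_fuse(H3[1], H4[1], W3c, W4c), "reduced")
})

test_that("self_attention_fuse matches its oracle and is permutation-invariant", {
  withr::with_seed(9, {
    H4 <- replicate(3, matrix(rnorm(8), 4, 2), simplify = FALSE)
  })
  got <- self_attention_fuse(H4)
  expect_equal(got$H5, oracle_self_attention(H4), tolerance = 1e-9)

  # identical inputs: output equals the shared H4
  same <- self_attention_fuse(list(H4[[1]], H4[[1]]))
  expect_equal(same$H5, H4[[1]], tolerance = 1e-12)

  # permuting the omics order leaves the pooled output unchanged
  perm <- self_attention_fuse(H4[c(3, 1, 2)])
  expect_equal(perm$H5, got$H5, tolerance = 1e-12)
})

test_that("output_probabilities produces stable softmax rows", {
  expect_equal(output_probabilities(matrix(c(0, 0), 1, 2)),
               matrix(c(0.5, 0.5), 1, 2))
  expect_equal(output_probabilities(matrix(c(log(2), 0), 1, 2)),
               matrix(c(2 / 3, 1 / 3), 1, 2), tolerance = 1e-12)
  withr::with_seed(31, {
    z <- matrix(rnorm(40, sd = 50), 10, 4)
  })
  p <- output_probabilities(z)
  expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-12)
  expect_true(all(p >= 0))
})

test_that("class weights and the weighted cross-entropy follow the printed forms", {
  expect_equal(unname(class_weights(c(0, 0, 1, 1))), c(0.5, 0.5))
  # paired-cohort arithmetic: 351 disease / 25 control scans
  w <- class_weights(c(rep(1, 351), rep(0, 25)))
  expect_equal(unname(w["1"]), 1 - 351 / 376, tolerance = 1e-12)
  expect_equal(unname(w["0"]), 1 - 25 / 376, tolerance = 1e-12)
  expect_equal(sum(w), 1)
  expect_error(class_weights(rep(1, 5)), "single-class")

  # perfect predictions: zero-loss limit
  expect_lt(weighted_cross_entropy(c(1, 0, 1), c(1, 0, 1), c("0" = .5, "1" = .5)),
            1e-10)
  # w = 0.5 halves the standard binary cross-entropy
  withr::with_seed(12, {
    y <- runif(20, 0.05, 0.95)
    lab <- rbinom(20, 1, 0.5)
  })
  bce <- mean(-lab * log(y) - (1 - lab) * log(1 - y))
  expect_equal(weighted_cross_entropy(y, lab, c("0" = .5, "1" = .5)), bce / 2,
               tolerance = 1e-12)
  # random batches against the per-sample loop oracle
  w2 <- c("0" = 0.2, "1" = 0.8)
  expect_equal(weighted_cross_entropy(y, lab, w2), oracle_weighted_ce(y, lab, w2),
               tolerance = 1e-12)
})

test_that("model_forward composes the layers and honours the reduced paths", {
  inp <- tiny_model_inputs(P = 5, J = 6, N = 2)
  tr <- model_forward(inp$Xc, inp$psg, inp$pogs, inp$params)
  expect_equal(dim(tr$probs), c(5, 2))
  expect_equal(rowSums(tr$probs), rep(1, 5), tolerance = 1e-12)
  # layer-by-layer agreement with the exported primitives
  H1 <- encoder_linear(inp$Xc, inp$params$W1, inp$params$b1)
  H2 <- gcn_propagate(H1, inp$psg, inp$params$W2, "relu")
  expect_equal(tr$H2, H2, tolerance = 1e-12)
  H3_1 <- gcn_propagate(H2, inp$pogs[[1]], inp$params$omics[[1]]$W3, "identity")
  expect_equal(tr$H3[[1]], H3_1, tolerance = 1e-12)
  expect_equal(tr$H4[[1]],
               omics_head(H3_1, inp$params$omics[[1]]$W4, inp$params$omics[[1]]$b4),
               tolerance = 1e-12)
  fused <- attention_fuse(tr$H3, tr$H4, inp$params$W3c, inp$params$W4c)
  expect_equal(tr$H5, fused$H5, tolerance = 1e-12)

  # N = 1: attention bypassed, head feeds the softmax
  p1 <- withr::with_seed(7, init_model_parameters(6, 1, inp$shapes))
  tr1 <- model_forward(inp$Xc, inp$psg, inp$pogs[1], p1)
  expect_equal(tr1$H5, tr1$H4[[1]])
  expect_null(tr1$scores)

  # N = 0: encoder output feeds a linear head
  p0 <- withr::with_seed(7, init_model_parameters(6, 0, inp$shapes))
  tr0 <- model_forward(inp$Xc, inp$psg, list(), p0)
  expect_equal(tr0$H5,
               sweep(tr0$H2d %*% p0$W_out, 2, -p0$b_out, "-"), tolerance = 1e-12)

  # evaluation-mode forward is bitwise reproducible
  tr_b <- model_forward(inp$Xc, inp$psg, inp$pogs, inp$params)
  expect_identical(tr$probs, tr_b$probs)
})

test_that("model_forward is permutation-equivariant over samples", {
  inp <- tiny_model_inputs(P = 6, J = 5, N = 2)
  tr <- model_forward(inp$Xc, inp$psg, inp$pogs, inp$params)
  perm <- c(4, 1, 6, 3, 2, 5)
  trp <- model_forward(inp$Xc[perm, ], inp$psg[perm, perm],
                       lapply(inp$pogs, function(a) a[perm, perm]), inp$params)
  expect_equal(trp$H5, tr$H5[perm, ], tolerance = 1e-9)
  expect_equal(trp$probs, tr$probs[perm, ], tolerance = 1e-9)
})

test_that("the graphless limit degrades to a per-sample multilayer perceptron", {
  inp <- tiny_model_inputs(P = 4, J = 5, N = 2)
  zero <- matrix(0, 4, 4)
  tr <- model_forward(inp$Xc, zero, list(zero, zero), inp$params)
  # direct MLP evaluation: every graph operator is the identity
  H1 <- pmax(sweep(inp$Xc %*% inp$params$W1, 2, -inp$params$b1, "-"), 0)
  H2 <- pmax(H1 %*% inp$params$W2, 0)
  H4 <- lapply(inp$params$omics, function(om) {
    H3 <- H2 %*% om$W3
    pmax(sweep(pmax(H3, 0) %*% om$W4, 2, -om$b4, "-"), 0)
  })
  H3l <- lapply(inp$params$omics, function(om) H2 %*% om$W3)
  mlp <- attention_fuse(H3l, H4, inp$params$W3c, inp$params$W4c)
  expect_equal(tr$H5, mlp$H5, tolerance = 1e-9)
})

test_that("attention score rows are distributions across random draws", {
  withr::with_seed(77, {
    for (rep in 1:50) {
      P <- sample(1:6, 1); N <- sample(2:4, 1)
      H3 <- replicate(N, matrix(rnorm(P * 3, sd = 5), P, 3), simplify = FALSE)
      H4 <- replicate(N, matrix(abs(rnorm(P * 2, sd = 5)), P, 2), simplify = FALSE)
      sc <- attention_fuse(H3, H4, matrix(rnorm(3), 3, 1),
                           matrix(rnorm(2), 2, 1))$scores
      expect_true(all(sc >= 0 & sc <= 1))
      sums <- apply(sc, c(1, 2), sum)
      expect_true(all(abs(sums - 1) < 1e-9))
    }
  })
})

test_that("analytic gradients match central finite differences", {
  inp <- tiny_model_inputs(P = 5, J = 4, N = 2, shapes = layer_shapes(3, 3, 3, 2))
  labels <- c(0, 1, 0, 1, 1)
  w <- class_weights(labels)
  train_idx <- 1:5
  Sp <- joingcla:::gcn_normalize(inp$psg)
  Sn <- lapply(inp$pogs, joingcla:::gcn_normalize)

  loss_at <- function(params) {
    tr <- joingcla:::forward_prenorm(inp$Xc, Sp, Sn, params, 0, FALSE, "joingcla")
    weighted_cross_entropy(tr$probs[, 2], labels, w)
  }
  check_block <- function(params, grads, get, set, label) {
    g_ana <- get(grads)
    x <- get(params)
    idx <- seq_along(x)
    if (length(idx) > 6) idx <- idx[seq(1, length(idx), length.out = 6)]
    for (k in idx) {
      eps <- 1e-6
      up <- params; xu <- x; xu[k] <- xu[k] + eps; up <- set(up, xu)
      dn <- params; xd <- x; xd[k] <- xd[k] - eps; dn <- set(dn, xd)
      g_num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_lt(abs(g_ana[k] - g_num), 1e-6 + 1e-4 * abs(g_num),
                label = sprintf("%s[%d] |analytic - numeric|", label, k))
    }
  }

  for (variant in c("joingcla", "self_attention")) {
    params <- inp$params
    tr <- joingcla:::forward_prenorm(inp$Xc, Sp, Sn, params, 0, FALSE, variant)
    dH5 <- joingcla:::loss_grad_logits(tr$probs, labels, w, train_idx)
    grads <- joingcla:::model_backward(inp$Xc, params, tr, dH5)
    loss_at <- function(params) {
      trx <- joingcla:::forward_prenorm(inp$Xc, Sp, Sn, params, 0, FALSE, variant)
      weighted_cross_entropy(trx$probs[, 2], labels, w)
    }
    check_block(params, grads, function(p) p$W1,
                function(p, v) { p$W1[] <- v; p }, paste(variant, "W1"))
    check_block(params, grads, function(p) p$b1,
                function(p, v) { p$b1 <- v; p }, paste(variant, "b1"))
    check_block(params, grads, function(p) p$W2,
                function(p, v) { p$W2[] <- v; p }, paste(variant, "W2"))
    for (n in 1:2) {
      check_block(params, grads, function(p) p$omics[[n]]$W3,
                  function(p, v) { p$omics[[n]]$W3[] <- v; p },
                  paste(variant, "W3", n))
      check_block(params, grads, function(p) p$omics[[n]]$W4,
                  function(p, v) { p$omics[[n]]$W4[] <- v; p },
                  paste(variant, "W4", n))
      check_block(params, grads, function(p) p$omics[[n]]$b4,
                  function(p, v) { p$omics[[n]]$b4 <- v; p },
                  paste(variant, "b4", n))
    }
    if (variant == "joingcla") {
      check_block(params, grads, function(p) p$W3c,
                  function(p, v) { p$W3c[] <- v; p }, "W3c")
      check_block(params, grads, function(p) p$W4c,
                  function(p, v) { p$W4c[] <- v; p }, "W4c")
    }
  }

  # reduced N = 0 head
  p0 <- withr::with_seed(8, init_model_parameters(4, 0, inp$shapes))
  tr0 <- joingcla:::forward_prenorm(inp$Xc, Sp, list(), p0, 0, FALSE, "joingcla")
  dH5 <- joingcla:::loss_grad_logits(tr0$probs, labels, w, train_idx)
  g0 <- joingcla:::model_backward(inp$Xc, p0, tr0, dH5)
  loss_at <- function(params) {
    trx <- joingcla:::forward_prenorm(inp$Xc, Sp, list(), params, 0, FALSE, "joingcla")
    weighted_cross_entropy(trx$probs[, 2], labels, w)
  }
  check_block(p0, g0, function(p) p$W_out,
              function(p, v) { p$W_out[] <- v; p }, "W_out")
  check_block(p0, g0, function(p) p$b_out,
              function(p, v) { p$b_out <- v; p }, "b_out")
})
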