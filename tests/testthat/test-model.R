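test_that("projection and graph convolution match hand computations", {
  # identity projection
  X <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
  expect_equal(project(X, diag(3)), X)
  # worked 1-batch 2-node example
  X2 <- array(0, c(1, 2, 2))
  X2[1, , ] <- matrix(c(1, 2, 3, 4), 2, byrow = TRUE)
  W <- matrix(c(1, 0, 1, 1), 2, byrow = TRUE)
  H <- project(X2, W)
  expect_equal(H[1, , ], matrix(c(3, 2, 7, 4), 2, byrow = TRUE))
  expect_error(project(X2, matrix(0, 3, 2)), "does not match")
  # graph conv: identity adjacency, averaging adjacency
  G <- array(0, c(2, 3, 3)); for (b in 1:2) G[b, , ] <- diag(3)
  expect_equal(graph_conv(G, X), X)
  Gm <- array(1 / 3, c(2, 3, 3))
  Z <- graph_conv(Gm, X)
  for (b in 1:2) {
    expect_equal(Z[b, , ], matrix(colMeans(X[b, , ]), 3, 3, byrow = TRUE))
  }
})

test_that("attention adjacency is row-stochastic then exactly symmetric", {
  # worked fixture: H = I2, A = I2
  H <- array(0, c(1, 2, 2)); H[1, , ] <- diag(2)
  ag <- attention_adjacency(H, diag(2))
  e <- exp(1)
  expect_equal(ag$presym[1, , ],
               matrix(c(e, 1, 1, e) / (e + 1), 2, byrow = TRUE),
               tolerance = 1e-12)
  expect_equal(ag$adjacency[1, , ], ag$presym[1, , ], tolerance = 1e-12)
  # random inputs: rows sum to 1 pre-symmetrization; symmetric after;
  # total entry sum E per item; entries in [0, 1]
  set.seed(3)
  for (i in 1:5) {
    Hr <- array(rnorm(3 * 5 * 4), c(3, 5, 4))
    Ar <- matrix(rnorm(16), 4)
    agr <- attention_adjacency(Hr, Ar)
    for (b in 1:3) {
      expect_equal(rowSums(agr$presym[b, , ]), rep(1, 5), tolerance = 1e-6)
      expect_lt(max(abs(agr$adjacency[b, , ] - t(agr$adjacency[b, , ]))),
                1e-7)
      expect_equal(sum(agr$adjacency[b, , ]), 5, tolerance = 1e-5)
      expect_true(all(agr$adjacency[b, , ] >= 0 & agr$adjacency[b, , ] <= 1))
    }
  }
})

test_that("classifier head is a softmax over four affine layers", {
  cfg <- tiny_config()
  p <- init_model_params(cfg, seed = 1)
  # zero weights -> uniform probabilities
  pz <- rapply(p$head, function(x) x * 0, how = "replace")
  out <- classify(matrix(rnorm(4 * cfg$head_in), 4), pz)
  expect_equal(out$probs, matrix(1 / 3, 4, 3), tolerance = 1e-12)
  expect_identical(out$class, rep(1L, 4L))  # tie -> lowest index
  # random weights: probabilities sum to 1
  out2 <- classify(matrix(rnorm(6 * cfg$head_in), 6), p$head)
  expect_equal(rowSums(out2$probs), rep(1, 6), tolerance = 1e-6)
  expect_error(classify(matrix(0, 2, cfg$head_in + 1L), p$head), "match")
})

test_that("global attention pooling normalizes and reweights", {
  # omega = [ln 3, 0] -> beta = [0.75, 0.25]
  Z <- array(0, c(1, 2, 2))
  Z[1, , ] <- rbind(c(log(3), 0), c(0, 0))
  pool <- global_attention_pool(Z, list(v = c(1, 0), b = 0))
  expect_equal(pool$beta[1, ], c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(pool$Zp[1, 1, ], 0.75 * Z[1, 1, ])
  # equal scores -> uniform beta; rows always sum to 1
  set.seed(4)
  Zr <- array(rnorm(3 * 6 * 4), c(3, 6, 4))
  pr <- global_attention_pool(Zr, list(v = rep(0, 4), b = 2))
  expect_equal(pr$beta, matrix(1 / 6, 3, 6), tolerance = 1e-12)
  pr2 <- global_attention_pool(Zr, list(v = rnorm(4), b = 0))
  expect_equal(rowSums(pr2$beta), rep(1, 3), tolerance = 1e-12)
})

test_that("forward pass matches the brute-force oracle at every stage", {
  set.seed(99)
  cfg <- tiny_config(E = 3L, F_in = 2L, layer_dims = c(3L, 2L))
  p <- init_model_params(cfg)
  X <- array(rnorm(2 * 3 * 2), c(2, 3, 2))
  fwd <- model_forward(p, X, cfg, keep_cache = TRUE)
  orc <- oracle_forward(X, p, cfg)
  expect_equal(fwd$probs, orc$probs, tolerance = 1e-6)
  for (b in 1:2) {
    expect_equal(fwd$Z[b, , ], orc$Z[[b]], tolerance = 1e-6)
    expect_equal(fwd$flat[b, ], orc$flat[[b]], tolerance = 1e-6)
    expect_equal(fwd$pool$beta[b, ], orc$beta[[b]], tolerance = 1e-6)
    for (l in 1:2) {
      st <- orc$stages[[paste(b, l, sep = "_")]]
      expect_equal(fwd$attention[[l]][b, , ], st$G, tolerance = 1e-6)
      expect_equal(fwd$cache$stack[[l]]$H[[b]], st$H, tolerance = 1e-6)
      expect_equal(fwd$cache$stack[[l]]$P[[b]], st$P, tolerance = 1e-6)
    }
  }
})

test_that("forward pass is permutation equivariant in the electrode axis", {
  set.seed(12)
  cfg <- tiny_config(E = 5L, F_in = 3L, layer_dims = c(4L, 3L))
  p <- init_model_params(cfg)
  X <- array(rnorm(2 * 5 * 3), c(2, 5, 3))
  perm <- c(3L, 5L, 1L, 4L, 2L)
  Xp <- X[, perm, , drop = FALSE]
  f1 <- model_forward(p, X, cfg, keep_cache = TRUE)
  f2 <- model_forward(p, Xp, cfg, keep_cache = TRUE)
  for (b in 1:2) {
    expect_equal(f2$Z[b, , ], f1$Z[b, perm, ], tolerance = 1e-10)
    for (l in 1:2) {
      expect_equal(f2$attention[[l]][b, , ],
                   f1$attention[[l]][b, perm, perm], tolerance = 1e-10)
    }
  }
  # probabilities are NOT invariant (flatten order changes), but the
  # pooled beta permutes consistently
  expect_equal(f2$pool$beta[, ], f1$pool$beta[, perm], tolerance = 1e-10)
})

test_that("backpropagation matches finite differences everywhere", {
  set.seed(77)
  cfg <- tiny_config(E = 4L, F_in = 3L, layer_dims = c(3L, 4L))
  p <- init_model_params(cfg)
  X <- array(rnorm(3 * 4 * 3), c(3, 4, 3))
  y <- c(1L, 2L, 3L)
  loss_of <- function(pp) {
    f <- model_forward(pp, X, cfg)
    -mean(log(f$probs[cbind(1:3, y)]))
  }
  fwd <- model_forward(p, X, cfg, keep_cache = TRUE)
  ce <- eegatt:::ce_loss_grad(fwd$probs, y)
  g <- model_backward(p, cfg, fwd, dlogits = ce$dlogits)$grads
  eps <- 1e-6
  checks <- list(
    function(pp, e) { pp$layers[[1]]$W[2] <- pp$layers[[1]]$W[2] + e; pp },
    function(pp, e) { pp$layers[[1]]$A[5] <- pp$layers[[1]]$A[5] + e; pp },
    function(pp, e) { pp$layers[[2]]$W[7] <- pp$layers[[2]]$W[7] + e; pp },
    function(pp, e) { pp$layers[[2]]$A[11] <- pp$layers[[2]]$A[11] + e; pp },
    function(pp, e) { pp$pool$v[3] <- pp$pool$v[3] + e; pp },
    function(pp, e) { pp$pool$b <- pp$pool$b + e; pp },
    function(pp, e) { pp$head$W1[9] <- pp$head$W1[9] + e; pp },
    function(pp, e) { pp$head$b2[1] <- pp$head$b2[1] + e; pp },
    function(pp, e) { pp$head$W4[2] <- pp$head$W4[2] + e; pp })
  ana <- c(g$layers[[1]]$W[2], g$layers[[1]]$A[5], g$layers[[2]]$W[7],
           g$layers[[2]]$A[11], g$pool$v[3], g$pool$b, g$head$W1[9],
           g$head$b2[1], g$head$W4[2])
  for (k in seq_along(checks)) {
    num <- (loss_of(checks[[k]](p, eps)) -
            loss_of(checks[[k]](p, -eps))) / (2 * eps)
    expect_equal(ana[k], num, tolerance = 1e-4)
  }
})

test_that("plain GCN ablation reduces correctly and preserves shapes", {
  # no edges -> Ahat = I -> layer reduces to projection
  E <- 4L
  Ahat <- diag(E)
  X <- array(rnorm(2 * E * 3), c(2, E, 3))
  W <- matrix(rnorm(9), 3)
  expect_equal(plain_gcn_layer(X, W, Ahat), project(X, W))
  # ring graph: symmetric, rows of Ahat bounded by 1 (4-cycle oracle:
  # regular graph -> Ahat row sums exactly 1)
  R <- normalized_ring_adjacency(4L, 1L)
  expect_true(isSymmetric(R))
  expect_equal(rowSums(R), rep(1, 4), tolerance = 1e-12)
  expect_error(plain_gcn_layer(X, W, matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0,
                                              0, 0, 0, 0, 0, 0, 0), 4)),
               "symmetric")
  # variant swap changes only layer internals, not output shapes
  cfgA <- tiny_config(E = 4L, F_in = 3L, conv = "attention")
  cfgG <- tiny_config(E = 4L, F_in = 3L, conv = "plain_gcn")
  pA <- init_model_params(cfgA, seed = 5)
  pG <- init_model_params(cfgG, seed = 5)
  fA <- model_forward(pA, X, cfgA)
  fG <- model_forward(pG, X, cfgG)
  expect_identical(dim(fA$probs), dim(fG$probs))
  expect_identical(dim(fA$Z), dim(fG$Z))
})

test_that("layer cost counter scales as E squared", {
  f1 <- attention_layer_flops(64, 62, 5, 32)
  f2 <- attention_layer_flops(64, 124, 5, 32)
  expect_equal(f2 / f1, 4)
  # full counter includes the E-linear stages and is strictly larger
  expect_gt(attention_layer_flops(64, 62, 5, 32, full = TRUE), f1)
  # doubling F' doubles the quadratic stage cost
  expect_equal(attention_layer_flops(1, 10, 5, 8) /
               attention_layer_flops(1, 10, 5, 4), 2)
})
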