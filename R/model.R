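#' Model configuration
#'
#' Architecture of the attention-driven dynamic graph convolutional
#' classifier. The input is a batch of segments x electrodes x bands
#' feature tensors; each attention-convolution layer projects node (=
#' electrode) features, builds a data-dependent electrode adjacency via a
#' bilinear attention kernel, and propagates features over that graph.
#' A global attention pooling stage reweights electrodes before a
#' four-layer fully connected softmax head.
#'
#' @param E electrode count (nodes).
#' @param F_in input feature dimension per electrode (frequency bands).
#' @param layer_dims output width of each attention-convolution layer.
#'   Defaults are desk-scale choices, not dictated by the method.
#' @param classifier_dims the three hidden widths of the four-layer head.
#' @param n_classes number of emotion classes (>= 2).
#' @param activation inter-layer nonlinearity (`"relu"` or `"identity"`);
#'   applied after every graph convolution except the last, and between
#'   the head's affine layers.
#' @param pooling `"global_attention"` (learned per-electrode weights) or
#'   `"sum"` (direct summation ablation).
#' @param conv `"attention"` (dynamic learned adjacency) or `"plain_gcn"`
#'   (fixed normalized ring graph ablation).
#' @param gcn_k neighbor radius of the fixed ring graph for the plain-GCN
#'   ablation.
#' @return object of class `model_config`.
#' @export
model_config <- function(E = 62L, F_in = 5L, layer_dims = c(16L, 32L),
                         classifier_dims = c(64L, 32L, 16L),
                         n_classes = 3L,
                         activation = c("relu", "identity"),
                         pooling = c("global_attention", "sum"),
                         conv = c("attention", "plain_gcn"),
                         gcn_k = 2L) {
  activation <- match.arg(activation)
  pooling <- match.arg(pooling)
  conv <- match.arg(conv)
  stopifnot(length(layer_dims) >= 1L, length(classifier_dims) == 3L,
            n_classes >= 2L, E >= 2L, F_in >= 1L)
  cfg <- list(E = as.integer(E), F_in = as.integer(F_in),
              layer_dims = as.integer(layer_dims),
              classifier_dims = as.integer(classifier_dims),
              n_classes = as.integer(n_classes),
              activation = activation, pooling = pooling, conv = conv,
              gcn_k = as.integer(gcn_k))
  if (conv == "plain_gcn") {
    cfg$static_adjacency <- normalized_ring_adjacency(cfg$E, cfg$gcn_k)
  }
  cfg$head_in <- if (pooling == "global_attention") {
    cfg$E * cfg$layer_dims[length(cfg$layer_dims)]
  } else {
    cfg$layer_dims[length(cfg$layer_dims)]
  }
  structure(cfg, class = "model_config")
}

#' Symmetrically normalized ring graph for the plain-GCN ablation
#'
#' Each node connects to its `k` neighbors on either side in montage
#' order (cyclic); self-loops are added and the adjacency is normalized
#' as `D^(-1/2) (A + I) D^(-1/2)`.
#'
#' @param E node count.
#' @param k neighbor radius.
#' @return E x E symmetric matrix.
#' @export
normalized_ring_adjacency <- function(E, k = 2L) {
  A <- matrix(0, E, E)
  for (d in seq_len(k)) {
    idx <- seq_len(E)
    j1 <- ((idx - 1L + d) %% E) + 1L
    A[cbind(idx, j1)] <- 1
    A[cbind(j1, idx)] <- 1
  }
  if (!isSymmetric(A)) stop("ring adjacency construction is not symmetric")
  Ai <- A + diag(E)
  dinv <- 1 / sqrt(rowSums(Ai))
  Ai * (dinv %o% dinv)
}

glorot <- function(nin, nout) {
  l <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -l, l), nin, nout)
}

#' Initialize model parameters
#'
#' Glorot-uniform initialization of all trainable arrays. Uses the
#' current RNG state; seed externally (or via `seed`) for reproducibility.
#'
#' @param config a [model_config()].
#' @param seed optional integer seed applied locally.
#' @return nested list: per-layer `W` (projection) and `A` (attention
#'   kernel), pooling scorer `v`,`b`, head weights `W1..W4`, `b1..b4`.
#' @export
init_model_params <- function(config, seed = NULL) {
  build <- function() {
    L <- length(config$layer_dims)
    dims_in <- c(config$F_in, config$layer_dims[-L])
    layers <- vector("list", L)
    for (l in seq_len(L)) {
      lp <- list(W = glorot(dims_in[l], config$layer_dims[l]))
      if (config$conv == "attention") {
        lp$A <- glorot(config$layer_dims[l], config$layer_dims[l])
      }
      layers[[l]] <- lp
    }
    p <- list(layers = layers)
    if (config$pooling == "global_attention") {
      fp <- config$layer_dims[L]
      p$pool <- list(v = drop(glorot(fp, 1L)), b = 0)
    }
    d <- c(config$head_in, config$classifier_dims, config$n_classes)
    p$head <- list()
    for (i in 1:4) {
      p$head[[paste0("W", i)]] <- glorot(d[i], d[i + 1L])
      p$head[[paste0("b", i)]] <- numeric(d[i + 1L])
    }
    p
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Linear projection of node features
#'
#' First stage of an attention-convolution layer: maps each electrode's
#' feature vector into the layer's latent space, `H = X W`.
#'
#' @param X batch x electrodes x features array.
#' @param W features x latent projection matrix.
#' @return batch x electrodes x latent array.
#' @export
project <- function(X, W) {
  stopifnot(length(dim(X)) == 3L)
  if (dim(X)[3L] != nrow(W)) {
    stop("feature axis of X (", dim(X)[3L],
         ") does not match nrow(W) (", nrow(W), ")")
  }
  bmm_project(X, W)
}

#' Data-dependent electrode adjacency from bilinear attention
#'
#' Scores every electrode pair as `S = H A H^T` per batch item, normalizes
#' rows with a stabilized softmax over the electrode axis, then symmetrizes
#' by averaging with the transpose. The symmetrized matrix has entries in
#' `[0, 1]` and total entry sum `E` per batch item.
#'
#' @param H batch x electrodes x latent array of projected node features.
#' @param A latent x latent attention kernel.
#' @return object of class `attention_graph`: list with `adjacency`
#'   (symmetrized, batch x E x E) and `presym` (row-stochastic softmax
#'   output before symmetrization).
#' @export
attention_adjacency <- function(H, A) {
  d <- dim(H)
  stopifnot(length(d) == 3L, nrow(A) == d[3L], ncol(A) == d[3L])
  if (!all(is.finite(H)) || !all(is.finite(A))) {
    stop("non-finite values in attention inputs")
  }
  M <- bmm_project(H, A)
  pre <- array(0, c(d[1L], d[2L], d[2L]))
  sym <- array(0, c(d[1L], d[2L], d[2L]))
  for (b in seq_len(d[1L])) {
    S <- bslice(M, b) %*% t(bslice(H, b))
    if (!all(is.finite(S))) stop("non-finite attention scores")
    P <- row_softmax(S)
    pre[b, , ] <- P
    sym[b, , ] <- (P + t(P)) / 2
  }
  structure(list(adjacency = sym, presym = pre), class = "attention_graph")
}

#' Graph convolution: propagate node features over an adjacency
#'
#' `Z = A_att H` per batch item. Cost scales as `O(B * E^2 * F')`.
#'
#' @param G an `attention_graph` or a batch x E x E adjacency array.
#' @param H batch x electrodes x latent array.
#' @return batch x electrodes x latent array.
#' @export
graph_conv <- function(G, H) {
  A <- if (inherits(G, "attention_graph")) G$adjacency else G
  d <- dim(H)
  stopifnot(identical(dim(A)[1:2], d[1:2]), dim(A)[3L] == d[2L])
  Z <- array(0, d)
  for (b in seq_len(d[1L])) {
    Z[b, , ] <- bslice(A, b) %*% bslice(H, b)
  }
  Z
}

#' Plain GCN layer over a fixed graph (ablation)
#'
#' `Z = A_hat (X W)` with a static symmetric degree-normalized adjacency;
#' replaces the dynamic attention adjacency in the "without attention
#' convolution" ablation.
#'
#' @param X batch x electrodes x features array.
#' @param W projection matrix.
#' @param adjacency fixed E x E symmetric normalized adjacency.
#' @return batch x electrodes x latent array.
#' @export
plain_gcn_layer <- function(X, W, adjacency) {
  if (!isSymmetric(unname(adjacency))) {
    stop("plain GCN requires a symmetric adjacency")
  }
  H <- project(X, W)
  d <- dim(H)
  Z <- array(0, d)
  for (b in seq_len(d[1L])) {
    Z[b, , ] <- adjacency %*% bslice(H, b)
  }
  Z
}

#' Global attention pooling over electrodes
#'
#' Scores each node with a learned linear map `omega_i = z_i . v + b`,
#' normalizes scores to weights `beta = softmax(omega)` per batch item,
#' and reweights node features `Z'_i = beta_i * Z_i`. The weights `beta`
#' are the exportable per-electrode importance profile.
#'
#' @param Z batch x electrodes x latent array.
#' @param scorer list with `v` (latent-dim vector) and scalar `b`.
#' @return list with `omega` (B x E), `beta` (B x E, rows sum to 1) and
#'   `Zp` (reweighted features, same shape as `Z`).
#' @export
global_attention_pool <- function(Z, scorer) {
  d <- dim(Z)
  stopifnot(length(scorer$v) == d[3L])
  omega <- matrix(Z, nrow = d[1L] * d[2L]) %*% scorer$v + scorer$b
  omega <- matrix(omega, d[1L], d[2L])
  beta <- row_softmax(omega)
  Zp <- Z * as.vector(beta)  # (b,e) varies fastest in both -> broadcast ok
  list(omega = omega, beta = beta, Zp = Zp)
}

#' Four-layer fully connected softmax classifier head
#'
#' `y_hat = softmax(W4 s(W3 s(W2 s(W1 flatten(Z')))))` with activation `s`
#' between affine layers (none after the last). Probabilities are computed
#' with a stabilized softmax; argmax ties break toward the lowest class
#' index.
#'
#' @param Zp pooled features: batch x electrodes x latent array, or an
#'   already flattened batch x D matrix.
#' @param head list of `W1..W4`, `b1..b4`.
#' @param activation `"relu"` or `"identity"`.
#' @return list with `probs` (B x n_classes), `logits`, and `class`
#'   (argmax indices).
#' @export
classify <- function(Zp, head, activation = "relu") {
  X <- if (is.matrix(Zp)) Zp else flatten_nodes(Zp)
  if (ncol(X) != nrow(head$W1)) {
    stop("flattened width ", ncol(X), " does not match head input ",
         nrow(head$W1))
  }
  act <- if (activation == "relu") relu else identity
  h <- X
  for (i in 1:3) {
    h <- act(sweep(h %*% head[[paste0("W", i)]], 2L,
                   head[[paste0("b", i)]], "+"))
  }
  logits <- sweep(h %*% head$W4, 2L, head$b4, "+")
  probs <- row_softmax(logits)
  list(probs = probs, logits = logits,
       class = max.col(probs, ties.method = "first"))
}

# flatten batch x E x F' node features to batch x (E*F') (column-major:
# electrode index varies fastest)
flatten_nodes <- function(Z) {
  d <- dim(Z)
  matrix(Z, d[1L], d[2L] * d[3L])
}

#' Stacked attention-convolution forward pass
#'
#' Applies project -> attention adjacency -> graph convolution per layer
#' (or the plain-GCN ablation), with the configured nonlinearity between
#' layers (none after the last). Each layer's symmetrized adjacency is
#' retained for attention-weight export.
#'
#' @param X batch x electrodes x bands input array.
#' @param params parameter list from [init_model_params()].
#' @param config a [model_config()].
#' @param keep_cache retain intermediates for backpropagation.
#' @return list with `Z` (final node embeddings), `attention` (per-layer
#'   symmetrized adjacency arrays; `NULL` entries for plain-GCN layers)
#'   and, when requested, `cache`.
#' @export
forward_stack <- function(X, params, config, keep_cache = FALSE) {
  core <- fwd_stack_core(array_to_list(X), params, config,
                         keep_cache = keep_cache)
  attention <- lapply(core$attn, function(Gl) {
    if (is.null(Gl)) NULL else list_to_array(Gl)
  })
  list(Z = list_to_array(core$out), attention = attention,
       cache = core$cache)
}

# list-of-matrices layer stack used internally; each batch item is a
# contiguous E x F matrix, all products are plain BLAS calls
fwd_stack_core <- function(Xl, params, config, keep_cache = FALSE) {
  L <- length(config$layer_dims)
  stopifnot(length(params$layers) == L)
  act <- config$activation == "relu"
  B <- length(Xl)
  attn <- vector("list", L)
  cache <- if (keep_cache) vector("list", L) else NULL
  inp <- Xl
  for (l in seq_len(L)) {
    W <- params$layers[[l]]$W
    Hl <- lapply(inp, function(Xb) Xb %*% W)
    if (config$conv == "attention") {
      A <- params$layers[[l]]$A
      Ml <- lapply(Hl, function(Hb) Hb %*% A)
      Pl <- vector("list", B)
      Gl <- vector("list", B)
      Zl <- vector("list", B)
      for (b in seq_len(B)) {
        S <- tcrossprod(Ml[[b]], Hl[[b]])
        if (!all(is.finite(S))) stop("non-finite attention scores")
        P <- row_softmax(S)
        G <- (P + t(P)) / 2
        Pl[[b]] <- P
        Gl[[b]] <- G
        Zl[[b]] <- G %*% Hl[[b]]
      }
      attn[[l]] <- Gl
    } else {
      Ahat <- config$static_adjacency
      Zl <- lapply(Hl, function(Hb) Ahat %*% Hb)
      Ml <- NULL; Pl <- NULL; Gl <- NULL
    }
    applied_act <- act && l < L
    out <- if (applied_act) lapply(Zl, relu) else Zl
    if (keep_cache) {
      cache[[l]] <- list(X = inp, H = Hl, M = Ml, P = Pl, G = Gl,
                         Z = Zl, applied_act = applied_act)
    }
    inp <- out
  }
  list(out = inp, attn = attn, cache = cache)
}

#' Full model forward pass
#'
#' @param params parameters from [init_model_params()].
#' @param X batch x electrodes x bands array.
#' @param config a [model_config()].
#' @param keep_cache retain intermediates for backpropagation.
#' @return list with `probs`, `logits`, `flat` (pooled features fed to the
#'   head and, via the gradient reversal layer, to the domain classifier),
#'   `pool` (omega/beta or node sums), `attention`, and `cache`.
#' @export
model_forward <- function(params, X, config, keep_cache = FALSE) {
  Xl <- array_to_list(X)
  core <- fwd_stack_core(Xl, params, config, keep_cache = keep_cache)
  Zl <- core$out
  B <- length(Zl)
  E <- nrow(Zl[[1L]])
  Fp <- ncol(Zl[[1L]])
  if (config$pooling == "global_attention") {
    v <- params$pool$v
    omega <- t(vapply(Zl, function(Zb) drop(Zb %*% v) + params$pool$b,
                      numeric(E)))
    beta <- row_softmax(omega)
    Zpl <- lapply(seq_len(B), function(b) Zl[[b]] * beta[b, ])
    flat <- t(vapply(Zpl, as.vector, numeric(E * Fp)))
    pool <- list(omega = omega, beta = beta)
  } else {
    sums <- vapply(Zl, colSums, numeric(Fp))
    flat <- if (is.matrix(sums)) t(sums) else matrix(sums, ncol = 1L)
    pool <- list(omega = NULL, beta = NULL)
  }
  head_cache <- head_forward(flat, params$head, config$activation)
  attention <- lapply(core$attn, function(Gl) {
    if (is.null(Gl)) NULL else list_to_array(Gl)
  })
  res <- list(probs = head_cache$probs, logits = head_cache$logits,
              flat = flat, pool = pool, attention = attention,
              Z = list_to_array(Zl))
  if (keep_cache) {
    res$cache <- list(stack = core$cache, Zl = Zl, pool = pool,
                      flat = flat, head = head_cache)
  }
  res
}

# head forward retaining pre-activations for backprop
head_forward <- function(X, head, activation) {
  act <- activation == "relu"
  a <- vector("list", 4L)
  h <- vector("list", 4L)
  hin <- X
  for (i in 1:4) {
    a[[i]] <- sweep(hin %*% head[[paste0("W", i)]], 2L,
                    head[[paste0("b", i)]], "+")
    h[[i]] <- if (i < 4L && act) relu(a[[i]]) else a[[i]]
    hin <- h[[i]]
  }
  logits <- a[[4L]]
  list(X = X, a = a, h = h, logits = logits, probs = row_softmax(logits))
}

#' Analytic operation count of one attention-convolution layer
#'
#' Counts multiply-accumulate operations. By default only the graph
#' stages that are quadratic in the electrode count are reported (the
#' attention-score product `M H^T` and the propagation `A_att H`), i.e.
#' the `O(B * E^2 * F')` complexity class of the layer; `full = TRUE`
#' adds the projection and kernel stages, which are linear in `E`.
#'
#' @param B batch size.
#' @param E electrode count.
#' @param F_in input feature width of the layer.
#' @param F_out latent width of the layer.
#' @param full include E-linear stages.
#' @return numeric operation count.
#' @export
attention_layer_flops <- function(B, E, F_in, F_out, full = FALSE) {
  quad <- 2 * B * E^2 * F_out        # S = M H^T and Z = A_att H
  if (!full) return(quad)
  quad + B * E * F_in * F_out + B * E * F_out^2
}

#' Total trainable parameter count
#'
#' @param params parameter list (model and/or domain classifier).
#' @return integer count of scalar parameters.
#' @export
count_params <- function(params) {
  n <- 0L
  rec <- function(p) {
    if (is.list(p)) lapply(p, rec) else n <<- n + length(p)
    invisible(NULL)
  }
  rec(params)
  n
}
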