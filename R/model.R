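#' Symmetrically normalized adjacency
#'
#' Computes `Atilde = Lambda^{-1/2} (E + I) Lambda^{-1/2}` with
#' `Lambda_ii = sum_j E_ij + 1`. Since valid edge matrices already carry a
#' unit diagonal, the literal formula gives every node a self-loop weight
#' of 2; `strict = TRUE` instead normalizes `E` itself (single self-loop),
#' the conventional GCN variant. Either way the result is symmetric,
#' non-negative, and has spectral radius 1 for a connected graph.
#'
#' @param E Binary symmetric edge matrix with unit diagonal.
#' @param strict Use the single-self-loop normalization (default `FALSE`).
#' @return Dense numeric matrix.
#' @export
normalize_adjacency <- function(E, strict = FALSE) {
  E <- as.matrix(E)
  if (!isSymmetric(unname(E))) stop("normalize_adjacency: E must be symmetric", call. = FALSE)
  if (any(E != 0 & E != 1)) stop("normalize_adjacency: E must be binary", call. = FALSE)
  if (any(diag(E) != 1)) stop("normalize_adjacency: E must have unit diagonal", call. = FALSE)
  if (strict) {
    b <- E
    lam <- rowSums(E)
  } else {
    b <- E + diag(nrow(E))
    lam <- rowSums(E) + 1
  }
  d <- 1 / sqrt(lam)
  a <- b * outer(d, d)
  dimnames(a) <- NULL
  a
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Row-wise layer normalization
#'
#' Each row (node) is standardized over its feature dimension and then
#' rescaled by gain `g` and offset `b`. The epsilon guard keeps constant
#' rows (e.g. all-zero features) finite.
#'
#' @param x Feature matrix (nodes x features).
#' @param g,b Gain and offset vectors, one entry per feature.
#' @param eps Variance guard (default 1e-5).
#' @return Normalized matrix.
#' @export
layer_norm <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  xhat <- xc / sqrt(v + eps)
  n <- nrow(x)
  xhat * rep(g, each = n) + rep(b, each = n)
}

#' Initialize DM-GNN model parameters
#'
#' Three graph-convolution weight matrices (input -> hidden, hidden ->
#' hidden, hidden -> hidden) with layer-norm gains/offsets between layers,
#' a one-output attention weight over the concatenated layer features, and
#' a two-layer fully connected classification head over the mean/max
#' readout. Weights use a fixed-seed scaled-uniform (Glorot) scheme.
#'
#' @param input_dim Node feature width (the landmark count for functional
#'   features; the trace-map bin count for the structural ablation).
#' @param hidden Hidden width of each convolution layer (default 64).
#' @param fc_hidden Hidden width of the classification head (default 64).
#' @param n_classes Number of output classes (default 2).
#' @param k Pooling ratio in (0, 1] (default 0.2).
#' @param seed RNG seed for initialization.
#' @return An object of class `dmgnn_params`.
#' @export
init_model_params <- function(input_dim, hidden = 64L, fc_hidden = 64L,
                              n_classes = 2L, k = 0.2, seed = 1L) {
  input_dim <- check_count(input_dim, "input_dim")
  hidden <- check_count(hidden, "hidden")
  fc_hidden <- check_count(fc_hidden, "fc_hidden")
  if (!(k > 0 && k <= 1)) stop_config("configuration error: 'k' must be in (0,1]")
  glorot <- function(fi, fo) {
    a <- sqrt(6 / (fi + fo))
    matrix(runif(fi * fo, -a, a), fi, fo)
  }
  with_seed(seed, {
    p <- list(
      W1 = glorot(input_dim, hidden),
      W2 = glorot(hidden, hidden),
      W3 = glorot(hidden, hidden),
      g1 = rep(1, hidden), b1 = rep(0, hidden),
      g2 = rep(1, hidden), b2 = rep(0, hidden),
      Ws = glorot(3L * hidden, 1L),
      Wf1 = glorot(6L * hidden, fc_hidden), bf1 = rep(0, fc_hidden),
      Wf2 = glorot(fc_hidden, n_classes), bf2 = rep(0, n_classes))
    attr(p, "hyper") <- list(input_dim = input_dim, hidden = hidden,
                             fc_hidden = fc_hidden, n_classes = n_classes,
                             k = k, seed = seed)
    class(p) <- "dmgnn_params"
    p
  })
}

#' @export
print.dmgnn_params <- function(x, ...) {
  h <- attr(x, "hyper")
  cat(sprintf("dmgnn_params: %d -> %d/%d/%d conv, attention over %d, FC %d -> %d -> %d, k = %g\n",
              h$input_dim, h$hidden, h$hidden, h$hidden, 3 * h$hidden,
              6 * h$hidden, h$fc_hidden, h$n_classes, h$k))
  invisible(x)
}

#' One graph convolution layer
#'
#' `activation(Atilde %*% f_in %*% W)`.
#'
#' @param f_in Node feature matrix.
#' @param adj Normalized adjacency (dense or sparse).
#' @param W Weight matrix (`ncol(f_in)` x output width).
#' @param activation Function applied element-wise (default rectifier;
#'   use `identity` for a linear layer).
#' @return Node feature matrix.
#' @export
gcn_layer <- function(f_in, adj, W, activation = relu) {
  if (ncol(f_in) != nrow(W)) {
    stop(sprintf("gcn_layer: feature width %d does not match weight rows %d",
                 ncol(f_in), nrow(W)), call. = FALSE)
  }
  activation(as.matrix(adj %*% f_in) %*% W)
}

#' Three-layer graph-convolution feature extractor
#'
#' Three rectified graph convolutions with layer normalization between
#' consecutive layers; returns the per-layer outputs and their
#' concatenation `f_c` (width `3 * hidden`).
#'
#' @param features Node feature matrix (N x input_dim).
#' @param adj Normalized adjacency.
#' @param params A `dmgnn_params`.
#' @return List with `f1`, `f2`, `f3`, `f_c`.
#' @export
feature_extractor <- function(features, adj, params) {
  f1 <- gcn_layer(features, adj, params$W1)
  l1 <- layer_norm(f1, params$g1, params$b1)
  f2 <- gcn_layer(l1, adj, params$W2)
  l2 <- layer_norm(f2, params$g2, params$b2)
  f3 <- gcn_layer(l2, adj, params$W3)
  list(f1 = f1, f2 = f2, f3 = f3, f_c = cbind(f1, f2, f3))
}

#' Self-attention graph pooling
#'
#' Attention scores `Z = sigma(Atilde %*% f_c %*% Ws)` (sigma = tanh); the
#' `floor(k * N)` highest-scoring nodes are retained in descending score
#' order (ties broken by the lower node index). With `gate = TRUE`
#' (default) the retained features are multiplied by their scores.
#'
#' @param feat Output of [feature_extractor()] (or a matrix taken as `f_c`).
#' @param adj Normalized adjacency.
#' @param params A `dmgnn_params` (supplies `Ws` and `k`).
#' @param gate Multiply retained features by their attention scores.
#' @return List with `Z` (all N scores), `index` (retained nodes,
#'   descending score), `Z_m` (retained scores) and `f_m` (retained,
#'   optionally gated, features).
#' @export
sagpool <- function(feat, adj, params, gate = TRUE) {
  f_c <- if (is.list(feat)) feat$f_c else feat
  k <- attr(params, "hyper")$k
  n <- nrow(f_c)
  kn <- floor(k * n)
  if (kn < 1L) {
    stop(sprintf("sagpool: pool size floor(k*N) = 0 for k = %g, N = %d", k, n),
         call. = FALSE)
  }
  z <- as.numeric(tanh(as.matrix(adj %*% f_c) %*% params$Ws))
  index <- order(-z, seq_len(n))[seq_len(kn)]
  f_m <- f_c[index, , drop = FALSE]
  if (gate) f_m <- f_m * z[index]
  list(Z = z, index = index, Z_m = z[index], f_m = f_m)
}

#' Mean/max graph readout
#'
#' @param pooled Output of [sagpool()] (uses `f_m`), or a matrix.
#' @return List with `f_GE` (column means), `f_GM` (column maxima) and
#'   their concatenation `f_G`.
#' @export
readout <- function(pooled) {
  f_m <- if (is.list(pooled)) pooled$f_m else pooled
  if (is.null(dim(f_m)) || nrow(f_m) == 0L) {
    stop("readout: empty pooled graph", call. = FALSE)
  }
  f_ge <- colMeans(f_m)
  f_gm <- apply(f_m, 2, max)
  list(f_GE = f_ge, f_GM = f_gm, f_G = c(f_ge, f_gm))
}

#' DM-GNN forward pass for one subject graph
#'
#' Feature extraction, self-attention pooling, readout and the two-layer
#' classification head. The predicted class is the argmax of the two
#' output scores (ties resolve to the first class).
#'
#' @param graph A `subject_graph` (or a list with `features` and `E`).
#' @param params A `dmgnn_params`.
#' @param gate Gate pooled features by attention scores (default `TRUE`).
#' @param strict_gcn Single-self-loop adjacency normalization.
#' @return List with `scores` (2 reals), `probs` (softmax), `pred` (1 or
#'   2, i.e. group A or B), `Z` (attention scores, one per node) and
#'   `index` (retained nodes).
#' @export
dmgnn_forward <- function(graph, params, gate = TRUE, strict_gcn = FALSE) {
  adj <- normalize_adjacency(graph$E, strict = strict_gcn)
  feat <- feature_extractor(graph$features, adj, params)
  pooled <- sagpool(feat, adj, params, gate = gate)
  ro <- readout(pooled)
  h <- relu(drop(ro$f_G %*% params$Wf1) + params$bf1)
  scores <- drop(h %*% params$Wf2) + params$bf2
  e <- exp(scores - max(scores))
  list(scores = scores, probs = e / sum(e), pred = which.max(scores),
       Z = pooled$Z, index = pooled$index)
}

# ---------------------------------------------------------------------------
# Batched training internals: all graphs of a batch are stacked as one
# disjoint-union graph (block-diagonal sparse adjacency), which is
# numerically identical to per-subject processing.

# Assemble a batch. graphs: list of subject_graph with equal N and width.
nn_batch <- function(graphs, strict_gcn = FALSE) {
  n <- nrow(graphs[[1]]$features)
  adjs <- lapply(graphs, function(g) {
    Matrix::Matrix(normalize_adjacency(g$E, strict = strict_gcn), sparse = TRUE)
  })
  list(A = Matrix::bdiag(adjs),
       X = do.call(rbind, lapply(graphs, `[[`, "features")),
       y = ifelse(vapply(graphs, `[[`, character(1), "label") == "A", 1L, 2L),
       N = n, B = length(graphs))
}

nn_forward <- function(batch, params, gate = TRUE, eps = 1e-5) {
  A <- batch$A; N <- batch$N; B <- batch$B
  k <- attr(params, "hyper")$k
  kn <- floor(k * N)
  if (kn < 1L) stop(sprintf("pool size floor(k*N) = 0 for k = %g, N = %d", k, N), call. = FALSE)
  ln_fwd <- function(h, g, b) {
    mu <- rowMeans(h)
    xc <- h - mu
    v <- rowMeans(xc^2)
    inv <- 1 / sqrt(v + eps)
    xhat <- xc * inv
    nr <- nrow(h)
    list(xhat = xhat, inv = inv, y = xhat * rep(g, each = nr) + rep(b, each = nr))
  }
  S1 <- as.matrix(A %*% batch$X)
  A1 <- S1 %*% params$W1; H1 <- relu(A1)
  ln1 <- ln_fwd(H1, params$g1, params$b1)
  S2 <- as.matrix(A %*% ln1$y)
  A2 <- S2 %*% params$W2; H2 <- relu(A2)
  ln2 <- ln_fwd(H2, params$g2, params$b2)
  S3 <- as.matrix(A %*% ln2$y)
  A3 <- S3 %*% params$W3; H3 <- relu(A3)
  FCc <- cbind(H1, H2, H3)
  U <- as.matrix(A %*% FCc)
  Z <- tanh(drop(U %*% params$Ws))
  # Per-graph top-kn selection (descending score, tie -> lower node index).
  idx <- integer(B * kn)
  for (g in seq_len(B)) {
    rows <- (g - 1L) * N + seq_len(N)
    zg <- Z[rows]
    idx[(g - 1L) * kn + seq_len(kn)] <- rows[order(-zg, seq_len(N))[seq_len(kn)]]
  }
  gidx <- rep(seq_len(B), each = kn)
  fm <- FCc[idx, , drop = FALSE]
  if (gate) fm <- fm * Z[idx]
  GE <- rowsum(fm, gidx) / kn
  nf <- ncol(FCc)
  GM <- matrix(0, B, nf)
  amax <- matrix(0L, B, nf)
  for (g in seq_len(B)) {
    block <- fm[(g - 1L) * kn + seq_len(kn), , drop = FALSE]
    am <- max.col(t(block), ties.method = "first")
    amax[g, ] <- am
    GM[g, ] <- block[cbind(am, seq_len(nf))]
  }
  G <- cbind(GE, GM)
  P1 <- G %*% params$Wf1 + rep(params$bf1, each = B)
  R1 <- relu(P1)
  O <- R1 %*% params$Wf2 + rep(params$bf2, each = B)
  Om <- O - apply(O, 1, max)
  expO <- exp(Om)
  P <- expO / rowSums(expO)
  loss <- -mean(log(pmax(P[cbind(seq_len(B), batch$y)], 1e-300)))
  list(S1 = S1, A1 = A1, H1 = H1, ln1 = ln1, S2 = S2, A2 = A2, H2 = H2,
       ln2 = ln2, S3 = S3, A3 = A3, H3 = H3, FCc = FCc, U = U, Z = Z,
       idx = idx, gidx = gidx, fm = fm, amax = amax, GE = GE, GM = GM,
       G = G, P1 = P1, R1 = R1, O = O, P = P, loss = loss, kn = kn)
}

nn_backward <- function(batch, params, fw, gate = TRUE) {
  A <- batch$A; N <- batch$N; B <- batch$B
  kn <- fw$kn
  nf <- ncol(fw$FCc)
  hidden <- ncol(fw$H1)
  dO <- fw$P
  dO[cbind(seq_len(B), batch$y)] <- dO[cbind(seq_len(B), batch$y)] - 1
  dO <- dO / B
  dWf2 <- crossprod(fw$R1, dO)
  dbf2 <- colSums(dO)
  dP1 <- (dO %*% t(params$Wf2)) * (fw$P1 > 0)
  dWf1 <- crossprod(fw$G, dP1)
  dbf1 <- colSums(dP1)
  dG <- dP1 %*% t(params$Wf1)
  dGE <- dG[, seq_len(nf), drop = FALSE]
  dGM <- dG[, nf + seq_len(nf), drop = FALSE]
  dfm <- dGE[fw$gidx, , drop = FALSE] / kn
  for (g in seq_len(B)) {
    rows <- (g - 1L) * kn + fw$amax[g, ]
    ij <- cbind(rows, seq_len(nf))
    dfm[ij] <- dfm[ij] + dGM[g, ]
  }
  dFC <- matrix(0, B * N, nf)
  dZ <- numeric(B * N)
  if (gate) {
    dFC[fw$idx, ] <- dfm * fw$Z[fw$idx]
    dZ[fw$idx] <- rowSums(dfm * fw$FCc[fw$idx, , drop = FALSE])
  } else {
    dFC[fw$idx, ] <- dfm
  }
  dzraw <- dZ * (1 - fw$Z^2)
  dWs <- crossprod(fw$U, dzraw)
  dU <- outer(dzraw, drop(params$Ws))
  dFC <- dFC + as.matrix(A %*% dU)
  dH1c <- dFC[, seq_len(hidden), drop = FALSE]
  dH2c <- dFC[, hidden + seq_len(hidden), drop = FALSE]
  dH3c <- dFC[, 2L * hidden + seq_len(hidden), drop = FALSE]
  ln_bwd <- function(dy, ln, g) {
    nr <- nrow(dy)
    dxhat <- dy * rep(g, each = nr)
    list(dg = colSums(dy * ln$xhat), db = colSums(dy),
         dx = (dxhat - rowMeans(dxhat) - ln$xhat * rowMeans(dxhat * ln$xhat)) * ln$inv)
  }
  dA3 <- dH3c * (fw$A3 > 0)
  dW3 <- crossprod(fw$S3, dA3)
  dL2 <- as.matrix(A %*% (dA3 %*% t(params$W3)))
  b2 <- ln_bwd(dL2, fw$ln2, params$g2)
  dH2 <- dH2c + b2$dx
  dA2 <- dH2 * (fw$A2 > 0)
  dW2 <- crossprod(fw$S2, dA2)
  dL1 <- as.matrix(A %*% (dA2 %*% t(params$W2)))
  b1 <- ln_bwd(dL1, fw$ln1, params$g1)
  dH1 <- dH1c + b1$dx
  dA1 <- dH1 * (fw$A1 > 0)
  dW1 <- crossprod(fw$S1, dA1)
  list(W1 = dW1, W2 = dW2, W3 = dW3,
       g1 = b1$dg, b1 = b1$db, g2 = b2$dg, b2 = b2$db,
       Ws = dWs, Wf1 = dWf1, bf1 = dbf1, Wf2 = dWf2, bf2 = dbf2)
}

adam_init <- function(params) {
  nm <- names(params)
  list(m = lapply(params[nm], function(x) x * 0),
       v = lapply(params[nm], function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 3e-4, weight_decay = 2e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
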