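test_that("normalized adjacency matches hand evaluation and has unit spectral radius", {
  # single node: E = [[1]] -> Lambda = 2, E + I = [[2]], Atilde = [[1]]
  expect_equal(normalize_adjacency(matrix(1, 1, 1)), matrix(1, 1, 1))
  # two connected nodes: Atilde = [[2/3, 1/3], [1/3, 2/3]]
  expect_equal(normalize_adjacency(matrix(1, 2, 2)),
               matrix(c(2, 1, 1, 2) / 3, 2, 2))
  set.seed(9)
  for (r in 1:25) {
    n <- sample(3:50, 1)
    E <- random_edge_matrix(n)
    A <- normalize_adjacency(E)
    expect_true(isSymmetric(A))
    expect_true(all(A >= 0))
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    expect_lt(abs(max(ev) - 1), 1e-10)
  }
  # strict (single self-loop) variant also has unit spectral radius
  E <- random_edge_matrix(10)
  ev <- eigen(normalize_adjacency(E, strict = TRUE), symmetric = TRUE,
              only.values = TRUE)$values
  expect_lt(abs(max(ev) - 1), 1e-10)
  expect_error(normalize_adjacency(matrix(c(1, 2, 2, 1), 2)), "binary")
  expect_error(normalize_adjacency(matrix(c(0, 1, 1, 0), 2)), "diagonal")
})

test_that("gcn_layer is the two-step matrix product", {
  # scalar case: single node, unit adjacency, linear activation
  expect_equal(gcn_layer(matrix(3), matrix(1), matrix(2), identity),
               matrix(6))
  # identity composition
  x <- matrix(rnorm(12), 4, 3)
  expect_equal(gcn_layer(x, diag(4), diag(3), identity), x)
  # random instance vs explicit product
  set.seed(10)
  A <- normalize_adjacency(random_edge_matrix(6))
  W <- matrix(rnorm(3 * 5), 3, 5)
  got <- gcn_layer(x[1:4, ], A[1:4, 1:4], W, identity)
  expect_error(gcn_layer(x, A, matrix(1, 7, 2)), "width")
  ref <- (A[1:4, 1:4] %*% x[1:4, ]) %*% W
  expect_lt(max(abs(got - ref)), 1e-10)
})

test_that("feature extractor produces a 3-layer concatenation and survives zeros", {
  params <- init_model_params(10, hidden = 8, fc_hidden = 4, seed = 1)
  g <- random_graph(n = 12, f0 = 10)
  A <- normalize_adjacency(g$E)
  fe <- feature_extractor(g$features, A, params)
  expect_equal(dim(fe$f_c), c(12L, 24L))
  expect_equal(fe$f_c, cbind(fe$f1, fe$f2, fe$f3))
  # zero input stays finite thanks to the layer-norm epsilon guard
  fe0 <- feature_extractor(matrix(0, 12, 10), A, params)
  expect_true(all(is.finite(fe0$f_c)))
  # determinism
  expect_identical(fe$f_c, feature_extractor(g$features, A, params)$f_c)
})

test_that("sagpool retains floor(kN) nodes and matches sort-and-slice", {
  set.seed(11)
  params <- init_model_params(10, hidden = 8, fc_hidden = 4, k = 0.2, seed = 2)
  # k = 1 retains everything
  p1 <- init_model_params(10, hidden = 8, fc_hidden = 4, k = 1, seed = 2)
  g <- random_graph(n = 3, f0 = 10)
  A <- normalize_adjacency(g$E)
  fe <- feature_extractor(g$features, A, p1)
  expect_length(sagpool(fe, A, p1)$index, 3)
  # floor convention: k = 0.2, N = 358 -> 71
  expect_equal(floor(0.2 * 358), 71)
  # oracle comparison on 100 random instances
  for (r in 1:100) {
    n <- sample(10:40, 1)
    gg <- random_graph(n = n, f0 = 10)
    AA <- normalize_adjacency(gg$E)
    ff <- feature_extractor(gg$features, AA, params)
    pl <- sagpool(ff, AA, params)
    kn <- floor(0.2 * n)
    expect_length(pl$index, kn)
    expect_false(anyDuplicated(pl$index) > 0)
    # brute force: sort scores descending, slice
    ord <- order(-pl$Z, seq_len(n))[seq_len(kn)]
    expect_identical(pl$index, ord)
    expect_equal(pl$Z_m, pl$Z[ord])
    # gated features
    expect_equal(pl$f_m, ff$f_c[ord, , drop = FALSE] * pl$Z[ord])
  }
  # tie-break: exactly equal scores resolve to lower node indices
  p_tie <- params
  p_tie$Ws[] <- 0                                # Z identically tanh(0) = 0
  pl <- sagpool(matrix(rnorm(240), 10, 24), diag(10), p_tie)
  expect_identical(pl$index, 1:2)
})

test_that("readout computes column mean, max, and their concatenation", {
  f_m <- matrix(c(1, 3, 2, 4), 2, 2)
  ro <- readout(f_m)
  expect_equal(ro$f_GE, c(2, 3))
  expect_equal(ro$f_GM, c(3, 4))
  expect_equal(ro$f_G, c(2, 3, 3, 4))
  # singleton: mean = max = the node
  one <- matrix(rnorm(5), 1)
  ro1 <- readout(one)
  expect_equal(ro1$f_GE, drop(one))
  expect_equal(ro1$f_GM, drop(one))
  # random oracle
  set.seed(12)
  m <- matrix(rnorm(40), 8, 5)
  ro2 <- readout(m)
  expect_equal(ro2$f_GE, apply(m, 2, mean))
  expect_equal(ro2$f_GM, apply(m, 2, max))
  expect_error(readout(m[0, , drop = FALSE]), "empty")
})

test_that("forward pass matches a straight-line reference implementation", {
  set.seed(13)
  relu_ref <- function(x) pmax(x, 0)
  ln_ref <- function(x, g, b, eps = 1e-5) {
    t(apply(x, 1, function(r) {
      (r - mean(r)) / sqrt(mean((r - mean(r))^2) + eps) * g + b
    }))
  }
  for (r in 1:5) {
    g <- random_graph(n = 12, f0 = 7, label = sample(c("A", "B"), 1))
    params <- init_model_params(7, hidden = 6, fc_hidden = 5, k = 0.25,
                                seed = 100 + r)
    out <- dmgnn_forward(g, params)
    # reference: explicit, loop-free composition of the printed formulas
    lam <- rowSums(g$E) + 1
    At <- (g$E + diag(12)) / sqrt(outer(lam, lam))
    f1 <- relu_ref(At %*% g$features %*% params$W1)
    f2 <- relu_ref(At %*% ln_ref(f1, params$g1, params$b1) %*% params$W2)
    f3 <- relu_ref(At %*% ln_ref(f2, params$g2, params$b2) %*% params$W3)
    fc <- cbind(f1, f2, f3)
    z <- tanh(drop(At %*% fc %*% params$Ws))
    kn <- floor(0.25 * 12)
    idx <- order(-z, 1:12)[1:kn]
    fm <- fc[idx, ] * z[idx]
    fG <- c(colMeans(fm), apply(fm, 2, max))
    h <- relu_ref(drop(fG %*% params$Wf1) + params$bf1)
    sc <- drop(h %*% params$Wf2) + params$bf2
    expect_lt(max(abs(out$scores - sc)), 1e-8)
    expect_equal(out$Z, z, tolerance = 1e-10)
    expect_identical(out$index, idx)
    expect_length(out$scores, 2)
    expect_equal(out$pred, which.max(sc))
  }
})

test_that("pre-pooling stack is permutation equivariant", {
  set.seed(14)
  g <- random_graph(n = 15, f0 = 9)
  params <- init_model_params(9, hidden = 6, fc_hidden = 4, seed = 3)
  A <- normalize_adjacency(g$E)
  fc <- feature_extractor(g$features, A, params)$f_c
  for (r in 1:5) {
    perm <- sample(15)
    Ep <- g$E[perm, perm]
    Xp <- g$features[perm, ]
    fcp <- feature_extractor(Xp, normalize_adjacency(Ep), params)$f_c
    expect_lt(max(abs(fcp - fc[perm, ])), 1e-10)
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(15)
  graphs <- lapply(1:4, function(i) {
    random_graph(n = 8, f0 = 6, label = c("A", "B")[1 + i %% 2],
                 id = paste0("g", i))
  })
  params <- init_model_params(6, hidden = 5, fc_hidden = 4, k = 0.5, seed = 4)
  batch <- dmgnn:::nn_batch(graphs)
  fw <- dmgnn:::nn_forward(batch, params)
  gr <- dmgnn:::nn_backward(batch, params, fw)
  h <- 1e-6
  for (nm in names(gr)) {
    for (ii in sample(length(params[[nm]]), min(4, length(params[[nm]])))) {
      pp <- params; pp[[nm]][ii] <- pp[[nm]][ii] + h
      pm <- params; pm[[nm]][ii] <- pm[[nm]][ii] - h
      num <- (dmgnn:::nn_forward(batch, pp)$loss -
                dmgnn:::nn_forward(batch, pm)$loss) / (2 * h)
      expect_equal(gr[[nm]][ii], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, ii))
    }
  }
})

test_that("batched forward agrees with the per-subject forward", {
  set.seed(16)
  graphs <- lapply(1:3, function(i) random_graph(n = 10, f0 = 8, id = paste0("g", i)))
  params <- init_model_params(8, hidden = 6, fc_hidden = 4, k = 0.3, seed = 5)
  batch <- dmgnn:::nn_batch(graphs)
  fw <- dmgnn:::nn_forward(batch, params)
  for (i in 1:3) {
    single <- dmgnn_forward(graphs[[i]], params)
    expect_lt(max(abs(fw$O[i, ] - single$scores)), 1e-10)
    expect_lt(max(abs(fw$Z[(i - 1) * 10 + 1:10] - single$Z)), 1e-12)
  }
})
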