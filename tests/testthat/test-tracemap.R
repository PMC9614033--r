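test_that("segment directions of simple fibers are geometrically correct", {
  straight <- cbind(0, 0, seq(0, 10, length.out = 7))
  d <- segment_directions(straight)
  expect_equal(dim(d), c(3L, 3L))
  expect_matrix_equal(d, matrix(c(0, 0, 1), 3, 3, byrow = TRUE), tol = 1e-12)

  # reversing the fiber negates and reverses the part directions
  set.seed(5)
  f <- random_fiber(12)
  d1 <- segment_directions(f)
  d2 <- segment_directions(f[nrow(f):1, ])
  expect_matrix_equal(d2, -d1[3:1, ], tol = 1e-9)

  expect_error(segment_directions(matrix(1, 4, 3), fiber_id = 9), "fiber 9")
})

test_that("quarter-circle arc yields the analytic third-arc chords", {
  # dense polyline along a unit quarter circle in the xy-plane
  t <- seq(0, pi / 2, length.out = 400)
  arc <- cbind(cos(t), sin(t), 0)
  d <- segment_directions(arc)
  # closed form: chord of the arc between angles a and b has direction
  # (cos b - cos a, sin b - sin a, 0), normalized
  brk <- seq(0, pi / 2, length.out = 4)
  expected <- t(vapply(1:3, function(i) {
    v <- c(cos(brk[i + 1]) - cos(brk[i]), sin(brk[i + 1]) - sin(brk[i]), 0)
    v / sqrt(sum(v^2))
  }, numeric(3)))
  expect_matrix_equal(d, expected, tol = 1e-3)
})

test_that("trace-map conserves mass and ignores fiber order", {
  p <- partition_sphere(122)
  set.seed(11)
  for (nb in c(1, 5, 17)) {
    bundle <- replicate(nb, random_fiber(), simplify = FALSE)
    tm <- bundle_tracemap(bundle, p)
    expect_length(tm, 122)
    expect_identical(sum(tm), 3 * nb)          # exact mass conservation
    perm <- sample(nb)
    expect_identical(as.numeric(bundle_tracemap(bundle[perm], p)),
                     as.numeric(tm))
  }
  expect_identical(as.numeric(bundle_tracemap(list(), p)), numeric(122))
})

test_that("a straight +z fiber puts all mass in the north-cap region", {
  p <- partition_sphere(122)
  tm <- bundle_tracemap(list(cbind(0, 0, 0:5)), p)
  expect_equal(tm[[direction_region(p, c(0, 0, 1))]], 3)
  expect_equal(sum(tm), 3)
})

test_that("landmark_bundle matches an exhaustive distance scan", {
  set.seed(21)
  fibers <- replicate(40, random_fiber(), simplify = FALSE)
  point <- c(1, 2, 3)
  for (radius in c(0.5, 2, 5)) {
    got <- landmark_bundle(fibers, point, radius)
    keep <- vapply(fibers, function(f) {
      dmin <- min(sqrt(colSums((t(f) - point)^2)))
      dmin <= radius
    }, logical(1))
    expect_identical(got, fibers[keep])
  }
  # fiber passing exactly through the point is included
  through <- rbind(point - c(5, 0, 0), point, point + c(5, 0, 0))
  expect_length(landmark_bundle(list(through), point, 0.1), 1)
  far <- through + 100
  expect_length(landmark_bundle(list(far), point, 0.1), 0)
})

test_that("ring neighborhoods match graph-distance computed independently", {
  mesh <- icosphere(1)
  expect_identical(ring_neighborhood(mesh, 5L, 0), 5L)
  # rings large enough saturates the closed mesh
  expect_identical(ring_neighborhood(mesh, 1L, 50), seq_len(42L))
  # icosahedron vertex has exactly 5 one-ring neighbors
  ico <- icosphere(0)
  expect_length(ring_neighborhood(ico, 3L, 1), 6L)
  # independent oracle: igraph shortest-path distances on the edge graph
  tr <- mesh$triangles
  edges <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  dmat <- igraph::distances(g)
  for (v in c(1L, 17L, 42L)) {
    for (rings in 0:4) {
      expect_identical(ring_neighborhood(mesh, v, rings),
                       which(dmat[v, ] <= rings))
    }
  }
  expect_error(ring_neighborhood(mesh, 999L, 1), "out of range")
})

test_that("optimize_landmark agrees with exhaustive scoring and breaks ties low", {
  p <- partition_sphere(30)
  set.seed(31)
  templates <- matrix(rpois(10 * 30, 3), 10, 30)
  for (rep in 1:100) {
    nc <- sample(2:8, 1)
    cands <- sort(sample(1000, nc))
    tms <- matrix(rpois(nc * 30, 3), nc, 30)
    got <- optimize_landmark(cands, tms, templates)
    # brute force
    sc <- rep(NA_real_, nc)
    for (i in seq_len(nc)) {
      if (sd(tms[i, ]) > 0) {
        sc[i] <- mean(apply(templates, 1, function(tpl) cor(tms[i, ], tpl)))
      }
    }
    best <- which(abs(sc - max(sc, na.rm = TRUE)) < 1e-15)
    expect_identical(as.integer(got), as.integer(min(cands[best])))
  }
  # perfect match wins with correlation 1
  tpl <- matrix(rep(1:30, each = 10), 10, 30)
  got <- optimize_landmark(c(4L, 9L), rbind(2:31, 30:1), tpl)
  expect_identical(as.integer(got), 4L)
  expect_equal(attr(got, "score"), 1)
  # identical candidates: lowest vertex index
  same <- rbind(1:30, 1:30, 1:30)
  expect_identical(as.integer(optimize_landmark(c(7L, 3L, 5L), same, tpl)), 3L)
  # all-constant trace-maps are an error
  expect_error(optimize_landmark(1:2, matrix(1, 2, 30), tpl), "correlation")
})

test_that("landmarks self-predict on the template reference subject", {
  co <- tiny_cohort(n_a = 2, n_b = 2, n_landmarks = 12, n_timepoints = 30)
  templates <- generate_templates(co, n_templates = 10, perturbation = 0)
  expect_equal(dim(templates$tracemaps), c(12, 10, 122))
  # perturbation 0: all templates identical to the reference
  for (t in 2:10) {
    expect_identical(templates$tracemaps[, t, ], templates$tracemaps[, 1, ])
  }
  ref <- co$subjects[[1]]
  lm <- predict_landmarks(co$mesh, ref$fibers, templates, rings = 2)
  expect_s3_class(lm, "landmark_set")
  expect_equal(nrow(lm), 12)
  expect_identical(lm$vertex, co$landmark_vertices)
})

test_that("landmarks are recovered near truth on a perturbed subject", {
  co <- tiny_cohort(n_a = 3, n_b = 3, n_landmarks = 40, n_timepoints = 30, seed = 13)
  templates <- generate_templates(co, n_templates = 10, perturbation = 0.1)
  adj_ok <- function(truth, got) {
    got == truth | got %in% ring_neighborhood(co$mesh, truth, 1)
  }
  sub <- co$subjects[[2]]  # same truth, independent fiber noise
  lm <- predict_landmarks(co$mesh, sub$fibers, templates, rings = 3)
  near <- mapply(adj_ok, co$landmark_vertices, lm$vertex)
  expect_gte(mean(near), 0.9)
})
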