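# Shared fixtures, all generated in code.

# A small cohort with a planted effect, cheap enough for unit tests.
tiny_cohort <- function(n_a = 6, n_b = 6, n_landmarks = 20, n_timepoints = 60,
                        effect_nodes = 1:6, functional_effect = 2,
                        structural_effect = 4, seed = 7) {
  generate_cohort(cohort_spec(
    n_group_a = n_a, n_group_b = n_b, n_landmarks = n_landmarks,
    n_timepoints = n_timepoints, effect_nodes = effect_nodes,
    functional_effect = functional_effect,
    structural_effect = structural_effect, seed = seed))
}

# A random connected binary symmetric edge matrix with unit diagonal.
random_edge_matrix <- function(n, p = 0.3) {
  E <- matrix(0, n, n)
  E[upper.tri(E)] <- runif(n * (n - 1) / 2) < p
  E <- E + t(E)
  # ensure connectivity with a ring
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    E[i, j] <- E[j, i] <- 1
  }
  diag(E) <- 1
  E
}

# A random small subject graph for model tests.
random_graph <- function(n = 12, f0 = 10, label = "A", id = "g1") {
  g <- list(id = id, label = label,
            features = matrix(rnorm(n * f0), n, f0),
            E = random_edge_matrix(n))
  class(g) <- "subject_graph"
  g
}

# A random fiber polyline.
random_fiber <- function(n_points = 8, scale = 10) {
  start <- runif(3, -scale, scale)
  step <- matrix(rnorm(n_points * 3), n_points)
  apply(rbind(start, step), 2, cumsum)
}

normalize_rows_for_test <- function(m) m / sqrt(rowSums(m^2))

expect_matrix_equal <- function(a, b, tol = 1e-12) {
  expect_equal(dim(a), dim(b))
  expect_lt(max(abs(a - b)), tol)
}
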