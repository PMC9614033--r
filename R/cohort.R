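#' Specification of a synthetic multimodal cohort
#'
#' Defines two groups of synthetic subjects with a planted, tunable group
#' difference. Node time series follow a latent-factor model (shared latent
#' components mixed through a loading matrix plus white noise); group B's
#' loadings on the first component are shifted by `functional_effect` at the
#' `effect_nodes`, which raises the pairwise correlation among those nodes.
#' Fibers are jittered arcs between nearby landmark pairs with
#' Poisson-distributed bundle sizes; on pairs of effect nodes the expected
#' bundle size differs by `structural_effect` in group B.
#'
#' @param n_group_a,n_group_b Subjects per group (default 43 each, the
#'   balanced two-cohort design the pipeline targets).
#' @param n_landmarks Number of landmarks/nodes (default 358).
#' @param n_timepoints Time-series length (default 2300).
#' @param effect_nodes Integer vector of 1-based landmark indices carrying
#'   the planted group difference (default none).
#' @param functional_effect Non-negative loading of the effect nodes on a
#'   dedicated latent component present only in group B (default 1). The
#'   planted correlation shift is confined to effect-node pairs (up to a
#'   second-order variance effect on mixed pairs).
#' @param structural_effect Non-negative shift of the expected fiber-bundle
#'   size on effect-node pairs in group B (default 2, against a baseline
#'   mean of 4 fibers per connected pair).
#' @param noise_sd Standard deviation of node-level white noise (default 1).
#' @param seed Integer RNG seed.
#' @param n_components Number of shared latent components (default 10).
#' @param subject_sd Standard deviation of per-subject loading variability
#'   (individual differences in functional coupling; default 0.3).
#' @param fiber_jitter Gaussian jitter of fiber points in mm (default 0.5).
#' @param base_bundle_mean Baseline Poisson mean bundle size (default 4).
#' @param n_neighbors Nearest landmark neighbors connected by fiber bundles
#'   (default 3).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_group_a = 43L, n_group_b = 43L,
                        n_landmarks = 358L, n_timepoints = 2300L,
                        effect_nodes = integer(0),
                        functional_effect = 1, structural_effect = 2,
                        noise_sd = 1, seed = 1L,
                        n_components = 10L, subject_sd = 0.3,
                        fiber_jitter = 0.5,
                        base_bundle_mean = 4, n_neighbors = 3L) {
  spec <- list(
    n_group_a = check_count(n_group_a, "n_group_a"),
    n_group_b = check_count(n_group_b, "n_group_b"),
    n_landmarks = check_count(n_landmarks, "n_landmarks"),
    n_timepoints = check_count(n_timepoints, "n_timepoints", min = 2L),
    effect_nodes = as.integer(effect_nodes),
    functional_effect = check_positive(functional_effect, "functional_effect", strict = FALSE),
    structural_effect = check_positive(structural_effect, "structural_effect", strict = FALSE),
    noise_sd = check_positive(noise_sd, "noise_sd"),
    seed = check_count(seed, "seed", min = 0L),
    n_components = check_count(n_components, "n_components"),
    subject_sd = check_positive(subject_sd, "subject_sd", strict = FALSE),
    fiber_jitter = check_positive(fiber_jitter, "fiber_jitter", strict = FALSE),
    base_bundle_mean = check_positive(base_bundle_mean, "base_bundle_mean"),
    n_neighbors = check_count(n_neighbors, "n_neighbors"))
  if (length(spec$effect_nodes) &&
      (any(is.na(spec$effect_nodes)) || any(spec$effect_nodes < 1L) ||
       any(spec$effect_nodes > spec$n_landmarks) || anyDuplicated(spec$effect_nodes))) {
    stop_config("configuration error: 'effect_nodes' must be distinct indices in 1..%d",
                spec$n_landmarks)
  }
  class(spec) <- "cohort_spec"
  spec
}

# Smallest icosphere with at least n vertices.
cohort_mesh <- function(n_landmarks, radius = 50) {
  nv <- 12L
  sub <- 0L
  while (nv < n_landmarks) {
    sub <- sub + 1L
    nv <- 10L * 4L^sub + 2L
  }
  icosphere(sub, radius = radius)
}

# One arc-shaped fiber between coordinates a and b, bulging radially outward,
# with Gaussian jitter.
arc_fiber <- function(a, b, jitter, n_points = 9L, bulge = 0.08) {
  t <- seq(0, 1, length.out = n_points)
  p <- outer(1 - t, a) + outer(t, b)
  r <- sqrt(rowSums(p^2))
  target <- r * (1 + bulge * sin(pi * t))
  p <- p * (target / r)
  p + matrix(rnorm(length(p), sd = jitter), ncol = 3)
}

# A short fiber passing through a landmark coordinate in a random direction.
local_fiber <- function(center, jitter, length_mm = 6, n_points = 5L) {
  d <- rnorm(3)
  d <- d / sqrt(sum(d^2))
  t <- seq(-length_mm / 2, length_mm / 2, length.out = n_points)
  outer(t, d) + rep(center, each = n_points) +
    matrix(rnorm(3L * n_points, sd = jitter), ncol = 3)
}

#' Generate a synthetic multimodal cohort
#'
#' Deterministic given `spec$seed`: running twice yields element-wise
#' identical cohorts. See [cohort_spec()] for the generative model.
#'
#' @param spec A `cohort_spec`.
#' @return An object of class `dm_cohort`: list with `spec`, the shared
#'   `mesh`, `landmark_vertices`, `landmark_coords`, and `subjects`, a list
#'   whose elements hold `id`, `label` (`"A"` or `"B"`), `timeseries`
#'   (`n_landmarks` x `n_timepoints`) and `fibers` (list of point matrices).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_landmarks
  mesh <- cohort_mesh(n)
  nv <- nrow(mesh$vertices)
  landmark_vertices <- as.integer(round(seq(1, nv, length.out = n)))
  coords <- mesh$vertices[landmark_vertices, , drop = FALSE]

  with_seed(spec$seed, {
    L <- spec$n_components
    loadings <- matrix(rnorm(n * L), n, L)
    # Dedicated effect component: loaded only by the effect nodes, and only
    # in group B, so the planted coupling shift is confined to effect pairs.
    effect_loading <- numeric(n)
    effect_loading[spec$effect_nodes] <- spec$functional_effect
    # Baseline fiber connectivity: each landmark linked to its nearest
    # neighbors; deduplicated unordered pairs.
    d2 <- as.matrix(stats::dist(coords))^2
    diag(d2) <- Inf
    pairs <- do.call(rbind, lapply(seq_len(n), function(i) {
      nb <- order(d2[i, ])[seq_len(min(spec$n_neighbors, n - 1L))]
      cbind(pmin(i, nb), pmax(i, nb))
    }))
    pairs <- unique(pairs)
    pair_effect <- pairs[, 1] %in% spec$effect_nodes &
      pairs[, 2] %in% spec$effect_nodes

    labels <- c(rep("A", spec$n_group_a), rep("B", spec$n_group_b))
    subjects <- vector("list", length(labels))
    for (si in seq_along(labels)) {
      grp <- labels[si]
      lam <- loadings + matrix(rnorm(n * L, sd = spec$subject_sd), n, L)
      if (grp == "B") lam <- cbind(lam, effect_loading)
      s <- matrix(rnorm(ncol(lam) * spec$n_timepoints), ncol(lam), spec$n_timepoints)
      ts <- lam %*% s +
        spec$noise_sd * matrix(rnorm(n * spec$n_timepoints), n, spec$n_timepoints)
      mean_counts <- rep(spec$base_bundle_mean, nrow(pairs))
      if (grp == "B") {
        mean_counts[pair_effect] <- mean_counts[pair_effect] + spec$structural_effect
      }
      counts <- rpois(nrow(pairs), mean_counts)
      fibers <- vector("list", sum(counts) + 3L * n)
      fi <- 0L
      for (pi in seq_len(nrow(pairs))) {
        for (r in seq_len(counts[pi])) {
          fi <- fi + 1L
          fibers[[fi]] <- arc_fiber(coords[pairs[pi, 1], ], coords[pairs[pi, 2], ],
                                    spec$fiber_jitter)
        }
      }
      for (i in seq_len(n)) {
        for (r in 1:3) {
          fi <- fi + 1L
          fibers[[fi]] <- local_fiber(coords[i, ], spec$fiber_jitter)
        }
      }
      subjects[[si]] <- list(id = sprintf("sub-%03d", si), label = grp,
                             timeseries = ts, fibers = fibers[seq_len(fi)])
    }
    out <- list(spec = spec, mesh = mesh,
                landmark_vertices = landmark_vertices,
                landmark_coords = coords, subjects = subjects)
    class(out) <- "dm_cohort"
    out
  })
}

#' @export
print.dm_cohort <- function(x, ...) {
  labs <- vapply(x$subjects, `[[`, character(1), "label")
  cat(sprintf("dm_cohort: %d subjects (A: %d, B: %d), %d landmarks, %d timepoints\n",
              length(x$subjects), sum(labs == "A"), sum(labs == "B"),
              x$spec$n_landmarks, x$spec$n_timepoints))
  invisible(x)
}

#' Generate a landmark template set from a reference subject
#'
#' Produces `n_templates` perturbed copies of the reference subject's
#' per-landmark trace-maps (the bundle of fibers within `radius` of each
#' true landmark). With `perturbation = 0` all templates equal the
#' reference exactly.
#'
#' @param cohort A `dm_cohort`; its first subject serves as the reference.
#' @param n_templates Number of templates (default 10).
#' @param perturbation Relative magnitude of Gaussian bin noise (default 0.1).
#' @param radius Fiber capture radius in mm (default 2).
#' @param partition Sphere partition (default 122 regions).
#' @param seed RNG seed (default derived from the cohort seed).
#' @return An object of class `template_set`: list with `tracemaps`
#'   (array `n_landmarks` x `n_templates` x `n_bins`), `init_vertices`,
#'   `n_landmarks`, `n_templates`, `n_bins`.
#' @export
generate_templates <- function(cohort, n_templates = 10L, perturbation = 0.1,
                               radius = 2, partition = partition_sphere(122L),
                               seed = cohort$spec$seed + 1000L) {
  stopifnot(inherits(cohort, "dm_cohort"))
  n_templates <- check_count(n_templates, "n_templates")
  perturbation <- check_positive(perturbation, "perturbation", strict = FALSE)
  ref <- cohort$subjects[[1]]
  n <- cohort$spec$n_landmarks
  inc <- fiber_incidence(ref$fibers, cohort$landmark_coords, radius)
  bins3 <- fiber_region_bins(ref$fibers, partition)
  ref_tm <- matrix(0, n, partition$n_regions)
  for (i in seq_len(n)) {
    f_idx <- which(inc[, i])
    if (length(f_idx)) ref_tm[i, ] <- tabulate(bins3[f_idx, ], nbins = partition$n_regions)
  }
  tm <- array(0, dim = c(n, n_templates, partition$n_regions))
  with_seed(seed, {
    scale <- mean(ref_tm[ref_tm > 0])
    for (t in seq_len(n_templates)) {
      noise <- if (perturbation > 0) {
        matrix(rnorm(length(ref_tm), sd = perturbation * scale), n)
      } else {
        0
      }
      tm[, t, ] <- pmax(0, ref_tm + noise)
    }
  })
  out <- list(tracemaps = tm, init_vertices = cohort$landmark_vertices,
              n_landmarks = n, n_templates = n_templates,
              n_bins = partition$n_regions)
  class(out) <- "template_set"
  out
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("template_set: %d landmarks x %d templates, %d-bin trace-maps\n",
              x$n_landmarks, x$n_templates, x$n_bins))
  invisible(x)
}
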