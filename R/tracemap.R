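#' Resample a fiber polyline to equidistant points
#'
#' Linear interpolation at equally spaced arc-length positions. Used before
#' splitting a fiber into three equal-length parts, so "equal parts" is well
#' defined for unevenly sampled polylines.
#'
#' @param fiber Numeric matrix, one 3D point per row, >= 2 rows.
#' @param n_points Number of output points (>= 2).
#' @return Matrix `n_points` x 3.
#' @export
resample_fiber <- function(fiber, n_points = 31L) {
  fiber <- as.matrix(fiber)
  if (nrow(fiber) < 2L) stop("resample_fiber: fiber needs at least 2 points", call. = FALSE)
  if (!all(is.finite(fiber))) stop("resample_fiber: non-finite coordinate", call. = FALSE)
  seg <- sqrt(rowSums((fiber[-1, , drop = FALSE] - fiber[-nrow(fiber), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total == 0) stop("resample_fiber: zero-length fiber", call. = FALSE)
  at <- seq(0, total, length.out = n_points)
  out <- matrix(0, n_points, 3)
  for (d in 1:3) out[, d] <- stats::approx(s, fiber[, d], xout = at, ties = "ordered")$y
  out
}

#' Main directions of the three equal parts of a fiber
#'
#' The fiber is resampled to `3 * points_per_part + 1` equidistant points so
#' the three parts span exactly the first, middle and last third of the arc
#' length; each part's direction is the unit chord from its first to its
#' last point.
#'
#' @param fiber Numeric matrix of 3D points (>= 2 rows).
#' @param points_per_part Resampled points per part (default 10).
#' @param fiber_id Optional identifier used in error messages.
#' @return 3 x 3 matrix; row i is the unit direction of part i.
#' @export
segment_directions <- function(fiber, points_per_part = 10L, fiber_id = NULL) {
  m <- check_count(points_per_part, "points_per_part")
  tag <- if (is.null(fiber_id)) "" else sprintf(" (fiber %s)", fiber_id)
  rs <- tryCatch(resample_fiber(fiber, 3L * m + 1L), error = function(e) {
    stop(sprintf("segment_directions: zero-direction fiber%s: %s", tag,
                 conditionMessage(e)), call. = FALSE)
  })
  ends <- rs[1L + (0:3) * m, , drop = FALSE]
  dirs <- ends[-1, , drop = FALSE] - ends[-4, , drop = FALSE]
  nrm <- sqrt(rowSums(dirs^2))
  if (any(nrm == 0)) {
    stop(sprintf("segment_directions: zero-direction part%s", tag), call. = FALSE)
  }
  dirs / nrm
}

#' Trace-map descriptor of a fiber bundle
#'
#' Each fiber contributes the directions of its three equal parts; each
#' direction increments the bin of the sphere-partition region containing
#' it. Bins are raw counts, so `sum(bins) == 3 * length(bundle)` exactly.
#'
#' @param bundle List of fiber point matrices (possibly empty).
#' @param partition A `sphere_partition` (default 122 regions).
#' @param points_per_part Resampling resolution per part.
#' @return An object of class `trace_map`: numeric bin vector of length
#'   `partition$n_regions`.
#' @export
bundle_tracemap <- function(bundle, partition = partition_sphere(122L),
                            points_per_part = 10L) {
  stopifnot(inherits(partition, "sphere_partition"))
  bins <- numeric(partition$n_regions)
  if (length(bundle)) {
    dirs <- do.call(rbind, lapply(seq_along(bundle), function(i) {
      segment_directions(bundle[[i]], points_per_part, fiber_id = i)
    }))
    reg <- direction_region(partition, dirs)
    tab <- tabulate(reg, nbins = partition$n_regions)
    bins <- as.numeric(tab)
  }
  structure(bins, class = "trace_map")
}

#' @export
print.trace_map <- function(x, ...) {
  cat(sprintf("trace_map: %d bins, mass %g (%g fibers)\n",
              length(x), sum(x), sum(x) / 3))
  invisible(x)
}

#' Fibers passing through a point
#'
#' Selects fibers having at least one polyline point within Euclidean
#' distance `radius` of `point`. This defines the fiber bundle "passing
#' through" a landmark.
#'
#' @param fibers List of fiber point matrices.
#' @param point Length-3 coordinate (mm).
#' @param radius Capture radius in mm (> 0), default 2.
#' @return Sub-list of `fibers` (possibly empty).
#' @export
landmark_bundle <- function(fibers, point, radius = 2) {
  radius <- check_positive(radius, "radius")
  point <- as.numeric(point)
  r2 <- radius^2
  hit <- vapply(fibers, function(f) {
    d2 <- (f[, 1] - point[1])^2 + (f[, 2] - point[2])^2 + (f[, 3] - point[3])^2
    any(d2 <= r2)
  }, logical(1))
  fibers[hit]
}

# --- fast incidence machinery used by predict_landmarks / structural_counts ---

# Stack all fiber points into one matrix with a fiber-id column.
fiber_point_stack <- function(fibers) {
  np <- vapply(fibers, nrow, integer(1))
  list(points = do.call(rbind, fibers),
       fiber = rep.int(seq_along(fibers), np))
}

# n_fibers x n_points(query) logical incidence: fiber has a point within
# `radius` of each query coordinate. Chunked over query columns.
fiber_incidence <- function(fibers, coords, radius) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  st <- fiber_point_stack(fibers)
  p <- st$points
  nf <- length(fibers)
  nq <- nrow(coords)
  r2 <- radius^2
  pn <- rowSums(p^2)
  inc <- matrix(FALSE, nf, nq)
  chunk <- max(1L, floor(4e6 / max(1, nrow(p))))
  for (start in seq(1L, nq, by = chunk)) {
    cols <- start:min(nq, start + chunk - 1L)
    q <- coords[cols, , drop = FALSE]
    d2 <- outer(pn, rowSums(q^2), "+") - 2 * p %*% t(q)
    hit <- d2 <= r2
    inc[, cols] <- rowsum(hit + 0, st$fiber) > 0
  }
  inc
}

# Per-fiber region triples (3 bins per fiber) under `partition`.
fiber_region_bins <- function(fibers, partition, points_per_part = 10L) {
  t(vapply(seq_along(fibers), function(i) {
    direction_region(partition,
                     segment_directions(fibers[[i]], points_per_part, fiber_id = i))
  }, integer(3)))
}

#' Select the landmark vertex best matching a template trace-map set
#'
#' Scores each candidate by the mean Pearson correlation between its
#' trace-map and the template trace-maps and returns the best candidate;
#' ties are broken by the lowest vertex index. Candidates whose trace-map
#' has zero variance (e.g. empty bundles) are excluded.
#'
#' @param candidates Integer vector of candidate vertex indices.
#' @param candidate_tracemaps Matrix, one row per candidate (bin vectors),
#'   or a list of `trace_map`s.
#' @param templates Matrix of template trace-maps, one row per template.
#' @return The selected vertex index (scalar integer), with the winning
#'   score in attribute `"score"`.
#' @export
optimize_landmark <- function(candidates, candidate_tracemaps, templates) {
  if (is.list(candidate_tracemaps)) {
    candidate_tracemaps <- do.call(rbind, lapply(candidate_tracemaps, as.numeric))
  }
  templates <- as.matrix(templates)
  if (length(candidates) != nrow(candidate_tracemaps)) {
    stop("optimize_landmark: one trace-map per candidate required", call. = FALSE)
  }
  ok <- apply(candidate_tracemaps, 1, function(x) stats::sd(x) > 0)
  tok <- apply(templates, 1, function(x) stats::sd(x) > 0)
  if (!any(ok) || !any(tok)) {
    stop("optimize_landmark: undefined correlation (all candidate or template trace-maps constant)",
         call. = FALSE)
  }
  cc <- cor(t(candidate_tracemaps[ok, , drop = FALSE]),
            t(templates[tok, , drop = FALSE]))
  score <- rowMeans(cc)
  cand_ok <- candidates[ok]
  best <- which(score == max(score))
  sel <- min(cand_ok[best])
  structure(as.integer(sel), score = max(score))
}

#' Predict corresponding landmarks on a subject
#'
#' For every landmark, candidate vertices are the `rings`-ring neighborhood
#' of the landmark's initial vertex; each candidate's fiber bundle (fibers
#' within `radius` of the candidate vertex) is summarized by its trace-map,
#' and the candidate whose trace-map best correlates (on average) with the
#' landmark's template trace-maps is selected.
#'
#' @param mesh A `surface_mesh`.
#' @param fibers List of fiber point matrices.
#' @param templates A `template_set` (see [generate_templates()]).
#' @param initial_vertices Integer vector, one initial vertex per landmark
#'   (defaults to the template set's initial vertices).
#' @param rings Ring-neighborhood radius for the candidate search (default 5).
#' @param radius Fiber capture radius in mm (default 2).
#' @param partition Sphere partition for trace-maps (default matches the
#'   template set).
#' @return An object of class `landmark_set`: a data.frame with columns
#'   `landmark`, `vertex`, `x`, `y`, `z`.
#' @export
predict_landmarks <- function(mesh, fibers, templates,
                              initial_vertices = templates$init_vertices,
                              rings = 5L, radius = 2, partition = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(templates, "template_set"))
  rings <- check_count(rings, "rings", min = 0L)
  radius <- check_positive(radius, "radius")
  n_lm <- templates$n_landmarks
  if (length(initial_vertices) != n_lm) {
    stop("predict_landmarks: one initial vertex per landmark required", call. = FALSE)
  }
  if (is.null(partition)) partition <- partition_sphere(templates$n_bins)
  cand_list <- lapply(initial_vertices, function(v) ring_neighborhood(mesh, v, rings))
  verts <- sort(unique(unlist(cand_list)))
  inc <- fiber_incidence(fibers, mesh$vertices[verts, , drop = FALSE], radius)
  bins3 <- fiber_region_bins(fibers, partition)
  # Trace-map of every distinct candidate vertex, computed once.
  tm <- matrix(0, length(verts), partition$n_regions)
  for (j in seq_along(verts)) {
    f_idx <- which(inc[, j])
    if (length(f_idx)) {
      tm[j, ] <- tabulate(bins3[f_idx, ], nbins = partition$n_regions)
    }
  }
  vert_pos <- integer(nrow(mesh$vertices))
  vert_pos[verts] <- seq_along(verts)
  sel <- integer(n_lm)
  for (i in seq_len(n_lm)) {
    cand <- cand_list[[i]]
    res <- tryCatch(
      optimize_landmark(cand, tm[vert_pos[cand], , drop = FALSE],
                        templates$tracemaps[i, , ]),
      error = function(e) {
        stop(sprintf("predict_landmarks: landmark %d: %s", i, conditionMessage(e)),
             call. = FALSE)
      })
    sel[i] <- res
  }
  out <- data.frame(landmark = seq_len(n_lm), vertex = sel,
                    x = mesh$vertices[sel, 1], y = mesh$vertices[sel, 2],
                    z = mesh$vertices[sel, 3])
  class(out) <- c("landmark_set", "data.frame")
  out
}
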