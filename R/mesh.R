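#' Construct a triangulated surface mesh
#'
#' @param vertices Numeric matrix, one row per vertex, 3 columns (mm).
#' @param triangles Integer matrix, one row per triangle, 3 columns of
#'   1-based vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  if (ncol(vertices) != 3) stop("surface_mesh: vertices must have 3 columns", call. = FALSE)
  if (!all(is.finite(vertices))) stop("surface_mesh: non-finite vertex coordinate", call. = FALSE)
  if (any(triangles < 1L) || any(triangles > nrow(vertices))) {
    stop("surface_mesh: triangle index out of range", call. = FALSE)
  }
  out <- list(vertices = vertices, triangles = triangles)
  class(out) <- "surface_mesh"
  out
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

# Vertex adjacency list from the triangle edge graph (cached on the mesh).
mesh_adjacency <- function(mesh) {
  if (!is.null(attr(mesh, "adjacency"))) return(attr(mesh, "adjacency"))
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  split(e[, 2], factor(e[, 1], levels = seq_len(nrow(mesh$vertices)))) |>
    lapply(function(v) sort(unique(v)))
}

#' Ring neighborhood of a mesh vertex
#'
#' All vertices within graph distance `rings` of `vertex` on the mesh edge
#' graph, including `vertex` itself. The candidate search for landmark
#' optimization uses `rings = 5`.
#'
#' @param mesh A `surface_mesh`.
#' @param vertex 1-based seed vertex index.
#' @param rings Number of rings (graph-distance radius), >= 0.
#' @return Sorted integer vector of vertex indices.
#' @export
ring_neighborhood <- function(mesh, vertex, rings) {
  stopifnot(inherits(mesh, "surface_mesh"))
  rings <- check_count(rings, "rings", min = 0L)
  nv <- nrow(mesh$vertices)
  if (length(vertex) != 1L || is.na(vertex) || vertex < 1L || vertex > nv) {
    stop(sprintf("ring_neighborhood: vertex index %s out of range 1..%d",
                 paste(vertex, collapse = ","), nv), call. = FALSE)
  }
  vertex <- as.integer(vertex)
  if (rings == 0L) return(vertex)
  adj <- mesh_adjacency(mesh)
  seen <- logical(nv)
  seen[vertex] <- TRUE
  frontier <- vertex
  for (r in seq_len(rings)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    if (!length(nxt)) break
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen)
}

# Unit icosahedron (12 vertices, 20 faces).
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- normalize_rows(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  surface_mesh(v, f)
}

#' Subdivided icosahedral sphere mesh
#'
#' Each subdivision step splits every triangle into four and projects the
#' new vertices onto the sphere, giving 12, 42, 162, 642, 2562, ... vertices.
#' This is the default synthetic cortical surface: a closed mesh with
#' near-uniform vertex spacing and well-defined ring neighborhoods.
#'
#' @param subdivisions Number of subdivision steps (>= 0).
#' @param radius Sphere radius in mm (default 50).
#' @return A `surface_mesh`.
#' @export
icosphere <- function(subdivisions = 3, radius = 50) {
  subdivisions <- check_count(subdivisions, "subdivisions", min = 0L)
  radius <- check_positive(radius, "radius")
  mesh <- icosahedron()
  for (s in seq_len(subdivisions)) {
    v <- mesh$vertices
    f <- mesh$triangles
    edge_key <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
    edges <- unique(c(edge_key(f[, 1], f[, 2]), edge_key(f[, 2], f[, 3]),
                      edge_key(f[, 3], f[, 1])))
    mid_idx <- seq_along(edges) + nrow(v)
    names(mid_idx) <- edges
    ab <- do.call(rbind, strsplit(edges, "_"))
    ia <- as.integer(ab[, 1]); ib <- as.integer(ab[, 2])
    mids <- normalize_rows((v[ia, , drop = FALSE] + v[ib, , drop = FALSE]) / 2)
    v2 <- rbind(v, mids)
    m12 <- mid_idx[edge_key(f[, 1], f[, 2])]
    m23 <- mid_idx[edge_key(f[, 2], f[, 3])]
    m31 <- mid_idx[edge_key(f[, 3], f[, 1])]
    f2 <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
                cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
    mesh <- surface_mesh(v2, f2)
  }
  surface_mesh(mesh$vertices * radius, mesh$triangles)
}

#' Read / write a mesh in OFF format
#'
#' @param path File path.
#' @return `read_off` returns a `surface_mesh`.
#' @export
read_off <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (toupper(lines[1]) != "OFF") stop(sprintf("read_off: '%s' is not an OFF file", path), call. = FALSE)
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  v <- matrix(scan(text = lines[3:(2 + nv)], quiet = TRUE), ncol = 3, byrow = TRUE)
  fraw <- matrix(scan(text = lines[(3 + nv):(2 + nv + nf)], quiet = TRUE), ncol = 4, byrow = TRUE)
  if (any(fraw[, 1] != 3)) stop("read_off: only triangular faces supported", call. = FALSE)
  surface_mesh(v, fraw[, 2:4] + 1L)
}

#' @rdname read_off
#' @param mesh A `surface_mesh`.
#' @export
write_off <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("OFF", sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles))), con)
  writeLines(apply(mesh$vertices, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  writeLines(apply(mesh$triangles - 1L, 1, function(r) paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}
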