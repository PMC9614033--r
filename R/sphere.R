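#' Deterministic equal-area partition of the unit sphere
#'
#' Builds a zonal equal-area partition: two polar caps plus a stack of
#' collars, each collar cut into equal-longitude sectors. Collar boundaries
#' are placed at colatitudes derived from cumulative region counts, so every
#' region has area exactly `4 * pi / n_regions`. The construction is pure
#' arithmetic and therefore identical across platforms.
#'
#' Trace-map descriptors bin fiber-segment directions on this partition;
#' the conventional resolution is 122 regions.
#'
#' @param n_regions Number of regions (default 122).
#' @return An object of class `sphere_partition` with elements
#'   `n_regions`, `colat_bounds` (collar boundary colatitudes, including the
#'   two cap boundaries), `sectors` (regions per collar) and `offsets`
#'   (cumulative region index offsets per collar).
#' @examples
#' p <- partition_sphere(122)
#' range(region_area_fractions(p)) # all exactly 1/122
#' @export
partition_sphere <- function(n_regions = 122) {
  n <- check_count(n_regions, "n_regions")
  if (n == 1L) {
    out <- list(n_regions = 1L, colat_bounds = numeric(0),
                sectors = integer(0), offsets = integer(0))
    class(out) <- "sphere_partition"
    return(out)
  }
  area <- 4 * pi / n
  theta_cap <- acos(1 - 2 / n)            # polar cap with area = `area`
  if (n == 2L) {
    out <- list(n_regions = 2L, colat_bounds = theta_cap,
                sectors = integer(0), offsets = integer(0))
    class(out) <- "sphere_partition"
    return(out)
  }
  delta_ideal <- sqrt(area)
  n_collars <- max(1L, as.integer(round((pi - 2 * theta_cap) / delta_ideal)))
  delta_fit <- (pi - 2 * theta_cap) / n_collars
  # Ideal (real-valued) region counts per collar, rounded with cumulative
  # correction so that the total is exact.
  a <- 0
  sectors <- integer(n_collars)
  for (i in seq_len(n_collars)) {
    lo <- theta_cap + (i - 1) * delta_fit
    hi <- theta_cap + i * delta_fit
    y <- 2 * pi * (cos(lo) - cos(hi)) / area
    sectors[i] <- as.integer(round(y + a))
    a <- a + y - sectors[i]
  }
  stopifnot(2L + sum(sectors) == n)
  keep <- sectors > 0L
  sectors <- sectors[keep]
  # Re-derive collar boundaries from cumulative counts: the boundary below
  # collar i encloses 1 + sectors[1..i] regions, each of area 4*pi/n.
  ncum <- 1L + cumsum(sectors)
  colat_bounds <- c(theta_cap, acos(pmax(-1, pmin(1, 1 - 2 * ncum / n))))
  offsets <- 1L + c(0L, cumsum(sectors)[-length(sectors)])
  out <- list(n_regions = n, colat_bounds = colat_bounds,
              sectors = sectors, offsets = offsets)
  class(out) <- "sphere_partition"
  out
}

#' Map unit directions to partition regions
#'
#' @param partition A `sphere_partition`.
#' @param directions Numeric matrix with 3 columns (or a length-3 vector);
#'   rows need not be normalized but must be non-zero.
#' @return Integer vector of region indices in `1..n_regions`.
#' @export
direction_region <- function(partition, directions) {
  stopifnot(inherits(partition, "sphere_partition"))
  if (is.null(dim(directions))) directions <- matrix(directions, ncol = 3)
  nrm <- sqrt(rowSums(directions^2))
  if (any(!is.finite(nrm)) || any(nrm == 0)) {
    stop("direction_region: non-finite or zero direction vector", call. = FALSE)
  }
  if (partition$n_regions == 1L) return(rep(1L, nrow(directions)))
  z <- directions[, 3] / nrm
  colat <- acos(pmax(-1, pmin(1, z)))
  nb <- length(partition$colat_bounds)
  band <- findInterval(colat, partition$colat_bounds)  # 0 = north cap
  idx <- integer(nrow(directions))
  idx[band == 0L] <- 1L
  idx[band >= nb] <- partition$n_regions
  inner <- which(band >= 1L & band < nb)
  if (length(inner)) {
    lon <- atan2(directions[inner, 2], directions[inner, 1])
    lon <- lon %% (2 * pi)
    m <- partition$sectors[band[inner]]
    sec <- pmin(m - 1L, floor(lon / (2 * pi) * m))
    idx[inner] <- partition$offsets[band[inner]] + as.integer(sec) + 1L
  }
  idx
}

#' Exact area fraction of each partition region
#'
#' Computed analytically from the collar boundaries; by construction every
#' fraction equals `1 / n_regions`.
#'
#' @param partition A `sphere_partition`.
#' @return Numeric vector of length `n_regions` summing to 1.
#' @export
region_area_fractions <- function(partition) {
  stopifnot(inherits(partition, "sphere_partition"))
  n <- partition$n_regions
  if (n == 1L) return(1)
  bounds <- c(0, partition$colat_bounds, pi)
  band_area <- (cos(bounds[-length(bounds)]) - cos(bounds[-1])) / 2  # fraction
  fr <- numeric(n)
  fr[1] <- band_area[1]
  fr[n] <- band_area[length(band_area)]
  for (i in seq_along(partition$sectors)) {
    m <- partition$sectors[i]
    fr[partition$offsets[i] + seq_len(m)] <- band_area[i + 1] / m
  }
  fr
}

#' @export
print.sphere_partition <- function(x, ...) {
  cat(sprintf("Equal-area sphere partition: %d regions (%d collars + 2 caps)\n",
              x$n_regions, length(x$sectors)))
  invisible(x)
}
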