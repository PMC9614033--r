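#' Write / read a numeric matrix as TSV
#'
#' Plain tab-separated decimal text at full (17 significant digit)
#' precision, no header by default, so a write-then-read round trip
#' reproduces values exactly. An empty matrix writes an empty file.
#'
#' @param m Numeric matrix.
#' @param path File path.
#' @param col_names Write/expect a header row (default `FALSE`).
#' @return `read_matrix_tsv` returns a numeric matrix.
#' @export
write_matrix_tsv <- function(m, path, col_names = FALSE) {
  m <- as.matrix(m)
  con <- file(path, "wb")
  on.exit(close(con))
  if (nrow(m) == 0L || ncol(m) == 0L) return(invisible(path))
  if (col_names && !is.null(colnames(m))) {
    writeLines(paste(colnames(m), collapse = "\t"), con)
  }
  txt <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(txt, con)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, col_names = FALSE) {
  lines <- readLines(path)
  if (!length(lines)) return(matrix(numeric(0), 0, 0))
  if (col_names) lines <- lines[-1]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  nc <- unique(lengths(cells))
  if (length(nc) != 1L) {
    stop(sprintf("read_matrix_tsv: '%s' row %d has %d columns, expected %d",
                 path, which(lengths(cells) != nc[1])[1],
                 lengths(cells)[lengths(cells) != nc[1]][1], nc[1]), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(unlist(cells)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop(sprintf("read_matrix_tsv: '%s' non-numeric cell at row %d, column %d",
                 path, (bad - 1L) %/% nc + 1L, (bad - 1L) %% nc + 1L), call. = FALSE)
  }
  matrix(vals, ncol = nc, byrow = TRUE)
}

#' Write / read fibers as blank-line-separated polyline blocks
#'
#' One polyline per block, one `x y z` (tab-separated) point per line,
#' blocks separated by blank lines.
#'
#' @param fibers List of fiber point matrices.
#' @param path File path.
#' @return `read_fibers_tsv` returns a list of point matrices.
#' @export
write_fibers_tsv <- function(fibers, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq_along(fibers)) {
    if (i > 1L) writeLines("", con)
    writeLines(apply(fibers[[i]], 1, function(r) {
      paste(sprintf("%.17g", r), collapse = "\t")
    }), con)
  }
  invisible(path)
}

#' @rdname write_fibers_tsv
#' @export
read_fibers_tsv <- function(path) {
  lines <- readLines(path)
  grp <- cumsum(!nzchar(lines))
  keep <- nzchar(lines)
  blocks <- split(lines[keep], grp[keep])
  lapply(unname(blocks), function(b) {
    matrix(as.numeric(unlist(strsplit(b, "\t", fixed = TRUE))), ncol = 3, byrow = TRUE)
  })
}

#' Write a landmark set as TSV
#'
#' Columns: `landmark`, `vertex`, `x`, `y`, `z` (tab-separated, header row).
#'
#' @param landmarks A `landmark_set`.
#' @param path File path.
#' @export
write_landmarks_tsv <- function(landmarks, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("landmark\tvertex\tx\ty\tz", con)
  writeLines(sprintf("%d\t%d\t%.17g\t%.17g\t%.17g", landmarks$landmark,
                     landmarks$vertex, landmarks$x, landmarks$y, landmarks$z), con)
  invisible(path)
}

#' Write / read a cohort directory
#'
#' Layout: `manifest.tsv` (subject_id, label, per-subject paths),
#' `mesh.off`, `landmarks.tsv` (ground-truth landmark vertices), a
#' `cohort.json` with the generating specification, and one directory per
#' subject holding `timeseries.tsv` (one landmark per row) and
#' `fibers.tsv`.
#'
#' @param cohort A `dm_cohort`.
#' @param dir Output directory (created if needed).
#' @return `read_cohort` returns a `dm_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dm_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_off(cohort$mesh, file.path(dir, "mesh.off"))
  lm <- data.frame(landmark = seq_along(cohort$landmark_vertices),
                   vertex = cohort$landmark_vertices,
                   x = cohort$landmark_coords[, 1],
                   y = cohort$landmark_coords[, 2],
                   z = cohort$landmark_coords[, 3])
  write_landmarks_tsv(lm, file.path(dir, "landmarks.tsv"))
  jsonlite::write_json(unclass(cohort$spec), file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  rows <- character(length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[i]]
    sdir <- file.path(dir, sub$id)
    dir.create(sdir, showWarnings = FALSE)
    write_matrix_tsv(sub$timeseries, file.path(sdir, "timeseries.tsv"))
    write_fibers_tsv(sub$fibers, file.path(sdir, "fibers.tsv"))
    rows[i] <- paste(sub$id, sub$label,
                     file.path(sub$id, "timeseries.tsv"),
                     file.path(sub$id, "fibers.tsv"), sep = "\t")
  }
  con <- file(file.path(dir, "manifest.tsv"), "wb")
  writeLines(c("subject_id\tlabel\ttimeseries\tfibers", rows), con)
  close(con)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(man_path)) {
    stop(sprintf("read_cohort: no manifest.tsv under '%s'", dir), call. = FALSE)
  }
  man <- utils::read.delim(man_path, stringsAsFactors = FALSE)
  spec <- do.call(cohort_spec, jsonlite::read_json(file.path(dir, "cohort.json"),
                                                   simplifyVector = TRUE))
  mesh <- read_off(file.path(dir, "mesh.off"))
  lm <- utils::read.delim(file.path(dir, "landmarks.tsv"))
  subjects <- lapply(seq_len(nrow(man)), function(i) {
    ts_path <- file.path(dir, man$timeseries[i])
    fb_path <- file.path(dir, man$fibers[i])
    if (!file.exists(ts_path) || !file.exists(fb_path)) {
      stop(sprintf("read_cohort: missing files for subject '%s'", man$subject_id[i]),
           call. = FALSE)
    }
    list(id = man$subject_id[i], label = man$label[i],
         timeseries = read_matrix_tsv(ts_path),
         fibers = read_fibers_tsv(fb_path))
  })
  out <- list(spec = spec, mesh = mesh,
              landmark_vertices = as.integer(lm$vertex),
              landmark_coords = as.matrix(lm[, c("x", "y", "z")]),
              subjects = subjects)
  class(out) <- "dm_cohort"
  out
}

#' Write / read a template set directory
#'
#' One TSV per template (`template_01.tsv`, ...): columns `landmark`,
#' `vertex`, then the trace-map bin values.
#'
#' @param templates A `template_set`.
#' @param dir Output directory.
#' @return `read_templates` returns a `template_set`.
#' @export
write_templates <- function(templates, dir) {
  stopifnot(inherits(templates, "template_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in seq_len(templates$n_templates)) {
    m <- cbind(seq_len(templates$n_landmarks), templates$init_vertices,
               templates$tracemaps[, t, ])
    write_matrix_tsv(m, file.path(dir, sprintf("template_%02d.tsv", t)))
  }
  invisible(dir)
}

#' @rdname write_templates
#' @export
read_templates <- function(dir) {
  files <- sort(list.files(dir, pattern = "^template_\\d+\\.tsv$", full.names = TRUE))
  if (!length(files)) stop(sprintf("read_templates: no template TSVs under '%s'", dir), call. = FALSE)
  mats <- lapply(files, read_matrix_tsv)
  n_lm <- nrow(mats[[1]])
  n_bins <- ncol(mats[[1]]) - 2L
  tm <- array(0, dim = c(n_lm, length(mats), n_bins))
  for (t in seq_along(mats)) tm[, t, ] <- mats[[t]][, -(1:2)]
  out <- list(tracemaps = tm, init_vertices = as.integer(mats[[1]][, 2]),
              n_landmarks = n_lm, n_templates = length(mats), n_bins = n_bins)
  class(out) <- "template_set"
  out
}
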