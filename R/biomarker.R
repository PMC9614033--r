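#' Min-max normalize a subject's attention scores
#'
#' Rescales to `[0, 1]` per subject, preserving rank order. A constant
#' vector maps to all zeros (guarded). `method = "zscore"` standardizes
#' instead (mean 0, sd 1).
#'
#' @param Z Numeric vector of raw attention scores.
#' @param method `"minmax"` (default) or `"zscore"`.
#' @return Normalized numeric vector.
#' @export
normalize_attention <- function(Z, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  if (any(!is.finite(Z))) {
    stop("normalize_attention: non-finite attention score", call. = FALSE)
  }
  if (method == "minmax") {
    rng <- range(Z)
    if (rng[1] == rng[2]) return(rep(0, length(Z)))
    (Z - rng[1]) / (rng[2] - rng[1])
  } else {
    s <- stats::sd(Z)
    if (s == 0) return(rep(0, length(Z)))
    (Z - mean(Z)) / s
  }
}

#' Select the top fraction of landmarks by score
#'
#' Retains the `floor(fraction * N)` highest-scoring landmarks in
#' descending score order; ties are broken by the lower landmark index
#' (deterministic across runs).
#'
#' @param scores Per-landmark numeric scores.
#' @param fraction Fraction in (0, 1] (default 0.3: with 358 landmarks the
#'   conventional top-30% set of 107).
#' @param source Provenance label (e.g. `"A"`, `"B"`, `"all"`, a subject id).
#' @return An object of class `biomarker_set`: list with `indices`
#'   (descending importance), `scores` (matching order), `fraction`,
#'   `source`.
#' @export
select_top_fraction <- function(scores, fraction = 0.3, source = "all") {
  if (!(is.numeric(fraction) && length(fraction) == 1L && fraction > 0 && fraction <= 1)) {
    stop_config("configuration error: 'fraction' must be in (0,1]")
  }
  n <- length(scores)
  m <- floor(fraction * n)
  if (m < 1L) stop_config("configuration error: floor(fraction * N) = 0 for N = %d", n)
  ord <- order(-scores, seq_len(n))[seq_len(m)]
  out <- list(indices = ord, scores = scores[ord], fraction = fraction,
              source = source)
  class(out) <- "biomarker_set"
  out
}

#' @export
print.biomarker_set <- function(x, ...) {
  cat(sprintf("biomarker_set (%s): %d landmarks (fraction %g), top: %s\n",
              x$source, length(x$indices), x$fraction,
              paste(head(x$indices, 8), collapse = ", ")))
  invisible(x)
}

#' Number of landmarks shared by two biomarker sets
#'
#' @param set_a,set_b `biomarker_set`s or plain index vectors.
#' @return Integer intersection size.
#' @export
overlap_count <- function(set_a, set_b) {
  a <- if (inherits(set_a, "biomarker_set")) set_a$indices else set_a
  b <- if (inherits(set_b, "biomarker_set")) set_b$indices else set_b
  length(intersect(a, b))
}

#' Group-level biomarker sets from normalized attention scores
#'
#' Computes the per-landmark mean normalized attention over group-A
#' subjects, group-B subjects and all subjects, selects the top fraction
#' for each, and reports pairwise overlaps plus the mean per-subject
#' overlap with the own-group set.
#'
#' @param Znorm Matrix of normalized attention scores, subjects x landmarks.
#' @param labels Group labels (`"A"`/`"B"`), one per subject.
#' @param fraction Retention fraction (default 0.3).
#' @return List with `importance` (per-landmark group means), `A`, `B`,
#'   `all` (`biomarker_set`s), `per_subject` (list of `biomarker_set`s) and
#'   `overlaps`.
#' @export
group_biomarkers <- function(Znorm, labels, fraction = 0.3) {
  stopifnot(nrow(Znorm) == length(labels))
  imp <- list(A = colMeans(Znorm[labels == "A", , drop = FALSE]),
              B = colMeans(Znorm[labels == "B", , drop = FALSE]),
              all = colMeans(Znorm))
  set_a <- select_top_fraction(imp$A, fraction, source = "A")
  set_b <- select_top_fraction(imp$B, fraction, source = "B")
  set_all <- select_top_fraction(imp$all, fraction, source = "all")
  per_subject <- lapply(seq_len(nrow(Znorm)), function(i) {
    select_top_fraction(Znorm[i, ], fraction,
                        source = rownames(Znorm)[i] %||% as.character(i))
  })
  own <- vapply(seq_along(per_subject), function(i) {
    overlap_count(per_subject[[i]], if (labels[i] == "A") set_a else set_b)
  }, numeric(1))
  list(importance = imp, A = set_a, B = set_b, all = set_all,
       per_subject = per_subject,
       overlaps = list(
         A_B = overlap_count(set_a, set_b),
         all_A = overlap_count(set_all, set_a),
         all_B = overlap_count(set_all, set_b),
         mean_subject_vs_group_A = mean(own[labels == "A"]),
         mean_subject_vs_group_B = mean(own[labels == "B"])))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hypergeometric enrichment of a planted node set among biomarkers
#'
#' One-sided test that the planted nodes are over-represented in the
#' selected biomarker set relative to drawing the same number of landmarks
#' uniformly at random.
#'
#' @param biomarkers A `biomarker_set` or index vector.
#' @param planted Planted (effect) node indices.
#' @param n_landmarks Total number of landmarks.
#' @return List with `overlap`, `expected` and `p_value`.
#' @export
planted_enrichment <- function(biomarkers, planted, n_landmarks) {
  sel <- if (inherits(biomarkers, "biomarker_set")) biomarkers$indices else biomarkers
  q <- length(intersect(sel, planted))
  m <- length(planted)
  k <- length(sel)
  p <- stats::phyper(q - 1, m, n_landmarks - m, k, lower.tail = FALSE)
  list(overlap = q, expected = k * m / n_landmarks, p_value = p)
}

# Normalize a region table to a data.frame(subject_id, landmark, region).
as_region_table <- function(region_table) {
  rt <- as.data.frame(region_table)
  need <- c("subject_id", "landmark", "region")
  if (!all(need %in% names(rt))) {
    stop(sprintf("region table must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  rt
}

# Per-subject named proportion vector over `regions` for one landmark set.
region_props <- function(sel, map, regions) {
  lab <- map[match(sel, map$landmark), "region"]
  lab[is.na(lab)] <- "unmapped"
  tab <- table(factor(lab, levels = regions))
  as.numeric(tab) / length(sel)
}

#' Distribution of biomarker landmarks over anatomical regions
#'
#' Two schemes. `registration_priority`: each subject's own biomarker set
#' is mapped through that subject's landmark-to-region labels and the
#' per-region proportions are averaged over subjects. `average_priority`:
#' one biomarker set (from group-mean scores) is mapped per subject, then
#' averaged. Landmarks without a label count under `"unmapped"`.
#'
#' @param biomarkers For `registration_priority`: a list of per-subject
#'   `biomarker_set`s (or index vectors), one per subject in the region
#'   table. For `average_priority`: a single set shared by all subjects.
#' @param region_table data.frame with columns `subject_id`, `landmark`,
#'   `region`.
#' @param scheme `"registration_priority"` or `"average_priority"`.
#' @return Named numeric vector of proportions (summing to 1, including
#'   any `"unmapped"` share).
#' @export
region_distribution <- function(biomarkers, region_table,
                                scheme = c("registration_priority", "average_priority")) {
  scheme <- match.arg(scheme)
  rt <- as_region_table(region_table)
  subjects <- unique(rt$subject_id)
  regions <- c(sort(unique(rt$region)), "unmapped")
  sets <- if (scheme == "registration_priority") {
    if (!is.list(biomarkers) || length(biomarkers) != length(subjects)) {
      stop("region_distribution: registration_priority needs one biomarker set per subject",
           call. = FALSE)
    }
    lapply(biomarkers, function(b) if (inherits(b, "biomarker_set")) b$indices else b)
  } else {
    sel <- if (inherits(biomarkers, "biomarker_set")) biomarkers$indices else biomarkers
    rep(list(sel), length(subjects))
  }
  props <- vapply(seq_along(subjects), function(i) {
    region_props(sets[[i]], rt[rt$subject_id == subjects[i], ], regions)
  }, numeric(length(regions)))
  out <- rowMeans(props)
  names(out) <- regions
  if (out["unmapped"] == 0) out <- out[names(out) != "unmapped"]
  out
}

#' Region-by-region fiber connectivity of biomarker landmarks
#'
#' For each pair of regions, sums the structural fiber counts `S[i, j]`
#' over biomarker landmarks i in the first region and j in the second,
#' per subject, then averages over subjects. Symmetric by construction.
#'
#' @param biomarkers A single `biomarker_set`/index vector shared by all
#'   subjects, or a list of per-subject sets.
#' @param region_table data.frame with columns `subject_id`, `landmark`,
#'   `region`.
#' @param S_list Named list of per-subject structural count matrices (names
#'   = subject ids), or an unnamed list in region-table subject order.
#' @return Symmetric region x region numeric matrix.
#' @export
region_fiber_connectivity <- function(biomarkers, region_table, S_list) {
  rt <- as_region_table(region_table)
  subjects <- unique(rt$subject_id)
  regions <- sort(unique(rt$region))
  per_subject <- is.list(biomarkers) && !inherits(biomarkers, "biomarker_set")
  acc <- matrix(0, length(regions), length(regions),
                dimnames = list(regions, regions))
  for (i in seq_along(subjects)) {
    sel <- if (per_subject) biomarkers[[i]] else biomarkers
    if (inherits(sel, "biomarker_set")) sel <- sel$indices
    S <- if (!is.null(names(S_list))) S_list[[as.character(subjects[i])]] else S_list[[i]]
    map <- rt[rt$subject_id == subjects[i], ]
    lab <- map[match(sel, map$landmark), "region"]
    keep <- !is.na(lab)
    sel <- sel[keep]; lab <- lab[keep]
    if (!length(sel)) next
    ind <- matrix(0, length(sel), length(regions))
    ind[cbind(seq_along(sel), match(lab, regions))] <- 1
    acc <- acc + t(ind) %*% S[sel, sel, drop = FALSE] %*% ind
  }
  acc / length(subjects)
}

#' Share of biomarker landmarks in each functional partition over time
#'
#' For each developmental time point, computes the mean (over subjects) of
#' the fraction of each subject's biomarker landmarks falling in each
#' functional partition. Partitions absent at a time point are reported as
#' `NA` (not applicable), never 0.
#'
#' @param biomarkers A list of per-subject `biomarker_set`s/index vectors,
#'   or a single set shared by all subjects.
#' @param partition_tables Named list (one element per time point, e.g.
#'   `"3mo"`) of data.frames with columns `subject_id`, `landmark`,
#'   `partition`.
#' @return Matrix: time points x the union of partition labels, rows
#'   summing to 1 over applicable partitions.
#' @export
functional_participation <- function(biomarkers, partition_tables) {
  all_parts <- sort(unique(unlist(lapply(partition_tables, function(tb) {
    unique(as.data.frame(tb)$partition)
  }))))
  out <- matrix(NA_real_, length(partition_tables), length(all_parts),
                dimnames = list(names(partition_tables), all_parts))
  for (ti in seq_along(partition_tables)) {
    tb <- as.data.frame(partition_tables[[ti]])
    names(tb)[names(tb) == "partition"] <- "region"
    rt <- as_region_table(tb)
    subjects <- unique(rt$subject_id)
    present <- sort(unique(rt$region))
    sets <- if (is.list(biomarkers) && !inherits(biomarkers, "biomarker_set")) {
      lapply(biomarkers, function(b) if (inherits(b, "biomarker_set")) b$indices else b)
    } else {
      sel <- if (inherits(biomarkers, "biomarker_set")) biomarkers$indices else biomarkers
      rep(list(sel), length(subjects))
    }
    props <- vapply(seq_along(subjects), function(i) {
      region_props(sets[[i]], rt[rt$subject_id == subjects[i], ],
                   c(present, "unmapped"))
    }, numeric(length(present) + 1L))
    mp <- rowMeans(props)
    out[ti, present] <- mp[seq_along(present)]
    if (mp[length(mp)] > 0) {
      warning(sprintf("functional_participation: %.1f%% of biomarkers unmapped at %s",
                      100 * mp[length(mp)], names(partition_tables)[ti]))
    }
  }
  out
}

#' Synthetic landmark-to-region mapping table
#'
#' Assigns landmarks to `n_regions` contiguous synthetic anatomical
#' regions by k-means clustering of the landmark coordinates (seeded,
#' deterministic); the same mapping is replicated for every subject, as a
#' stand-in for a per-subject atlas registration.
#'
#' @param cohort A `dm_cohort`.
#' @param n_regions Number of regions (default 36).
#' @param seed Clustering seed.
#' @param label_prefix Region label prefix (default `"region"`).
#' @return data.frame with columns `subject_id`, `landmark`, `region`.
#' @export
generate_region_table <- function(cohort, n_regions = 36L, seed = 1L,
                                  label_prefix = "region") {
  stopifnot(inherits(cohort, "dm_cohort"))
  n_regions <- check_count(n_regions, "n_regions")
  km <- with_seed(seed, kmeans(cohort$landmark_coords,
                               centers = min(n_regions, cohort$spec$n_landmarks),
                               nstart = 5))
  lab <- sprintf("%s_%02d", label_prefix, km$cluster)
  ids <- vapply(cohort$subjects, `[[`, character(1), "id")
  do.call(rbind, lapply(ids, function(id) {
    data.frame(subject_id = id, landmark = seq_len(cohort$spec$n_landmarks),
               region = lab)
  }))
}

#' Synthetic functional partition tables per developmental time point
#'
#' Mirrors an infant functional parcellation that gains partitions with
#' age: by default 7 partitions at 3 months, 9 at 6 months and 10 at 9 and
#' 12 months, produced by seeded k-means on landmark coordinates.
#'
#' @param cohort A `dm_cohort`.
#' @param n_partitions Named integer vector: partitions per time point.
#' @param seed Clustering seed.
#' @return Named list of data.frames (`subject_id`, `landmark`,
#'   `partition`).
#' @export
generate_partition_tables <- function(cohort,
                                      n_partitions = c("3mo" = 7L, "6mo" = 9L,
                                                       "9mo" = 10L, "12mo" = 10L),
                                      seed = 1L) {
  stopifnot(inherits(cohort, "dm_cohort"))
  ids <- vapply(cohort$subjects, `[[`, character(1), "id")
  out <- lapply(seq_along(n_partitions), function(ti) {
    km <- with_seed(seed + ti, kmeans(cohort$landmark_coords,
                                      centers = min(n_partitions[ti],
                                                    cohort$spec$n_landmarks),
                                      nstart = 5))
    lab <- sprintf("partition_%02d", km$cluster)
    do.call(rbind, lapply(ids, function(id) {
      data.frame(subject_id = id, landmark = seq_len(cohort$spec$n_landmarks),
                 partition = lab)
    }))
  })
  names(out) <- names(n_partitions)
  out
}
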