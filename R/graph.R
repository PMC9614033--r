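#' Functional similarity matrix from node time series
#'
#' Pearson correlation between every pair of node time series.
#'
#' @param ts Numeric matrix, one node per row, time points in columns.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
functional_similarity <- function(ts) {
  ts <- as.matrix(ts)
  if (any(!is.finite(ts))) stop("functional_similarity: non-finite value in time series", call. = FALSE)
  v <- apply(ts, 1, stats::var)
  if (any(v == 0)) {
    stop(sprintf("functional_similarity: degenerate (zero-variance) signal at landmark %s",
                 paste(which(v == 0), collapse = ",")), call. = FALSE)
  }
  f <- cor(t(ts))
  diag(f) <- 1
  f
}

#' Group-difference mask from entry-wise two-sample t-tests
#'
#' For every matrix entry, the values across group-A training subjects and
#' group-B training subjects are compared by a two-sample t-test; the entry
#' is retained (mask 1) iff p < `f_s`. The mask is the feature
#' sparsification: it is computed on training subjects only and then applied
#' to every subject of the fold. Entries constant across all training
#' subjects (e.g. the unit diagonal) have an undefined t statistic and are
#' masked to 0.
#'
#' @param F_list List of similarity matrices (training subjects).
#' @param labels Character vector of group labels `"A"`/`"B"`, one per matrix.
#' @param f_s Significance threshold in (0, 1) (default 0.05).
#' @param var_equal If `TRUE` use the pooled-variance (Student) test;
#'   default `FALSE` (Welch).
#' @return An object of class `group_mask`: list with binary matrix `mask`,
#'   matrix `p` of p-values, `f_s`, `var_equal` and group sizes.
#' @export
group_ttest_mask <- function(F_list, labels, f_s = 0.05, var_equal = FALSE) {
  if (length(F_list) != length(labels)) {
    stop("group_ttest_mask: one label per matrix required", call. = FALSE)
  }
  if (!(f_s > 0 && f_s < 1)) stop_config("configuration error: 'f_s' must be in (0,1)")
  ia <- which(labels == "A"); ib <- which(labels == "B")
  na <- length(ia); nb <- length(ib)
  if (na < 2L || nb < 2L) {
    stop(sprintf("group_ttest_mask: insufficient sample (group A: %d, group B: %d; need >= 2 each)",
                 na, nb), call. = FALSE)
  }
  sum_ <- function(idx) Reduce(`+`, F_list[idx])
  sumsq <- function(idx) Reduce(`+`, lapply(F_list[idx], function(m) m * m))
  ma <- sum_(ia) / na
  mb <- sum_(ib) / nb
  va <- pmax(0, (sumsq(ia) - na * ma^2) / (na - 1))
  vb <- pmax(0, (sumsq(ib) - nb * mb^2) / (nb - 1))
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- matrix(na + nb - 2, nrow(ma), ncol(ma))
  } else {
    se2 <- va / na + vb / nb
    df <- se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  }
  tstat <- (ma - mb) / sqrt(se2)
  p <- 2 * pt(-abs(tstat), df)
  # Degenerate entries: zero variance in both groups. Equal means => the
  # entry is constant across subjects: not significant. Unequal means =>
  # perfect separation: maximally significant.
  degen <- se2 == 0
  p[degen & (ma == mb)] <- 1
  p[degen & (ma != mb)] <- 0
  mask <- (p < f_s) + 0
  diag(mask) <- 0
  out <- list(mask = mask, p = p, f_s = f_s, var_equal = var_equal,
              n_a = na, n_b = nb)
  class(out) <- "group_mask"
  out
}

#' @export
print.group_mask <- function(x, ...) {
  off <- row(x$mask) != col(x$mask)
  cat(sprintf("group_mask: %dx%d, f_s = %g (%s), retained %.1f%% of off-diagonal entries\n",
              nrow(x$mask), ncol(x$mask), x$f_s,
              if (x$var_equal) "Student" else "Welch",
              100 * mean(x$mask[off])))
  invisible(x)
}

#' Apply a group mask to a similarity matrix
#'
#' Element-wise product; entries not retained by the mask become 0.
#'
#' @param F Similarity matrix.
#' @param mask A `group_mask` or a binary matrix of matching shape.
#' @return Masked matrix (the node feature matrix, one row per node).
#' @export
apply_mask <- function(F, mask) {
  m <- if (inherits(mask, "group_mask")) mask$mask else mask
  if (!all(dim(F) == dim(m))) {
    stop(sprintf("apply_mask: dimension mismatch (%s vs %s)",
                 paste(dim(F), collapse = "x"), paste(dim(m), collapse = "x")),
         call. = FALSE)
  }
  F * m
}

#' Fiber-count structural connectivity matrix
#'
#' `S[i, j]` counts fibers having at least one point within `radius` of
#' landmark i and at least one point within `radius` of landmark j;
#' `S[i, i]` counts fibers incident to landmark i.
#'
#' @param fibers List of fiber point matrices.
#' @param landmarks A `landmark_set` or a numeric matrix of landmark
#'   coordinates (one row per landmark).
#' @param radius Capture radius in mm (default 2).
#' @return Symmetric integer matrix.
#' @export
structural_counts <- function(fibers, landmarks, radius = 2) {
  radius <- check_positive(radius, "radius")
  coords <- if (inherits(landmarks, "landmark_set")) {
    as.matrix(landmarks[, c("x", "y", "z")])
  } else {
    as.matrix(landmarks)
  }
  inc <- fiber_incidence(fibers, coords, radius)
  s <- crossprod(inc + 0)
  storage.mode(s) <- "integer"
  dimnames(s) <- NULL
  s
}

#' Binary edge matrix from structural counts
#'
#' Off-diagonal edges are 1 where the fiber count exceeds `t_s`; the
#' diagonal is forced to 1 (every node has a self-loop).
#'
#' @param S Symmetric count matrix.
#' @param t_s Count threshold (>= 0, default 0: any shared fiber makes an
#'   edge).
#' @return Binary symmetric matrix with unit diagonal.
#' @export
edge_matrix <- function(S, t_s = 0) {
  t_s <- check_positive(t_s, "t_s", strict = FALSE)
  e <- (S > t_s) + 0
  diag(e) <- 1
  e
}

# Per-subject multimodal summaries reused across folds: functional
# similarity F, structural counts S, edge matrix E and (for the structural
# ablation) per-landmark trace-map features.
precompute_subject_data <- function(cohort, radius = 2, t_s = 0,
                                    landmarks = NULL, tracemap_features = FALSE,
                                    partition = partition_sphere(122L),
                                    per_subject_landmarks = NULL) {
  shared_coords <- if (is.null(landmarks)) cohort$landmark_coords else
    as.matrix(if (inherits(landmarks, "landmark_set")) landmarks[, c("x", "y", "z")] else landmarks)
  lapply(seq_along(cohort$subjects), function(si) {
    sub <- cohort$subjects[[si]]
    coords <- if (is.null(per_subject_landmarks)) shared_coords else {
      ls <- per_subject_landmarks[[si]]
      as.matrix(if (inherits(ls, "landmark_set") || is.data.frame(ls)) ls[, c("x", "y", "z")] else ls)
    }
    F <- functional_similarity(sub$timeseries)
    S <- structural_counts(sub$fibers, coords, radius)
    E <- edge_matrix(S, t_s)
    tmf <- NULL
    if (tracemap_features) {
      inc <- fiber_incidence(sub$fibers, coords, radius)
      bins3 <- fiber_region_bins(sub$fibers, partition)
      tmf <- matrix(0, nrow(coords), partition$n_regions)
      for (i in seq_len(nrow(coords))) {
        fx <- which(inc[, i])
        if (length(fx)) tmf[i, ] <- tabulate(bins3[fx, ], nbins = partition$n_regions)
      }
    }
    list(id = sub$id, label = sub$label, F = F, S = S, E = E, tracemap = tmf)
  })
}

#' Build per-fold subject graphs
#'
#' For each cross-validation fold, the t-test mask is computed from that
#' fold's training subjects only and applied to the features of all
#' subjects (train and test) of the fold.
#'
#' @param cohort A `dm_cohort`.
#' @param fold_assignment Integer vector of fold ids, one per subject (see
#'   [stratified_kfold()]).
#' @param f_s t-test significance threshold (default 0.05).
#' @param t_s Structural count threshold (default 0).
#' @param radius Fiber capture radius in mm (default 2).
#' @param landmarks Optional landmark coordinates (default: the cohort's
#'   true landmarks).
#' @param features `"functional"` (masked similarity rows) or
#'   `"tracemap"` (structural ablation: per-landmark trace-map vectors,
#'   no mask).
#' @param var_equal Student instead of Welch t-test (default `FALSE`).
#' @param per_subject_landmarks Optional list of per-subject landmark sets
#'   (e.g. predicted landmarks), overriding `landmarks`.
#' @return List with one element per fold: `mask` (a `group_mask` or `NULL`
#'   for the ablation), `train`/`test` subject indices, and `graphs`, a list
#'   of `subject_graph` objects (fields `id`, `label`, `features`, `E`, `S`).
#' @export
build_subject_graphs <- function(cohort, fold_assignment, f_s = 0.05, t_s = 0,
                                 radius = 2, landmarks = NULL,
                                 features = c("functional", "tracemap"),
                                 var_equal = FALSE, per_subject_landmarks = NULL) {
  features <- match.arg(features)
  stopifnot(inherits(cohort, "dm_cohort"))
  if (length(fold_assignment) != length(cohort$subjects)) {
    stop("build_subject_graphs: one fold id per subject required", call. = FALSE)
  }
  dat <- precompute_subject_data(cohort, radius = radius, t_s = t_s,
                                 landmarks = landmarks,
                                 tracemap_features = features == "tracemap",
                                 per_subject_landmarks = per_subject_landmarks)
  labels <- vapply(dat, `[[`, character(1), "label")
  folds <- sort(unique(fold_assignment))
  lapply(folds, function(k) {
    train <- which(fold_assignment != k)
    test <- which(fold_assignment == k)
    mask <- NULL
    graphs <- if (features == "functional") {
      mask <- group_ttest_mask(lapply(dat[train], `[[`, "F"), labels[train],
                               f_s = f_s, var_equal = var_equal)
      lapply(dat, function(d) {
        g <- list(id = d$id, label = d$label,
                  features = apply_mask(d$F, mask), E = d$E, S = d$S)
        class(g) <- "subject_graph"
        g
      })
    } else {
      lapply(dat, function(d) {
        g <- list(id = d$id, label = d$label, features = d$tracemap,
                  E = d$E, S = d$S)
        class(g) <- "subject_graph"
        g
      })
    }
    list(fold = k, train = train, test = test, mask = mask, graphs = graphs)
  })
}
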