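#' Training configuration
#'
#' Defaults follow the study protocol: Adam with learning rate 3e-4 and
#' weight decay 2e-3, 800 epochs of full-batch training, 5 stratified
#' folds, pooling ratio 0.2, hidden width 64, t-test threshold 0.05,
#' structural count threshold 0, 2 mm capture radius, top fraction 0.3.
#'
#' @param learning_rate Adam learning rate (default 3e-4).
#' @param weight_decay L2 weight decay added to gradients (default 2e-3).
#' @param epochs Training epochs, no early stopping (default 800).
#' @param folds Cross-validation folds (default 5).
#' @param k Pooling ratio (default 0.2).
#' @param hidden,fc_hidden Hidden widths (default 64).
#' @param f_s t-test significance threshold (default 0.05).
#' @param t_s Structural count threshold (default 0).
#' @param radius Fiber capture radius, mm (default 2).
#' @param top_fraction Biomarker retention fraction (default 0.3).
#' @param fold_seed,init_seed RNG seeds for fold shuffling and weight
#'   initialization.
#' @param gate Gate pooled features by attention scores (default `TRUE`).
#' @param strict_gcn Single-self-loop adjacency normalization (default
#'   `FALSE`, the literal double-self-loop form).
#' @param var_equal Student instead of Welch t-test (default `FALSE`).
#' @param features `"functional"` or `"tracemap"` (structural ablation).
#' @param attention_from Use each subject's `"test"`-fold model (default)
#'   or first `"train"`-fold model for its attention scores.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 3e-4, weight_decay = 2e-3,
                         epochs = 800L, folds = 5L, k = 0.2,
                         hidden = 64L, fc_hidden = 64L,
                         f_s = 0.05, t_s = 0, radius = 2,
                         top_fraction = 0.3,
                         fold_seed = 1L, init_seed = 2L,
                         gate = TRUE, strict_gcn = FALSE, var_equal = FALSE,
                         features = c("functional", "tracemap"),
                         attention_from = c("test", "train")) {
  cfg <- list(
    learning_rate = check_positive(learning_rate, "learning_rate"),
    weight_decay = check_positive(weight_decay, "weight_decay", strict = FALSE),
    epochs = check_count(epochs, "epochs"),
    folds = check_count(folds, "folds", min = 2L),
    k = k, hidden = check_count(hidden, "hidden"),
    fc_hidden = check_count(fc_hidden, "fc_hidden"),
    f_s = f_s, t_s = t_s, radius = check_positive(radius, "radius"),
    top_fraction = top_fraction,
    fold_seed = check_count(fold_seed, "fold_seed", min = 0L),
    init_seed = check_count(init_seed, "init_seed", min = 0L),
    gate = isTRUE(gate), strict_gcn = isTRUE(strict_gcn),
    var_equal = isTRUE(var_equal),
    features = match.arg(features),
    attention_from = match.arg(attention_from))
  if (!(cfg$k > 0 && cfg$k <= 1)) stop_config("configuration error: 'k' must be in (0,1]")
  if (!(cfg$top_fraction > 0 && cfg$top_fraction <= 1)) {
    stop_config("configuration error: 'top_fraction' must be in (0,1]")
  }
  class(cfg) <- "train_config"
  cfg
}

#' Stratified k-fold assignment
#'
#' Subjects are shuffled within each class under `seed` and dealt to folds
#' in one continuous round-robin across classes, so fold sizes differ by at
#' most one overall and per class; every subject appears in exactly one
#' test fold.
#'
#' @param ids Subject identifiers.
#' @param labels Class labels (`"A"`/`"B"`), one per subject.
#' @param folds Number of folds.
#' @param seed Shuffle seed.
#' @return Integer vector of fold ids (1..folds), named by `ids`.
#' @export
stratified_kfold <- function(ids, labels, folds = 5L, seed = 1L) {
  folds <- check_count(folds, "folds", min = 2L)
  if (length(ids) != length(labels)) stop("stratified_kfold: ids and labels differ in length", call. = FALSE)
  classes <- unique(labels)
  if (length(classes) < 2L) stop("stratified_kfold: both classes must be present", call. = FALSE)
  sizes <- table(labels)
  if (any(sizes < folds)) {
    stop(sprintf("stratified_kfold: class '%s' has %d subjects, fewer than %d folds",
                 names(sizes)[which.min(sizes)], min(sizes), folds), call. = FALSE)
  }
  assignment <- integer(length(ids))
  with_seed(seed, {
    pos <- 0L
    for (cl in sort(classes)) {
      members <- which(labels == cl)
      members <- members[sample.int(length(members))]
      assignment[members] <- ((pos + seq_along(members) - 1L) %% folds) + 1L
      pos <- pos + length(members)
    }
  })
  names(assignment) <- ids
  assignment
}

#' Train one fold of the DM-GNN
#'
#' Full-batch Adam for exactly `config$epochs` epochs; the final-epoch
#' model is the fold model (no early stopping). Attention scores are
#' recorded for every subject from the fold model.
#'
#' @param train_graphs,test_graphs Lists of `subject_graph`s built with
#'   this fold's mask.
#' @param config A `train_config`.
#' @param init_seed Weight initialization seed (default from `config`).
#' @return List with `params` (trained weights), `loss` (per-epoch
#'   training loss), `test_scores` (data.frame: id, label, score of the
#'   positive class A, predicted label) and `Z` (matrix of attention
#'   scores, one row per train+test subject, rownames = subject ids).
#' @export
train_fold <- function(train_graphs, test_graphs, config,
                       init_seed = config$init_seed) {
  stopifnot(inherits(config, "train_config"))
  batch <- nn_batch(train_graphs, strict_gcn = config$strict_gcn)
  params <- init_model_params(ncol(train_graphs[[1]]$features),
                              hidden = config$hidden,
                              fc_hidden = config$fc_hidden,
                              k = config$k, seed = init_seed)
  state <- adam_init(params)
  loss <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    fw <- nn_forward(batch, params, gate = config$gate)
    if (!is.finite(fw$loss)) {
      stop(sprintf("train_fold: training failure (non-finite loss at epoch %d)", ep),
           call. = FALSE)
    }
    loss[ep] <- fw$loss
    gr <- nn_backward(batch, params, fw, gate = config$gate)
    upd <- adam_step(params, gr, state, lr = config$learning_rate,
                     weight_decay = config$weight_decay)
    params <- upd$params
    state <- upd$state
  }
  all_graphs <- c(train_graphs, test_graphs)
  outs <- lapply(all_graphs, dmgnn_forward, params = params,
                 gate = config$gate, strict_gcn = config$strict_gcn)
  Z <- do.call(rbind, lapply(outs, `[[`, "Z"))
  rownames(Z) <- vapply(all_graphs, `[[`, character(1), "id")
  nte <- length(test_graphs)
  te <- outs[length(train_graphs) + seq_len(nte)]
  test_scores <- data.frame(
    id = vapply(test_graphs, `[[`, character(1), "id"),
    label = vapply(test_graphs, `[[`, character(1), "label"),
    score_a = vapply(te, function(o) o$probs[1], numeric(1)),
    pred = ifelse(vapply(te, `[[`, integer(1), "pred") == 1L, "A", "B"))
  list(params = params, loss = loss, test_scores = test_scores, Z = Z)
}

#' Classification metrics from confusion counts
#'
#' `ACC = (TP+TN)/(TP+FN+TN+FP)`, `SEN = TP/(TP+FN)`, `SPE = TN/(TN+FP)`;
#' group A is the positive class. A zero denominator yields `NA` for that
#' metric (reported as not available, never as 0).
#'
#' @param tp,fp,tn,fn Confusion counts, or pass a single list/vector with
#'   those names as `tp`.
#' @return List with `ACC`, `SEN`, `SPE`.
#' @export
confusion_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.list(tp) || (length(tp) == 4L && !is.null(names(tp)))) {
    cc <- as.list(tp)
    tp <- cc$tp; fp <- cc$fp; tn <- cc$tn; fn <- cc$fn
  }
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  total <- tp + fn + tn + fp
  list(ACC = if (total > 0) (tp + tn) / total else NA_real_,
       SEN = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       SPE = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

# Confusion counts with group A as the positive class.
confusion_counts <- function(pred, truth) {
  list(tp = sum(pred == "A" & truth == "A"),
       fp = sum(pred == "A" & truth == "B"),
       tn = sum(pred == "B" & truth == "B"),
       fn = sum(pred == "B" & truth == "A"))
}

#' Pooled ROC-AUC over cross-validation test scores
#'
#' Test-fold scores are concatenated across folds and a single ROC-AUC is
#' computed via the rank-statistic (Mann-Whitney) formulation, which
#' handles ties by midranks.
#'
#' @param scores Numeric scores (higher = more positive-class).
#' @param labels Class labels; `positive` marks the positive class.
#' @param positive Positive class label (default `"A"`).
#' @return AUC in `[0, 1]`.
#' @export
pooled_roc_auc <- function(scores, labels, positive = "A") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("pooled_roc_auc: undefined AUC (pooled set contains a single class)", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Run the full cross-validated experiment
#'
#' Builds per-fold masks and graphs, trains one model per fold, evaluates
#' accuracy/sensitivity/specificity per fold and pooled ROC-AUC, and
#' collects per-subject attention scores and biomarker sets.
#'
#' @param cohort A `dm_cohort`.
#' @param config A `train_config`.
#' @param landmarks Optional landmark coordinates (default: cohort truth).
#' @param subset Optional logical or integer subject filter (e.g. for
#'   balanced subgroup experiments); stratification is recomputed on the
#'   subset.
#' @param per_subject_landmarks Optional list of per-subject landmark sets
#'   (e.g. predicted), used for the structural connectivity of each
#'   subject.
#' @return An object of class `dmgnn_result`: list with `fold_metrics`
#'   (data.frame), `mean`/`sd` summaries, `auc`, `scores` (pooled
#'   per-subject test scores), `Z` (subjects x landmarks attention
#'   matrix), `Znorm`, `biomarkers` (see [group_biomarkers()]),
#'   `fold_assignment`, `mask_retention` (per fold), `loss` (per fold) and
#'   `config`.
#' @export
run_experiment <- function(cohort, config = train_config(), landmarks = NULL,
                           subset = NULL, per_subject_landmarks = NULL) {
  stopifnot(inherits(cohort, "dm_cohort"), inherits(config, "train_config"))
  if (!is.null(subset)) {
    cohort$subjects <- cohort$subjects[subset]
    if (!is.null(per_subject_landmarks)) {
      per_subject_landmarks <- per_subject_landmarks[subset]
    }
  }
  ids <- vapply(cohort$subjects, `[[`, character(1), "id")
  labels <- vapply(cohort$subjects, `[[`, character(1), "label")
  fold_assignment <- stratified_kfold(ids, labels, config$folds, config$fold_seed)
  fold_data <- build_subject_graphs(cohort, fold_assignment,
                                    f_s = config$f_s, t_s = config$t_s,
                                    radius = config$radius, landmarks = landmarks,
                                    features = config$features,
                                    var_equal = config$var_equal,
                                    per_subject_landmarks = per_subject_landmarks)
  n_lm <- cohort$spec$n_landmarks
  Z <- matrix(NA_real_, length(ids), n_lm, dimnames = list(ids, NULL))
  z_filled <- logical(length(ids))
  scores <- vector("list", length(fold_data))
  fold_metrics <- vector("list", length(fold_data))
  losses <- vector("list", length(fold_data))
  z_folds <- vector("list", length(fold_data))
  retention <- numeric(length(fold_data))
  for (fi in seq_along(fold_data)) {
    fd <- fold_data[[fi]]
    res <- train_fold(fd$graphs[fd$train], fd$graphs[fd$test], config,
                      init_seed = config$init_seed + fd$fold)
    losses[[fi]] <- res$loss
    z_folds[[fi]] <- res$Z
    retention[fi] <- if (is.null(fd$mask)) NA_real_ else {
      off <- row(fd$mask$mask) != col(fd$mask$mask)
      mean(fd$mask$mask[off])
    }
    cc <- confusion_counts(res$test_scores$pred, res$test_scores$label)
    m <- confusion_metrics(cc)
    fold_metrics[[fi]] <- data.frame(fold = fd$fold, ACC = m$ACC, SEN = m$SEN,
                                     SPE = m$SPE)
    scores[[fi]] <- res$test_scores
    take <- if (config$attention_from == "test") ids[fd$test] else
      setdiff(ids[fd$train], ids[z_filled])
    take <- intersect(take, rownames(res$Z))
    Z[take, ] <- res$Z[take, , drop = FALSE]
    z_filled[match(take, ids)] <- TRUE
  }
  fold_metrics <- do.call(rbind, fold_metrics)
  scores <- do.call(rbind, scores)
  auc <- pooled_roc_auc(scores$score_a, scores$label)
  Znorm <- t(apply(Z, 1, normalize_attention))
  bm <- group_biomarkers(Znorm, labels, fraction = config$top_fraction)
  out <- list(
    fold_metrics = fold_metrics,
    mean = colMeans(fold_metrics[, c("ACC", "SEN", "SPE")]),
    sd = apply(fold_metrics[, c("ACC", "SEN", "SPE")], 2, stats::sd),
    auc = auc, scores = scores, Z = Z, Znorm = Znorm, Z_folds = z_folds,
    biomarkers = bm, fold_assignment = fold_assignment,
    mask_retention = retention, loss = losses, config = config)
  class(out) <- "dmgnn_result"
  out
}

#' @export
print.dmgnn_result <- function(x, ...) {
  cat("DM-GNN cross-validated experiment\n")
  cat(sprintf("  folds: %d, epochs: %d, features: %s\n",
              x$config$folds, x$config$epochs, x$config$features))
  cat(sprintf("  ACC %.3f +/- %.3f | SEN %.3f +/- %.3f | SPE %.3f +/- %.3f | pooled AUC %.3f\n",
              x$mean["ACC"], x$sd["ACC"], x$mean["SEN"], x$sd["SEN"],
              x$mean["SPE"], x$sd["SPE"], x$auc))
  cat(sprintf("  biomarkers: top %d%% = %d landmarks per set\n",
              round(100 * x$config$top_fraction), length(x$biomarkers$all$indices)))
  invisible(x)
}
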