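test_that("stratified folds are balanced, disjoint, exhaustive, reproducible", {
  ids <- sprintf("s%02d", 1:86)
  labels <- rep(c("A", "B"), each = 43)
  fa <- stratified_kfold(ids, labels, folds = 5, seed = 3)
  sizes <- sort(as.integer(table(fa)), decreasing = TRUE)
  expect_equal(sizes, c(18L, 17L, 17L, 17L, 17L))   # 4:1 train:test ratio
  # union of test folds = all subjects, pairwise disjoint
  expect_equal(sort(unlist(lapply(1:5, function(k) names(fa)[fa == k]))),
               sort(ids))
  # per-class fold sizes differ by at most one
  for (cl in c("A", "B")) {
    cs <- table(fa[labels == cl])
    expect_lte(max(cs) - min(cs), 1)
  }
  expect_identical(fa, stratified_kfold(ids, labels, folds = 5, seed = 3))
  expect_false(identical(fa, stratified_kfold(ids, labels, folds = 5, seed = 4)))
  expect_error(stratified_kfold(ids[1:6], c(rep("A", 5), "B"), folds = 5),
               "fewer than")
  expect_error(stratified_kfold(ids[1:6], rep("A", 6), folds = 2), "both classes")
})

test_that("confusion metrics evaluate the closed-form definitions", {
  m <- confusion_metrics(tp = 3, fp = 2, tn = 2, fn = 1)
  expect_equal(m$SEN, 0.75)
  expect_equal(m$SPE, 0.5)
  expect_equal(m$ACC, 0.625)
  perfect <- confusion_metrics(tp = 5, fp = 0, tn = 7, fn = 0)
  expect_equal(unlist(perfect), c(ACC = 1, SEN = 1, SPE = 1))
  # zero denominators: NA, not 0
  expect_true(is.na(confusion_metrics(tp = 0, fp = 2, tn = 3, fn = 0)$SEN))
  # 100 random tables vs exact rational arithmetic
  set.seed(17)
  for (r in 1:100) {
    cc <- as.list(stats::setNames(sample(0:30, 4, replace = TRUE),
                                  c("tp", "fp", "tn", "fn")))
    m <- confusion_metrics(cc)
    tot <- cc$tp + cc$fp + cc$tn + cc$fn
    if (tot > 0) expect_identical(m$ACC, (cc$tp + cc$tn) / tot)
    if (cc$tp + cc$fn > 0) expect_identical(m$SEN, cc$tp / (cc$tp + cc$fn))
    if (cc$tn + cc$fp > 0) expect_identical(m$SPE, cc$tn / (cc$tn + cc$fp))
    # ACC identity: ACC * total = SEN * (TP+FN) + SPE * (TN+FP)
    if (cc$tp + cc$fn > 0 && cc$tn + cc$fp > 0 && tot > 0) {
      expect_equal(m$ACC * tot,
                   m$SEN * (cc$tp + cc$fn) + m$SPE * (cc$tn + cc$fp))
    }
  }
})

test_that("pooled ROC-AUC equals the pairwise comparison statistic", {
  # perfect separation
  expect_equal(pooled_roc_auc(c(0.9, 0.8, 0.2, 0.1), c("A", "A", "B", "B")), 1)
  expect_equal(pooled_roc_auc(c(0.1, 0.2, 0.8, 0.9), c("A", "A", "B", "B")), 0)
  # O(n^2) oracle with ties counted half
  set.seed(18)
  for (r in 1:50) {
    n <- sample(8:40, 1)
    labels <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), 1)                  # rounding forces ties
    got <- pooled_roc_auc(scores, labels)
    pos <- scores[labels == "A"]; neg <- scores[labels == "B"]
    wins <- 0
    for (p in pos) for (q in neg) {
      wins <- wins + (p > q) + 0.5 * (p == q)
    }
    expect_equal(got, wins / (length(pos) * length(neg)), tolerance = 1e-12)
  }
  # labels independent of scores: near 0.5
  set.seed(19)
  auc_null <- pooled_roc_auc(rnorm(4000), sample(c("A", "B"), 4000, TRUE))
  expect_lt(abs(auc_null - 0.5), 0.05)
  expect_error(pooled_roc_auc(1:3, c("A", "A", "A")), "single class")
})

test_that("training reduces the loss and is bit-reproducible", {
  co <- tiny_cohort()
  ids <- vapply(co$subjects, `[[`, character(1), "id")
  labels <- vapply(co$subjects, `[[`, character(1), "label")
  fa <- stratified_kfold(ids, labels, folds = 3, seed = 2)
  fd <- build_subject_graphs(co, fa)[[1]]
  cfg <- train_config(epochs = 60, folds = 3, hidden = 16, fc_hidden = 8)
  r1 <- train_fold(fd$graphs[fd$train], fd$graphs[fd$test], cfg, init_seed = 9)
  r2 <- train_fold(fd$graphs[fd$train], fd$graphs[fd$test], cfg, init_seed = 9)
  expect_identical(r1$params, r2$params)          # determinism contract
  expect_identical(r1$Z, r2$Z)
  expect_lt(r1$loss[60], r1$loss[1])              # planted effect is learnable
  # attention scores recorded for every train + test subject
  expect_equal(nrow(r1$Z), length(fd$train) + length(fd$test))
  # trained weights do not depend on test subjects (no leakage)
  flipped <- fd$graphs[fd$test]
  for (i in seq_along(flipped)) {
    flipped[[i]]$label <- ifelse(flipped[[i]]$label == "A", "B", "A")
  }
  r3 <- train_fold(fd$graphs[fd$train], flipped, cfg, init_seed = 9)
  expect_identical(r3$params, r1$params)
})

test_that("a full experiment reports per-fold metrics and reproduces exactly", {
  co <- tiny_cohort(n_a = 8, n_b = 8, n_landmarks = 16, n_timepoints = 50)
  cfg <- train_config(epochs = 40, folds = 4, hidden = 12, fc_hidden = 8,
                      fold_seed = 1, init_seed = 2)
  res <- run_experiment(co, cfg)
  expect_s3_class(res, "dmgnn_result")
  expect_equal(nrow(res$fold_metrics), 4)
  expect_true(all(c("ACC", "SEN", "SPE") %in% names(res$fold_metrics)))
  expect_length(res$mean, 3)
  expect_length(res$sd, 3)
  expect_true(res$auc >= 0 && res$auc <= 1)
  expect_true(all(res$fold_metrics$ACC >= 0 & res$fold_metrics$ACC <= 1, na.rm = TRUE))
  # every subject scored exactly once across test folds
  expect_equal(sort(res$scores$id), sort(vapply(co$subjects, `[[`, character(1), "id")))
  # bit-reproducibility given identical seeds
  res2 <- run_experiment(co, cfg)
  expect_identical(res$fold_metrics, res2$fold_metrics)
  expect_identical(res$Z, res2$Z)
  expect_identical(res$biomarkers$all$indices, res2$biomarkers$all$indices)
})

test_that("a null cohort classifies at chance level", {
  accs <- unlist(lapply(1:3, function(r) {
    co <- generate_cohort(cohort_spec(
      n_group_a = 8, n_group_b = 8, n_landmarks = 12, n_timepoints = 60,
      effect_nodes = integer(0), functional_effect = 0, structural_effect = 0,
      seed = 300 + r))
    cfg <- train_config(epochs = 30, folds = 2, hidden = 8, fc_hidden = 6,
                        fold_seed = r, init_seed = r + 10)
    res <- run_experiment(co, cfg)
    res$scores$pred == res$scores$label
  }))
  # 48 pooled null predictions: accuracy within binomial noise of 0.5
  expect_gt(mean(accs), 0.5 - 2.58 * sqrt(0.25 / length(accs)) - 0.05)
  expect_lt(mean(accs), 0.5 + 2.58 * sqrt(0.25 / length(accs)) + 0.05)
})

test_that("the structural trace-map ablation runs the same protocol", {
  co <- tiny_cohort(n_a = 6, n_b = 6, n_landmarks = 12, n_timepoints = 40)
  cfg <- train_config(epochs = 20, folds = 3, hidden = 8, fc_hidden = 6,
                      features = "tracemap")
  res <- run_experiment(co, cfg)
  expect_equal(nrow(res$fold_metrics), 3)
  expect_true(all(is.na(res$mask_retention)))     # no t-test mask in ablation
})
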