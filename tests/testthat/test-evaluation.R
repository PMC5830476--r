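test_that("auc_roc reproduces the analytic anchors and pairwise concordance", {
  expect_identical(auc_roc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1) # perfect
  expect_equal(auc_roc(c(0.9, 0.3, 0.4, 0.1), c(1, 1, 0, 0)), 0.75) # 3/4 pairs concordant
  expect_equal(auc_roc(rep(0.5, 10), rep(c(1, 0), 5)), 0.5) # all ties
  expect_error(auc_roc(1:4, c(1, 1, 1, 1)), "one class")
})

test_that("auc_roc equals the O(n^2) concordance oracle on random instances", {
  set.seed(11)
  for (rep in 1:60) {
    n <- sample(4:200, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (sum(y) == 0 || sum(y) == n) next
    # heavy ties: few distinct score levels
    s <- sample(seq_len(sample(2:8, 1)), n, replace = TRUE) / 10
    expect_equal(auc_roc(s, y), auc_concordance_oracle(s, y), tolerance = 1e-12)
  }
})

test_that("auc_roc is invariant under strictly monotone score transforms", {
  set.seed(12)
  s <- rnorm(80)
  y <- rbinom(80, 1, 0.4)
  base <- auc_roc(s, y)
  expect_equal(auc_roc(exp(s), y), base, tolerance = 1e-12)
  expect_equal(auc_roc(rank(s, ties.method = "average"), y), base, tolerance = 1e-12)
  expect_equal(auc_roc(2 * s - 5, y), base, tolerance = 1e-12)
})

test_that("balanced accuracy follows (sens + spec)/2", {
  # 20 compounds: 10 positive with 8 hits, 10 negative with 6 correct rejections
  y <- c(rep(1, 10), rep(0, 10))
  pred <- c(rep(1, 8), rep(0, 2), rep(0, 6), rep(1, 4))
  expect_equal(balanced_accuracy(pred, y), 0.7)
  expect_identical(balanced_accuracy(y, y), 1)
  expect_identical(balanced_accuracy(1 - y, y), 0)
  expect_error(balanced_accuracy(pred, rep(1, 20)), "one class")
})

test_that("binary-feature AUC equals the predict-iff-present balanced accuracy", {
  set.seed(13)
  for (rep in 1:50) {
    n <- sample(10:80, 1)
    f <- rbinom(n, 1, runif(1, 0.1, 0.9))
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    expect_equal(auc_roc(f, y), balanced_accuracy(f, y), tolerance = 1e-12)
  }
})

test_that("split plans partition compounds into near-equal halves, reproducibly", {
  ids <- paste0("c", 1:101)
  plan <- split_plan(ids, n_splits = 10, seed = 5)
  for (sp in plan$splits) {
    expect_setequal(c(sp$train, sp$test), ids)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_lte(abs(length(sp$train) - length(sp$test)), 1)
  }
  plan2 <- split_plan(ids, n_splits = 10, seed = 5)
  expect_identical(plan, plan2)
  expect_false(identical(plan$splits, split_plan(ids, n_splits = 10, seed = 6)$splits))
})

test_that("repeated holdout is deterministic and solves the separable case", {
  # labels are a noiseless function of one feature: every split AUC is 1
  set.seed(21)
  n <- 60
  f_causal <- rbinom(n, 1, 0.5)
  X <- cbind(f1 = f_causal, f2 = rbinom(n, 1, 0.3))
  rownames(X) <- paste0("c", 1:n)
  feats <- feature_matrix(X, "assay")
  labels <- ade_label_matrix(matrix(f_causal, n, 1, dimnames = list(rownames(X), "ade1")))
  plan <- split_plan(rownames(X), n_splits = 5, seed = 3)
  res <- run_repeated_holdout(feats, labels, plan)
  expect_equal(res$auc, rep(1, 5))
  expect_true(all(res$n_test_pos >= 1 & res$n_test_neg >= 1))
  expect_identical(res, run_repeated_holdout(feats, labels, plan))
})

test_that("degenerate splits are redrawn for rare ADEs", {
  set.seed(22)
  n <- 40
  X <- matrix(rbinom(n * 3, 1, 0.4), n, 3,
    dimnames = list(paste0("c", 1:n), paste0("f", 1:3))
  )
  y <- integer(n)
  y[1:2] <- 1L # 2 positives in 40: planned splits often one-class
  labels <- ade_label_matrix(matrix(y, n, 1, dimnames = list(rownames(X), "rare")))
  plan <- split_plan(rownames(X), n_splits = 10, seed = 1)
  res <- suppressWarnings(run_repeated_holdout(feature_matrix(X), labels, plan))
  expect_true(all(res$n_test_pos >= 1 & res$n_test_neg >= 1))
})

test_that("model summaries aggregate per ADE then over ADEs", {
  res <- data.frame(
    ade_id = rep(c("a1", "a2"), each = 3),
    split = rep(1:3, 2),
    auc = c(0.9, 0.8, 0.7, 0.5, 0.6, 0.7),
    n_test_pos = 5, n_test_neg = 5
  )
  class(res) <- c("evaluation_result", "data.frame")
  s <- summarize_model_set(res, "demo")
  expect_equal(s$per_ade$mean_auc, c(0.8, 0.6))
  expect_equal(s$grand_mean_auc, 0.7)
  expect_equal(s$best_auc, 0.8)
  expect_identical(s$n_above_0.75, 1L)
})

test_that("permute_feature_block preserves margins and severs linkage", {
  b <- random_block(30, 6, p = 0.4, block = "dta", seed = 9)
  bp <- permute_feature_block(b, seed = 4)
  expect_identical(colSums(bp), colSums(b))
  expect_identical(rownames(bp), rownames(b))
  expect_false(identical(unclass(bp), unclass(b)))
  # distinct seeds give distinct permutations
  expect_false(identical(unclass(permute_feature_block(b, seed = 5)), unclass(bp)))
  expect_error(permute_feature_block(random_block(5, 2, missing = 0.5)), "missing")
})

test_that("label permutation produces fresh draws and the add-one p-value", {
  ds <- generate_synthetic(generator_config(
    n_compounds = 80, n_readouts = 15, n_assayed_targets = 8,
    n_targets = 20, n_dtas = 20, n_ades = 4, seed = 2
  ))
  plan <- split_plan(rownames(ds$ades), n_splits = 3, seed = 2)
  pn <- permutation_null(ds$assay, ds$ades, plan, n_perm = 4, seed = 6)
  expect_length(pn$null_means, 4)
  expect_equal(
    pn$p_value,
    (1 + sum(pn$null_means >= pn$observed)) / 5
  )
  # reruns with the same seed reproduce; a different seed differs
  pn2 <- permutation_null(ds$assay, ds$ades, plan, n_perm = 4, seed = 6)
  expect_identical(pn$null_means, pn2$null_means)
  pn3 <- permutation_null(ds$assay, ds$ades, plan, n_perm = 4, seed = 7)
  expect_false(identical(pn$null_means, pn3$null_means))
})

test_that("model-set comparison runs ANOVA with Bonferroni-adjusted pairs", {
  mk <- function(label, aucs) {
    structure(
      list(
        model_label = label,
        per_ade = data.frame(ade_id = paste0("a", seq_along(aucs)), mean_auc = aucs),
        grand_mean_auc = mean(aucs), best_auc = max(aucs),
        n_above_0.75 = sum(aucs > 0.75)
      ),
      class = "model_set_summary"
    )
  }
  set.seed(31)
  base <- runif(50, 0.5, 0.7)

  # identical sets: no difference, adjusted p = 1
  cmp_same <- compare_model_sets(list(mk("m1", base), mk("m2", base)))
  expect_equal(cmp_same$pairwise$p_adj, 1)

  # clearly separated sets: p < 0.001 (simulation mirror of the printed contrast)
  lo <- rnorm(100, 0.55, 0.01)
  hi <- rnorm(100, 0.70, 0.01)
  mk2 <- function(label, aucs) mk(label, aucs)
  cmp_sep <- compare_model_sets(list(
    structure(list(model_label = "lo",
      per_ade = data.frame(ade_id = paste0("a", 1:100), mean_auc = lo),
      grand_mean_auc = mean(lo), best_auc = max(lo), n_above_0.75 = 0L),
      class = "model_set_summary"),
    structure(list(model_label = "hi",
      per_ade = data.frame(ade_id = paste0("a", 1:100), mean_auc = hi),
      grand_mean_auc = mean(hi), best_auc = max(hi), n_above_0.75 = 0L),
      class = "model_set_summary")
  ))
  expect_lt(cmp_sep$anova_p, 0.001)
  expect_lt(cmp_sep$pairwise$p_adj, 0.001)

  # three sets: three pairwise rows, each raw p scaled by 3 and capped at 1
  s3 <- list(mk("m1", base), mk("m2", base + 0.001), mk("m3", base + 0.002))
  cmp3 <- compare_model_sets(s3)
  expect_identical(nrow(cmp3$pairwise), 3L)
  raw <- stats::pairwise.t.test(cmp3$data$auc, cmp3$data$model,
    p.adjust.method = "none"
  )$p.value
  raw <- raw[!is.na(raw)]
  expect_equal(sort(cmp3$pairwise$p_adj), sort(pmin(1, 3 * raw)), tolerance = 1e-12)
  expect_true(all(cmp3$pairwise$p_adj <= 1))

  # mismatched ADE lists are rejected
  bad <- mk("mX", base[1:49])
  expect_error(compare_model_sets(list(mk("m1", base), bad)), "different ADE lists")
})
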