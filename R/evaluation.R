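#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a randomly chosen
#' positive compound outscores a randomly chosen negative one, with ties
#' credited 0.5. Equals the trapezoidal area under the ROC curve — the plot
#' of sensitivity TP/(TP+FN) against 1 - specificity TN/(TN+FP) over all
#' score thresholds. 0.5 indicates a random classifier, 1 a perfect one.
#'
#' @param scores numeric score vector (higher = more likely positive).
#' @param labels binary 0/1 vector of the same length.
#' @return AUC-ROC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (anyNA(scores) || anyNA(labels)) stop("scores and labels must not contain NA")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: labels contain only one class")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Balanced accuracy of binary predictions
#'
#' BA = (sensitivity + specificity) / 2.
#'
#' @param predictions binary 0/1 predictions.
#' @param labels binary 0/1 labels.
#' @return value in `[0, 1]`.
#' @export
balanced_accuracy <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("balanced accuracy undefined: labels contain only one class")
  sens <- sum(predictions == 1L & labels == 1L) / n1
  spec <- sum(predictions == 0L & labels == 0L) / n0
  (sens + spec) / 2
}

#' Repeated 50/50 holdout split plan
#'
#' Draws `n_splits` independent unstratified random partitions of the
#' compound set into training and test halves of approximately equal size
#' (sizes differ by at most one). The same plan is reused across the model
#' sets being compared, so performance differences reflect the input data
#' rather than split luck.
#'
#' @param compound_ids character vector of compound ids.
#' @param n_splits number of random splits (default 10).
#' @param split_fraction fraction assigned to training (default 0.5).
#' @param seed integer seed for the split draws.
#' @return object of class `split_plan`: list with `splits` (each a list of
#'   `train` and `test` id vectors), `seed`, and the inputs.
#' @export
split_plan <- function(compound_ids, n_splits = 10L, split_fraction = 0.5, seed = 1L) {
  stopifnot(length(compound_ids) >= 4L, n_splits >= 1L,
    split_fraction > 0, split_fraction < 1)
  n <- length(compound_ids)
  n_train <- round(n * split_fraction)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  splits <- lapply(seq_len(n_splits), function(i) {
    tr <- sample(compound_ids, n_train)
    list(train = tr, test = setdiff(compound_ids, tr))
  })
  structure(
    list(splits = splits, seed = seed, n_splits = n_splits,
      split_fraction = split_fraction, compound_ids = compound_ids),
    class = "split_plan"
  )
}

# Save/restore the global RNG state so helper draws do not disturb callers.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Evaluate WFS models by repeated holdout
#'
#' For every ADE and every split of the plan: fit the comprehensive feature
#' fingerprint on the training half, score the test half, and record the
#' test AUC-ROC. If a split leaves the training or the test half without
#' both label classes for an ADE, that split is redrawn for that ADE (up to
#' 100 attempts, deterministically seeded); if no valid redraw is found the
#' ADE x split cell is skipped with a warning.
#'
#' @param features a [feature_matrix()] (concatenate blocks first for
#'   combined models, see [cbind_blocks()]).
#' @param labels an [ade_label_matrix()], rows aligned with `features`.
#' @param plan a [split_plan()] over the same compound ids.
#' @param alpha WFS weighting factor.
#' @return data.frame of class `evaluation_result` with columns `ade_id`,
#'   `split`, `auc`, `n_test_pos`, `n_test_neg`.
#' @export
run_repeated_holdout <- function(features, labels, plan, alpha = 1) {
  stopifnot(inherits(plan, "split_plan"))
  if (!identical(rownames(features), rownames(labels))) {
    stop("features and labels are not aligned; call align_compounds() first")
  }
  ids <- rownames(features)
  X <- unclass(features)
  rows <- vector("list", ncol(labels) * plan$n_splits)
  k <- 0L
  for (a in seq_len(ncol(labels))) {
    y_all <- unclass(labels)[, a]
    ade <- colnames(labels)[a]
    for (s in seq_len(plan$n_splits)) {
      sp <- valid_split_for(plan, s, y_all, ids)
      if (is.null(sp)) {
        warning(sprintf("no valid split found for ADE '%s', split %d; skipped", ade, s))
        next
      }
      tr <- match(sp$train, ids)
      te <- match(sp$test, ids)
      fp <- build_fingerprint(
        feature_matrix(X[tr, , drop = FALSE], attr(features, "block")),
        y_all[tr], ade_id = ade
      )
      sc <- if (length(fp) == 0L) {
        # no feature observed in any positive training compound: the model
        # carries no evidence, every test compound scores 0
        stats::setNames(rep(0, length(te)), ids[te])
      } else {
        score_matrix(
          wfs_model(fp, alpha = alpha),
          feature_matrix(X[te, , drop = FALSE], attr(features, "block"))
        )
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        ade_id = ade, split = s,
        auc = auc_roc(sc, y_all[te]),
        n_test_pos = sum(y_all[te] == 1L),
        n_test_neg = sum(y_all[te] == 0L),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  class(out) <- c("evaluation_result", "data.frame")
  out
}

# Returns the planned split if it keeps both label classes on both sides;
# otherwise redraws (seeded from the plan) up to 100 times, or NULL.
valid_split_for <- function(plan, s, y_all, ids) {
  both_classes <- function(sp) {
    ytr <- y_all[match(sp$train, ids)]
    yte <- y_all[match(sp$test, ids)]
    any(ytr == 1L) && any(ytr == 0L) && any(yte == 1L) && any(yte == 0L)
  }
  sp <- plan$splits[[s]]
  if (both_classes(sp)) return(sp)
  n_train <- length(sp$train)
  old <- local_seed(plan$seed * 1000L + s)
  on.exit(restore_seed(old))
  for (i in seq_len(100L)) {
    tr <- sample(plan$compound_ids, n_train)
    cand <- list(train = tr, test = setdiff(plan$compound_ids, tr))
    if (both_classes(cand)) return(cand)
  }
  NULL
}

#' Summarize an evaluation over splits and ADEs
#'
#' Averages each ADE's AUC over the splits, then summarizes the model set:
#' grand mean AUC (mean of the per-ADE means), best per-ADE mean AUC, and
#' the count of ADEs with split-averaged AUC strictly above 0.75.
#'
#' @param results an `evaluation_result` from [run_repeated_holdout()].
#' @param model_label name of the model set (e.g. `"assay"`, `"assay+dta"`).
#' @return object of class `model_set_summary`: list with `model_label`,
#'   `per_ade` (data.frame `ade_id`, `mean_auc`), `grand_mean_auc`,
#'   `best_auc`, `n_above_0.75`.
#' @export
summarize_model_set <- function(results, model_label = "model") {
  stopifnot(inherits(results, "evaluation_result") || is.data.frame(results))
  per_ade <- stats::aggregate(auc ~ ade_id, data = results, FUN = mean)
  names(per_ade)[2L] <- "mean_auc"
  structure(
    list(
      model_label = model_label,
      per_ade = per_ade,
      grand_mean_auc = mean(per_ade$mean_auc),
      best_auc = max(per_ade$mean_auc),
      n_above_0.75 = sum(per_ade$mean_auc > 0.75)
    ),
    class = "model_set_summary"
  )
}

#' @export
print.model_set_summary <- function(x, ...) {
  cat(sprintf(
    "<model_set_summary '%s'> %d ADEs; mean AUC %.3f; best %.3f; %d ADEs > 0.75\n",
    x$model_label, nrow(x$per_ade), x$grand_mean_auc, x$best_auc, x$n_above_0.75
  ))
  invisible(x)
}

#' Label-permutation null distribution of the grand mean AUC
#'
#' Each replicate independently permutes every ADE label column across
#' compounds (breaking any compound-effect linkage while preserving ADE
#' frequencies), reruns the full repeated-holdout evaluation, and records
#' the grand mean AUC. A calibrated pipeline centers the null at 0.50. The
#' one-sided empirical p-value for the observed grand mean uses the add-one
#' estimator (1 + #{null >= observed}) / (n_perm + 1).
#'
#' @inheritParams run_repeated_holdout
#' @param n_perm number of permutation replicates.
#' @param seed seed for the permutation draws.
#' @return list with `observed` (grand mean AUC on the real labels),
#'   `null_means` (numeric vector, one per replicate), and `p_value`.
#' @export
permutation_null <- function(features, labels, plan, n_perm = 50L, seed = 1L, alpha = 1) {
  stopifnot(n_perm >= 1L)
  observed <- summarize_model_set(
    run_repeated_holdout(features, labels, plan, alpha = alpha)
  )$grand_mean_auc
  Y <- unclass(labels)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  null_means <- vapply(seq_len(n_perm), function(i) {
    Yp <- apply(Y, 2L, sample)
    rownames(Yp) <- rownames(Y)
    perm <- ade_label_matrix(Yp)
    summarize_model_set(
      run_repeated_holdout(features, perm, plan, alpha = alpha)
    )$grand_mean_auc
  }, numeric(1L))
  list(
    observed = observed,
    null_means = null_means,
    p_value = (1 + sum(null_means >= observed)) / (n_perm + 1)
  )
}

#' Permute a feature block against the compound ids
#'
#' Shuffles the rows of an annotation block relative to the compounds,
#' severing every compound-annotation link while preserving the column
#' margins exactly. Used to show that the performance gain of a combined
#' model (e.g. assay plus DTA) vanishes when the annotations are random.
#'
#' @param features a [feature_matrix()] without missing values.
#' @param seed integer seed.
#' @return a `feature_matrix` with the same dimnames, rows permuted.
#' @export
permute_feature_block <- function(features, seed = 1L) {
  if (anyNA(features)) stop("cannot permute a block with missing values")
  X <- unclass(features)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  perm <- sample(nrow(X))
  Xp <- X[perm, , drop = FALSE]
  rownames(Xp) <- rownames(X)
  feature_matrix(Xp, block_label = attr(features, "block"))
}

#' Compare model sets by one-way ANOVA with Bonferroni post hoc tests
#'
#' Treats each ADE's split-averaged AUC as one observation and tests whether
#' the model sets differ, following the one-way analysis of variance with
#' Bonferroni-adjusted pairwise comparisons. All summaries must cover the
#' same ADE list.
#'
#' @param summaries list of [summarize_model_set()] objects (>= 2).
#' @return list with `anova_p` (overall F-test p-value), `pairwise`
#'   (data.frame `model_a`, `model_b`, `p_adj` with Bonferroni-adjusted
#'   p-values capped at 1), and `data` (the long per-ADE table).
#' @export
compare_model_sets <- function(summaries) {
  stopifnot(is.list(summaries), length(summaries) >= 2L)
  ades <- lapply(summaries, function(s) sort(s$per_ade$ade_id))
  if (!all(vapply(ades[-1L], identical, logical(1L), ades[[1L]]))) {
    stop("model set summaries cover different ADE lists")
  }
  long <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(
      model = s$model_label, ade_id = s$per_ade$ade_id,
      auc = s$per_ade$mean_auc, stringsAsFactors = FALSE
    )
  }))
  long$model <- factor(long$model, levels = vapply(summaries, `[[`, character(1L), "model_label"))
  fit <- stats::aov(auc ~ model, data = long)
  anova_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
  pt <- stats::pairwise.t.test(long$auc, long$model, p.adjust.method = "bonferroni")
  pm <- pt$p.value
  pairs <- which(!is.na(pm), arr.ind = TRUE)
  pairwise <- data.frame(
    model_a = rownames(pm)[pairs[, 1L]],
    model_b = colnames(pm)[pairs[, 2L]],
    p_adj = pm[pairs],
    stringsAsFactors = FALSE
  )
  list(anova_p = anova_p, pairwise = pairwise, data = long)
}
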