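#' Univariate predictive screen of binary features
#'
#' Evaluates each feature of a block (each DTA, each assay readout) as a
#' standalone predictor of every ADE: the AUC-ROC obtained when the 0/1
#' feature itself is the score, and the balanced accuracy of the rule
#' "predict positive iff the feature is present". The screen runs on the
#' full compound set — it is a ranking step, not a validated model, so the
#' reported values are optimistic and must not be read as holdout
#' performance.
#'
#' @param features a [feature_matrix()] without missing values (annotation
#'   contract).
#' @param labels an [ade_label_matrix()], rows aligned with `features`.
#' @param threshold pass threshold for this block (strict inequality on AUC
#'   or BA); conventionally 0.6 for DTA blocks and 0.65 for assay readouts.
#' @return data.frame with columns `feature_id`, `ade_id`, `auc`, `ba`,
#'   `constant` (no variation in the feature), `passes`.
#' @export
univariate_eval <- function(features, labels, threshold = 0.6) {
  if (anyNA(features)) stop("univariate screen requires a block without missing values")
  if (!identical(rownames(features), rownames(labels))) {
    stop("features and labels are not aligned; call align_compounds() first")
  }
  X <- unclass(features)
  Y <- unclass(labels)
  grid <- expand.grid(
    feature_id = colnames(X), ade_id = colnames(Y),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  res <- Map(function(f, a) {
    x <- X[, f]
    y <- Y[, a]
    if (all(x == x[1L])) {
      c(auc = 0.5, ba = 0.5, constant = 1)
    } else {
      c(auc = auc_roc(x, y), ba = balanced_accuracy(x, y), constant = 0)
    }
  }, grid$feature_id, grid$ade_id)
  res <- do.call(rbind, res)
  out <- cbind(grid, as.data.frame(res))
  out$constant <- out$constant == 1
  out$passes <- out$auc > threshold | out$ba > threshold
  rownames(out) <- NULL
  out
}

#' Select features predictive of at least one ADE
#'
#' A feature is selected iff its univariate AUC-ROC or balanced accuracy
#' strictly exceeds the threshold for at least one ADE (the OR rule).
#' Selection is monotone: raising the threshold never adds features.
#'
#' @param records data.frame from [univariate_eval()].
#' @param threshold strict pass threshold; if `NULL`, the `passes` flags
#'   already present in `records` are used.
#' @return character vector of selected feature ids (possibly empty).
#' @export
select_features <- function(records, threshold = NULL) {
  if (nrow(records) == 0L) stop("empty univariate record list")
  passes <- if (is.null(threshold)) {
    records$passes
  } else {
    records$auc > threshold | records$ba > threshold
  }
  sort(unique(records$feature_id[passes]))
}

#' Most predictive univariate contributor per ADE
#'
#' Convenience ranking: for each ADE, the feature with the highest
#' univariate AUC and that value.
#'
#' @param records data.frame from [univariate_eval()].
#' @return data.frame with columns `ade_id`, `feature_id`, `auc`.
#' @export
top_contributors <- function(records) {
  if (nrow(records) == 0L) stop("empty univariate record list")
  do.call(rbind, lapply(split(records, records$ade_id), function(d) {
    best <- d[which.max(d$auc), ]
    data.frame(
      ade_id = best$ade_id, feature_id = best$feature_id,
      auc = best$auc, stringsAsFactors = FALSE
    )
  }))
}
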