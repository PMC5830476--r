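#' One-sided Fisher enrichment p-value for a single feature
#'
#' Tests whether a binary feature is enriched among compounds carrying an
#' adverse effect relative to compounds without it. Rows where the feature
#' value is missing are omitted from the 2x2 table. If the feature is
#' strictly *less* frequent among ADE-positive compounds than among
#' ADE-negative ones (depletion), the p-value is set to exactly 1 — only
#' enrichment counts as evidence. Equal frequencies do not trigger the
#' depletion rule; the one-sided test is computed.
#'
#' The one-sided p equals the upper hypergeometric tail
#' \eqn{P(X \ge x)} for \eqn{x} feature-positive compounds among the
#' ADE-positive group, conditioning on the table margins.
#'
#' @param feature_col vector of 0/1/`NA` feature values.
#' @param ade_labels binary 0/1 vector of ADE labels, same length.
#' @return p-value in (0, 1].
#' @export
fisher_enrichment_p <- function(feature_col, ade_labels) {
  stopifnot(length(feature_col) == length(ade_labels))
  if (anyNA(ade_labels)) stop("ADE labels must not be missing")
  keep <- !is.na(feature_col)
  y <- ade_labels[keep]
  f <- feature_col[keep]
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L) {
    warning("all feature values missing in one label class; p-value undefined, returning 1")
    return(1)
  }
  unname(fisher_p_columns(matrix(f, ncol = 1L), y))
}

# Vectorized enrichment p over the columns of a 0/1/NA matrix.
# Returns a named vector of p in (0,1]; depleted columns get exactly 1.
fisher_p_columns <- function(X, y) {
  obs <- !is.na(X)
  pres <- !is.na(X) & X == 1L
  pos <- y == 1L
  n1 <- colSums(obs[pos, , drop = FALSE])
  n0 <- colSums(obs[!pos, , drop = FALSE])
  x1 <- colSums(pres[pos, , drop = FALSE])
  x0 <- colSums(pres[!pos, , drop = FALSE])
  p <- rep(1, ncol(X))
  names(p) <- colnames(X)
  undef <- n1 == 0L | n0 == 0L
  if (any(undef)) {
    warning(sprintf(
      "%d feature(s) with all values missing in one label class; p set to 1",
      sum(undef)
    ))
  }
  ok <- !undef & (x1 / n1 >= x0 / n0)
  # upper tail P(X >= x1) of Hypergeometric(white = x1+x0, black = rest, drawn = n1)
  p[ok] <- stats::phyper(x1[ok] - 1L, x1[ok] + x0[ok],
    (n1[ok] - x1[ok]) + (n0[ok] - x0[ok]), n1[ok],
    lower.tail = FALSE
  )
  pmin(p, 1)
}

#' Build the comprehensive feature fingerprint for one adverse effect
#'
#' The fingerprint maps every feature present (value 1) in at least one
#' ADE-positive training compound to its one-sided Fisher enrichment
#' p-value, computed over all training compounds. Features never observed
#' in a positive compound are absent from the fingerprint; a drug carrying
#' them at scoring time is penalized through the unannotated-feature count.
#'
#' @param features [feature_matrix()] of training compounds.
#' @param ade_labels binary 0/1 vector, one label per training compound.
#' @param ade_id identifier stored on the fingerprint.
#' @return a `feature_fingerprint`: named numeric vector of p-values with
#'   attributes `ade_id` and `universe` (all training feature ids).
#' @export
build_fingerprint <- function(features, ade_labels, ade_id = "ade") {
  stopifnot(nrow(features) == length(ade_labels))
  if (sum(ade_labels == 1L) == 0L) stop("no ADE-positive training compounds")
  if (sum(ade_labels == 0L) == 0L) stop("no ADE-negative training compounds")
  X <- unclass(features)
  pos <- ade_labels == 1L
  in_m <- colSums(!is.na(X[pos, , drop = FALSE]) & X[pos, , drop = FALSE] == 1L) >= 1L
  p <- fisher_p_columns(X[, in_m, drop = FALSE], ade_labels)
  structure(p,
    ade_id = ade_id, universe = colnames(X),
    class = "feature_fingerprint"
  )
}

#' @export
print.feature_fingerprint <- function(x, ...) {
  cat(sprintf(
    "<feature_fingerprint '%s'> %d features; min p = %.3g\n",
    attr(x, "ade_id"), length(x), if (length(x)) min(x) else NA_real_
  ))
  invisible(x)
}

#' Weighted Feature Significance model
#'
#' Wraps a [build_fingerprint()] result with the weighting factor alpha and
#' the cached minimum log p-value used as the normalizer. For a drug with
#' feature set C and fingerprint feature set M, the WFS score is
#'
#' \deqn{WFS = \frac{\sum_{i \in M \cap C} \ln p_i}
#'   {\min_{i \in M} \ln p_i \times (\alpha N_{C-M} + N_{M \cap C})}}
#'
#' The sum runs over the drug's fingerprint features (p-values exist only
#' there); the minimum runs over the whole fingerprint, so every drug is
#' normalized against the strongest evidence attainable for the ADE.
#' \eqn{N_{C-M}} counts the drug's features absent from the fingerprint —
#' each such feature dilutes the score, with weight alpha. A high score
#' indicates a strong potential for the adverse effect.
#'
#' @param fingerprint a `feature_fingerprint`.
#' @param alpha weighting factor for unannotated features; the reference
#'   protocol fixes alpha = 1.
#' @return an object of class `wfs_model`.
#' @export
wfs_model <- function(fingerprint, alpha = 1) {
  stopifnot(inherits(fingerprint, "feature_fingerprint"), alpha >= 0)
  if (length(fingerprint) == 0L) stop("fingerprint is empty")
  structure(
    list(
      fingerprint = fingerprint,
      alpha = alpha,
      min_log_p = min(log(as.numeric(fingerprint)))
    ),
    class = "wfs_model"
  )
}

#' @export
print.wfs_model <- function(x, ...) {
  cat(sprintf(
    "<wfs_model '%s'> %d fingerprint features; alpha = %g; min ln p = %.3f\n",
    attr(x$fingerprint, "ade_id"), length(x$fingerprint), x$alpha, x$min_log_p
  ))
  invisible(x)
}

#' Score one drug with a WFS model
#'
#' @param model a [wfs_model()].
#' @param present_features character vector: ids of the features present
#'   (value 1) in the drug.
#' @return non-negative score; 0 when the drug shares no feature with the
#'   fingerprint, when all shared p-values equal 1, or when the fingerprint
#'   carries no evidence at all (all p = 1).
#' @export
wfs_score <- function(model, present_features) {
  stopifnot(inherits(model, "wfs_model"))
  m_ids <- names(model$fingerprint)
  shared <- present_features[present_features %in% m_ids]
  n_unannotated <- length(present_features) - length(shared)
  numerator <- sum(log(as.numeric(model$fingerprint[shared])))
  denominator <- model$min_log_p * (model$alpha * n_unannotated + length(shared))
  if (numerator == 0 || denominator == 0) return(0)
  numerator / denominator
}

#' Score every compound of a feature matrix
#'
#' Missing feature values are treated as "not present": an untested assay
#' contributes neither evidence nor penalty. All feature ids of the matrix
#' must belong to the model's training universe.
#'
#' @param model a [wfs_model()].
#' @param features a [feature_matrix()].
#' @return named numeric vector of scores, one per compound.
#' @export
score_matrix <- function(model, features) {
  stopifnot(inherits(model, "wfs_model"))
  X <- unclass(features)
  universe <- attr(model$fingerprint, "universe")
  unknown <- setdiff(colnames(X), universe)
  if (length(unknown) > 0L) {
    stop("feature id(s) not in the model's training universe: ",
      paste(utils::head(unknown, 5L), collapse = ", "))
  }
  pres <- !is.na(X) & X == 1L
  m_ids <- names(model$fingerprint)
  in_m <- colnames(X) %in% m_ids
  logp <- log(as.numeric(model$fingerprint[colnames(X)[in_m]]))
  numerator <- as.numeric(pres[, in_m, drop = FALSE] %*% logp)
  n_shared <- rowSums(pres[, in_m, drop = FALSE])
  n_unannotated <- rowSums(pres[, !in_m, drop = FALSE])
  denominator <- model$min_log_p * (model$alpha * n_unannotated + n_shared)
  score <- ifelse(numerator == 0 | denominator == 0, 0, numerator / denominator)
  names(score) <- rownames(X)
  score
}
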