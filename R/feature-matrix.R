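#' Binary feature matrix with missing-value support
#'
#' A `feature_matrix` holds a compounds-by-features block of 0/1 values, with
#' `NA` marking untested (missing) cells. Four kinds of block occur in ADE
#' modeling: qHTS assay activity calls (`"assay"`, may contain `NA` for
#' compounds not tested in an assay), drug-target annotations (`"dta"`),
#' structure fingerprint bits (`"structure"`), and animal toxicity endpoints
#' (`"animal"`). Annotation-style blocks (DTA, structure) are complete by
#' construction — absence of a report is coded 0, never `NA` — and the
#' constructor enforces that.
#'
#' @param values integer or numeric matrix of 0/1/`NA` with unique rownames
#'   (compound ids) and colnames (feature ids).
#' @param block_label one of `"assay"`, `"dta"`, `"structure"`, `"animal"`,
#'   or any other short label naming the data type.
#' @return an object of class `feature_matrix`: the validated integer matrix
#'   with attribute `block`.
#' @export
feature_matrix <- function(values, block_label = "assay") {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have rownames (compound ids) and colnames (feature ids)")
  }
  check_unique_ids(rownames(values), "compound")
  check_unique_ids(colnames(values), "feature")
  bad <- !(values %in% c(0L, 1L) | is.na(values))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(values)), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "invalid cell value %s at compound '%s', feature '%s': must be 0, 1 or missing",
      format(values[idx[1L], idx[2L]]), rownames(values)[idx[1L]], colnames(values)[idx[2L]]
    ))
  }
  if (block_label %in% c("dta", "structure") && anyNA(values)) {
    stop(sprintf("'%s' blocks must not contain missing values", block_label))
  }
  storage.mode(values) <- "integer"
  structure(values, block = block_label, class = c("feature_matrix", "matrix", "array"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix '%s'> %d compounds x %d features; %.1f%% ones, %.1f%% missing\n",
    attr(x, "block"), nrow(x), ncol(x),
    100 * mean(x == 1L, na.rm = TRUE), 100 * mean(is.na(x))
  ))
  invisible(x)
}

#' Adverse drug effect label matrix
#'
#' Compounds-by-ADEs binary matrix with no missing values: a 1 records that
#' the adverse effect has been reported for the compound, a 0 that it has not.
#'
#' @param values 0/1 matrix with unique rownames (compound ids) and colnames
#'   (ADE ids).
#' @return an object of class `ade_labels`.
#' @export
ade_label_matrix <- function(values) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have rownames (compound ids) and colnames (ADE ids)")
  }
  check_unique_ids(rownames(values), "compound")
  check_unique_ids(colnames(values), "ADE")
  if (anyNA(values)) stop("ADE labels must not contain missing values")
  if (!all(values %in% c(0L, 1L))) stop("ADE labels must be 0 or 1")
  storage.mode(values) <- "integer"
  structure(values, class = c("ade_labels", "matrix", "array"))
}

#' @export
print.ade_labels <- function(x, ...) {
  cat(sprintf(
    "<ade_labels> %d compounds x %d ADEs; median positives per ADE: %d\n",
    nrow(x), ncol(x), as.integer(stats::median(colSums(x)))
  ))
  invisible(x)
}

check_unique_ids <- function(ids, what) {
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicated %s id(s): %s", what, paste(unique(dup), collapse = ", ")))
  }
  invisible(TRUE)
}

read_wide_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path,
    header = TRUE, sep = sep, check.names = FALSE,
    colClasses = "character", quote = "\"", comment.char = "", fileEncoding = "UTF-8"
  )
  if (ncol(df) < 2L) stop("expected an id column plus at least one feature column: ", path)
  ids <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  m[m == "" | toupper(m) == "NA"] <- NA_character_
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m)))
  bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-numeric cell '%s' at row '%s', column '%s' in %s",
      m[bad[1L, 1L], bad[1L, 2L]], ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]], path
    ))
  }
  rownames(num) <- ids
  num
}

#' Read a wide binary feature matrix from CSV/TSV
#'
#' First column holds compound ids, header row holds feature ids; cells are
#' 0, 1, empty, or `NA` (empty and the literal string `NA` both parse as
#' missing). The delimiter is inferred from the file extension (`.tsv` is
#' tab-separated, anything else comma-separated).
#'
#' @param path path to the file.
#' @param block_label data-type label, see [feature_matrix()].
#' @return a validated [feature_matrix()].
#' @export
read_feature_matrix <- function(path, block_label = "assay") {
  feature_matrix(read_wide_matrix(path), block_label = block_label)
}

#' Read an ADE label matrix from CSV/TSV
#'
#' @inheritParams read_feature_matrix
#' @return a validated [ade_label_matrix()].
#' @export
read_ade_labels <- function(path) {
  ade_label_matrix(read_wide_matrix(path))
}

#' Write a feature or label matrix as CSV/TSV
#'
#' Missing values are written as empty cells, so a write/read round-trip is
#' value-identical including missingness.
#'
#' @param x a `feature_matrix` or `ade_labels` object.
#' @param path output path; `.tsv` extension selects tab separation.
#' @export
write_matrix_file <- function(x, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- data.frame(compound_id = rownames(x), unclass(x)[, , drop = FALSE],
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(df, path,
    sep = sep, row.names = FALSE, quote = FALSE, na = "",
    fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Drop rarely-reported adverse effects
#'
#' Retains only ADE columns reported for at least `min_drugs` compounds.
#' Rare ADEs leave too few positives to train and test enrichment models on;
#' the reference protocol for the NPC library keeps ADEs with at least 100
#' associated drugs.
#'
#' @param labels an [ade_label_matrix()].
#' @param min_drugs minimum positive count; ADEs with fewer than this many
#'   positives (strictly) are removed.
#' @return the filtered `ade_labels` matrix; the compound set is unchanged.
#' @export
filter_ades <- function(labels, min_drugs = 100L) {
  stopifnot(inherits(labels, "ade_labels"), min_drugs >= 1L)
  keep <- colSums(labels) >= min_drugs
  if (!any(keep)) {
    stop(sprintf(
      "no ADE has >= %d positive compounds; lower `min_drugs` (max positives: %d)",
      min_drugs, max(colSums(labels))
    ))
  }
  ade_label_matrix(unclass(labels)[, keep, drop = FALSE])
}

#' Align feature blocks and labels on a common compound set
#'
#' Restricts every block and the label matrix to the intersection of their
#' compound ids, in a single shared row order (the order of the intersection
#' as it appears in the label matrix, or in the first block if no labels are
#' given). Matching is exact string equality on ids.
#'
#' @param blocks named list of [feature_matrix()] objects.
#' @param labels optional [ade_label_matrix()].
#' @return list with elements `blocks` (same names, aligned), `labels`
#'   (aligned or `NULL`), and `dropped` (named integer vector of rows removed
#'   from each input).
#' @export
align_compounds <- function(blocks, labels = NULL) {
  stopifnot(is.list(blocks), length(blocks) > 0L)
  id_sets <- lapply(blocks, rownames)
  if (!is.null(labels)) id_sets <- c(id_sets, list(rownames(labels)))
  common <- Reduce(intersect, id_sets)
  if (length(common) == 0L) stop("no compound ids shared by all inputs")
  ref <- if (!is.null(labels)) rownames(labels) else rownames(blocks[[1L]])
  common <- ref[ref %in% common]
  dropped <- vapply(id_sets, function(ids) length(ids) - length(common), integer(1L))
  names(dropped) <- c(names(blocks), if (!is.null(labels)) ".labels")
  aligned <- lapply(blocks, function(b) {
    feature_matrix(unclass(b)[common, , drop = FALSE], block_label = attr(b, "block"))
  })
  out_labels <- if (!is.null(labels)) {
    ade_label_matrix(unclass(labels)[common, , drop = FALSE])
  }
  list(blocks = aligned, labels = out_labels, dropped = dropped)
}

#' Concatenate aligned feature blocks column-wise
#'
#' Combined models (e.g. assay plus DTA) use the blocks side by side as
#' additional descriptors; no interaction terms are formed. Blocks must
#' already share an identical compound id order (use [align_compounds()]).
#'
#' @param blocks named list of aligned [feature_matrix()] objects.
#' @param block_label label for the combined block.
#' @return a single [feature_matrix()]; feature ids are prefixed with the
#'   block name (`"assay:..."`) when names would otherwise collide.
#' @export
cbind_blocks <- function(blocks, block_label = "combined") {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  ids <- rownames(blocks[[1L]])
  for (b in blocks) {
    if (!identical(rownames(b), ids)) stop("blocks are not aligned; call align_compounds() first")
  }
  all_feats <- unlist(lapply(blocks, colnames), use.names = FALSE)
  if (anyDuplicated(all_feats)) {
    nm <- names(blocks)
    if (is.null(nm)) nm <- paste0("block", seq_along(blocks))
    blocks <- Map(function(b, n) {
      colnames(b) <- paste0(n, ":", colnames(b))
      b
    }, blocks, nm)
  }
  m <- do.call(cbind, lapply(blocks, unclass))
  feature_matrix(m, block_label = block_label)
}
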