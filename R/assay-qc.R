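#' Binary activity call from a qHTS curve rank
#'
#' Curve rank is a signed summary of a concentration-response curve's
#' quality and direction: positive values indicate activation, negative
#' values inhibition, and larger magnitudes higher confidence. Compounds
#' with absolute curve rank strictly greater than 0.5 are called active (1),
#' inactive (0) otherwise; the boundary value 0.5 is inactive.
#'
#' @param curve_rank numeric vector of signed curve ranks (finite).
#' @return integer vector of 0/1 activity calls.
#' @seealso [call_direction()]
#' @export
call_activity <- function(curve_rank) {
  if (any(!is.finite(curve_rank))) stop("curve ranks must be finite")
  out <- as.integer(abs(curve_rank) > 0.5)
  names(out) <- names(curve_rank)
  out
}

#' Direction of a curve-rank activity call
#'
#' @param curve_rank numeric vector of signed curve ranks.
#' @return character vector: `"activation"` for positive active calls,
#'   `"inhibition"` for negative active calls, `"inactive"` otherwise.
#' @export
call_direction <- function(curve_rank) {
  act <- call_activity(curve_rank)
  out <- ifelse(act == 1L, ifelse(curve_rank > 0, "activation", "inhibition"), "inactive")
  names(out) <- names(curve_rank)
  out
}

TRIPLICATE_CALLS <- c("activation", "inhibition", "inactive", "inconclusive")

#' Long table of triplicate activity calls
#'
#' Screening each assay against three copies of the compound library gives
#' three independent activity calls per compound. The table is long format
#' with exactly three replicates per (compound, assay) pair; each call is
#' one of `"activation"`, `"inhibition"`, `"inactive"`, `"inconclusive"`.
#'
#' @param df data.frame with columns `compound_id`, `assay_id`, `replicate`
#'   (1..3), `call`.
#' @return validated data.frame of class `triplicate_calls`.
#' @export
triplicate_call_table <- function(df) {
  need <- c("compound_id", "assay_id", "replicate", "call")
  if (!all(need %in% names(df))) {
    stop("need columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(df$call), TRIPLICATE_CALLS)
  if (length(bad) > 0L) stop("unknown call value(s): ", paste(bad, collapse = ", "))
  counts <- table(df$compound_id, df$assay_id)
  if (any(counts != 3L)) {
    stop("every (compound, assay) pair must have exactly three calls")
  }
  class(df) <- c("triplicate_calls", "data.frame")
  df
}

#' Reproducibility rates of one assay's triplicate calls
#'
#' Classifies each compound's three calls:
#' * active match — all three active in the same direction (all activation
#'   or all inhibition);
#' * inactive match — all three inactive;
#' * mismatch — active calls in opposite directions present;
#' * inconclusive — any other pattern (partial agreement or inconclusive
#'   calls).
#'
#' @param table a [triplicate_call_table()].
#' @param assay_id assay to summarize.
#' @return named numeric vector of percentages over compounds
#'   (`active_match`, `inactive_match`, `inconclusive`, `mismatch`),
#'   summing to 100.
#' @export
triplicate_rates <- function(table, assay_id) {
  stopifnot(inherits(table, "triplicate_calls"))
  d <- table[table$assay_id == assay_id, ]
  if (nrow(d) == 0L) stop("no calls for assay: ", assay_id)
  cls <- vapply(split(d$call, d$compound_id), classify_triplicate, character(1L))
  tab <- base::table(
    factor(cls, levels = c("active_match", "inactive_match", "inconclusive", "mismatch"))
  )
  pct <- 100 * as.vector(tab) / length(cls)
  names(pct) <- names(tab)
  pct
}

classify_triplicate <- function(calls) {
  if (length(calls) != 3L) stop("expected exactly three replicate calls")
  if (all(calls == "activation") || all(calls == "inhibition")) return("active_match")
  if (all(calls == "inactive")) return("inactive_match")
  if ("activation" %in% calls && "inhibition" %in% calls) return("mismatch")
  "inconclusive"
}

#' Assay reproducibility score and grade
#'
#' score = 2 x %active match + %inactive match - %inconclusive -
#' 2 x %mismatch. Active matches are double-weighted because reproducing an
#' active call is the harder and more informative event in a sparse
#' screen, so the score can exceed 100. Grades: A for score >= 90, B for
#' 80 <= score < 90, C for 70 <= score < 80, D below 70.
#'
#' @param rates named percentages as returned by [triplicate_rates()]
#'   (must sum to 100).
#' @return list with `score` and `grade`.
#' @export
reproducibility_score <- function(rates) {
  need <- c("active_match", "inactive_match", "inconclusive", "mismatch")
  if (!all(need %in% names(rates))) {
    stop("need rates named: ", paste(need, collapse = ", "))
  }
  rates <- rates[need]
  if (any(rates < 0)) stop("rates must be non-negative")
  if (abs(sum(rates) - 100) > 1e-6) stop("rates must sum to 100")
  score <- 2 * rates[["active_match"]] + rates[["inactive_match"]] -
    rates[["inconclusive"]] - 2 * rates[["mismatch"]]
  grade <- if (score >= 90) "A" else if (score >= 80) "B" else if (score >= 70) "C" else "D"
  list(score = score, grade = grade)
}

#' Reproducibility report for all assays of a triplicate table
#'
#' @param table a [triplicate_call_table()].
#' @return data.frame with one row per assay: the four rates, score, grade.
#' @export
qc_report <- function(table) {
  stopifnot(inherits(table, "triplicate_calls"))
  assays <- unique(table$assay_id)
  do.call(rbind, lapply(assays, function(a) {
    r <- triplicate_rates(table, a)
    s <- reproducibility_score(r)
    data.frame(
      assay_id = a,
      pct_active_match = r[["active_match"]],
      pct_inactive_match = r[["inactive_match"]],
      pct_inconclusive = r[["inconclusive"]],
      pct_mismatch = r[["mismatch"]],
      score = s$score, grade = s$grade,
      stringsAsFactors = FALSE
    )
  }))
}
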