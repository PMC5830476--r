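# Small fixture builders shared across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_matrix <- function(values, nrow, compounds = NULL, features = NULL, block = "assay") {
  m <- matrix(values, nrow = nrow, byrow = TRUE)
  dimnames(m) <- list(
    compounds %||% paste0("c", seq_len(nrow(m))),
    features %||% paste0("f", seq_len(ncol(m)))
  )
  feature_matrix(m, block_label = block)
}

# Random 0/1 matrix with dimnames, optionally with missing values.
random_block <- function(n, m, p = 0.3, missing = 0, block = "assay", seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rbinom(n * m, 1L, p), n, m,
      dimnames = list(paste0("c", seq_len(n)), paste0("f", seq_len(m)))
    )
    if (missing > 0) x[matrix(runif(n * m) < missing, n, m)] <- NA_integer_
    feature_matrix(x, block_label = block)
  })
}

random_labels <- function(n, k, p = 0.3, seed = 2) {
  withr::with_seed(seed, {
    ade_label_matrix(matrix(rbinom(n * k, 1L, p), n, k,
      dimnames = list(paste0("c", seq_len(n)), paste0("ade", seq_len(k)))
    ))
  })
}

# Exhaustive hypergeometric upper-tail oracle for the one-sided Fisher
# enrichment p: P(X >= x) with X ~ Hypergeom(K present, N-K absent, n1 drawn),
# summed term by term from choose() -- independent of phyper().
hyper_tail_oracle <- function(x, K, N, n1) {
  kk <- seq(x, min(K, n1))
  sum(choose(K, kk) * choose(N - K, n1 - kk)) / choose(N, n1)
}

# O(n^2) pairwise-concordance oracle for the AUC.
auc_concordance_oracle <- function(scores, labels) {
  sp <- scores[labels == 1L]
  sn <- scores[labels == 0L]
  total <- 0
  for (a in sp) total <- total + sum(a > sn) + 0.5 * sum(a == sn)
  total / (length(sp) * length(sn))
}

# Hand-built fingerprint for worked WFS examples.
fingerprint_from <- function(p, ade_id = "ade", universe = NULL) {
  structure(p,
    ade_id = ade_id,
    universe = universe %||% union(names(p), paste0("u", seq_len(4L))),
    class = "feature_fingerprint"
  )
}
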