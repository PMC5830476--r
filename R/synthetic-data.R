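#' Configuration for the synthetic ADE dataset generator
#'
#' The generator emulates the statistical structure of a qHTS
#' pharmacovigilance dataset: sparse binary compound features linked to
#' multi-label adverse-effect outcomes through a latent compound-target
#' interaction matrix. Assay readouts report a subset of the targets with
#' call noise and missingness; DTA columns annotate true interactions
#' incompletely but without false positives; structure bits reflect latent
#' scaffolds that bias target interactions; animal endpoints are noisy
#' reporters of small target subsets. Causal targets of each ADE are biased
#' toward the *unassayed* targets, so annotation data genuinely expand the
#' biological space covered by the assays.
#'
#' @param n_compounds,n_targets,n_assayed_targets,n_readouts,n_dtas,n_fingerprint_bits,n_ades,n_animal_endpoints dimensions.
#' @param p_interact baseline per (compound, target) interaction probability.
#' @param flip_noise probability an assay call is flipped.
#' @param missing_rate probability an assay value is masked missing.
#' @param dta_coverage probability a true interaction is annotated.
#' @param ade_background baseline ADE probability.
#' @param ade_link ADE probability increment per causal target hit
#'   (capped at 1 overall).
#' @param targets_per_ade number of causal targets per ADE.
#' @param unassayed_bias sampling weight placed on unassayed targets when
#'   drawing causal targets (0.8 means 80% of the weight mass).
#' @param n_scaffolds,p_scaffold,scaffold_bias,targets_per_scaffold latent
#'   scaffold structure: membership probability, interaction-probability
#'   boost for scaffold-linked targets, and targets linked per scaffold.
#' @param bit_noise flip probability for structure fingerprint bits.
#' @param targets_per_animal_endpoint,animal_noise,animal_missing animal
#'   endpoint reporters: targets per endpoint, flip noise, missing rate.
#' @param seed integer random seed; the generator derives one sub-stream
#'   per matrix so adding a block never perturbs the others.
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(n_compounds = 300L,
                             n_targets = 50L,
                             n_assayed_targets = 15L,
                             n_readouts = 30L,
                             n_dtas = 50L,
                             n_fingerprint_bits = 64L,
                             n_ades = 20L,
                             n_animal_endpoints = 12L,
                             p_interact = 0.12,
                             flip_noise = 0.05,
                             missing_rate = 0.02,
                             dta_coverage = 0.9,
                             ade_background = 0.05,
                             ade_link = 0.6,
                             targets_per_ade = 2L,
                             unassayed_bias = 0.8,
                             n_scaffolds = 12L,
                             p_scaffold = 0.08,
                             scaffold_bias = 0.25,
                             targets_per_scaffold = 2L,
                             bit_noise = 0.1,
                             targets_per_animal_endpoint = 2L,
                             animal_noise = 0.1,
                             animal_missing = 0.05,
                             seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(
    "p_interact", "flip_noise", "missing_rate", "dta_coverage",
    "ade_background", "ade_link", "unassayed_bias", "p_scaffold",
    "scaffold_bias", "bit_noise", "animal_noise", "animal_missing"
  )
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || v < 0 || v > 1) stop(sprintf("`%s` must be in [0, 1]", p))
  }
  counts <- c(
    "n_compounds", "n_targets", "n_assayed_targets", "n_readouts", "n_dtas",
    "n_fingerprint_bits", "n_ades", "n_animal_endpoints", "targets_per_ade",
    "n_scaffolds", "targets_per_scaffold", "targets_per_animal_endpoint"
  )
  for (p in counts) {
    v <- cfg[[p]]
    if (!is.numeric(v) || v < 1 || v != round(v)) stop(sprintf("`%s` must be a positive integer", p))
    cfg[[p]] <- as.integer(v)
  }
  if (cfg$n_assayed_targets > cfg$n_targets) stop("n_assayed_targets must be <= n_targets")
  if (cfg$targets_per_ade > cfg$n_targets) stop("targets_per_ade must be <= n_targets")
  if (cfg$targets_per_scaffold > cfg$n_targets) stop("targets_per_scaffold must be <= n_targets")
  if (cfg$targets_per_animal_endpoint > cfg$n_targets) {
    stop("targets_per_animal_endpoint must be <= n_targets")
  }
  if (cfg$n_readouts < cfg$n_assayed_targets) {
    stop("n_readouts must be >= n_assayed_targets (every assayed target needs a readout)")
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "generator_config")
}

pad_ids <- function(prefix, n) sprintf("%s%0*d", prefix, nchar(as.character(n)), seq_len(n))

# One deterministic sub-seed per matrix, drawn up front from the global
# seed; component k always receives the same sub-seed regardless of which
# other blocks are generated.
derive_subseeds <- function(seed, n = 12L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  sample.int(.Machine$integer.max - 1L, n)
}

rbern_mat <- function(n, m, p, dimnames = NULL) {
  matrix(as.integer(stats::runif(n * m) < p), n, m, dimnames = dimnames)
}

#' Generate a linked synthetic ADE modeling dataset
#'
#' Draws every matrix of the pipeline from one latent compound-target
#' interaction model (see [generator_config()] for the mechanism) and
#' returns them together with the ground truth needed for recovery tests.
#' Fully reproducible from the config seed.
#'
#' @param config a [generator_config()].
#' @return object of class `synthetic_dataset`: list with feature blocks
#'   `assay`, `dta`, `structure`, `animal` (each a [feature_matrix()]),
#'   labels `ades` (an [ade_label_matrix()]), `truth` (latent interaction
#'   matrix, readout/DTA target maps, per-ADE causal targets, scaffold
#'   structure), and `config`.
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  seeds <- derive_subseeds(cfg$seed)
  compounds <- pad_ids("C", cfg$n_compounds)
  targets <- pad_ids("T", cfg$n_targets)

  # latent scaffolds and their target links
  old <- local_seed(seeds[1L])
  scaffolds <- rbern_mat(cfg$n_compounds, cfg$n_scaffolds, cfg$p_scaffold,
    list(compounds, pad_ids("S", cfg$n_scaffolds)))
  scaffold_targets <- lapply(seq_len(cfg$n_scaffolds), function(s) {
    sample(targets, cfg$targets_per_scaffold)
  })
  restore_seed(old)

  # latent compound x target interactions: baseline coin flips, with the
  # probability boosted for scaffold-linked (compound, target) pairs
  old <- local_seed(seeds[2L])
  linked <- matrix(0L, cfg$n_compounds, cfg$n_targets, dimnames = list(compounds, targets))
  for (s in seq_len(cfg$n_scaffolds)) {
    linked[scaffolds[, s] == 1L, scaffold_targets[[s]]] <- 1L
  }
  p_mat <- pmin(1, cfg$p_interact + cfg$scaffold_bias * linked)
  interactions <- matrix(
    as.integer(stats::runif(length(p_mat)) < p_mat),
    cfg$n_compounds, cfg$n_targets, dimnames = list(compounds, targets)
  )
  restore_seed(old)

  # assay readouts: each maps to an assayed target; value = interaction
  # XOR flip noise, then masked missing
  old <- local_seed(seeds[3L])
  readout_target <- targets[((seq_len(cfg$n_readouts) - 1L) %% cfg$n_assayed_targets) + 1L]
  assay_vals <- interactions[, readout_target, drop = FALSE]
  flips <- rbern_mat(cfg$n_compounds, cfg$n_readouts, cfg$flip_noise)
  assay_vals <- as.integer(xor(assay_vals == 1L, flips == 1L)) |>
    matrix(cfg$n_compounds, cfg$n_readouts)
  mask <- rbern_mat(cfg$n_compounds, cfg$n_readouts, cfg$missing_rate)
  assay_vals[mask == 1L] <- NA_integer_
  dimnames(assay_vals) <- list(compounds, pad_ids("R", cfg$n_readouts))
  names(readout_target) <- colnames(assay_vals)
  restore_seed(old)

  # DTA columns: annotate true interactions with probability dta_coverage,
  # never annotate non-interactions
  old <- local_seed(seeds[4L])
  dta_target <- targets[((seq_len(cfg$n_dtas) - 1L) %% cfg$n_targets) + 1L]
  keep <- rbern_mat(cfg$n_compounds, cfg$n_dtas, cfg$dta_coverage)
  dta_vals <- interactions[, dta_target, drop = FALSE] * keep
  dimnames(dta_vals) <- list(compounds, pad_ids("DTA", cfg$n_dtas))
  names(dta_target) <- colnames(dta_vals)
  restore_seed(old)

  # ADE labels: causal targets drawn with weight biased toward unassayed
  # targets; noisy-OR-like additive link with capping
  old <- local_seed(seeds[5L])
  assayed <- targets %in% targets[seq_len(cfg$n_assayed_targets)]
  w <- ifelse(assayed, 1 - cfg$unassayed_bias, cfg$unassayed_bias)
  ade_ids <- pad_ids("ADE", cfg$n_ades)
  ade_targets <- lapply(ade_ids, function(a) sample(targets, cfg$targets_per_ade, prob = w))
  names(ade_targets) <- ade_ids
  ade_vals <- vapply(ade_targets, function(tt) {
    hits <- rowSums(interactions[, tt, drop = FALSE])
    p <- pmin(1, cfg$ade_background + cfg$ade_link * hits)
    as.integer(stats::runif(cfg$n_compounds) < p)
  }, integer(cfg$n_compounds))
  dimnames(ade_vals) <- list(compounds, ade_ids)
  restore_seed(old)

  # structure fingerprint bits: noisy reporters of scaffold membership
  old <- local_seed(seeds[6L])
  bit_scaffold <- ((seq_len(cfg$n_fingerprint_bits) - 1L) %% cfg$n_scaffolds) + 1L
  bit_vals <- scaffolds[, bit_scaffold, drop = FALSE]
  bflips <- rbern_mat(cfg$n_compounds, cfg$n_fingerprint_bits, cfg$bit_noise)
  bit_vals <- matrix(as.integer(xor(bit_vals == 1L, bflips == 1L)),
    cfg$n_compounds, cfg$n_fingerprint_bits,
    dimnames = list(compounds, pad_ids("FP", cfg$n_fingerprint_bits))
  )
  restore_seed(old)

  # animal endpoints: noisy any-hit reporters of random target subsets
  old <- local_seed(seeds[7L])
  animal_targets <- lapply(seq_len(cfg$n_animal_endpoints), function(e) {
    sample(targets, cfg$targets_per_animal_endpoint)
  })
  animal_vals <- vapply(animal_targets, function(tt) {
    as.integer(rowSums(interactions[, tt, drop = FALSE]) > 0L)
  }, integer(cfg$n_compounds))
  aflips <- rbern_mat(cfg$n_compounds, cfg$n_animal_endpoints, cfg$animal_noise)
  animal_vals <- matrix(as.integer(xor(animal_vals == 1L, aflips == 1L)),
    cfg$n_compounds, cfg$n_animal_endpoints)
  amask <- rbern_mat(cfg$n_compounds, cfg$n_animal_endpoints, cfg$animal_missing)
  animal_vals[amask == 1L] <- NA_integer_
  dimnames(animal_vals) <- list(compounds, pad_ids("AX", cfg$n_animal_endpoints))
  names(animal_targets) <- colnames(animal_vals)
  restore_seed(old)

  structure(
    list(
      assay = feature_matrix(assay_vals, "assay"),
      dta = feature_matrix(dta_vals, "dta"),
      structure = feature_matrix(bit_vals, "structure"),
      animal = feature_matrix(animal_vals, "animal"),
      ades = ade_label_matrix(ade_vals),
      truth = list(
        interactions = interactions,
        readout_target = readout_target,
        dta_target = dta_target,
        ade_targets = ade_targets,
        scaffold_membership = scaffolds,
        scaffold_targets = scaffold_targets,
        animal_targets = animal_targets,
        assayed_targets = targets[seq_len(cfg$n_assayed_targets)]
      ),
      config = cfg
    ),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d compounds; %d readouts, %d DTAs, %d bits, %d animal endpoints, %d ADEs (seed %d)\n",
    x$config$n_compounds, x$config$n_readouts, x$config$n_dtas,
    x$config$n_fingerprint_bits, x$config$n_animal_endpoints,
    x$config$n_ades, x$config$seed
  ))
  invisible(x)
}

#' Generate triplicate activity calls with replicate noise
#'
#' Simulates screening each assay against three copies of the compound
#' library: a latent true call per (compound, assay) is drawn from the
#' state frequencies, then each replicate reports the latent call, or with
#' probability `call_noise` flips to one of the other states (uniformly).
#'
#' @param config a [generator_config()] (supplies compound/assay counts and
#'   the seed).
#' @param call_noise per-replicate probability of reporting a wrong state.
#' @param states call states in use; defaults to activation / inhibition /
#'   inactive.
#' @param state_probs latent frequencies of the states (sums to 1); the
#'   default gives ~6% active calls, matching sparse qHTS screens.
#' @return a [triplicate_call_table()].
#' @export
generate_triplicates <- function(config, call_noise = 0.05,
                                 states = c("activation", "inhibition", "inactive"),
                                 state_probs = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (call_noise < 0 || call_noise > 1) stop("`call_noise` must be in [0, 1]")
  stopifnot(length(states) >= 2L, all(states %in% TRIPLICATE_CALLS))
  if (is.null(state_probs)) {
    state_probs <- c(0.03, 0.03, 0.94)[seq_along(states)]
    state_probs <- state_probs / sum(state_probs)
  }
  stopifnot(length(state_probs) == length(states), abs(sum(state_probs) - 1) < 1e-9)
  seeds <- derive_subseeds(config$seed)
  old <- local_seed(seeds[8L])
  on.exit(restore_seed(old))
  compounds <- pad_ids("C", config$n_compounds)
  assays <- pad_ids("A", config$n_readouts)
  grid <- expand.grid(
    compound_id = compounds, assay_id = assays,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  latent <- sample(states, nrow(grid), replace = TRUE, prob = state_probs)
  reps <- lapply(1:3, function(r) {
    flip <- stats::runif(nrow(grid)) < call_noise
    call <- latent
    if (any(flip)) {
      call[flip] <- vapply(latent[flip], function(s) {
        sample(setdiff(states, s), 1L)
      }, character(1L))
    }
    data.frame(grid, replicate = r, call = call, stringsAsFactors = FALSE)
  })
  triplicate_call_table(do.call(rbind, reps))
}

#' Write a synthetic dataset to a directory
#'
#' Writes the five matrices as CSV (missing values as empty cells) plus the
#' latent ground truth as JSON, so a run can be archived or consumed by
#' other tools.
#'
#' @param dataset a [generate_synthetic()] result.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in c("assay", "dta", "structure", "animal")) {
    write_matrix_file(dataset[[b]], file.path(dir, paste0(b, ".csv")))
  }
  write_matrix_file(dataset$ades, file.path(dir, "ades.csv"))
  truth <- dataset$truth
  truth$interactions <- list(
    compound_ids = rownames(truth$interactions),
    target_ids = colnames(truth$interactions),
    values = unname(apply(truth$interactions, 1L, paste0, collapse = ""))
  )
  truth$scaffold_membership <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
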