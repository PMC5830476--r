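#' Experiment configuration
#'
#' Describes a full model-set comparison run: where the data come from
#' (a [generator_config()] or paths to CSV/TSV matrices), which feature
#' blocks each model set concatenates, the split plan, and optional
#' permutation-null settings. Model sets reference blocks by name
#' (`"assay"`, `"dta"`, `"structure"`, `"animal"`); the special name
#' `"dta_selected"` means the DTA block restricted to the features passing
#' the univariate screen at `dta_threshold`.
#'
#' @param generator a [generator_config()], or `NULL` when `paths` given.
#' @param paths named list of input files (`assay`, `dta`, `structure`,
#'   `animal`, `ades`), or `NULL` when generating.
#' @param model_sets named list; each element a character vector of block
#'   names to concatenate.
#' @param n_splits,split_fraction,seed split-plan settings.
#' @param n_perm label-permutation replicates (0 disables the null).
#' @param permute_dta if `TRUE`, also run the combined model with a
#'   row-permuted DTA block to test whether combined-model gains survive.
#' @param dta_threshold,readout_threshold univariate screen thresholds.
#' @param output_dir directory for result CSVs, or `NULL` to skip writing.
#' @return validated list of class `experiment_config`.
#' @export
experiment_config <- function(generator = generator_config(),
                              paths = NULL,
                              model_sets = list(
                                assay = "assay",
                                `assay+dta` = c("assay", "dta")
                              ),
                              n_splits = 10L,
                              split_fraction = 0.5,
                              seed = 1L,
                              n_perm = 0L,
                              permute_dta = FALSE,
                              dta_threshold = 0.6,
                              readout_threshold = 0.65,
                              output_dir = NULL) {
  if (is.null(generator) && is.null(paths)) stop("need `generator` or `paths`")
  if (!is.null(paths)) {
    if (!("ades" %in% names(paths))) stop("`paths` must include 'ades'")
    missing <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(missing) > 0L) {
      stop("input path(s) do not exist: ", paste(missing, collapse = ", "))
    }
  }
  if (length(model_sets) < 1L) stop("define at least one model set")
  if (is.null(names(model_sets)) || any(names(model_sets) == "")) {
    stop("`model_sets` must be a named list")
  }
  known <- c("assay", "dta", "structure", "animal", "dta_selected")
  bad <- setdiff(unlist(model_sets), known)
  if (length(bad) > 0L) stop("unknown block name(s): ", paste(bad, collapse = ", "))
  structure(
    list(
      generator = generator, paths = paths, model_sets = model_sets,
      n_splits = as.integer(n_splits), split_fraction = split_fraction,
      seed = as.integer(seed), n_perm = as.integer(n_perm),
      permute_dta = isTRUE(permute_dta),
      dta_threshold = dta_threshold, readout_threshold = readout_threshold,
      output_dir = output_dir
    ),
    class = "experiment_config"
  )
}

#' Load an experiment configuration from YAML or JSON
#'
#' @param path config file; `generator` and all [experiment_config()]
#'   fields are accepted as top-level keys.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$generator)) raw$generator <- do.call(generator_config, raw$generator)
  if (!is.null(raw$model_sets)) raw$model_sets <- lapply(raw$model_sets, unlist)
  do.call(experiment_config, raw)
}

load_blocks <- function(config) {
  if (!is.null(config$paths)) {
    p <- config$paths
    blocks <- list()
    for (b in c("assay", "dta", "structure", "animal")) {
      if (!is.null(p[[b]])) blocks[[b]] <- read_feature_matrix(p[[b]], block_label = b)
    }
    list(blocks = blocks, labels = read_ade_labels(p$ades), truth = NULL)
  } else {
    ds <- generate_synthetic(config$generator)
    list(
      blocks = list(assay = ds$assay, dta = ds$dta,
        structure = ds$structure, animal = ds$animal),
      labels = ds$ades, truth = ds$truth
    )
  }
}

#' Run a configured model-set comparison experiment
#'
#' Loads or generates the data, aligns every block with the ADE labels,
#' concatenates the blocks of each model set, evaluates each set with the
#' shared repeated-holdout plan, and compares the sets by one-way ANOVA
#' with Bonferroni post hoc tests. Optionally adds a label-permutation
#' null for the first model set and a DTA-row-permutation control for the
#' first combined set containing `"dta"`. When `output_dir` is set, writes
#' tidy per-split results, a model-set summary table (best AUC, mean AUC,
#' ADEs above 0.75), the comparison table, and a JSON run log with every
#' seed used.
#'
#' @param config an [experiment_config()].
#' @return list with `summaries` (per model set), `results` (per-split
#'   data.frames), `comparison` ([compare_model_sets()] output, `NULL` for
#'   a single set), `label_null`, `dta_permutation`, `selected_dtas`,
#'   `plan`, and `summary_table` (one row per model set).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  dat <- load_blocks(config)
  al <- align_compounds(dat$blocks, dat$labels)
  blocks <- al$blocks
  labels <- al$labels
  plan <- split_plan(rownames(labels),
    n_splits = config$n_splits,
    split_fraction = config$split_fraction, seed = config$seed
  )

  selected_dtas <- NULL
  if ("dta_selected" %in% unlist(config$model_sets)) {
    if (is.null(blocks$dta)) stop("model sets reference 'dta_selected' but no DTA block is present")
    screen <- univariate_eval(blocks$dta, labels, threshold = config$dta_threshold)
    selected_dtas <- select_features(screen)
    if (length(selected_dtas) == 0L) {
      stop("univariate screen selected no DTAs; cannot build 'dta_selected' model sets")
    }
    blocks$dta_selected <- feature_matrix(
      unclass(blocks$dta)[, selected_dtas, drop = FALSE], "dta"
    )
  }

  results <- list()
  summaries <- list()
  for (ms in names(config$model_sets)) {
    parts <- config$model_sets[[ms]]
    absent <- parts[vapply(parts, function(b) is.null(blocks[[b]]), logical(1L))]
    if (length(absent) > 0L) {
      stop(sprintf("model set '%s' references missing block(s): %s",
        ms, paste(absent, collapse = ", ")))
    }
    feats <- if (length(parts) == 1L) {
      blocks[[parts]]
    } else {
      cbind_blocks(blocks[parts], block_label = paste(parts, collapse = "+"))
    }
    res <- run_repeated_holdout(feats, labels, plan)
    results[[ms]] <- res
    summaries[[ms]] <- summarize_model_set(res, model_label = ms)
  }

  comparison <- if (length(summaries) >= 2L) compare_model_sets(summaries)

  label_null <- NULL
  if (config$n_perm > 0L) {
    first <- names(config$model_sets)[1L]
    parts <- config$model_sets[[first]]
    feats <- if (length(parts) == 1L) blocks[[parts]] else cbind_blocks(blocks[parts])
    label_null <- permutation_null(feats, labels, plan,
      n_perm = config$n_perm, seed = config$seed + 1L
    )
  }

  dta_perm <- NULL
  if (config$permute_dta) {
    combined <- Filter(function(p) "dta" %in% p && length(p) > 1L, config$model_sets)
    if (length(combined) > 0L) {
      parts <- combined[[1L]]
      b2 <- blocks[parts]
      b2$dta <- permute_feature_block(b2$dta, seed = config$seed + 2L)
      res <- run_repeated_holdout(cbind_blocks(b2), labels, plan)
      dta_perm <- summarize_model_set(res, model_label = paste0(names(combined)[1L], " (DTA permuted)"))
    }
  }

  summary_table <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(
      model = s$model_label, n_ades = nrow(s$per_ade),
      best_auc = s$best_auc, mean_auc = s$grand_mean_auc,
      ades_above_0.75 = s$n_above_0.75, stringsAsFactors = FALSE
    )
  }))
  rownames(summary_table) <- NULL

  out <- list(
    summaries = summaries, results = results, comparison = comparison,
    label_null = label_null, dta_permutation = dta_perm,
    selected_dtas = selected_dtas, plan = plan,
    summary_table = summary_table, truth = dat$truth
  )
  if (!is.null(config$output_dir)) write_experiment(out, config)
  out
}

write_experiment <- function(out, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  od <- config$output_dir
  for (ms in names(out$results)) {
    utils::write.csv(out$results[[ms]],
      file.path(od, paste0("results_", gsub("[^A-Za-z0-9_]+", "_", ms), ".csv")),
      row.names = FALSE
    )
  }
  utils::write.csv(out$summary_table, file.path(od, "model_set_summary.csv"), row.names = FALSE)
  if (!is.null(out$comparison)) {
    utils::write.csv(out$comparison$pairwise, file.path(od, "model_set_comparison.csv"),
      row.names = FALSE)
  }
  if (!is.null(out$selected_dtas)) {
    utils::write.csv(data.frame(feature_id = out$selected_dtas),
      file.path(od, "selected_dtas.csv"), row.names = FALSE)
  }
  log <- list(
    seed = config$seed, n_splits = config$n_splits,
    split_fraction = config$split_fraction, n_perm = config$n_perm,
    model_sets = config$model_sets,
    label_null_p = if (!is.null(out$label_null)) out$label_null$p_value,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(log, file.path(od, "run_log.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(od)
}
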