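test_that("generator configs validate probabilities and counts", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(p_interact = 1.2), "must be in \\[0, 1\\]")
  expect_error(generator_config(flip_noise = -0.1), "must be in \\[0, 1\\]")
  expect_error(generator_config(n_ades = 0), "positive integer")
  expect_error(generator_config(n_assayed_targets = 99, n_targets = 50), "<= n_targets")
  expect_error(generator_config(targets_per_ade = 99), "<= n_targets")
})

test_that("same seed gives identical datasets; different seeds differ", {
  cfg <- generator_config(n_compounds = 60, n_ades = 5, seed = 123)
  d1 <- generate_synthetic(cfg)
  d2 <- generate_synthetic(cfg)
  expect_identical(d1, d2)
  d3 <- generate_synthetic(generator_config(n_compounds = 60, n_ades = 5, seed = 124))
  expect_false(identical(unclass(d1$assay), unclass(d3$assay)))
})

test_that("all matrices share one compound set and truth matches the config", {
  cfg <- generator_config(n_compounds = 50, n_ades = 6, seed = 3)
  ds <- generate_synthetic(cfg)
  ids <- rownames(ds$assay)
  for (b in list(ds$dta, ds$structure, ds$animal, ds$ades)) {
    expect_identical(rownames(b), ids)
  }
  expect_identical(dim(ds$truth$interactions), c(cfg$n_compounds, cfg$n_targets))
  expect_length(ds$truth$ade_targets, cfg$n_ades)
  expect_true(all(lengths(ds$truth$ade_targets) == cfg$targets_per_ade))
  # annotation blocks carry no missing values
  expect_false(anyNA(ds$dta))
  expect_false(anyNA(ds$structure))
})

test_that("in the noiseless limit DTA columns equal the readouts of assayed targets", {
  ds <- generate_synthetic(generator_config(
    flip_noise = 0, missing_rate = 0, dta_coverage = 1,
    n_compounds = 80, seed = 5
  ))
  for (r in colnames(ds$assay)) {
    t <- ds$truth$readout_target[[r]]
    dtas <- names(ds$truth$dta_target)[ds$truth$dta_target == t]
    expect_identical(unname(unclass(ds$assay)[, r]), unname(ds$truth$interactions[, t]))
    for (d in dtas) {
      expect_identical(unname(unclass(ds$dta)[, d]), unname(unclass(ds$assay)[, r]))
    }
  }
})

test_that("DTA columns never annotate non-interactions", {
  ds <- generate_synthetic(generator_config(n_compounds = 100, seed = 6))
  for (d in colnames(ds$dta)) {
    t <- ds$truth$dta_target[[d]]
    expect_true(all(unclass(ds$dta)[, d] <= ds$truth$interactions[, t]))
  }
})

test_that("empirical rates match config probabilities within binomial error", {
  # 10,000 Bernoulli draws per check; tolerance ~4 SD of a binomial proportion
  cfg <- generator_config(
    n_compounds = 500, n_ades = 4, scaffold_bias = 0, p_scaffold = 0,
    missing_rate = 0.05, seed = 77
  )
  ds <- generate_synthetic(cfg)
  tol <- function(p, n) 4 * sqrt(p * (1 - p) / n)

  n_cells <- prod(dim(ds$truth$interactions))
  p_hat <- mean(ds$truth$interactions)
  expect_lt(abs(p_hat - cfg$p_interact), tol(cfg$p_interact, n_cells))

  miss_hat <- mean(is.na(ds$assay))
  n_assay <- prod(dim(ds$assay))
  expect_lt(abs(miss_hat - cfg$missing_rate), tol(cfg$missing_rate, n_assay))

  # flip noise: disagreement between a readout and its source target
  agree <- mapply(function(r, t) {
    obs <- !is.na(unclass(ds$assay)[, r])
    mean(unclass(ds$assay)[obs, r] != ds$truth$interactions[obs, t])
  }, colnames(ds$assay), ds$truth$readout_target)
  expect_lt(abs(mean(agree) - cfg$flip_noise), tol(cfg$flip_noise, n_assay))

  # DTA coverage among true interactions
  cov_num <- 0
  cov_den <- 0
  for (d in colnames(ds$dta)) {
    t <- ds$truth$dta_target[[d]]
    inter <- ds$truth$interactions[, t] == 1L
    cov_num <- cov_num + sum(unclass(ds$dta)[inter, d])
    cov_den <- cov_den + sum(inter)
  }
  expect_lt(abs(cov_num / cov_den - cfg$dta_coverage), tol(cfg$dta_coverage, cov_den))
})

test_that("a dataset with no feature-ADE link yields chance-level models", {
  ds <- generate_synthetic(generator_config(
    ade_link = 0, n_compounds = 200, n_ades = 10, seed = 15
  ))
  plan <- split_plan(rownames(ds$ades), n_splits = 5, seed = 15)
  s <- summarize_model_set(run_repeated_holdout(ds$assay, ds$ades, plan))
  expect_lt(abs(s$grand_mean_auc - 0.5), 0.04)
})

test_that("raising assay flip noise degrades assay-only models", {
  mean_auc_at <- function(noise) {
    ds <- generate_synthetic(generator_config(
      flip_noise = noise, unassayed_bias = 0, n_compounds = 250,
      n_ades = 10, seed = 20
    ))
    plan <- split_plan(rownames(ds$ades), n_splits = 5, seed = 20)
    summarize_model_set(run_repeated_holdout(ds$assay, ds$ades, plan))$grand_mean_auc
  }
  expect_gt(mean_auc_at(0.02), mean_auc_at(0.35))
})

test_that("dataset files round-trip through the directory writer", {
  ds <- generate_synthetic(generator_config(n_compounds = 30, n_ades = 3, seed = 2))
  dir <- withr::local_tempdir()
  write_synthetic_dataset(ds, dir)
  expect_identical(
    unclass(read_feature_matrix(file.path(dir, "assay.csv"), "assay")),
    unclass(ds$assay)
  )
  expect_identical(
    unclass(read_ade_labels(file.path(dir, "ades.csv"))),
    unclass(ds$ades)
  )
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_identical(truth$interactions$compound_ids, rownames(ds$assay))
})

test_that("triplicate generation is seeded and respects the noise model", {
  cfg <- generator_config(n_compounds = 40, n_readouts = 15, seed = 30)
  t0 <- generate_triplicates(cfg, call_noise = 0)
  expect_s3_class(t0, "triplicate_calls")
  # noiseless: all three calls identical for every (compound, assay)
  agree <- tapply(t0$call, list(t0$compound_id, t0$assay_id), function(v) length(unique(v)))
  expect_true(all(agree == 1L))

  expect_identical(generate_triplicates(cfg, call_noise = 0.2),
    generate_triplicates(cfg, call_noise = 0.2))

  # two call states at noise 0.5: replicates are independent coin flips, so
  # the probability all three agree is 2 * (1/2)^3 = 1/4 (chance level)
  cfg_big <- generator_config(n_compounds = 150, n_readouts = 15, seed = 31)
  t5 <- generate_triplicates(cfg_big,
    call_noise = 0.5,
    states = c("activation", "inactive"), state_probs = c(0.5, 0.5)
  )
  match_rate <- mean(
    tapply(t5$call, list(t5$compound_id, t5$assay_id), function(v) length(unique(v)) == 1L)
  )
  expect_lt(abs(match_rate - 0.25), 0.03)
})
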