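test_that("simulation is deterministic under a fixed config", {
  cfg <- sim_config(n_subjects = 50, organs = c("brain", "liver"),
                    n_proteins_per_organ = 3, n_background_proteins = 5,
                    seed = 11)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  cfg2 <- sim_config(n_subjects = 50, organs = c("brain", "liver"),
                     n_proteins_per_organ = 3, n_background_proteins = 5,
                     seed = 12)
  expect_false(identical(simulate_cohort(cfg)$cohort,
                         simulate_cohort(cfg2)$cohort))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(age_min = 70, age_max = 37), "age_min")
  expect_error(sim_config(organs = c("brain", "brain")), "unique")
  expect_error(sim_config(missing_rate = 1.5), "missing_rate")
  expect_error(sim_config(offset_sd = -1), "offset_sd")
  expect_error(sim_config(n_subjects = 0), "n_subjects")
})

test_that("demographics match the study design", {
  subj <- simulate_subjects(sim_config(n_subjects = 500, seed = 3))
  expect_equal(nrow(subj), 500)
  expect_true(all(subj$age >= 37 & subj$age <= 70))
  expect_s3_class(subj$sex, "factor")
  expect_true(all(c("bmi", "deprivation") %in% names(subj)))
  # degenerate age range
  const <- simulate_subjects(sim_config(n_subjects = 20, age_min = 50,
                                        age_max = 50, seed = 3))
  expect_true(all(const$age == 50))
})

test_that("default organ list covers the ten organ systems", {
  cfg <- sim_config()
  expect_setequal(cfg$organs,
                  c("brain", "heart", "lung", "immune", "artery",
                    "intestine", "liver", "kidney", "muscle", "pancreas"))
})

test_that("planted tissue enrichment is recoverable by the fold rule", {
  cfg <- sim_config(n_subjects = 10, n_proteins_per_organ = 4,
                    n_background_proteins = 20, expr_noise_sd = 0, seed = 5)
  tex <- simulate_tissue_expression(cfg)
  organ_expr <- collapse_tissues_to_organs(tex$discovery, tex$tissue_map)
  ann <- call_enriched(organ_expr, fold_threshold = 4)
  truth <- tex$truth$enriched_protein_labels
  got <- ann[!is.na(ann$organ), ]
  expect_setequal(got$protein_id, truth$protein_id)
  expect_identical(got$organ[match(truth$protein_id, got$protein_id)],
                   truth$organ)
})

test_that("nothing exceeds fourfold when no enrichment is planted", {
  cfg <- sim_config(n_subjects = 10, n_proteins_per_organ = 0,
                    n_background_proteins = 30, expr_noise_sd = 0.2, seed = 5)
  tex <- simulate_tissue_expression(cfg)
  ann <- call_enriched(
    collapse_tissues_to_organs(tex$discovery, tex$tissue_map))
  expect_true(all(is.na(ann$organ)))
})

test_that("noise-free proteome is an exact affine function of age + offset", {
  cfg <- sim_config(n_subjects = 40, organs = "brain",
                    n_proteins_per_organ = 1, frac_age_informative = 1,
                    nonlinear_fraction = 0, n_background_proteins = 0,
                    noise_sd = 0, missing_rate = 0, seed = 9)
  subj <- simulate_subjects(cfg)
  prot <- simulate_proteome(subj, NULL, cfg)
  p <- prot$truth$protein_params[prot$truth$protein_params$informative, ]
  eff_age <- subj$age + prot$truth$organ_offsets$brain
  vals <- prot$cohort[[p$protein_id]]
  # two-point slope recovery
  slope_hat <- (vals[2] - vals[1]) / (eff_age[2] - eff_age[1])
  expect_equal(slope_hat, p$slope, tolerance = 1e-10)
  expect_equal(vals, p$intercept + p$slope * eff_age, tolerance = 1e-10)
})

test_that("zero slope range leaves no age correlation beyond a permutation null", {
  cfg <- sim_config(n_subjects = 400, organs = "brain",
                    n_proteins_per_organ = 15, frac_age_informative = 1,
                    slope_range = 0, n_background_proteins = 15,
                    missing_rate = 0, seed = 13)
  subj <- simulate_subjects(cfg)
  prot <- simulate_proteome(subj, NULL, cfg)
  m <- as.matrix(prot$cohort[, prot$truth$protein_params$protein_id])
  obs <- max(abs(cor(subj$age, m)))
  null_max <- withr::with_seed(1, {
    replicate(100, max(abs(cor(sample(subj$age), m))))
  })
  expect_lte(obs, quantile(null_max, 0.99))
})

test_that("missingness rate matches its binomial expectation", {
  cfg <- sim_config(n_subjects = 1000, organs = "brain",
                    n_proteins_per_organ = 50, n_background_proteins = 50,
                    missing_rate = 0.1, seed = 17)
  prot <- simulate_proteome(simulate_subjects(cfg), NULL, cfg)
  m <- as.matrix(prot$cohort[, prot$truth$protein_params$protein_id])
  expect_equal(mean(is.na(m)), 0.1, tolerance = 0.01)
})

test_that("latent offsets have the configured moments", {
  cfg <- sim_config(n_subjects = 2000, organs = c("brain", "heart"),
                    n_proteins_per_organ = 2, n_background_proteins = 0,
                    offset_sd = 3, seed = 19)
  prot <- simulate_proteome(simulate_subjects(cfg), NULL, cfg)
  off <- prot$truth$organ_offsets$brain
  se_mean <- 3 / sqrt(2000)
  expect_lt(abs(mean(off)), 3 * se_mean)
  se_sd <- 3 / sqrt(2 * (2000 - 1))
  expect_lt(abs(sd(off) - 3), 3 * se_sd)
})

test_that("ground truth closes over every planted signal", {
  sim <- small_sim()
  truth <- sim$truth
  expect_true(all(truth$informative_proteins$protein_id %in%
                    truth$enriched_protein_labels$protein_id))
  # informative proteins belong to their own organ's enriched set
  joined <- merge(truth$informative_proteins,
                  truth$enriched_protein_labels, by = "protein_id")
  expect_identical(joined$organ.x, joined$organ.y)
  expect_identical(colnames(truth$organ_offsets)[-1], sim$config$organs)
  expect_true(all(truth$protein_params$slope[
    !truth$protein_params$informative] == 0))
})

test_that("survival outcomes respect the censoring horizon", {
  cfg_short <- sim_config(
    n_subjects = 800, organs = "brain", n_proteins_per_organ = 2,
    n_background_proteins = 0, seed = 23,
    outcome_specs = list(outcome_spec("death", "survival",
                                     baseline_hazard = 0.03, horizon = 5)))
  cfg_long <- sim_config(
    n_subjects = 800, organs = "brain", n_proteins_per_organ = 2,
    n_background_proteins = 0, seed = 23,
    outcome_specs = list(outcome_spec("death", "survival",
                                      baseline_hazard = 0.03, horizon = 15)))
  p_short <- simulate_proteome(simulate_subjects(cfg_short), NULL, cfg_short)
  out_short <- simulate_outcomes(simulate_subjects(cfg_short),
                                 p_short$truth, cfg_short)
  out_long <- simulate_outcomes(simulate_subjects(cfg_long),
                                p_short$truth, cfg_long)
  expect_true(all(out_short$time <= 5))
  expect_lt(mean(out_short$event), mean(out_long$event))
})

test_that("nonpositive baseline hazard is rejected", {
  expect_error(outcome_spec("bad", "survival", baseline_hazard = 0),
               "baseline_hazard")
})

test_that("written simulation files round-trip as text", {
  dir <- withr::local_tempdir()
  sim <- small_sim()
  write_simulation(sim, dir)
  expect_true(all(file.exists(file.path(
    dir, c("tissue_discovery.tsv", "cohort.tsv", "outcomes.tsv",
           "truth.json")))))
  back <- utils::read.delim(file.path(dir, "cohort.tsv"))
  expect_equal(nrow(back), nrow(sim$cohort))
})
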