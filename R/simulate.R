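#' Specify a simulated outcome
#'
#' Describes one outcome generated by [simulate_outcomes()]: either a
#' right-censored survival outcome drawn from an exponential
#' proportional-hazards model, or a binary label drawn from a logistic model.
#' In both cases the linear predictor is `sum_g beta_g * offset_g / offset_sd`
#' over latent per-organ aging offsets, plus optional covariate effects, so
#' the stated coefficients are log-hazard (or log-odds) ratios per one
#' standard deviation of the latent offsets.
#'
#' @param name Outcome name.
#' @param type `"survival"` or `"binary"`.
#' @param beta Named numeric vector of per-1-s.d. coefficients, one entry per
#'   organ (missing organs get 0).
#' @param baseline_hazard Baseline hazard per year (survival outcomes; must be
#'   positive).
#' @param horizon Administrative censoring horizon in years.
#' @param intercept Logistic intercept (binary outcomes).
#' @param covariate_beta Named numeric vector of effects on the listed
#'   demographic covariates (applied to raw covariate values).
#' @return An `outcome_spec` list.
#' @export
outcome_spec <- function(name, type = c("survival", "binary"), beta = numeric(),
                         baseline_hazard = 0.024, horizon = 15,
                         intercept = -2, covariate_beta = numeric()) {
  type <- match.arg(type)
  if (type == "survival" && baseline_hazard <= 0) {
    abort("`baseline_hazard` must be positive")
  }
  structure(
    list(name = name, type = type, beta = beta,
         baseline_hazard = baseline_hazard, horizon = horizon,
         intercept = intercept, covariate_beta = covariate_beta),
    class = "outcome_spec"
  )
}

default_outcome_specs <- function() {
  # Headline-scale effects: mortality-like HR 1.44 and dementia-like HR 1.88
  # per 1 s.d. of the brain offset, plus a binary cognitive-transition label.
  list(
    outcome_spec("mortality", "survival", beta = c(brain = log(1.44)),
                 baseline_hazard = 0.024, horizon = 15),
    outcome_spec("dementia", "survival", beta = c(brain = log(1.88)),
                 baseline_hazard = 0.012, horizon = 15),
    outcome_spec("mci", "binary", beta = c(brain = 0.5), intercept = -2)
  )
}

#' Simulation configuration
#'
#' Collects every parameter of the synthetic cohort generator: tissue
#' expression structure, demographics, protein trajectories, latent per-organ
#' aging offsets, missingness and outcome models. Defaults describe a
#' population cohort with a 37-70 year baseline age range and the ten organ
#' systems (brain, heart, lung, immune, artery, intestine, liver, kidney,
#' muscle, pancreas) used throughout the package.
#'
#' @param n_subjects Number of subjects.
#' @param age_min,age_max Age range in years (uniform sampling).
#' @param organs Character vector of unique organ names.
#' @param n_proteins_per_organ Planted organ-enriched proteins per organ.
#' @param n_background_proteins Age-independent background proteins.
#' @param frac_age_informative Fraction of each organ's enriched proteins
#'   carrying an age signal.
#' @param slope_range Maximum |slope| of the linear age trend, in log2 units
#'   per year; slopes are drawn uniformly from `[slope_range/2, slope_range]`
#'   with random sign.
#' @param nonlinear_fraction Fraction of informative proteins that also get an
#'   accelerating (quadratic-ramp) trajectory.
#' @param nonlinear_onset Age (years) at which the quadratic ramp starts.
#' @param offset_sd Standard deviation (years) of the latent per-organ aging
#'   offset.
#' @param noise_sd Residual s.d. of protein values, log2 units.
#' @param missing_rate Probability that any protein entry is missing
#'   (completely at random).
#' @param planted_fold Expression fold planted for enriched genes in their own
#'   organ's tissues.
#' @param expr_noise_sd Lognormal sigma of multiplicative tissue-expression
#'   noise (0 = noise-free).
#' @param tissues_per_organ Tissue subtypes per organ (>= 2).
#' @param outcome_specs List of [outcome_spec()] objects.
#' @param seed Master seed; one sub-stream per generator stage is derived
#'   from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_subjects = 2000,
                       age_min = 37, age_max = 70,
                       organs = c("brain", "heart", "lung", "immune",
                                  "artery", "intestine", "liver", "kidney",
                                  "muscle", "pancreas"),
                       n_proteins_per_organ = 10,
                       n_background_proteins = 100,
                       frac_age_informative = 0.5,
                       slope_range = 0.04,
                       nonlinear_fraction = 0.2,
                       nonlinear_onset = 55,
                       offset_sd = 3,
                       noise_sd = 0.5,
                       missing_rate = 0.02,
                       planted_fold = 8,
                       expr_noise_sd = 0.2,
                       tissues_per_organ = 2,
                       outcome_specs = default_outcome_specs(),
                       seed = 1) {
  assert_count(n_subjects, "n_subjects")
  if (!is.numeric(age_min) || !is.numeric(age_max) || age_min > age_max) {
    abort("`age_min` must be <= `age_max`")
  }
  if (length(organs) == 0 || anyDuplicated(organs) > 0) {
    abort("`organs` must be nonempty and unique")
  }
  assert_count(n_proteins_per_organ, "n_proteins_per_organ", min = 0)
  assert_count(n_background_proteins, "n_background_proteins", min = 0)
  assert_count(tissues_per_organ, "tissues_per_organ", min = 1)
  assert_fraction(frac_age_informative, "frac_age_informative")
  assert_fraction(nonlinear_fraction, "nonlinear_fraction")
  assert_fraction(missing_rate, "missing_rate")
  if (offset_sd < 0) abort("`offset_sd` must be >= 0")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (planted_fold <= 1) abort("`planted_fold` must exceed 1")
  stopifnot(all(vapply(outcome_specs, inherits, logical(1), "outcome_spec")))
  structure(
    list(n_subjects = as.integer(n_subjects), age_min = age_min,
         age_max = age_max, organs = organs,
         n_proteins_per_organ = as.integer(n_proteins_per_organ),
         n_background_proteins = as.integer(n_background_proteins),
         frac_age_informative = frac_age_informative,
         slope_range = slope_range,
         nonlinear_fraction = nonlinear_fraction,
         nonlinear_onset = nonlinear_onset,
         offset_sd = offset_sd, noise_sd = noise_sd,
         missing_rate = missing_rate, planted_fold = planted_fold,
         expr_noise_sd = expr_noise_sd,
         tissues_per_organ = as.integer(tissues_per_organ),
         outcome_specs = outcome_specs, seed = as.integer(seed)),
    class = "sim_config"
  )
}

sim_protein_ids <- function(config) {
  enriched <- unlist(lapply(config$organs, function(o) {
    if (config$n_proteins_per_organ == 0) return(character())
    sprintf("%s_p%02d", o, seq_len(config$n_proteins_per_organ))
  }))
  background <- if (config$n_background_proteins > 0) {
    sprintf("bg_p%03d", seq_len(config$n_background_proteins))
  } else character()
  list(enriched = enriched, background = background)
}

#' Simulate tissue-expression matrices with planted organ enrichment
#'
#' Generates a discovery-like and a confirmation-like gene-by-tissue
#' expression matrix. Each planted enriched gene is expressed `planted_fold`
#' times higher (before noise) in its own organ's tissue subtypes than
#' anywhere else, in both matrices; background genes are near-uniform.
#' Multiplicative lognormal noise (`expr_noise_sd`) is drawn independently per
#' matrix. The tissue-to-organ map and the planted labels are returned so
#' downstream enrichment calling can be scored against the truth.
#'
#' @param config A [sim_config()].
#' @return A list with `discovery` and `confirmation` (wide tibbles,
#'   `gene_id` + one column per tissue), `tissue_map` (tibble: tissue, organ),
#'   and `truth` (list carrying `enriched_protein_labels`).
#' @export
simulate_tissue_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$organs) == 0) abort("no organs configured")
  ids <- sim_protein_ids(config)
  genes <- c(ids$enriched, ids$background)
  if (length(genes) == 0) abort("no genes to simulate")
  tissue_map <- tidyr::expand_grid(
    organ = config$organs, sub = seq_len(config$tissues_per_organ)
  ) |>
    mutate(tissue = sprintf("%s_t%d", .data$organ, .data$sub)) |>
    select("tissue", "organ")

  labels <- tibble(
    protein_id = genes,
    organ = c(rep(config$organs, each = config$n_proteins_per_organ),
              rep(NA_character_, length(ids$background)))
  )

  with_seed(stage_seed(config$seed, "tissue"), {
    base <- runif(length(genes), 0.5, 2)
    make_matrix <- function() {
      vals <- outer(base, rep(1, nrow(tissue_map)))
      target <- outer(labels$organ, tissue_map$organ, `==`)
      target[is.na(target)] <- FALSE
      vals[target] <- vals[target] * config$planted_fold
      if (config$expr_noise_sd > 0) {
        vals <- vals * exp(matrix(rnorm(length(vals), 0, config$expr_noise_sd),
                                  nrow(vals)))
      }
      colnames(vals) <- tissue_map$tissue
      bind_cols(tibble(gene_id = genes), as_tibble(vals))
    }
    discovery <- make_matrix()
    confirmation <- make_matrix()
  })

  list(discovery = discovery, confirmation = confirmation,
       tissue_map = tissue_map,
       truth = list(enriched_protein_labels = labels |> filter(!is.na(.data$organ)),
                    background_proteins = ids$background))
}

#' Simulate cohort demographics
#'
#' Ages are uniform on the configured range, sex is balanced Bernoulli, and
#' two continuous covariates (body-mass-index-like and a deprivation-like
#' index) are drawn per subject. Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return Tibble: subject_id, age, sex, bmi, deprivation.
#' @export
simulate_subjects <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  if (n <= 0) abort("`n_subjects` must be positive")
  with_seed(stage_seed(config$seed, "subjects"), {
    tibble(
      subject_id = sprintf("S%05d", seq_len(n)),
      age = runif(n, config$age_min, config$age_max),
      sex = factor(ifelse(rbinom(n, 1, 0.5) == 1, "male", "female"),
                   levels = c("female", "male")),
      bmi = rnorm(n, 27, 4),
      deprivation = rnorm(n, 0, 1)
    )
  })
}

#' Simulate the plasma proteome
#'
#' Draws latent per-organ aging offsets `Normal(0, offset_sd)` per subject,
#' then generates protein values on a log2 relative scale: an informative
#' protein of organ g follows
#' `intercept + slope * (age + offset_g)` plus, for an accelerating subset, a
#' quadratic ramp beginning at `nonlinear_onset`, plus Gaussian noise.
#' Background proteins are age-independent noise. Entries are then set
#' missing completely at random at `missing_rate`. All generating parameters
#' are recorded in the returned truth.
#'
#' @param subjects Demographics from [simulate_subjects()].
#' @param truth Truth list from [simulate_tissue_expression()] (planted
#'   enrichment labels); may be `NULL` when only the proteome is needed.
#' @param config A [sim_config()].
#' @return List: `cohort` (wide tibble, demographics + one column per
#'   protein) and `truth` extended with `organ_offsets`,
#'   `informative_proteins` and `protein_params`.
#' @export
simulate_proteome <- function(subjects, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- sim_protein_ids(config)
  genes <- c(ids$enriched, ids$background)
  organ_of <- c(rep(config$organs, each = config$n_proteins_per_organ),
                rep(NA_character_, length(ids$background)))
  n <- nrow(subjects)

  with_seed(stage_seed(config$seed, "proteome"), {
    offsets <- matrix(rnorm(n * length(config$organs), 0, config$offset_sd),
                      n, length(config$organs),
                      dimnames = list(NULL, config$organs))
    n_info <- round(config$frac_age_informative * config$n_proteins_per_organ)
    informative <- unlist(lapply(config$organs, function(o) {
      own <- genes[!is.na(organ_of) & organ_of == o]
      if (n_info == 0) return(character())
      sort(sample(own, n_info))
    }))
    params <- tibble(
      protein_id = genes,
      organ = organ_of,
      informative = genes %in% informative,
      intercept = rnorm(length(genes), 0, 1),
      slope = 0, ramp = 0
    )
    k <- sum(params$informative)
    if (k > 0) {
      sign <- sample(c(-1, 1), k, replace = TRUE)
      params$slope[params$informative] <-
        sign * runif(k, config$slope_range / 2, config$slope_range)
      nl <- which(params$informative)[
        as.logical(rbinom(k, 1, config$nonlinear_fraction))]
      # Convex acceleration after onset, same sign as the linear trend.
      params$ramp[nl] <- params$slope[nl] / 20
    }
    values <- matrix(rnorm(n * length(genes), 0, config$noise_sd),
                     n, length(genes), dimnames = list(NULL, genes))
    for (j in seq_along(genes)) {
      p <- params[j, ]
      eff_age <- if (!is.na(p$organ)) subjects$age + offsets[, p$organ]
                 else subjects$age
      values[, j] <- values[, j] + p$intercept + p$slope * eff_age +
        p$ramp * pmax(0, eff_age - config$nonlinear_onset)^2
    }
    if (config$missing_rate > 0) {
      values[matrix(rbinom(length(values), 1, config$missing_rate) == 1,
                    nrow(values))] <- NA_real_
    }
  })

  truth <- truth %||% list()
  truth$organ_offsets <- bind_cols(
    tibble(subject_id = subjects$subject_id), as_tibble(offsets))
  truth$protein_params <- params
  truth$informative_proteins <- params |>
    filter(.data$informative) |> select("protein_id", "organ")
  truth$offset_sd <- config$offset_sd

  list(cohort = bind_cols(subjects, as_tibble(values)), truth = truth)
}

#' Simulate survival and binary outcomes
#'
#' Survival outcomes follow an exponential proportional-hazards model whose
#' linear predictor is the sum of the configured per-1-s.d. coefficients
#' applied to the latent organ offsets (standardised by the generating
#' `offset_sd`), plus any covariate effects; times are administratively
#' censored at the horizon. Binary outcomes follow a logistic model with the
#' same linear predictor.
#'
#' @param subjects Demographics table.
#' @param truth Truth list carrying `organ_offsets` (from
#'   [simulate_proteome()]).
#' @param config A [sim_config()] with nonempty `outcome_specs`.
#' @return Tibble: subject_id, outcome, type, event (0/1), time (years; `NA`
#'   for binary outcomes).
#' @export
simulate_outcomes <- function(subjects, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$outcome_specs) == 0) abort("`outcome_specs` is empty")
  offsets <- as.matrix(truth$organ_offsets[, config$organs, drop = FALSE])
  z <- if (config$offset_sd > 0) offsets / config$offset_sd else offsets * 0
  n <- nrow(subjects)

  with_seed(stage_seed(config$seed, "outcomes"), {
    purrr::map_dfr(config$outcome_specs, function(spec) {
      lp <- rep(0, n)
      for (o in names(spec$beta)) {
        if (!o %in% colnames(z)) abort(paste0("unknown organ in beta: ", o))
        lp <- lp + spec$beta[[o]] * z[, o]
      }
      for (cv in names(spec$covariate_beta)) {
        lp <- lp + spec$covariate_beta[[cv]] * subjects[[cv]]
      }
      if (spec$type == "survival") {
        if (spec$baseline_hazard <= 0) abort("nonpositive baseline hazard")
        t_event <- rexp(n, rate = spec$baseline_hazard * exp(lp))
        tibble(subject_id = subjects$subject_id, outcome = spec$name,
               type = "survival",
               event = as.integer(t_event <= spec$horizon),
               time = pmin(t_event, spec$horizon))
      } else {
        p <- plogis(spec$intercept + lp)
        tibble(subject_id = subjects$subject_id, outcome = spec$name,
               type = "binary", event = rbinom(n, 1, p), time = NA_real_)
      }
    })
  })
}

#' Simulate a full synthetic study
#'
#' Runs the four generator stages (tissue expression, demographics, proteome,
#' outcomes) under independent sub-streams of the master seed and bundles the
#' results with the complete ground truth.
#'
#' @param config A [sim_config()].
#' @return An `aging_cohort_sim` list: `tissue` (discovery/confirmation
#'   matrices + tissue map), `cohort`, `outcomes`, `truth`, `protein_ids`,
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  tissue <- simulate_tissue_expression(config)
  subjects <- simulate_subjects(config)
  prot <- simulate_proteome(subjects, tissue$truth, config)
  outcomes <- simulate_outcomes(subjects, prot$truth, config)
  ids <- sim_protein_ids(config)
  structure(
    list(tissue = tissue[c("discovery", "confirmation", "tissue_map")],
         cohort = prot$cohort, outcomes = outcomes, truth = prot$truth,
         protein_ids = c(ids$enriched, ids$background), config = config),
    class = "aging_cohort_sim"
  )
}

#' @export
print.aging_cohort_sim <- function(x, ...) {
  cat("Synthetic aging cohort\n")
  cat(sprintf("  subjects: %d  proteins: %d  organs: %d\n",
              nrow(x$cohort), length(x$protein_ids),
              length(x$config$organs)))
  cat(sprintf("  outcomes: %s\n",
              paste(unique(x$outcomes$outcome), collapse = ", ")))
  invisible(x)
}

#' Write a simulated study to delimited text files
#'
#' Exports the discovery/confirmation expression matrices, the tissue map and
#' the wide cohort table as TSV, the outcomes as TSV, and the ground truth as
#' JSON, into `dir`.
#'
#' @param sim An `aging_cohort_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "aging_cohort_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(sim$tissue$discovery, "tissue_discovery.tsv")
  w(sim$tissue$confirmation, "tissue_confirmation.tsv")
  w(sim$tissue$tissue_map, "tissue_map.tsv")
  w(sim$cohort, "cohort.tsv")
  w(sim$outcomes, "outcomes.tsv")
  truth <- sim$truth
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}
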