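#' Run the full organ-aging pipeline on a simulated study
#'
#' End-to-end driver: simulate a study, map proteins to organs (fourfold
#' enrichment with confirmation), preprocess the cohort (missingness QC,
#' 0-1 rescale + median centering), train the requested clocks, sparsify the
#' organismal clock by SHAP-guided RFE, derive aging phenotypes, and run the
#' Cox association family of age gaps against the simulated outcomes with
#' FDR control. Fully deterministic given the configuration (which carries
#' the master seed).
#'
#' @param config A [sim_config()].
#' @param space A [clock_search_space()]; desk-scale defaults.
#' @param organs Clocks to train: `"organismal"` and/or organ names with
#'   confirmed enriched proteins.
#' @param retention RFE retention fraction for [choose_panel()].
#' @param run_rfe Sparsify the organismal clock (default TRUE).
#' @param covariates Covariates for the association models.
#' @return An `aging_pipeline` list: `sim`, `annotations`, `qc`, `clocks`
#'   (named list of `organ_clock`), `rfe` (path + panel, or NULL),
#'   `phenotypes`, `burden`, `associations`.
#' @export
run_pipeline <- function(config = sim_config(),
                         space = clock_search_space(),
                         organs = "organismal",
                         retention = 0.85, run_rfe = TRUE,
                         covariates = c("age", "sex")) {
  sim <- simulate_cohort(config)

  organ_expr <- collapse_tissues_to_organs(sim$tissue$discovery,
                                           sim$tissue$tissue_map)
  ann <- call_enriched(organ_expr)
  ann <- confirm_enrichment(ann, sim$tissue$confirmation,
                            tissue_map = sim$tissue$tissue_map)

  prep <- preprocess_cohort(sim$cohort)

  clocks <- list()
  for (org in organs) {
    candidates <- if (org == "organismal") prep$proteins else {
      intersect(ann$protein_id[ann$organ == org], prep$proteins)
    }
    if (length(candidates) < 2) {
      warn(sprintf("organ '%s' has < 2 candidate proteins; skipped", org))
      next
    }
    clocks[[org]] <- train_clock(prep$cohort, candidates, organ = org,
                                 space = space, seed = config$seed)
  }
  if (length(clocks) == 0) abort("no clock could be trained")

  rfe <- NULL
  if (run_rfe && "organismal" %in% names(clocks) &&
      length(clocks$organismal$selected_proteins) >= 2) {
    cl <- clocks$organismal
    train <- prep$cohort[prep$cohort$subject_id %in% cl$train_ids, ]
    path <- rfe_shap(train, cl$selected_proteins,
                     cl$hyperparameters$final, k = space$k_folds,
                     seed = config$seed)
    rfe <- list(path = path, panel = choose_panel(path, retention))
  }

  predictions <- purrr::imap_dfr(clocks, function(cl, org) {
    cl$oof |> mutate(organ = org) |>
      select("subject_id", "organ", "proteomic_age")
  })
  pheno <- derive_phenotypes(predictions, sim$cohort)

  gap_wide <- pheno$phenotypes |>
    select("subject_id", "organ", "age_gap") |>
    tidyr::pivot_wider(names_from = "organ", values_from = "age_gap",
                       names_prefix = "gap_")
  surv <- sim$outcomes |> filter(.data$type == "survival")
  assoc <- NULL
  if (nrow(surv) > 0) {
    wide_outcomes <- surv |>
      tidyr::pivot_wider(id_cols = "subject_id", names_from = "outcome",
                         values_from = c("event", "time"))
    analysis <- sim$cohort |>
      select("subject_id", "age", "sex", "bmi", "deprivation") |>
      inner_join(gap_wide, by = "subject_id") |>
      inner_join(wide_outcomes, by = "subject_id")
    fam <- tibble(outcome = unique(surv$outcome), type = "survival",
                  time = paste0("time_", unique(surv$outcome)),
                  event = paste0("event_", unique(surv$outcome)))
    assoc <- run_associations(analysis, fam,
                              exposures = names(gap_wide)[-1],
                              covariates = covariates)
  }

  structure(
    list(sim = sim, annotations = ann, qc = prep$report,
         scaling = prep$params, clocks = clocks, rfe = rfe,
         phenotypes = pheno$phenotypes, burden = pheno$burden,
         gap_models = pheno$models, associations = assoc,
         config = config),
    class = "aging_pipeline"
  )
}

#' @export
print.aging_pipeline <- function(x, ...) {
  cat("Organ aging pipeline\n")
  cat(sprintf("  clocks: %s\n", paste(names(x$clocks), collapse = ", ")))
  for (cl in x$clocks) {
    cat(sprintf("    %-12s r = %.3f  (%d proteins)\n", cl$organ,
                cl$evaluation$r, length(cl$selected_proteins)))
  }
  if (!is.null(x$rfe)) {
    cat(sprintf("  refined panel: %d proteins (r2 %.3f vs full %.3f)\n",
                x$rfe$panel$size, x$rfe$panel$r2, x$rfe$panel$full_r2))
  }
  invisible(x)
}
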