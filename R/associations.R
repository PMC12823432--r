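#' Cox proportional-hazards association per 1 s.d.
#'
#' Standardises the exposure by its analysis-sample standard deviation and
#' maximises the Cox partial likelihood (Efron tie convention) with the
#' given covariates, so the reported hazard ratio is per one standard
#' deviation of the exposure. Non-convergence or separation is flagged
#' rather than raising, so flagged rows can be excluded from an FDR family.
#'
#' @param data Tibble with time, event, exposure and covariate columns.
#' @param time,event Column names of follow-up time and the 0/1 event
#'   indicator.
#' @param exposure Exposure column name.
#' @param covariates Character vector of covariate column names.
#' @param outcome Label stored in the result.
#' @param min_events Minimum number of events required (default 10).
#' @return One-row tibble: outcome, exposure, estimate (HR per 1 s.d.),
#'   conf.low, conf.high, log_hr, se, z, p, n, n_events, flagged. The fitted
#'   `coxph` object is attached as attribute `"fit"`.
#' @export
fit_cox <- function(data, time, event, exposure, covariates = character(),
                    outcome = event, min_events = 10) {
  d <- data[stats::complete.cases(data[, c(time, event, exposure, covariates)]), ]
  n_events <- sum(d[[event]])
  if (n_events < min_events) {
    abort(sprintf("only %d events (< %d required)", n_events, min_events))
  }
  d$.exposure_z <- d[[exposure]] / sd(d[[exposure]])
  rhs <- paste(c(".exposure_z", covariates), collapse = " + ")
  fml <- as.formula(sprintf("survival::Surv(%s, %s) ~ %s", time, event, rhs))
  flagged <- FALSE
  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph(fml, data = d, ties = "efron"),
      warning = function(w) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    res <- tibble(outcome = outcome, exposure = exposure,
                  estimate = NA_real_, conf.low = NA_real_,
                  conf.high = NA_real_, log_hr = NA_real_, se = NA_real_,
                  z = NA_real_, p = NA_real_, n = nrow(d),
                  n_events = n_events, flagged = TRUE)
    return(res)
  }
  s <- summary(fit)
  b <- s$coefficients[".exposure_z", ]
  res <- tibble(
    outcome = outcome, exposure = exposure,
    estimate = unname(b["exp(coef)"]),
    conf.low = exp(unname(b["coef"]) - 1.96 * unname(b["se(coef)"])),
    conf.high = exp(unname(b["coef"]) + 1.96 * unname(b["se(coef)"])),
    log_hr = unname(b["coef"]), se = unname(b["se(coef)"]),
    z = unname(b["z"]), p = unname(b["Pr(>|z|)"]),
    n = nrow(d), n_events = n_events, flagged = flagged
  )
  attr(res, "fit") <- fit
  res
}

#' Logistic association per 1 s.d.
#'
#' Maximum-likelihood logistic regression of a binary label on the
#' standardised exposure plus covariates; the odds ratio is per one standard
#' deviation of the exposure. Separation (fitted probabilities of 0/1) is
#' flagged.
#'
#' @inheritParams fit_cox
#' @param label Column name of the 0/1 outcome label.
#' @return One-row tibble with `estimate` holding the OR per 1 s.d.; the
#'   fitted `glm` is attached as attribute `"fit"`.
#' @export
fit_logistic <- function(data, label, exposure, covariates = character(),
                         outcome = label) {
  d <- data[stats::complete.cases(data[, c(label, exposure, covariates)]), ]
  y <- d[[label]]
  if (length(unique(y)) < 2) abort("both outcome classes must be present")
  d$.exposure_z <- d[[exposure]] / sd(d[[exposure]])
  rhs <- paste(c(".exposure_z", covariates), collapse = " + ")
  fml <- as.formula(sprintf("%s ~ %s", label, rhs))
  flagged <- FALSE
  fit <- withCallingHandlers(
    glm(fml, data = d, family = binomial()),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  b <- summary(fit)$coefficients[".exposure_z", ]
  res <- tibble(
    outcome = outcome, exposure = exposure,
    estimate = exp(unname(b["Estimate"])),
    conf.low = exp(unname(b["Estimate"]) - 1.96 * unname(b["Std. Error"])),
    conf.high = exp(unname(b["Estimate"]) + 1.96 * unname(b["Std. Error"])),
    log_or = unname(b["Estimate"]), se = unname(b["Std. Error"]),
    z = unname(b["z value"]), p = unname(b["Pr(>|z|)"]),
    n = nrow(d), n_events = sum(y), flagged = flagged
  )
  attr(res, "fit") <- fit
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment within one declared family of
#' tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   propagated).
#' @return Vector of q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Schoenfeld-residual proportional-hazards check
#'
#' Tests the proportional-hazards assumption of a fitted Cox model (e.g. the
#' `"fit"` attribute of [fit_cox()]) via the scaled Schoenfeld residual
#' slope test.
#'
#' @param fit A `coxph` object.
#' @return Tibble: term, chisq, df, p.
#' @export
check_proportional_hazards <- function(fit) {
  zph <- survival::cox.zph(fit)
  tab <- zph$table
  tibble(term = rownames(tab), chisq = tab[, "chisq"], df = tab[, "df"],
         p = tab[, "p"])
}

#' Relative contribution of significant exposures
#'
#' Restricts one outcome's association results to FDR-significant terms and
#' scales their absolute z-scores to sum to one, giving each organ's (or
#' protein's) relative contribution to the outcome.
#'
#' @param results Association tibble for one outcome with `exposure`, `z`
#'   and `q` columns.
#' @param alpha FDR significance cutoff (default 0.05).
#' @return Tibble: exposure, z, weight (weights sum to 1); zero rows when no
#'   term is significant.
#' @export
relative_contribution <- function(results, alpha = 0.05) {
  if (length(unique(results$outcome)) > 1) {
    abort("results must share a single outcome")
  }
  sig <- results |> filter(!is.na(.data$q), .data$q < alpha, !.data$flagged)
  if (nrow(sig) == 0) {
    return(tibble(exposure = character(), z = numeric(), weight = numeric()))
  }
  sig |>
    mutate(weight = abs(.data$z) / sum(abs(.data$z))) |>
    select("exposure", "z", "weight")
}

#' Run an association family with FDR control
#'
#' Fits one model per outcome-exposure pair (Cox for survival outcomes,
#' logistic for binary labels) and applies Benjamini-Hochberg adjustment
#' within the family, excluding flagged (non-converged) fits from the
#' adjustment. The family definition is attached as attribute `"family"`.
#'
#' @param data Wide analysis tibble (one row per subject) holding exposures,
#'   covariates and, per outcome, time/event or label columns.
#' @param outcomes Tibble describing the family: columns `outcome`, `type`
#'   (`"survival"`/`"binary"`), `time`, `event` (column names; `event` doubles
#'   as the label column for binary outcomes).
#' @param exposures Character vector of exposure columns.
#' @param covariates Character vector of covariate columns.
#' @return Association tibble with a `q` column.
#' @export
run_associations <- function(data, outcomes, exposures,
                             covariates = character()) {
  res <- purrr::pmap_dfr(outcomes, function(outcome, type, time, event, ...) {
    purrr::map_dfr(exposures, function(ex) {
      if (type == "survival") {
        fit_cox(data, time = time, event = event, exposure = ex,
                covariates = covariates, outcome = outcome)
      } else {
        r <- fit_logistic(data, label = event, exposure = ex,
                          covariates = covariates, outcome = outcome)
        rename(r, log_hr = "log_or")
      }
    })
  })
  res$q <- NA_real_
  ok <- !res$flagged & !is.na(res$p)
  res$q[ok] <- bh_fdr(res$p[ok])
  attr(res, "family") <- list(outcomes = outcomes$outcome,
                              exposures = exposures,
                              covariates = covariates, m = sum(ok))
  res
}

#' Cognitive and distress transition labels
#'
#' Labels mild cognitive impairment (MCI) when a follow-up global cognitive
#' score falls 1.5 s.d. or more below the baseline mean of cognitively
#' normal participants within the subject's education stratum, and
#' psychological distress when a PHQ-4-like score is >= 6 (inclusive).
#' Strata with fewer than 2 reference subjects are skipped with a warning
#' (their members get `NA`).
#'
#' @param data Tibble with score, stratum and reference-flag columns.
#' @param score Column of the global cognitive score.
#' @param stratum Column of the education stratum.
#' @param reference Logical column flagging the baseline cognitively normal
#'   reference group whose mean/s.d. define each stratum's threshold.
#' @param distress_score Optional column of PHQ-4-like scores.
#' @param threshold_sd MCI threshold in reference s.d. (default 1.5).
#' @param distress_cutoff Distress cutoff (default 6, inclusive).
#' @return The tibble with `mci` (logical) and, when `distress_score` is
#'   given, `distress` added; per-stratum reference statistics attached as
#'   attribute `"reference_stats"`.
#' @export
define_transitions <- function(data, score, stratum, reference,
                               distress_score = NULL, threshold_sd = 1.5,
                               distress_cutoff = 6) {
  ref <- data[data[[reference]], ]
  stats_tbl <- ref |>
    group_by(stratum = .data[[stratum]]) |>
    summarise(ref_mean = mean(.data[[score]], na.rm = TRUE),
              ref_sd = sd(.data[[score]], na.rm = TRUE),
              n_ref = sum(!is.na(.data[[score]])), .groups = "drop")
  small <- stats_tbl$stratum[stats_tbl$n_ref < 2]
  if (length(small) > 0) {
    warn(paste0("stratum with < 2 reference subjects skipped: ",
                paste(small, collapse = ", ")))
    stats_tbl <- stats_tbl[!stats_tbl$stratum %in% small, ]
  }
  idx <- match(data[[stratum]], stats_tbl$stratum)
  thr <- stats_tbl$ref_mean[idx] - threshold_sd * stats_tbl$ref_sd[idx]
  out <- mutate(data, mci = .data[[score]] <= thr)
  if (!is.null(distress_score)) {
    out <- mutate(out, distress = .data[[distress_score]] >= distress_cutoff)
  }
  attr(out, "reference_stats") <- stats_tbl
  out
}

#' Multimorbidity labels
#'
#' A subject is multimorbid within a disease category (and in the combined
#' category) when they accumulate two or more incident diseases in it.
#'
#' @param incident Long tibble of incident diagnoses: `subject_id`,
#'   `disease`.
#' @param category_map Tibble mapping `disease` to `category`.
#' @param subjects Optional vector of all subject ids (so disease-free
#'   subjects appear with zero counts).
#' @return Tibble: subject_id, category (including `"combined"`),
#'   n_diseases, multimorbid.
#' @export
define_multimorbidity <- function(incident, category_map, subjects = NULL) {
  unmapped <- setdiff(incident$disease, category_map$disease)
  if (length(unmapped) > 0) {
    abort(paste0("diseases missing from `category_map`: ",
                 paste(unmapped, collapse = ", ")))
  }
  subjects <- subjects %||% unique(incident$subject_id)
  cats <- unique(category_map$category)
  tagged <- incident |>
    distinct(.data$subject_id, .data$disease) |>
    left_join(category_map, by = "disease")
  per_cat <- tidyr::expand_grid(subject_id = subjects,
                                category = c(cats, "combined")) |>
    left_join(
      bind_rows(
        tagged |> dplyr::count(.data$subject_id, .data$category,
                               name = "n_diseases"),
        tagged |> dplyr::count(.data$subject_id, name = "n_diseases") |>
          mutate(category = "combined")
      ),
      by = c("subject_id", "category")
    ) |>
    mutate(n_diseases = dplyr::coalesce(.data$n_diseases, 0L),
           multimorbid = .data$n_diseases >= 2)
  per_cat
}

#' Match controls to cases by age and sex
#'
#' For each case, samples up to `ratio` controls without replacement from
#' the pool, requiring `|age difference| <= age_tolerance` and (optionally)
#' identical sex. A control is never reused across cases. Cases with no
#' eligible control are reported in the `"unmatched"` attribute.
#'
#' @param cases Tibble of cases: `subject_id`, `age`, `sex`.
#' @param pool Tibble of candidate controls (must exclude subjects with the
#'   outcome), same columns.
#' @param ratio Controls per case (default 5).
#' @param age_tolerance Maximum |age difference| in years (default 2).
#' @param match_sex Require identical sex (default TRUE).
#' @param seed Integer seed.
#' @return Tibble: case_id, control_id, one row per matched control.
#' @export
match_controls <- function(cases, pool, ratio = 5, age_tolerance = 2,
                           match_sex = TRUE, seed = 1) {
  if (nrow(pool) == 0) abort("empty control pool")
  available <- rep(TRUE, nrow(pool))
  out <- list()
  unmatched <- character()
  with_seed(stage_seed(seed, "match"), {
    for (i in seq_len(nrow(cases))) {
      ok <- available & abs(pool$age - cases$age[i]) <= age_tolerance
      if (match_sex) ok <- ok & pool$sex == cases$sex[i]
      idx <- which(ok)
      if (length(idx) == 0) {
        unmatched <- c(unmatched, cases$subject_id[i])
        next
      }
      take <- if (length(idx) <= ratio) idx else sample(idx, ratio)
      available[take] <- FALSE
      out[[length(out) + 1]] <- tibble(case_id = cases$subject_id[i],
                                       control_id = pool$subject_id[take])
    }
  })
  res <- bind_rows(out)
  attr(res, "unmatched") <- unmatched
  res
}

# Mann-Whitney AUC from scores and 0/1 labels.
fast_auc <- function(score, label) {
  r <- rank(score, ties.method = "average")
  n1 <- sum(label == 1)
  n0 <- length(label) - n1
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Compare model discrimination by paired bootstrap
#'
#' Fits one logistic model per specification on the common subjects and
#' computes each model's AUC from the fitted scores. Pairwise AUC
#' differences are then assessed by a paired bootstrap over subjects
#' (`n_boot` resamples, default 2000) with the scores held fixed: the
#' two-sided p-value is the percentile position of zero in the bootstrap
#' distribution of the difference. Draws in which one class is absent are
#' redrawn (and counted). The percentile test calibrates correctly when the
#' compared models carry genuine signal; for exactly uninformative
#' predictors the data-driven orientation of the fit makes it conservative.
#'
#' @param data Analysis tibble.
#' @param label Column name of the 0/1 outcome.
#' @param model_specs Named list; each element is a character vector of
#'   predictor columns for one model.
#' @param n_boot Bootstrap iterations (default 2000).
#' @param seed Integer seed.
#' @return List: `auc` (tibble: model, auc), `pairwise` (tibble: model_a,
#'   model_b, auc_diff, p), `n_boot`, `n_redraws`.
#' @export
compare_auc <- function(data, label, model_specs, n_boot = 2000, seed = 1) {
  y <- data[[label]]
  if (length(unique(y)) < 2) abort("both outcome classes must be present")
  n <- length(y)
  # separation (AUC 1) is legitimate here; the fits are only scorers
  xmats <- purrr::map(model_specs, function(vars) {
    cbind(1, as.matrix(data[, vars, drop = FALSE]))
  })
  fit_score <- function(X, yy, idx) {
    fit <- suppressWarnings(
      stats::glm.fit(X[idx, , drop = FALSE], yy[idx], family = binomial()))
    cf <- coef(fit)
    cf[is.na(cf)] <- 0
    as.numeric(X[idx, , drop = FALSE] %*% cf)
  }
  all_idx <- seq_len(n)
  scores <- purrr::map(xmats, fit_score, yy = y, idx = all_idx)
  aucs <- vapply(scores, fast_auc, numeric(1), label = y)
  auc_tbl <- tibble(model = names(model_specs), auc = unname(aucs))
  pairwise <- NULL
  n_redraws <- 0L
  if (length(model_specs) > 1) {
    pairs <- utils::combn(names(model_specs), 2)
    boot_auc <- matrix(NA_real_, n_boot, length(model_specs),
                       dimnames = list(NULL, names(model_specs)))
    with_seed(stage_seed(seed, "boot"), {
      for (i in seq_len(n_boot)) {
        repeat {
          idx <- sample.int(n, n, replace = TRUE)
          if (length(unique(y[idx])) == 2) break
          n_redraws <- n_redraws + 1L
        }
        for (m in seq_along(scores)) {
          boot_auc[i, m] <- fast_auc(scores[[m]][idx], y[idx])
        }
      }
    })
    pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      d <- boot_auc[, pairs[1, j]] - boot_auc[, pairs[2, j]]
      p <- 2 * min(mean(d <= 0), mean(d >= 0))
      tibble(model_a = pairs[1, j], model_b = pairs[2, j],
             auc_diff = aucs[[pairs[1, j]]] - aucs[[pairs[2, j]]],
             p = min(p, 1))
    })
  }
  list(auc = auc_tbl, pairwise = pairwise, n_boot = n_boot,
       n_redraws = n_redraws)
}

#' Cumulative incidence by group
#'
#' One minus the Kaplan-Meier survivor estimate within each group, with
#' at-risk and event counts at every step. Empty groups are skipped with a
#' warning.
#'
#' @param data Analysis tibble.
#' @param time,event Column names of follow-up time and 0/1 event indicator.
#' @param group Column name of the grouping factor.
#' @return A `cuminc_curves` tibble: group, time, cuminc, n_risk, n_event.
#' @export
cumulative_incidence <- function(data, time, event, group) {
  g <- data[[group]]
  if (is.factor(g)) {
    empty <- levels(g)[table(g) == 0]
    if (length(empty) > 0) {
      warn(paste0("empty group(s) skipped: ", paste(empty, collapse = ", ")))
    }
    data <- data[!is.na(g), ]
    data[[group]] <- droplevels(data[[group]])
  }
  fml <- as.formula(sprintf("survival::Surv(%s, %s) ~ %s", time, event, group))
  sf <- survival::survfit(fml, data = data)
  strata <- if (is.null(sf$strata)) {
    rep(as.character(unique(data[[group]]))[1], length(sf$time))
  } else {
    rep(sub("^.*=", "", names(sf$strata)), sf$strata)
  }
  out <- tibble(group = strata, time = sf$time, cuminc = 1 - sf$surv,
                n_risk = sf$n.risk, n_event = sf$n.event)
  class(out) <- c("cuminc_curves", class(out))
  out
}

#' Lifestyle category from unhealthy-factor counts
#'
#' Maps the number of unhealthy lifestyle factors (0-9) to the categories
#' favorable (0-2), intermediate (3-5) and unfavorable (6-9).
#'
#' @param counts Integer vector of unhealthy-factor counts in `[0, 9]`.
#' @return Ordered factor with levels favorable < intermediate <
#'   unfavorable.
#' @export
lifestyle_category <- function(counts) {
  if (any(counts < 0 | counts > 9, na.rm = TRUE)) {
    abort("counts must lie in [0, 9]")
  }
  cut(counts, breaks = c(-0.5, 2.5, 5.5, 9.5),
      labels = c("favorable", "intermediate", "unfavorable"),
      ordered_result = TRUE)
}
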