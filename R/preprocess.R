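#' Decimal chronological age
#'
#' Computes age in decimal years as the number of calendar days between the
#' assigned birth date and the visit date, divided by 365.25. Only birth year
#' and month are assumed known; the first day of the birth month is assigned
#' as the birth date.
#'
#' @param birth_year_month Birth year-month, either `"YYYY-MM"` strings or
#'   `Date`s (day component ignored and reset to 1).
#' @param visit_date Visit date (`Date` or `"YYYY-MM-DD"` string).
#' @return Numeric vector of decimal ages in years.
#' @export
compute_decimal_age <- function(birth_year_month, visit_date) {
  birth <- if (inherits(birth_year_month, "Date")) {
    as.Date(format(birth_year_month, "%Y-%m-01"))
  } else {
    as.Date(paste0(as.character(birth_year_month), "-01"))
  }
  visit <- as.Date(visit_date)
  if (anyNA(birth) || anyNA(visit)) abort("unparseable dates")
  days <- as.numeric(visit - birth)
  if (any(days < 0)) abort("visit date precedes assigned birth date")
  days / 365.25
}

#' Filter proteins and subjects by missingness
#'
#' Drops proteins missing in strictly more than `protein_max` of subjects,
#' then subjects missing strictly more than `subject_max` of the retained
#' proteins (the boundary fractions are kept). The defaults mirror the usual
#' plasma-proteomics QC of excluding proteins missing in >20% of participants
#' and participants with >50% missing proteins.
#'
#' @param cohort Wide cohort tibble.
#' @param proteins Protein column names; default: every column other than
#'   `subject_id`, `age`, `sex` and any in `metadata`.
#' @param protein_max Maximum tolerated per-protein missing fraction.
#' @param subject_max Maximum tolerated per-subject missing fraction.
#' @param metadata Extra non-protein columns to ignore.
#' @return List: `cohort` (filtered), `proteins` (retained ids), `report`
#'   (list with dropped protein/subject tibbles and counts).
#' @export
filter_missingness <- function(cohort, proteins = NULL,
                               protein_max = 0.20, subject_max = 0.50,
                               metadata = c("bmi", "deprivation")) {
  assert_fraction(protein_max, "protein_max")
  assert_fraction(subject_max, "subject_max")
  proteins <- protein_columns(cohort, proteins,
                              exclude = c("subject_id", "age", "sex", metadata))
  m <- protein_matrix(cohort, proteins)
  prot_frac <- unname(colMeans(is.na(m)))
  drop_prot <- prot_frac > protein_max
  kept_prot <- proteins[!drop_prot]
  if (length(kept_prot) == 0) {
    abort("all proteins exceed the missingness threshold")
  }
  subj_frac <- rowMeans(is.na(m[, kept_prot, drop = FALSE]))
  drop_subj <- subj_frac > subject_max
  if (all(drop_subj)) abort("all subjects exceed the missingness threshold")
  report <- list(
    dropped_proteins = tibble(protein_id = proteins[drop_prot],
                              missing_fraction = prot_frac[drop_prot]),
    dropped_subjects = tibble(subject_id = cohort$subject_id[drop_subj],
                              missing_fraction = subj_frac[drop_subj]),
    n_proteins_in = length(proteins), n_proteins_kept = length(kept_prot),
    n_subjects_in = nrow(cohort), n_subjects_kept = sum(!drop_subj),
    protein_max = protein_max, subject_max = subject_max
  )
  list(
    cohort = cohort[!drop_subj,
                    c(setdiff(names(cohort), proteins), kept_prot)],
    proteins = kept_prot,
    report = report
  )
}

#' Rescale protein values to [0, 1] and centre on the median
#'
#' Per protein: `x' = (x - min) / (max - min)`, then `x'' = x' - median(x')`,
#' computed over non-missing values. Missing entries stay missing. Constant
#' proteins (undefined range) are dropped with a warning. The per-protein
#' scaling parameters are returned so an external cohort can be projected
#' with frozen training-set scaling.
#'
#' @param cohort Wide cohort tibble.
#' @param proteins Protein column names (default: inferred as in
#'   [filter_missingness()]).
#' @param params Optional scaling parameters from a previous call (frozen
#'   mode); when supplied they are applied as-is.
#' @param metadata Extra non-protein columns to ignore.
#' @return List: `cohort` (scaled), `proteins`, `params` (tibble:
#'   protein_id, min, max, median).
#' @export
scale_values <- function(cohort, proteins = NULL, params = NULL,
                         metadata = c("bmi", "deprivation")) {
  proteins <- protein_columns(cohort, proteins,
                              exclude = c("subject_id", "age", "sex", metadata))
  m <- protein_matrix(cohort, proteins)
  if (is.null(params)) {
    mins <- apply(m, 2, min, na.rm = TRUE)
    maxs <- apply(m, 2, max, na.rm = TRUE)
    constant <- !is.finite(mins) | !is.finite(maxs) | maxs - mins == 0
    if (any(constant)) {
      warn(paste0("dropping constant protein(s): ",
                  paste(proteins[constant], collapse = ", ")))
    }
    keep <- proteins[!constant]
    scaled <- sweep(sweep(m[, keep, drop = FALSE], 2, mins[keep]),
                    2, (maxs - mins)[keep], "/")
    meds <- apply(scaled, 2, median, na.rm = TRUE)
    scaled <- sweep(scaled, 2, meds)
    params <- tibble(protein_id = keep, min = unname(mins[keep]),
                     max = unname(maxs[keep]), median = unname(meds))
  } else {
    keep <- intersect(proteins, params$protein_id)
    p <- params[match(keep, params$protein_id), ]
    scaled <- sweep(sweep(m[, keep, drop = FALSE], 2, p$min),
                    2, p$max - p$min, "/")
    scaled <- sweep(scaled, 2, p$median)
    params <- p
  }
  out <- cohort[, setdiff(names(cohort), proteins)]
  list(cohort = bind_cols(out, as_tibble(scaled)), proteins = keep,
       params = params)
}

#' Preprocess a cohort: QC filters then scaling
#'
#' Convenience wrapper running [filter_missingness()] followed by
#' [scale_values()].
#'
#' @inheritParams filter_missingness
#' @param scaling_params Optional frozen scaling parameters for projecting an
#'   external cohort; default re-estimates scaling within the cohort.
#' @return List: `cohort`, `proteins`, `report`, `params`.
#' @export
preprocess_cohort <- function(cohort, proteins = NULL, protein_max = 0.20,
                              subject_max = 0.50, scaling_params = NULL,
                              metadata = c("bmi", "deprivation")) {
  f <- filter_missingness(cohort, proteins, protein_max, subject_max, metadata)
  s <- scale_values(f$cohort, f$proteins, params = scaling_params,
                    metadata = metadata)
  list(cohort = s$cohort, proteins = s$proteins, report = f$report,
       params = s$params)
}
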