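#' Age gap: residual of proteomic age on chronological age
#'
#' Regresses proteomic age on chronological age by ordinary least squares
#' (with intercept) and returns the residuals — positive gaps mean
#' accelerated aging relative to same-aged peers. The fitted slope and
#' intercept are returned so external cohorts can be scored with the frozen
#' regression.
#'
#' @param data Tibble with proteomic and chronological age columns.
#' @param proteomic_age,chronological_age Column names (strings).
#' @param model Optional list with `intercept` and `slope` from a previous
#'   fit (frozen mode); when supplied, gaps are computed against that line
#'   without refitting.
#' @return The input tibble with an `age_gap` column added; the regression
#'   coefficients are attached as attribute `"gap_model"`.
#' @export
compute_age_gap <- function(data, proteomic_age = "proteomic_age",
                            chronological_age = "age", model = NULL) {
  pa <- data[[proteomic_age]]
  ca <- data[[chronological_age]]
  if (is.null(model)) {
    if (length(ca) < 3) abort("need >= 3 subjects")
    if (sd(ca) == 0) abort("constant chronological age")
    fit <- lm(pa ~ ca)
    model <- list(intercept = unname(coef(fit)[1]),
                  slope = unname(coef(fit)[2]))
  }
  out <- mutate(data, age_gap = pa - (model$intercept + model$slope * ca))
  attr(out, "gap_model") <- model
  out
}

#' Classify extreme ageotypes
#'
#' Standardises each age gap by the cohort standard deviation and labels
#' subjects `aged` when the gap exceeds `+threshold_sd` s.d., `youthful`
#' below `-threshold_sd` s.d., and `normal` otherwise.
#'
#' @param data Tibble with an age-gap column.
#' @param gap Column name of the age gap.
#' @param threshold_sd Threshold in cohort standard deviations (default 1.5).
#' @param gap_sd Optional frozen s.d. (external projection); default:
#'   estimated from the data.
#' @return The tibble with `age_gap_z` and `ageotype` (factor: youthful,
#'   normal, aged) added; the s.d. used is attached as attribute `"gap_sd"`.
#' @export
classify_ageotypes <- function(data, gap = "age_gap", threshold_sd = 1.5,
                               gap_sd = NULL) {
  g <- data[[gap]]
  gap_sd <- gap_sd %||% sd(g, na.rm = TRUE)
  if (!is.finite(gap_sd) || gap_sd == 0) abort("zero-variance age gap")
  z <- g / gap_sd
  out <- mutate(
    data, age_gap_z = z,
    ageotype = factor(
      dplyr::case_when(z > threshold_sd ~ "aged",
                       z < -threshold_sd ~ "youthful",
                       TRUE ~ "normal"),
      levels = c("youthful", "normal", "aged"))
  )
  attr(out, "gap_sd") <- gap_sd
  out
}

#' Count extremely aged / youthful organs per subject
#'
#' From per-subject, per-organ ageotype labels, counts the organs labelled
#' aged and youthful and maps each count to the burden groups 0, 1-2, 3-4
#' and 5+.
#'
#' @param labels Long tibble: `subject_id`, `organ`, `ageotype`.
#' @return Tibble: subject_id, n_aged, n_youthful, burden_aged,
#'   burden_youthful (factors with levels `0`, `1-2`, `3-4`, `5+`).
#' @export
count_extreme_organs <- function(labels) {
  burden <- function(k) {
    cut(k, breaks = c(-0.5, 0.5, 2.5, 4.5, Inf),
        labels = c("0", "1-2", "3-4", "5+"))
  }
  labels |>
    group_by(.data$subject_id) |>
    summarise(n_aged = sum(.data$ageotype == "aged"),
              n_youthful = sum(.data$ageotype == "youthful"),
              .groups = "drop") |>
    mutate(burden_aged = burden(.data$n_aged),
           burden_youthful = burden(.data$n_youthful))
}

#' Combine two standardised scores into five bins
#'
#' Averages two z-scores, re-standardises the mean (the default; set
#' `restandardize = FALSE` to bin the raw mean), and bins the combined score
#' at -1.5, -0.5, +0.5, +1.5 into bins -2, -1, 0, +1, +2. Intervals are
#' closed on the left, so boundary values go to the upper bin.
#'
#' @param data Tibble holding both score columns.
#' @param score_a,score_b Column names of the two z-standardised scores.
#' @param restandardize Re-standardise the mean score before binning.
#' @return The tibble with `combined_z` and `combined_bin` (ordered factor
#'   `-2` ... `+2`) added.
#' @export
combine_scores <- function(data, score_a, score_b, restandardize = TRUE) {
  a <- data[[score_a]]; b <- data[[score_b]]
  if (length(a) != length(b)) abort("score columns differ in length")
  comb <- (a + b) / 2
  if (restandardize) comb <- as.numeric(scale(comb))
  mutate(
    data, combined_z = comb,
    combined_bin = cut(comb, breaks = c(-Inf, -1.5, -0.5, 0.5, 1.5, Inf),
                       labels = c("-2", "-1", "0", "+1", "+2"),
                       right = FALSE, ordered_result = TRUE)
  )
}

#' Derive the full aging-phenotype table
#'
#' Given per-organ proteomic ages, computes per-organ age gaps (OLS residual
#' on chronological age), standardised gaps, ageotype labels, and per-subject
#' extreme-organ burden groups.
#'
#' @param predictions Long tibble: `subject_id`, `organ`, `proteomic_age`.
#' @param demographics Tibble with `subject_id` and `age`.
#' @param threshold_sd Ageotype threshold in s.d. (default 1.5).
#' @return List: `phenotypes` (long tibble: subject_id, organ, age,
#'   proteomic_age, age_gap, age_gap_z, ageotype), `burden` (per-subject
#'   tibble from [count_extreme_organs()]), `models` (per-organ gap
#'   regressions and s.d.s, for external projection).
#' @export
derive_phenotypes <- function(predictions, demographics, threshold_sd = 1.5) {
  joined <- predictions |>
    inner_join(demographics |> select("subject_id", "age"), by = "subject_id")
  models <- list()
  pheno <- joined |>
    group_by(.data$organ) |>
    dplyr::group_modify(function(d, key) {
      d <- compute_age_gap(d)
      d <- classify_ageotypes(d, threshold_sd = threshold_sd)
      models[[key$organ]] <<- list(gap_model = attr(d, "gap_model"),
                                   gap_sd = attr(d, "gap_sd"))
      d
    }) |>
    ungroup()
  list(phenotypes = pheno, burden = count_extreme_organs(pheno),
       models = models)
}
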