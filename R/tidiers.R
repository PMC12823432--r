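#' Tidy an organ clock: per-protein SHAP importance
#'
#' @param x An `organ_clock`.
#' @param ... Unused.
#' @return Tibble: protein_id, importance (mean |SHAP|, training data),
#'   ordered by decreasing importance.
#' @method tidy organ_clock
#' @export
tidy.organ_clock <- function(x, ...) {
  imp <- x$final_fit$importance
  tibble(protein_id = names(imp), importance = unname(imp)) |>
    arrange(dplyr::desc(.data$importance))
}

#' One-row summary of an organ clock
#'
#' @param x An `organ_clock`.
#' @param ... Unused.
#' @return Tibble: organ, n_candidates, n_selected, r (held-out), r2
#'   (held-out), r_oof (out-of-fold, full cohort), n_test.
#' @method glance organ_clock
#' @export
glance.organ_clock <- function(x, ...) {
  tibble(
    organ = x$organ,
    n_candidates = length(x$candidate_proteins),
    n_selected = length(x$selected_proteins),
    r = x$evaluation$r, r2 = x$evaluation$r2,
    r_oof = stats::cor(x$oof$age, x$oof$proteomic_age,
                       use = "complete.obs"),
    n_test = x$evaluation$n_test
  )
}

#' Out-of-fold predictions versus chronological age
#'
#' @param object An `organ_clock`.
#' @param ... Unused.
#' @return A ggplot: proteomic age against chronological age with the
#'   identity line.
#' @method autoplot organ_clock
#' @export
autoplot.organ_clock <- function(object, ...) {
  ggplot2::ggplot(object$oof,
                  ggplot2::aes(x = .data$age, y = .data$proteomic_age)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "red") +
    ggplot2::labs(
      x = "Chronological age (years)", y = "Proteomic age (years)",
      title = sprintf("%s clock: out-of-fold predictions", object$organ),
      subtitle = sprintf("r = %.2f", stats::cor(object$oof$age,
                                                object$oof$proteomic_age))
    ) +
    ggplot2::theme_minimal()
}

#' Performance along the recursive-elimination path
#'
#' @param object An `rfe_path`.
#' @param retention Optional retention fraction; when given, the chosen
#'   panel size is marked.
#' @param ... Unused.
#' @return A ggplot of cross-validated R-squared against panel size.
#' @method autoplot rfe_path
#' @export
autoplot.rfe_path <- function(object, retention = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$panel_size, y = .data$r2)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Panel size (proteins)",
                  y = expression("Cross-validated" ~ r^2),
                  title = "SHAP-guided recursive feature elimination") +
    ggplot2::theme_minimal()
  if (!is.null(retention)) {
    sel <- choose_panel(object, retention)
    p <- p +
      ggplot2::geom_vline(xintercept = sel$size, linetype = 2,
                          colour = "red") +
      ggplot2::geom_hline(yintercept = sel$threshold, linetype = 3)
  }
  p
}

#' Cumulative incidence curves
#'
#' @param object A `cuminc_curves` tibble from [cumulative_incidence()].
#' @param ... Unused.
#' @return A ggplot of step curves, one per group.
#' @method autoplot cuminc_curves
#' @export
autoplot.cuminc_curves <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$cuminc,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Follow-up time (years)", y = "Cumulative incidence",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Relative-contribution bar chart
#'
#' @param profile Tibble from [relative_contribution()].
#' @return A ggplot bar chart of per-exposure weights.
#' @export
plot_contributions <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = stats::reorder(.data$exposure,
                                                  .data$weight),
                               y = .data$weight)) +
    ggplot2::geom_col() + ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Relative contribution") +
    ggplot2::theme_minimal()
}
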