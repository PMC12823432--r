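#' Collapse tissue-level expression to organ level
#'
#' Each organ's expression for a gene is the maximum over that organ's tissue
#' subtypes, following the convention used to map transcriptome atlases onto
#' organs before enrichment calling.
#'
#' @param expr Wide tibble: `gene_id` plus one numeric column per tissue.
#' @param tissue_map Tibble with columns `tissue`, `organ`; every tissue
#'   column of `expr` must be covered.
#' @return Wide tibble: `gene_id` plus one column per organ.
#' @export
collapse_tissues_to_organs <- function(expr, tissue_map) {
  tissues <- setdiff(names(expr), "gene_id")
  if (nrow(expr) == 0 || length(tissues) == 0) abort("empty expression matrix")
  unmapped <- setdiff(tissues, tissue_map$tissue)
  if (length(unmapped) > 0) {
    abort(paste0("tissues missing from `tissue_map`: ",
                 paste(unmapped, collapse = ", ")))
  }
  vals <- as.matrix(expr[, tissues, drop = FALSE])
  if (any(vals < 0, na.rm = TRUE)) abort("expression values must be >= 0")
  organs <- unique(tissue_map$organ[tissue_map$tissue %in% tissues])
  out <- vapply(organs, function(o) {
    cols <- tissue_map$tissue[tissue_map$organ == o]
    cols <- intersect(cols, tissues)
    apply(vals[, cols, drop = FALSE], 1, max)
  }, numeric(nrow(expr)))
  out <- matrix(out, nrow = nrow(expr), dimnames = list(NULL, organs))
  bind_cols(tibble(gene_id = expr$gene_id), as_tibble(out))
}

#' Call organ-enriched genes by the fourfold rule
#'
#' A gene is assigned to an organ when its expression there is at least
#' `fold_threshold` times its expression in every other organ. The boundary
#' case (exactly fourfold) qualifies; a runner-up of zero with positive top
#' expression is treated as an unbounded ratio and assigned. At most one
#' organ can satisfy the rule, so assignments are unique by construction.
#'
#' @param organ_expr Gene-by-organ tibble from
#'   [collapse_tissues_to_organs()] (>= 2 organ columns).
#' @param fold_threshold Enrichment fold (> 1); default 4.
#' @return Tibble with one row per gene: `protein_id`, `organ` (`NA` when no
#'   organ qualifies), `fold` (top / runner-up expression ratio, `Inf` when
#'   the runner-up is zero, 0 when the gene is silent everywhere).
#' @export
call_enriched <- function(organ_expr, fold_threshold = 4) {
  if (fold_threshold <= 1) abort("`fold_threshold` must exceed 1")
  organs <- setdiff(names(organ_expr), "gene_id")
  if (length(organs) < 2) abort("need >= 2 organs to test enrichment")
  vals <- as.matrix(organ_expr[, organs, drop = FALSE])
  top_idx <- max.col(vals, ties.method = "first")
  top <- vals[cbind(seq_len(nrow(vals)), top_idx)]
  second <- vapply(seq_len(nrow(vals)), function(i) {
    max(vals[i, -top_idx[i]])
  }, numeric(1))
  fold <- ifelse(top == 0, 0, ifelse(second == 0, Inf, top / second))
  assigned <- top > 0 & (second == 0 | top >= fold_threshold * second)
  tibble(
    protein_id = organ_expr$gene_id,
    organ = ifelse(assigned, organs[top_idx], NA_character_),
    fold = fold,
    confirmed = NA
  )
}

#' Confirm enrichment calls in a second expression resource
#'
#' Re-applies the same fold rule to a second (confirmation) gene-by-organ
#' matrix and keeps a protein only when both resources assign the same
#' organ. Genes absent from the confirmation matrix are dropped by default
#' (strict mode); with `lenient = TRUE` they are kept unconfirmed.
#'
#' @param annotations Output of [call_enriched()] on the discovery matrix.
#' @param second_expr Confirmation matrix, either tissue-level (then
#'   `tissue_map` is required and it is collapsed first) or already
#'   gene-by-organ.
#' @param tissue_map Optional tissue-to-organ map for `second_expr`.
#' @param fold_threshold Enrichment fold; default 4.
#' @param lenient Keep genes missing from the confirmation matrix
#'   (unconfirmed) instead of dropping them.
#' @return Filtered annotation tibble with `confirmed` set.
#' @export
confirm_enrichment <- function(annotations, second_expr, tissue_map = NULL,
                               fold_threshold = 4, lenient = FALSE) {
  if (!is.null(tissue_map)) {
    second_expr <- collapse_tissues_to_organs(second_expr, tissue_map)
  }
  second <- call_enriched(second_expr, fold_threshold)
  assigned <- annotations |> filter(!is.na(.data$organ))
  joined <- assigned |>
    left_join(second |> select("protein_id", organ2 = "organ"),
              by = "protein_id") |>
    mutate(present = .data$protein_id %in% second$protein_id)
  keep <- joined |>
    mutate(confirmed = .data$present & !is.na(.data$organ2) &
             .data$organ2 == .data$organ) |>
    filter(.data$confirmed | (lenient & !.data$present)) |>
    select("protein_id", "organ", "fold", "confirmed")
  keep
}

#' Per-organ first principal components of the proteome
#'
#' Summarises each organ's protein profile as the leading principal component
#' of the standardised organ-protein submatrix (missing entries mean-imputed
#' for this summary only). Subject scores are centred; the loading vector is
#' oriented so its largest-magnitude entry is positive. Also returns the
#' organ-by-organ Pearson correlation matrix of subject scores.
#'
#' @param cohort Wide cohort tibble (`subject_id` + protein columns).
#' @param annotations Annotation tibble (`protein_id`, `organ`), e.g. from
#'   [confirm_enrichment()].
#' @return An `organ_pc_profiles` list: `scores` (tibble, subject_id + one
#'   column per organ), `loadings` (named list of named numeric vectors),
#'   `var_explained` (named numeric), `correlations` (matrix).
#' @export
organ_pc1 <- function(cohort, annotations) {
  ann <- annotations |> filter(!is.na(.data$organ))
  organs <- unique(ann$organ)
  scores <- list(); loadings <- list(); varexp <- numeric()
  for (o in organs) {
    prots <- intersect(ann$protein_id[ann$organ == o], names(cohort))
    if (length(prots) < 2) {
      warn(sprintf("organ '%s' has < 2 measured proteins; skipped", o))
      next
    }
    m <- protein_matrix(cohort, prots)
    for (j in seq_len(ncol(m))) {
      mu <- mean(m[, j], na.rm = TRUE)
      m[is.na(m[, j]), j] <- mu
    }
    sds <- apply(m, 2, sd)
    m <- m[, sds > 0, drop = FALSE]
    if (ncol(m) < 2) {
      warn(sprintf("organ '%s' has < 2 variable proteins; skipped", o))
      next
    }
    pc <- prcomp(m, center = TRUE, scale. = TRUE, rank. = 1)
    load <- pc$rotation[, 1]
    if (load[which.max(abs(load))] < 0) load <- -load
    sc <- as.numeric(scale(m, pc$center, pc$scale) %*% load)
    scores[[o]] <- sc
    loadings[[o]] <- load
    varexp[o] <- pc$sdev[1]^2 / sum(apply(scale(m), 2, var))
  }
  if (length(scores) == 0) abort("no organ had >= 2 measured proteins")
  score_tbl <- bind_cols(tibble(subject_id = cohort$subject_id),
                         as_tibble(scores))
  structure(
    list(scores = score_tbl, loadings = loadings, var_explained = varexp,
         correlations = stats::cor(as.matrix(score_tbl[, -1]))),
    class = "organ_pc_profiles"
  )
}

#' @export
print.organ_pc_profiles <- function(x, ...) {
  cat(sprintf("Organ PC1 profiles: %d organs, %d subjects\n",
              ncol(x$scores) - 1, nrow(x$scores)))
  cat("variance explained by PC1:\n")
  print(round(x$var_explained, 3))
  invisible(x)
}
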