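# Internal helpers shared across modules.

# Derive a reproducible sub-seed for a named pipeline stage from a master
# seed, so stages can be regenerated independently. Kept below 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(
    tissue = 101L, subjects = 211L, proteome = 307L, outcomes = 401L,
    split = 503L, tune = 601L, boruta = 701L, retune = 809L, fit = 907L,
    oof = 1009L, rfe = 1103L, match = 1201L, boot = 1301L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483629)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# global .Random.seed is untouched.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

assert_fraction <- function(x, name, closed = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (closed) x >= 0 && x <= 1 else x > 0 && x < 1)
  if (!ok) abort(sprintf("`%s` must be a single value in %s",
                         name, if (closed) "[0, 1]" else "(0, 1)"))
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) && x >= min &&
    x == as.integer(x)
  if (!ok) abort(sprintf("`%s` must be a single integer >= %d", name, min))
  invisible(as.integer(x))
}

# Columns of `data` holding protein measurements. If `protein_ids` is NULL,
# every column not listed in `exclude` is taken to be a protein.
protein_columns <- function(data, protein_ids = NULL,
                            exclude = c("subject_id", "age", "sex")) {
  if (!is.null(protein_ids)) {
    missing <- setdiff(protein_ids, names(data))
    if (length(missing) > 0) {
      abort(paste0("proteins absent from the data: ",
                   paste(missing, collapse = ", ")))
    }
    return(protein_ids)
  }
  setdiff(names(data), exclude)
}

# Numeric matrix of protein values (subjects x proteins), NAs preserved.
protein_matrix <- function(data, proteins) {
  m <- as.matrix(data[, proteins, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- data$subject_id
  m
}

# Squared Pearson correlation, NA-safe; 0 when degenerate.
r_squared <- function(obs, pred) {
  ok <- is.finite(obs) & is.finite(pred)
  if (sum(ok) < 3 || sd(obs[ok]) == 0 || sd(pred[ok]) == 0) return(0)
  stats::cor(obs[ok], pred[ok])^2
}
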