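#' Log2 counts-per-million transform
#'
#' Standard variance-stabilising transform used before confounder correction,
#' differential expression and clustering: `log2(1e6 * count / library_size + 1)`.
#'
#' @param counts integer matrix, genes x samples.
#' @param library_sizes per-sample totals; defaults to column sums.
#' @return numeric matrix of the same shape.
#' @export
log_cpm <- function(counts, library_sizes = colSums(counts)) {
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  log2(sweep(counts, 2, library_sizes / 1e6, "/") + 1)
}

#' Percentage with fixed rounding
#'
#' Bookkeeping helper used in filter reports: `round(100 * n / total, digits)`.
#'
#' @param n numerator count.
#' @param total denominator count.
#' @param digits decimal places (default 2).
#' @export
pct <- function(n, total, digits = 2) {
  if (total <= 0) stop("total must be positive")
  round(100 * n / total, digits)
}

#' Correlation ratio (eta) between a numeric vector and a categorical factor
#'
#' Square root of the between-group fraction of total variance; the analogue
#' of |Pearson r| for a categorical covariate, used when screening genes
#' against categorical confounders such as purification batch.
#'
#' @param x numeric vector.
#' @param g factor (or coercible).
#' @return eta in [0, 1]; 0 for a constant `x`.
#' @export
correlation_ratio <- function(x, g) {
  g <- as.factor(g)
  tot <- sum((x - mean(x))^2)
  if (tot == 0) return(0)
  gm <- tapply(x, g, mean)
  n <- tabulate(g)
  between <- sum(n * (gm - mean(x))^2)
  sqrt(between / tot)
}

# Row-wise z-score; rows with zero variance are returned as zeros and flagged.
row_zscore <- function(mat) {
  mu <- rowMeans(mat)
  sd <- apply(mat, 1, stats::sd)
  z <- (mat - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  attr(z, "zero_variance") <- rownames(mat)[sd == 0]
  z
}

# Association of a sample-level vector with one confounder column:
# |Pearson r| for numeric, correlation ratio for categorical.
confounder_assoc <- function(x, conf) {
  if (is.numeric(conf)) {
    if (stats::sd(conf) == 0 || stats::sd(x) == 0) return(0)
    abs(stats::cor(x, conf))
  } else {
    correlation_ratio(x, conf)
  }
}

# Run an expression with a locally seeded RNG, restoring global state after.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
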