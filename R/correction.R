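#' Select a stable-gene panel for confounder correction
#'
#' Screens every gene's log-expression against each confounder: absolute
#' Pearson correlation for numeric covariates, correlation ratio (eta) for
#' categorical ones. Genes whose maximum association across all confounders
#' is below `corr_threshold` form the panel, ranked by increasing variance.
#' Missing covariate values (e.g. gestational age of non-pregnant controls)
#' are handled by complete-case association.
#'
#' @param logmat log-expression matrix (genes x samples), e.g. [log_cpm()].
#' @param meta sample metadata, one row per column of `logmat`.
#' @param confounders metadata column names; default the five corrected
#'   variables: maternal age, library size, gestational age, fetal
#'   fraction, purification.
#' @param corr_threshold cross-correlation threshold (default 0.5).
#' @param min_panel minimum admissible panel size (default 50).
#' @return object of class `cf_stable_panel`: list with `genes` (ids in
#'   variance rank order), `max_assoc` (per-gene max association), `assoc`
#'   (gene x confounder matrix).
#' @export
select_stable_genes <- function(logmat, meta,
                                confounders = c("maternal_age", "library_size",
                                                "gestational_age",
                                                "fetal_fraction", "purification"),
                                corr_threshold = 0.5, min_panel = 50) {
  meta <- meta[match(colnames(logmat), meta$sample_id), ]
  missing_cols <- setdiff(confounders, names(meta))
  if (length(missing_cols))
    stop("confounder(s) absent from metadata: ",
         paste(missing_cols, collapse = ", "))
  assoc <- sapply(confounders, function(cv) {
    conf <- meta[[cv]]
    keep <- !is.na(conf)
    apply(logmat[, keep, drop = FALSE], 1, confounder_assoc, conf = conf[keep])
  })
  assoc <- matrix(assoc, nrow = nrow(logmat),
                  dimnames = list(rownames(logmat), confounders))
  max_assoc <- apply(assoc, 1, max)
  stable <- max_assoc < corr_threshold
  if (sum(stable) < min_panel)
    stop("stable panel too small (", sum(stable), " < ", min_panel, ")")
  vars <- apply(logmat[stable, , drop = FALSE], 1, stats::var)
  genes <- rownames(logmat)[stable][order(vars)]
  structure(list(genes = genes, max_assoc = max_assoc[genes],
                 assoc = assoc[genes, , drop = FALSE],
                 corr_threshold = corr_threshold),
            class = "cf_stable_panel")
}

#' @export
print.cf_stable_panel <- function(x, ...) {
  cat(sprintf("stable panel: %d genes (max association < %.2f)\n",
              length(x$genes), x$corr_threshold))
  invisible(x)
}

#' Remove unwanted variation using the stable-gene panel
#'
#' Factor-based correction in the control-gene style: unwanted factors are
#' the right singular vectors of the stable-gene submatrix after removing
#' protected-group means per gene, so the group contrast of interest cannot
#' be absorbed. Factors are accepted one at a time while they associate
#' with at least one stated confounder at or above `corr_threshold` (up to
#' `k_max`); accepted factors are then regressed out of every gene jointly
#' with the protected group means. With no accepted factor the input is
#' returned unchanged.
#'
#' @param logmat log-expression matrix (genes x samples).
#' @param panel `cf_stable_panel` or character vector of control gene ids.
#' @param groups protected group label per sample (factor/character).
#' @param meta,confounders metadata and confounder columns used for the
#'   factor acceptance rule; if `confounders` is `NULL` no factor is
#'   accepted (k = 0).
#' @param k_max maximum number of factors (default 5, one per stated
#'   confounder).
#' @param corr_threshold factor acceptance threshold (default 0.5, reusing
#'   the cross-correlation threshold).
#' @return object of class `cf_corrected`: list with `mat` (corrected
#'   matrix, same shape), `k`, `W` (samples x k factor matrix), and
#'   `factor_assoc` (factor x confounder association matrix).
#' @export
remove_unwanted_variation <- function(logmat, panel, groups, meta = NULL,
                                      confounders = NULL, k_max = 5,
                                      corr_threshold = 0.5) {
  if (k_max < 0) stop("k_max must be >= 0")
  genes <- if (inherits(panel, "cf_stable_panel")) panel$genes else panel
  genes <- intersect(genes, rownames(logmat))
  if (length(genes) < 2) stop("control-gene submatrix is degenerate")
  groups <- as.factor(groups)
  if (length(groups) != ncol(logmat))
    stop("groups must label every sample")

  ctrl <- logmat[genes, , drop = FALSE]
  gm <- vapply(levels(groups), function(g)
    rowMeans(ctrl[, groups == g, drop = FALSE]), numeric(nrow(ctrl)))
  centered <- ctrl - gm[, as.integer(groups)]
  if (all(abs(centered) < 1e-12)) stop("control-gene submatrix is degenerate")
  sv <- svd(centered)
  n_avail <- sum(sv$d > sv$d[1] * 1e-8)

  ## assess the leading k_max factors of the control submatrix and keep
  ## those that associate with at least one stated confounder; a factor
  ## carrying no confounder signal is left in the data
  selected <- integer()
  assoc_rows <- list()
  if (!is.null(meta) && !is.null(confounders)) {
    meta <- meta[match(colnames(logmat), meta$sample_id), ]
    for (j in seq_len(min(k_max, n_avail))) {
      v <- sv$v[, j]
      a <- vapply(confounders, function(cv) {
        conf <- meta[[cv]]
        keep <- !is.na(conf)
        confounder_assoc(v[keep], conf[keep])
      }, numeric(1))
      if (max(a) >= corr_threshold) {
        selected <- c(selected, j)
        assoc_rows[[length(assoc_rows) + 1]] <- a
      }
    }
  }
  k <- length(selected)

  if (k == 0) {
    out <- list(mat = logmat, k = 0L, W = NULL,
                factor_assoc = NULL, panel_size = length(genes))
    return(structure(out, class = "cf_corrected"))
  }

  W <- sv$v[, selected, drop = FALSE]
  design <- cbind(stats::model.matrix(~ 0 + groups), W)
  qr_d <- qr(design)
  coefs <- t(qr.coef(qr_d, t(logmat)))
  coefs[is.na(coefs)] <- 0
  bW <- coefs[, ncol(design) - rev(seq_len(k)) + 1, drop = FALSE]
  corrected <- logmat - bW %*% t(W)
  structure(list(mat = corrected, k = as.integer(k), W = W,
                 factor_assoc = do.call(rbind, assoc_rows),
                 panel_size = length(genes)),
            class = "cf_corrected")
}

#' @export
print.cf_corrected <- function(x, ...) {
  cat(sprintf("corrected matrix: %d genes x %d samples, k = %d unwanted factor(s)\n",
              nrow(x$mat), ncol(x$mat), x$k))
  invisible(x)
}
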