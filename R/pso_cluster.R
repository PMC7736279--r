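#' Hierarchical clustering of samples on a selected gene set
#'
#' Genes are Z-scored across samples, samples are clustered with
#' Pearson-correlation distance (1 - r) and complete linkage, and the tree
#' is cut at k = number of label levels. The separation score is the
#' adjusted Rand index between the cut and the labels, truncated at zero,
#' so 1 means the cut coincides exactly with the groups and a random
#' assignment scores about 0.
#'
#' @param mat (corrected) log-expression matrix, genes x samples.
#' @param gene_set gene ids to cluster on.
#' @param labels group label per sample.
#' @param dist_method `"correlation"` (default) or any [stats::dist()]
#'   method.
#' @param linkage agglomeration method (default `"complete"`).
#' @return object of class `cf_clustering`: list with `tree` (hclust),
#'   `clusters`, `score`, `genes`, `zmat`, `labels`.
#' @export
cluster_samples <- function(mat, gene_set, labels,
                            dist_method = "correlation",
                            linkage = "complete") {
  gene_set <- intersect(gene_set, rownames(mat))
  if (length(gene_set) == 0) stop("gene set is empty")
  labels <- as.factor(as.character(labels))
  if (any(table(labels) < 1) || nlevels(labels) < 2)
    stop("need >= 2 label levels")
  sub <- mat[gene_set, , drop = FALSE]
  z <- row_zscore(sub)
  zero_var <- attr(z, "zero_variance")
  if (length(zero_var) == length(gene_set))
    stop("all selected genes have zero variance")
  z <- z[setdiff(rownames(z), zero_var), , drop = FALSE]
  d <- if (dist_method == "correlation") stats::as.dist(1 - stats::cor(z))
       else stats::dist(t(z), method = dist_method)
  tree <- stats::hclust(d, method = linkage)
  clusters <- stats::cutree(tree, k = nlevels(labels))
  ari <- mclust::adjustedRandIndex(clusters, labels)
  structure(list(tree = tree, clusters = clusters,
                 score = max(0, ari), ari = ari,
                 genes = rownames(z), zmat = z, labels = labels,
                 dist_method = dist_method, linkage = linkage),
            class = "cf_clustering")
}

#' @export
print.cf_clustering <- function(x, ...) {
  cat(sprintf("clustering: %d genes, %d samples, separation score %.3f\n",
              length(x$genes), length(x$clusters), x$score))
  invisible(x)
}

#' Particle swarm optimisation (maximiser)
#'
#' Standard global-best PSO with constriction-style parameters (inertia
#' 0.72, cognitive/social 1.49). Velocities are clamped to the box range;
#' positions are reflected into the box. Deterministic for a fixed seed.
#' The returned optimum is never worse than the best initial particle.
#'
#' @param fn objective to maximise; takes a numeric vector of
#'   `length(lower)`.
#' @param lower,upper box bounds.
#' @param n_particles swarm size (default 20).
#' @param iterations number of iterations (default 50).
#' @param inertia,c_cognitive,c_social PSO coefficients.
#' @param seed RNG seed.
#' @return list with `par`, `value`, and `trace` (best value per
#'   iteration, including initialisation).
#' @export
pso_optimize <- function(fn, lower, upper, n_particles = 20, iterations = 50,
                         inertia = 0.72, c_cognitive = 1.49, c_social = 1.49,
                         seed = 1L) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower))
  with_local_seed(seed, {
    span <- upper - lower
    pos <- matrix(stats::runif(n_particles * d, lower, upper), n_particles, d,
                  byrow = TRUE)
    vel <- matrix(stats::runif(n_particles * d, -span, span), n_particles, d,
                  byrow = TRUE) * 0.1
    fit <- apply(pos, 1, fn)
    pbest <- pos
    pbest_fit <- fit
    g <- which.max(fit)
    gbest <- pos[g, ]
    gbest_fit <- fit[g]
    trace <- numeric(iterations + 1)
    trace[1] <- gbest_fit
    for (it in seq_len(iterations)) {
      r1 <- matrix(stats::runif(n_particles * d), n_particles, d)
      r2 <- matrix(stats::runif(n_particles * d), n_particles, d)
      vel <- inertia * vel +
        c_cognitive * r1 * (pbest - pos) +
        c_social * r2 * (matrix(gbest, n_particles, d, byrow = TRUE) - pos)
      vel <- pmin(pmax(vel, matrix(-span, n_particles, d, byrow = TRUE)),
                  matrix(span, n_particles, d, byrow = TRUE))
      pos <- pos + vel
      ## reflect at the bounds
      for (j in seq_len(d)) {
        over <- pos[, j] > upper[j]
        pos[over, j] <- 2 * upper[j] - pos[over, j]
        under <- pos[, j] < lower[j]
        pos[under, j] <- 2 * lower[j] - pos[under, j]
        pos[, j] <- pmin(pmax(pos[, j], lower[j]), upper[j])
      }
      fit <- apply(pos, 1, fn)
      better <- fit > pbest_fit
      pbest[better, ] <- pos[better, , drop = FALSE]
      pbest_fit[better] <- fit[better]
      g <- which.max(pbest_fit)
      if (pbest_fit[g] > gbest_fit) {
        gbest <- pbest[g, ]
        gbest_fit <- pbest_fit[g]
      }
      trace[it + 1] <- gbest_fit
    }
    list(par = gbest, value = gbest_fit, trace = trace)
  })
}

#' PSO optimisation of the FDR threshold for heatmap clustering
#'
#' The particle swarm tunes a single scalar: the FDR cutoff that decides
#' which differentially expressed genes enter the hierarchical clustering.
#' Fitness is the separation score of [cluster_samples()] on the genes
#' passing the cutoff; thresholds admitting fewer than `min_genes` genes
#' score -1.
#'
#' @param mat corrected log-expression matrix.
#' @param dge `cf_dge` table providing per-gene FDR values.
#' @param labels group labels per sample.
#' @param bounds threshold search interval (default `c(1e-4, 0.2)`).
#' @param swarm_size,iterations PSO settings.
#' @param seed RNG seed (results are reproducible given the seed).
#' @param min_genes minimum genes for a valid clustering (default 2).
#' @param ... passed to [cluster_samples()].
#' @return list with `threshold`, `clustering` (at the optimum), `score`,
#'   and `trace`.
#' @export
optimize_fdr_threshold <- function(mat, dge, labels, bounds = c(1e-4, 0.2),
                                   swarm_size = 20, iterations = 50,
                                   seed = 1L, min_genes = 2, ...) {
  if (bounds[1] <= 0 || bounds[1] > bounds[2])
    stop("bounds must satisfy 0 < lower <= upper")
  fdr <- stats::setNames(dge$fdr, dge$gene)
  if (sum(fdr < bounds[2]) < min_genes)
    stop("no threshold in bounds admits >= ", min_genes, " genes")
  fitness <- function(t) {
    genes <- names(fdr)[fdr < t]
    if (length(genes) < min_genes) return(-1)
    cluster_samples(mat, genes, labels, ...)$score
  }
  opt <- pso_optimize(fitness, lower = bounds[1], upper = bounds[2],
                      n_particles = swarm_size, iterations = iterations,
                      seed = seed)
  best <- opt$par[1]
  clustering <- cluster_samples(mat, names(fdr)[fdr < best], labels, ...)
  list(threshold = best, clustering = clustering, score = opt$value,
       trace = opt$trace)
}
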