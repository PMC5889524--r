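#' Principal component analysis of a genotype panel
#'
#' EIGENSOFT-style individual-level PCA: each SNP column is centered on its
#' mean dosage and scaled by `sqrt(p(1-p))` with the shrunken frequency
#' `p = (1 + sum dosages) / (2 + 2 n_nonmissing)` (the add-one shrinkage
#' avoids division by zero at near-monomorphic sites); missing cells are set
#' to 0 after centering. Scores come from the eigendecomposition of the
#' sample covariance of the normalized matrix. Variance fractions are
#' reported in two conventions: relative to the total variance and relative
#' to the sum of the top ten eigenvalues.
#'
#' @param panel a `genotype_panel` (>= 2 samples, >= 1 polymorphic SNP; a
#'   single-SNP panel is allowed so one-marker AIM panels can be scored).
#' @param n_components number of components to return.
#' @return a `pca_result`: `coordinates` (samples x components),
#'   `eigenvalues` (all, non-increasing), `var_frac_total`,
#'   `var_frac_top10`, `pop_of`.
#' @export
pca_panel <- function(panel, n_components = 10) {
  n <- n_samples(panel)
  if (n < 2 || n_snps(panel) < 1) stop("need >= 2 samples and >= 1 SNP")
  g <- panel$dosages
  nonmiss <- colSums(!is.na(g))
  s <- colSums(g, na.rm = TRUE)
  p_hat <- (1 + s) / (2 + 2 * nonmiss)
  mu <- s / nonmiss
  sd_ <- sqrt(p_hat * (1 - p_hat))
  poly <- which(sd_ > 0 & nonmiss > 0 & mu > 0 & mu < 2)
  if (!length(poly)) stop("no polymorphic SNPs for PCA")
  x <- sweep(g[, poly, drop = FALSE], 2, mu[poly], "-")
  x[is.na(x)] <- 0
  x <- sweep(x, 2, sd_[poly], "/")
  cv <- tcrossprod(x) / length(poly)
  eig <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  n_components <- min(n_components, n)
  coords <- eig$vectors[, seq_len(n_components), drop = FALSE] *
    rep(sqrt(ev[seq_len(n_components)]), each = n)
  rownames(coords) <- panel$sample_ids
  colnames(coords) <- paste0("PC", seq_len(n_components))
  top10 <- ev[seq_len(min(10L, length(ev)))]
  structure(
    list(coordinates = coords,
         eigenvalues = ev,
         var_frac_total = ev / sum(ev),
         var_frac_top10 = ev / sum(top10),
         pop_of = panel$pop_of),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(3L, ncol(x$coordinates))
  cat(sprintf(
    "pca_result: %d samples; PC1..PC%d explain %s of total variance\n",
    nrow(x$coordinates), k,
    paste(sprintf("%.1f%%", 100 * x$var_frac_total[1:k]), collapse = ", ")
  ))
  invisible(x)
}

#' K-means clustering on top principal components
#'
#' Clusters individuals on their first `n_pcs` PC scores with `stats::kmeans`
#' (25 random restarts under a fixed seed, so results are reproducible) and
#' tabulates, per population, the fraction of its samples assigned to each
#' cluster.
#'
#' @param pca a `pca_result`.
#' @param K number of clusters (1 <= K <= samples).
#' @param n_pcs number of leading PCs to use (default 10).
#' @param seed integer seed for the restarts.
#' @return a `kmeans_result`: `K`, `assignments` (named integer vector),
#'   `fractions` (population x cluster matrix, rows sum to 1), `seed`.
#' @export
kmeans_on_pcs <- function(pca, K, n_pcs = 10, seed = 1) {
  n <- nrow(pca$coordinates)
  if (K > n) stop("K cannot exceed the number of samples")
  stopifnot(K >= 1)
  n_pcs <- min(n_pcs, ncol(pca$coordinates))
  x <- pca$coordinates[, seq_len(n_pcs), drop = FALSE]
  set.seed(seed)
  km <- stats::kmeans(x, centers = K, nstart = 25, iter.max = 100)
  assignments <- stats::setNames(km$cluster, rownames(x))
  pops <- unique(unname(pca$pop_of))
  fractions <- t(vapply(pops, function(p) {
    tabulate(assignments[names(pca$pop_of)[pca$pop_of == p]], nbins = K) /
      sum(pca$pop_of == p)
  }, numeric(K)))
  if (K == 1) fractions <- matrix(fractions, ncol = 1, dimnames = list(pops, NULL))
  rownames(fractions) <- pops
  colnames(fractions) <- paste0("cluster", seq_len(K))
  structure(list(K = K, assignments = assignments, fractions = fractions,
                 seed = seed),
            class = "kmeans_result")
}
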