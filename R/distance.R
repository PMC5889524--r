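#' Allele sharing distance between individuals
#'
#' `d(i, j)` is the mean over SNPs non-missing in both individuals of
#' `|g_i - g_j| / 2` (dosages 0/1/2), i.e. one minus the fraction of shared
#' alleles; it lies in `[0, 1]` and is 0 for identical genotype vectors.
#'
#' @param panel a `genotype_panel` with >= 2 samples.
#' @return a `dist_matrix`: list with `sample_ids` and symmetric `values`.
#' @export
asd_matrix <- function(panel) {
  n <- n_samples(panel)
  if (n < 2) stop("need >= 2 samples")
  g <- panel$dosages
  obs <- !is.na(g)
  g0 <- g
  g0[!obs] <- 0L
  # sum |gi - gj| over shared SNPs via the identity |a-b| expansion on 0/1/2:
  # count shared SNPs and accumulate absolute differences with matrix products
  shared <- obs %*% t(obs)
  # absolute dosage difference decomposes over indicators of each level
  I0 <- (g0 == 0L) & obs; I1 <- (g0 == 1L) & obs; I2 <- (g0 == 2L) & obs
  abs_sum <- (I0 %*% t(I1)) + (I1 %*% t(I0)) +
    2 * ((I0 %*% t(I2)) + (I2 %*% t(I0))) +
    (I1 %*% t(I2)) + (I2 %*% t(I1))
  if (any(shared == 0 & row(shared) != col(shared))) {
    w <- which(shared == 0 & row(shared) != col(shared), arr.ind = TRUE)[1L, ]
    stop("no shared SNPs between ", panel$sample_ids[w[1]], " and ",
         panel$sample_ids[w[2]])
  }
  vals <- abs_sum / (2 * shared)
  diag(vals) <- 0
  dimnames(vals) <- list(panel$sample_ids, panel$sample_ids)
  structure(list(sample_ids = panel$sample_ids, values = vals),
            class = "dist_matrix")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining (via `ape::nj`); negative branch
#' lengths, an artifact the estimator permits, are clamped to zero with the
#' deficit transferred to the adjacent branch so path lengths are preserved
#' as closely as possible.
#'
#' @param dist a `dist_matrix` (or any symmetric numeric matrix with
#'   dimnames) over >= 3 taxa.
#' @return an `ape::phylo` tree.
#' @export
nj_tree <- function(dist) {
  m <- if (inherits(dist, "dist_matrix")) dist$values else as.matrix(dist)
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (nrow(m) < 3) stop("need >= 3 taxa")
  tr <- ape::nj(stats::as.dist(m))
  # clamp negative edges; move the deficit onto the sister edge at the same node
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    sib <- which(tr$edge[, 1] == tr$edge[e, 1] & seq_along(tr$edge.length) != e)
    if (length(sib)) {
      tr$edge.length[sib[1]] <- max(0, tr$edge.length[sib[1]] + deficit)
    }
  }
  tr
}

#' Write a tree in newick format
#' @param tree an `ape::phylo`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
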