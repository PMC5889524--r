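#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; when any
#' factor of the denominator is zero the coefficient is defined as 0 (the
#' usual convention for degenerate confusion tables).
#'
#' @param TP,TN,FP,FN non-negative integer counts.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(TP, TN, FP, FN) {
  if (any(c(TP, TN, FP, FN) < 0)) stop("counts must be non-negative")
  den2 <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  if (den2 == 0) return(0)
  (TP * TN - FP * FN) / sqrt(den2)
}

#' Classify two populations by PC1 of a marker panel
#'
#' Runs PCA on the two populations' samples restricted to the given SNPs,
#' thresholds PC1 at the midpoint of the two population means (orientation
#' chosen so `popA` is the positive class) and counts the confusion table
#' against the true labels.
#'
#' @param panel a `genotype_panel` already restricted to the candidate AIMs.
#' @param popA,popB population names; `popA` is the positive class.
#' @return list with `TP`, `TN`, `FP`, `FN` and `mcc`.
#' @export
classify_by_pc1 <- function(panel, popA, popB) {
  ids <- c(samples_of(panel, popA), samples_of(panel, popB))
  sub <- subset_panel(panel, sample_ids = ids)
  pc <- pca_panel(sub, n_components = 1)
  pc1 <- pc$coordinates[, 1]
  labs <- sub$pop_of
  mA <- mean(pc1[labs == popA]); mB <- mean(pc1[labs == popB])
  if (mA < mB) pc1 <- -pc1  # orient popA positive
  mid <- (mean(pc1[labs == popA]) + mean(pc1[labs == popB])) / 2
  pred_a <- pc1 > mid
  TP <- sum(pred_a & labs == popA)
  FN <- sum(!pred_a & labs == popA)
  FP <- sum(pred_a & labs == popB)
  TN <- sum(!pred_a & labs == popB)
  list(TP = TP, TN = TN, FP = FP, FN = FN, mcc = mcc(TP, TN, FP, FN))
}

#' Select an ancestry-informative-marker panel for a population pair
#'
#' Greedy selection under the three screening criteria: rank SNPs by per-SNP
#' pairwise F_ST (descending), repeatedly add the highest-ranked SNP lying
#' more than `min_gap_bp` from every already-selected SNP on the same
#' chromosome, and after each addition score the panel by the MCC of the
#' PC1 midpoint classifier on the training individuals. Selection stops when
#' the MCC reaches `target_mcc` or `max_snps` markers have been taken.
#'
#' @param panel a `genotype_panel`.
#' @param popA,popB distinct population names.
#' @param min_gap_bp minimum pairwise spacing of selected markers (default
#'   500 kb).
#' @param target_mcc stop once the panel's MCC reaches this (default 1.0,
#'   perfect separation).
#' @param max_snps cap on panel size.
#' @return an `aim_panel`: `pair`, `snps` (ids in selection order),
#'   `snp_fst`, `mcc_trajectory`, `final_mcc`, `min_gap_bp`, and
#'   `target_reached` flag (with a warning when the target was not reached).
#' @export
select_aims <- function(panel, popA, popB, min_gap_bp = 500000,
                        target_mcc = 1.0, max_snps = 200) {
  if (popA == popB) stop("populations must be distinct")
  fst <- per_snp_fst(panel, popA, popB)
  ord <- order(fst, decreasing = TRUE, na.last = NA)  # ties: SNP order
  ids <- c(samples_of(panel, popA), samples_of(panel, popB))
  sel <- integer(0)
  trajectory <- numeric(0)
  final <- 0
  for (cand in ord) {
    if (length(sel) >= max_snps) break
    same <- sel[panel$snps$chrom[sel] == panel$snps$chrom[cand]]
    if (length(same) &&
        any(abs(panel$snps$pos_bp[same] - panel$snps$pos_bp[cand]) <= min_gap_bp)) {
      next
    }
    sel <- c(sel, cand)
    res <- tryCatch(
      classify_by_pc1(subset_panel(panel, snp_idx = sel, sample_ids = ids),
                      popA, popB),
      error = function(e) NULL
    )
    m <- if (is.null(res)) 0 else res$mcc
    trajectory <- c(trajectory, m)
    final <- m
    if (m >= target_mcc) break
  }
  reached <- final >= target_mcc
  if (!reached) {
    warning(sprintf("MCC target %.2f not reached (best %.3f with %d SNPs)",
                    target_mcc, final, length(sel)))
  }
  structure(
    list(pair = c(popA, popB),
         snps = panel$snps$id[sel],
         snp_fst = fst[sel],
         mcc_trajectory = trajectory,
         final_mcc = final,
         min_gap_bp = min_gap_bp,
         target_reached = reached),
    class = "aim_panel"
  )
}

#' @export
print.aim_panel <- function(x, ...) {
  cat(sprintf("aim_panel %s/%s: %d SNPs, final MCC %.3f%s\n",
              x$pair[1], x$pair[2], length(x$snps), x$final_mcc,
              if (x$target_reached) "" else " (target not reached)"))
  invisible(x)
}
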