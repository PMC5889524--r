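#' Delete-m block jackknife for ratio statistics
#'
#' Splits the SNPs (in storage order, a proxy for physical linkage blocks)
#' into `n_blocks` contiguous blocks of near-equal size and recomputes the
#' statistic `sum(num)/sum(den)` with each block deleted. The standard error
#' uses the weighted delete-m jackknife variance (block weights proportional
#' to SNP counts), which reduces to the ordinary delete-1 jackknife for
#' equal blocks.
#'
#' @param num,den per-SNP numerator and denominator contributions (use
#'   `den = rep(1, n)` for a plain mean).
#' @param n_blocks number of contiguous blocks (>= 10; must not exceed the
#'   number of SNPs).
#' @return list with `estimate`, `se`, `Z`, `n_blocks`, `n_snps`.
#' @export
block_jackknife <- function(num, den = rep(1, length(num)), n_blocks = 500) {
  ok <- !is.na(num) & !is.na(den)
  num <- num[ok]; den <- den[ok]
  n <- length(num)
  if (n_blocks < 10) stop("n_blocks must be >= 10")
  if (n < n_blocks) {
    stop("fewer SNPs (", n, ") than blocks (", n_blocks,
         "); use a smaller n_blocks")
  }
  block <- ceiling(seq_len(n) / (n / n_blocks))
  block <- pmin(block, n_blocks)
  sn <- as.numeric(tapply(num, block, sum))
  sd_ <- as.numeric(tapply(den, block, sum))
  m_j <- as.numeric(tabulate(block, n_blocks))
  tot_n <- sum(sn); tot_d <- sum(sd_)
  if (tot_d == 0) stop("no informative SNPs")
  theta <- tot_n / tot_d
  theta_j <- (tot_n - sn) / (tot_d - sd_)
  g <- n_blocks
  h_j <- n / m_j
  theta_J <- g * theta - sum((1 - m_j / n) * theta_j)
  var_J <- sum((h_j * theta - (h_j - 1) * theta_j - theta_J)^2 / (h_j - 1)) / g
  se <- sqrt(var_J)
  list(estimate = theta, se = se,
       Z = if (se > 0) theta / se else NA_real_,
       n_blocks = g, n_snps = n)
}

fstat_result <- function(statistic, pops, jk) {
  structure(
    list(statistic = statistic, pops = pops, value = jk$estimate,
         jackknife_se = jk$se, Z = jk$Z,
         significant = !is.na(jk$Z) && abs(jk$Z) > 2.58,
         n_blocks = jk$n_blocks, n_snps = jk$n_snps),
    class = "fstat_result"
  )
}

#' @export
print.fstat_result <- function(x, ...) {
  cat(sprintf("%s(%s) = %.5f  SE = %.5f  Z = %.3f%s  [%d SNPs, %d blocks]\n",
              x$statistic, paste(x$pops, collapse = ","), x$value,
              x$jackknife_se, x$Z, if (x$significant) " *" else "",
              x$n_snps, x$n_blocks))
  invisible(x)
}

get_freqs <- function(freqs, pops) {
  missing_p <- setdiff(pops, freqs$populations)
  if (length(missing_p)) stop("population(s) not in table: ",
                              paste(missing_p, collapse = ", "))
  lapply(pops, function(p) freqs$freq[p, ])
}

#' ABBA-BABA D statistic
#'
#' Per SNP, `Num = (w - x)(y - z)` and `Den = (w + x - 2wx)(y + z - 2yz)`
#' where `w, x, y, z` are the sample allele frequencies of populations
#' W, X, Y, Z; the statistic is aggregated as `sum(Num)/sum(Den)` (ratio of
#' sums; `per_snp_mean = TRUE` averages per-SNP ratios instead). SNPs with
#' any undefined frequency or a zero denominator are skipped with a logged
#' count. Standard error and Z come from the delete-m block jackknife; the
#' call is flagged significant at `|Z| > 2.58` (p < 0.01).
#'
#' @param freqs an `allele_freq_table`.
#' @param W,X,Y,Z population names (X is the outgroup in the usual layout).
#' @param n_blocks jackknife blocks.
#' @param per_snp_mean average per-SNP ratios instead of ratio of sums.
#' @return an `fstat_result`.
#' @export
d_stat <- function(freqs, W, X, Y, Z, n_blocks = 500, per_snp_mean = FALSE) {
  fr <- get_freqs(freqs, c(W, X, Y, Z))
  w <- fr[[1]]; x <- fr[[2]]; y <- fr[[3]]; z <- fr[[4]]
  num <- (w - x) * (y - z)
  den <- (w + x - 2 * w * x) * (y + z - 2 * y * z)
  bad <- is.na(num) | is.na(den) | den == 0
  if (any(bad)) message(sum(bad), " SNP(s) skipped (undefined or uninformative)")
  num[bad] <- NA; den[bad] <- NA
  if (all(bad)) stop("no informative SNPs")
  jk <- if (per_snp_mean) block_jackknife(num / den, rep(1, length(num)), n_blocks)
        else block_jackknife(num, den, n_blocks)
  fstat_result("D", c(W, X, Y, Z), jk)
}

#' f2, f3 and f4 drift statistics
#'
#' Means over SNPs of products of sample-allele-frequency differences, with
#' delete-m jackknife errors: `f2(A,B) = E[(a - b)^2]` (drift separating A
#' and B), `f3(C; A, B) = E[(c - a)(c - b)]` (drift on the path shared by
#' C->A and C->B; significantly negative values indicate the target C is
#' admixed between sources related to A and B), and
#' `f4(A,B; C,D) = E[(a - b)(c - d)]` (overlap of the A->B and C->D drift
#' paths). Computed on raw sample frequencies without finite-sample bias
#' correction, so e.g. `f2` of two small samples from one population is
#' slightly positive.
#'
#' @param freqs an `allele_freq_table`.
#' @param A,B,C,D population names (see each statistic's argument order).
#' @param n_blocks jackknife blocks.
#' @return an `fstat_result`.
#' @export
f2_stat <- function(freqs, A, B, n_blocks = 500) {
  fr <- get_freqs(freqs, c(A, B))
  contrib <- (fr[[1]] - fr[[2]])^2
  fstat_result("f2", c(A, B), block_jackknife(contrib, n_blocks = n_blocks))
}

#' @rdname f2_stat
#' @export
f3_stat <- function(freqs, C, A, B, n_blocks = 500) {
  fr <- get_freqs(freqs, c(C, A, B))
  contrib <- (fr[[1]] - fr[[2]]) * (fr[[1]] - fr[[3]])
  fstat_result("f3", c(C, A, B), block_jackknife(contrib, n_blocks = n_blocks))
}

#' @rdname f2_stat
#' @export
f4_stat <- function(freqs, A, B, C, D, n_blocks = 500) {
  fr <- get_freqs(freqs, c(A, B, C, D))
  contrib <- (fr[[1]] - fr[[2]]) * (fr[[3]] - fr[[4]])
  fstat_result("f4", c(A, B, C, D), block_jackknife(contrib, n_blocks = n_blocks))
}

#' Admixture proportions by F4 regression
#'
#' For gene flow into targets X from donors A (proportion `alpha`) and B
#' (proportion `1 - alpha`), with outgroup O, the statistics
#' `y = F4(A,O; X,B) = alpha * l` and `x = F4(B,O; X,A) = (1 - alpha) * m`
#' (with `l`, `m` the unknown shared drift lengths) satisfy
#' `y = l - (l/m) x`. Ordinary least squares across a series of targets
#' estimates the intercept `l` and slope `-l/m`, eliminating the drift
#' lengths, and each target's admixture proportion is `alpha_X = y_X / l`
#' (clamped to `[0, 1]`, with a flag when clamping occurred). Per-target
#' uncertainties come from jackknifing the whole procedure over SNP blocks.
#'
#' @param freqs an `allele_freq_table`.
#' @param O outgroup population.
#' @param A,B donor populations (`alpha` is the A-share).
#' @param targets character vector of target populations (>= 2; a warning
#'   is attached when fewer than 3).
#' @param n_blocks jackknife blocks for the alpha standard errors.
#' @return an `admixture_regression`: `outgroup`, `donors`, `targets`,
#'   `points` (per-target x, y), `intercept_l`, `slope`, `m_edge`,
#'   `r_squared`, `alphas`, `alpha_se`, `clamped`.
#' @export
f4_ratio_regression <- function(freqs, O, A, B, targets, n_blocks = 500) {
  if (length(targets) < 2) stop("need >= 2 target populations")
  if (length(targets) < 3) warning("fewer than 3 targets: regression is exact fit")
  fr <- get_freqs(freqs, c(O, A, B))
  o <- fr[[1]]; a <- fr[[2]]; b <- fr[[3]]
  tx <- get_freqs(freqs, targets)
  L <- length(o)
  # per-SNP contributions: y = F4(A,O;X,B), x = F4(B,O;X,A)
  ycon <- vapply(tx, function(x_) (a - o) * (x_ - b), numeric(L))
  xcon <- vapply(tx, function(x_) (b - o) * (x_ - a), numeric(L))
  ok <- stats::complete.cases(cbind(ycon, xcon))
  ycon <- ycon[ok, , drop = FALSE]; xcon <- xcon[ok, , drop = FALSE]
  n <- sum(ok)
  if (n < n_blocks) stop("fewer SNPs than jackknife blocks")

  fit_alphas <- function(ym, xm) {
    y <- colMeans(ym); x <- colMeans(xm)
    co <- stats::coef(stats::lm(y ~ x))
    l <- unname(co[1]); slope <- unname(co[2])
    alpha <- y / l
    list(l = l, slope = slope, alpha = alpha, x = x, y = y)
  }
  full <- fit_alphas(ycon, xcon)
  if (full$l <= 0) stop("non-positive intercept: admixture model geometry violated")
  if (!is.na(full$slope) && full$slope >= 0) {
    warning("non-negative slope: model geometry violated (check donor choice)")
  }
  r2 <- summary(stats::lm(full$y ~ full$x))$r.squared

  # jackknife alphas over SNP blocks
  block <- pmin(ceiling(seq_len(n) / (n / n_blocks)), n_blocks)
  ysum <- apply(ycon, 2, function(v) tapply(v, block, sum))
  xsum <- apply(xcon, 2, function(v) tapply(v, block, sum))
  m_j <- tabulate(block, n_blocks)
  ytot <- colSums(ysum); xtot <- colSums(xsum)
  alpha_jk <- matrix(NA_real_, n_blocks, length(targets))
  for (jb in seq_len(n_blocks)) {
    yj <- (ytot - ysum[jb, ]) / (n - m_j[jb])
    xj <- (xtot - xsum[jb, ]) / (n - m_j[jb])
    co <- stats::coef(stats::lm(yj ~ xj))
    alpha_jk[jb, ] <- yj / unname(co[1])
  }
  g <- n_blocks; h_j <- n / m_j
  alpha_se <- vapply(seq_along(targets), function(k) {
    th <- full$alpha[k]; thj <- alpha_jk[, k]
    thJ <- g * th - sum((1 - m_j / n) * thj)
    sqrt(sum((h_j * th - (h_j - 1) * thj - thJ)^2 / (h_j - 1)) / g)
  }, numeric(1))

  clamped <- full$alpha < 0 | full$alpha > 1
  alphas <- pmin(pmax(full$alpha, 0), 1)
  structure(
    list(outgroup = O, donors = c(A, B), targets = targets,
         points = data.frame(target = targets, x = full$x, y = full$y),
         intercept_l = full$l, slope = full$slope,
         m_edge = -full$l / full$slope,
         r_squared = r2,
         alphas = stats::setNames(alphas, targets),
         alpha_se = stats::setNames(alpha_se, targets),
         clamped = stats::setNames(clamped, targets),
         n_snps = n, n_blocks = n_blocks),
    class = "admixture_regression"
  )
}

#' @export
print.admixture_regression <- function(x, ...) {
  cat(sprintf(
    "F4 regression [O=%s; donors %s/%s]: l = %.5f, slope = %.3f, R2 = %.3f\n",
    x$outgroup, x$donors[1], x$donors[2], x$intercept_l, x$slope, x$r_squared))
  for (t in x$targets) {
    cat(sprintf("  alpha(%s from %s) = %.3f +/- %.3f%s\n", t, x$donors[1],
                x$alphas[t], x$alpha_se[t],
                if (x$clamped[t]) " (clamped)" else ""))
  }
  invisible(x)
}

#' Renormalized three-way source contributions
#'
#' Combines pairwise F4-regression estimates for the three donor pairs of a
#' three-source model into per-target percentages that sum to one. This is a
#' declared post-processing convention: each donor's share is averaged over
#' the two pairwise regressions involving it, then the three shares are
#' renormalized.
#'
#' @param reg_ab,reg_ac,reg_bc `admixture_regression` objects for donor
#'   pairs (A,B), (A,C), (B,C), fitted on the same targets.
#' @return matrix targets x 3 donors of proportions summing to 1 per row.
#' @export
three_way_contributions <- function(reg_ab, reg_ac, reg_bc) {
  targets <- reg_ab$targets
  stopifnot(identical(targets, reg_ac$targets), identical(targets, reg_bc$targets))
  A <- (reg_ab$alphas + reg_ac$alphas) / 2
  B <- ((1 - reg_ab$alphas) + reg_bc$alphas) / 2
  C <- ((1 - reg_ac$alphas) + (1 - reg_bc$alphas)) / 2
  out <- cbind(A, B, C)
  out <- out / rowSums(out)
  rownames(out) <- targets
  colnames(out) <- c(reg_ab$donors[1], reg_ab$donors[2], reg_ac$donors[2])
  out
}
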