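---
title: "Models and methods behind popdrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind popdrift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`popdrift` implements a connected chain of population-genetic estimators —
differentiation, marker selection, LD-based demography, and f-statistic
gene-flow inference — for diploid SNP panels of closely related
populations. This vignette states each model, its assumptions, the
numerical choices made where a convention was genuinely open, and what the
synthetic-data recovery tests do and do not establish.

## The genotype panel and its filters

All stages consume a `genotype_panel`: an individuals × SNPs matrix of
alt-allele dosages in {0, 1, 2, NA} with SNP metadata, a
sample→population map and, when every VCF genotype is `|`-phased, the
underlying haplotypes. Dosage orientation follows the VCF REF/ALT fields;
every statistic in the package is algebraically invariant to flipping that
orientation at any subset of SNPs (tested by randomized recoding), so no
strand harmonization is needed beyond consistent REF/ALT.

Filters mirror common array-QC practice:

- `qc_missingness()` removes SNPs whose missing-call fraction is **not
  strictly below** the threshold (default 0.05) — a SNP missing in exactly
  5% of samples is removed.
- `thin_by_distance()` is a greedy per-chromosome scan keeping a SNP iff it
  lies more than `min_gap_bp` (default 500 kb) past the last kept SNP;
  deterministic, and the first SNP of each chromosome is always kept.
- `ld_prune()` slides a window (default 50 SNPs, step 5) and, while any
  pair exceeds the r² threshold (default 0.8, inclusive up to float slack
  so a threshold of 1 still removes perfect duplicates), drops the member
  with more missing data (tie: the later position). The window/step/r²
  defaults are a declared convention — array studies rarely publish their
  exact pruning parameters — and are exposed as arguments.

When no genetic map is supplied, cM positions default to 1 cM/Mb, the
conventional genome-wide average; `attach_genetic_map()` interpolates a
user map instead (linear, with terminal-interval extrapolation).

## Differentiation and structure

**F_ST.** `pairwise_fst()` implements the Weir–Cockerham (1984) unbiased
estimator from per-SNP variance components a (between populations) and
a+b+c (total), with per-SNP non-missing sample sizes, aggregated as a ratio
of sums Σa/Σ(a+b+c). Ratio-of-sums is the standard multi-locus form and is
stable when many SNPs are nearly monomorphic; a per-SNP-mean mode is
available for sensitivity (`per_snp_mean = TRUE`). Estimates can be
slightly negative on weakly differentiated pairs; that is a property of the
unbiased estimator, not an error. SNPs monomorphic across the pooled pair,
or with fewer than two genotyped samples in either population, are
skipped. Under the package's Balding–Nichols generator with equal branch
drifts F per population, the estimator converges to ≈ F (the mean of the
two branch drifts), which the recovery tests pin at ±20%.

**ASD and trees.** The allele-sharing distance is d(i,j) = mean over
jointly observed SNPs of |gᵢ−gⱼ|/2 — equivalently one minus the shared
allele fraction of unphased dosages. Among the several "allele sharing"
variants in use, this one was chosen because it is a metric on complete
data (triangle inequality tested) and lies in [0,1] with the natural
extremes. Trees come from canonical Saitou–Nei neighbor joining (`ape`);
negative branch lengths — an NJ artifact — are clamped to zero with the
deficit moved to the sister edge, keeping path lengths as close to
additive as possible. On exactly additive matrices NJ reproduces the
generating tree to numerical precision (tested). Population-level trees are
built by applying NJ to the F_ST matrix; this is a deliberate,
clearly-labeled substitute for likelihood-based population trees, which are
out of scope.

**PCA.** Genotypes are column-centered and scaled by √(p̂(1−p̂)) with the
shrunken frequency p̂ = (1+Σg)/(2+2n) — the add-one shrinkage avoids
division by zero at nearly monomorphic sites — and missing cells are set to
the column mean (zero after centering). Scores are eigenvectors of the
sample covariance scaled by √λ. Variance fractions are reported in two
conventions, against the total variance and against the sum of the top ten
eigenvalues, because both are commonly quoted and they differ by an order
of magnitude on weakly structured panels. A single-SNP panel is permitted
so that one-marker AIM panels can be scored.

**K-means.** Clustering runs on the top 10 PCs via `stats::kmeans` with 25
random restarts under a fixed seed. R's standard K-means with multiple
restarts was chosen over specialized seeding schemes: it is the tool this
analysis is normally done with, and with 25 restarts on ≤ a few hundred
samples the global optimum is reached reliably (duplicate runs are
byte-identical by construction). Output includes, per population, the
fraction of its samples in each cluster — the natural summary when cluster
and population labels disagree.

## AIM selection

Candidate markers are ranked by per-SNP pairwise F_ST (ties broken by SNP
order, so selection is deterministic). The greedy loop adds the
highest-ranked SNP farther than 500 kb from every already-chosen SNP on the
same chromosome, then scores the panel: PCA on the two populations
restricted to the panel, PC1 thresholded at the midpoint of the two
population means (orientation fixed so the first population is positive),
and the confusion table summarized by the MCC, whose denominator is
computed as a single product before the square root so a perfect split
yields exactly 1 (the stopping rule compares against a target of 1.0).
Selection stops at the target MCC or a panel-size cap, recording the full
MCC trajectory. The MCC is evaluated on the training individuals by
default — perfect-separation panel sizes should be read as training-set
figures, and a held-out evaluation is available by scoring a disjoint
sample subset. With 40–50 samples per population, training MCC reaches 1
quickly even for weakly differentiated pairs, so panel sizes mostly
reflect the tail of the per-SNP F_ST ranking rather than the global
differentiation; the recovery tests therefore assert the monotone trend
(size non-increasing in simulated drift, fixed seeds) rather than absolute
sizes.

## LD, N_e(t) and divergence dating

For one population's phased haplotypes, all same-chromosome SNP pairs with
genetic distance in [c_min, c_max) — default 0.001–2.5 cM in 2500 classes
of 0.001 cM — contribute r² = D²/(p₁q₁p₂q₂) to their class; each class
reports mean r² minus 1/n, the standard correction for the number n of
chromosomes sampled. The class at distance c Morgans is interpreted through
the drift–recombination equilibrium relation E[r²_adj] = 1/(2+4N_e c),
giving

- t = 1/(2c) generations ago (so 0.01 cM ↔ 5000 generations and 0.25 cM ↔
  200 generations), and
- N_e = (1/r²_adj − 2)/(4c),

with classes failing the guards (fewer than `min_pairs` pairs, non-positive
adjusted r²) reported as missing. The class midpoint represents c — the
width is 0.001 cM, so any within-class position convention changes nothing
at reporting precision. The inter-population N_e used for dating is the
harmonic mean of each population's per-class N_e over the 0.01–0.25 cM
classes, then the arithmetic mean of the two harmonic means; a pooled
alternative (one harmonic mean over both populations' classes) is available
behind `pooled = TRUE` because the averaging convention is genuinely
ambiguous. Divergence is dated as T_F = 2·N_e·F_ST generations, converted
at 25 years per generation (an argument). Negative F_ST estimates are
clamped to zero with a warning. This dating is known to be biased downward
when gene flow continued after the split; the package reports the estimate
and leaves that caveat to the analyst.

**What the Wright–Fisher recovery shows.** The forward simulator evolves
2N_e haplotypes with Poisson crossovers for 4N_e generations from linkage
equilibrium and has no mutation. Without mutation the simulated equilibrium
r² at scaled distance ρ = 4N_e c is close to 1/(1+ρ), while the estimator
inverts 1/(2+ρ) (the mutation-drift convention); the two agree to within
~1/(1+ρ). The end-to-end recovery experiments therefore use distance
classes with ρ ∈ [8, 40], where the discrepancy is under ~11% and the
estimator is also far from its 1/r²−2 singularity; bins are pooled over 80
replicate chromosomes before the harmonic mean, which keeps the
genealogical noise of single short chromosomes out of the heavy-tailed
per-seed harmonic means. Under those conditions N_e ∈ {200, 500, 1000} is
recovered within 30% (typically 10–20%, with a mild upward tendency at
N_e = 1000 consistent with the constant mismatch). This validates the
estimator pipeline — binning, adjustment, inversion, harmonic averaging —
at desk scale; it does not validate the 1/(2+ρ) constant itself for
mutation-driven polymorphism, nor human-genome bin widths, which the
defaults nevertheless follow.

## f-statistics and gene flow

D, f2, f3 and f4 are computed from per-population **sample** allele
frequencies (with per-SNP haploid sample sizes from the non-missing
genotypes):

- D = ΣNum/ΣDen with Num = (w−x)(y−z), Den = (w+x−2wx)(y+z−2yz). The
  per-SNP ratio notation in the literature is ambiguous about aggregation;
  ratio of sums is the standard, numerically stable choice, and a
  per-SNP-mean mode exists for sensitivity. SNPs with undefined frequencies
  or zero denominator are skipped with a logged count.
- f2(A,B) = mean (a−b)²; f3(C;A,B) = mean (c−a)(c−b); f4(A,B;C,D) =
  mean (a−b)(c−d). **No finite-sample bias correction is applied** — the
  implemented formulas contain none. The documented consequences: f2 of two
  finite samples from one population is positive (≈ Σpq/n), and f3 of an
  admixed target carries an upward bias ≈ E[pq]/n_C, so admixture is
  detectable only when α(1−α)·f2(donors) exceeds that term. The analysis
  scripts size their admixture scenario accordingly (donor drift 0.04,
  100-sample targets); with closer donors or smaller samples a true
  admixture signal can be hidden — a real limitation of the uncorrected
  estimator, inherited deliberately.
- Significance is |Z| > 2.58 (two-sided p < 0.01); no multiple-testing
  correction is applied, matching standard practice for these scans.

**Jackknife.** Standard errors come from a delete-m jackknife over
contiguous blocks in SNP order (default 500 blocks), a proxy for physical
linkage blocks. The variance formula is the weighted delete-m form (block
weights proportional to SNP counts), which reduces to the ordinary
jackknife for equal blocks; against iid contributions it reproduces σ/√n
within 15% and is stable to doubling the block count. Blocks are SNP-count
balanced rather than genetic-length balanced — with roughly uniform marker
spacing the difference is minor; with very uneven maps the block count is
an argument.

**F4 regression.** For targets X admixed between donors A (share α) and B,
with outgroup O, y = F4(A,O;X,B) = αl and x = F4(B,O;X,A) = (1−α)m imply
y = l − (l/m)x: OLS over the target series estimates l (intercept) and m
(−intercept/slope), and α_X = y_X/l̂, clamped to [0,1] with a flag. The
geometry checks are enforced: a non-positive intercept is an error, a
non-negative slope with a real fit warns that the donors are likely
misspecified. Per-α uncertainties jackknife the **whole** procedure
(points, fit, ratio) over SNP blocks. Two targets are the algebraic
minimum; fewer than three draws a warning since the line is then an exact
fit. Noiseless mixture targets are recovered to machine precision and
simulated series (5 targets, 5×10⁴ SNPs) within ±0.05 — both tested.
Three-source percentages are produced by `three_way_contributions()`, which
averages each donor's share over the two pairwise regressions involving it
and renormalizes the three shares to sum to one; this is a declared
post-processing convention, not an identified three-way model.

## Synthetic-data generators: scope of evidence

- `simulate_divergence()` draws, per SNP, an ancestral frequency from
  Uniform(0.05, 0.95) (avoiding monomorphic sites; configurable) and each
  population's frequency from the Balding–Nichols Beta with its branch
  drift F, then binomial genotypes. It matches the F_ST scale and the
  star-tree covariance structure of real close populations but has
  **independent SNPs** (no LD), no ascertainment bias, and no shared
  internal branches unless composed explicitly.
- `simulate_admixed_targets()` draws each target allele from donor A's
  sample frequency with probability α, else donor B's — instantaneous
  admixture with no post-admixture drift and no LD decay of ancestry
  blocks.
- `simulate_wright_fisher_haplotypes()` (compiled core) provides real
  genealogical LD with known N_e, but constant size, no mutation and no
  selection.

Passing recovery tests on these generators demonstrates estimator
correctness — formulas, aggregation, error calibration — under the stated
models. It does not demonstrate robustness to ascertainment, phasing
error, batch effects or non-equilibrium demography, which real panels all
have.

## Problem sizes and determinism

Test and script workloads were sized for a single desktop core: unit
panels of 10³–10⁴ SNPs and tens of samples; acceptance-level experiments
at 2–5×10⁴ SNPs, 200 D-test null replicates, and 80 pooled Wright–Fisher
chromosomes per N_e. Every stochastic stage takes an explicit seed and is
reproducible bit-for-bit; the pipeline manifest records seeds, parameters
and per-stage SNP counts so a run can be reproduced from its outputs.
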