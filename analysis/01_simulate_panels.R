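#!/usr/bin/env Rscript
# Build the synthetic study panels used by the downstream analysis scripts.
#
# The divergence panel emulates a set of closely related East-Asian-style
# populations on a star tree. Pairwise Weir-Cockerham F_ST under this model
# comes out near the mean of the two branch drifts, so the drift values
# below put the close pairs at the few-per-mil F_ST scale typical of
# mainland/peninsula/island comparisons (~0.0014-0.005) with a distant
# outgroup an order of magnitude beyond. Truth (per-branch drift values) is
# written alongside so later scripts can compare estimates against it.

suppressPackageStartupMessages(library(popdrift))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
seed <- 20260926

drifts <- c(NORTH = 0.0014, SOUTH = 0.0014, PEN = 0.0038, ISL = 0.0052,
            SDAI = 0.009, OUT = 0.16)
model <- divergence_model(drifts, n_samples = 40, n_snps = 20000,
                          spacing_bp = 150000)
panel <- simulate_divergence(model, seed = seed)
cat("simulated:", n_samples(panel), "samples x", n_snps(panel), "SNPs,",
    length(populations(panel)), "populations\n")

write_vcf(panel, "results/data/divergence_panel.vcf",
          "results/data/divergence_panel.pops.tsv")
jsonlite::write_json(
  list(seed = seed, drift = as.list(drifts), n_samples = 40, n_snps = 20000),
  "results/data/divergence_panel.truth.json", auto_unbox = TRUE, digits = NA)

# Admixture series for the gene-flow stage, built on its own tree: two
# moderately diverged donors (NDON, SDON; drift 0.04 each, the scale of
# donor proxies a few percent F_ST from the targets), a distant outgroup
# (OUTG), and targets mixing the donors at known alphas. Donor divergence
# and the 100-sample targets keep the admixture signal of f3 above the
# finite-sample variance term the uncorrected estimator carries.
adm_model <- divergence_model(c(OUTG = 0.15, NDON = 0.04, SDON = 0.04),
                              n_samples = 100, n_snps = 30000,
                              spacing_bp = 100000)
adm_src <- simulate_divergence(adm_model, seed = seed + 1)
alphas <- c(mixA = 0.2, mixB = 0.4, mixC = 0.6, mixD = 0.8)
targets <- simulate_admixed_targets(adm_src, "NDON", "SDON", alphas,
                                    n_samples = 100, seed = seed + 2)
adm <- combine_panels(adm_src, targets)
write_vcf(adm, "results/data/admixture_panel.vcf",
          "results/data/admixture_panel.pops.tsv")
jsonlite::write_json(list(seed = seed + 1, alphas = as.list(alphas),
                          donors = c("NDON", "SDON"), outgroup = "OUTG"),
                     "results/data/admixture_panel.truth.json",
                     auto_unbox = TRUE, digits = NA)
cat("admixture series written: targets", paste(names(alphas), collapse = ", "),
    "with alpha", paste(alphas, collapse = ", "), "\n")
cat("done; panels under results/data/\n")
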