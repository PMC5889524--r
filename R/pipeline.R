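#' Run the full analysis pipeline on a genotype panel
#'
#' Config-driven orchestration of the package's stages in dependency order:
#' missingness QC, population structure (F_ST matrix, ASD + NJ tree, PCA,
#' K-means on top PCs), AIM panel selection, LD-based N_e trajectories with
#' F_ST divergence dating, D/f3 tests, and F4-regression admixture
#' proportions. Each enabled stage writes TSV/newick outputs under
#' `out_dir` and the run ends with a JSON manifest recording parameters,
#' seeds, per-stage SNP counts and any stage errors. A stage that fails
#' (or cannot run, e.g. LD on an unphased panel) is recorded with its
#' reason; independent stages still run. Reruns with identical config and
#' input reproduce identical outputs.
#'
#' @param config a list:
#'   \describe{
#'     \item{panel}{a `genotype_panel`, or `input = list(vcf=, pop_table=,
#'       map=)` to read one.}
#'     \item{out_dir}{output directory (created).}
#'     \item{seed}{integer seed recorded and used for seeded stages.}
#'     \item{qc}{`list(max_missing=0.05)`.}
#'     \item{structure}{`NULL` to skip, else `list(thin_gap_bp=500000,
#'       n_pcs=10, K=<int or NULL>)`.}
#'     \item{aims}{`NULL` or `list(pairs=list(c(A,B),...), min_gap_bp,
#'       target_mcc, max_snps)`.}
#'     \item{ld}{`NULL` or `list(populations=<chr>, pairs=list(c(A,B),...),
#'       c_min_cM, c_max_cM, width_cM, interpop_range_cM,
#'       years_per_generation)`.}
#'     \item{fstats}{`NULL` or `list(d_tests=list(c(W,X,Y,Z),...),
#'       f3_tests=list(c(C,A,B),...), n_blocks)`.}
#'     \item{f4reg}{`NULL` or `list(O=, A=, B=, targets=<chr>, n_blocks)`.}
#'   }
#' @return the manifest list, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  panel <- if (!is.null(config$panel)) config$panel
           else read_vcf(config$input$vcf, config$input$pop_table,
                         map = config$input$map)
  manifest <- list(seed = seed, input_snps = n_snps(panel),
                   input_samples = n_samples(panel),
                   stages = list(), outputs = character(0))
  fail <- function(stage, msg) {
    manifest$stages[[stage]] <<- list(status = "failed", reason = msg)
  }
  done <- function(stage, info) {
    manifest$stages[[stage]] <<- c(list(status = "ok"), info)
  }
  add_out <- function(f) manifest$outputs <<- c(manifest$outputs, basename(f))
  tsv <- function(df, name) {
    f <- file.path(out_dir, name)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    add_out(f)
    f
  }

  ## QC
  max_missing <- if (is.null(config$qc$max_missing)) 0.05 else config$qc$max_missing
  before <- n_snps(panel)
  panel <- qc_missingness(panel, max_missing)
  done("qc", list(max_missing = max_missing, snps_in = before,
                  snps_removed = before - n_snps(panel),
                  snps_out = n_snps(panel)))

  ## structure
  if (!is.null(config$structure)) {
    st <- config$structure
    tryCatch({
      gap <- if (is.null(st$thin_gap_bp)) 500000 else st$thin_gap_bp
      sp <- thin_by_distance(panel, gap)
      fm <- fst_matrix(panel)
      tsv(data.frame(population = fm$populations, round(fm$values, 6)),
          "fst_matrix.tsv")
      am <- asd_matrix(sp)
      tsv(data.frame(sample = am$sample_ids, round(am$values, 6)),
          "asd_matrix.tsv")
      if (n_samples(sp) >= 3) {
        write_newick(nj_tree(am), file.path(out_dir, "nj_individuals.nwk"))
        add_out(file.path(out_dir, "nj_individuals.nwk"))
      }
      if (length(fm$populations) >= 3) {
        write_newick(nj_tree(fm$values), file.path(out_dir, "nj_populations.nwk"))
        add_out(file.path(out_dir, "nj_populations.nwk"))
      }
      n_pcs <- if (is.null(st$n_pcs)) 10 else st$n_pcs
      pc <- pca_panel(sp, n_components = n_pcs)
      k <- min(n_pcs, ncol(pc$coordinates))
      tsv(data.frame(sample = rownames(pc$coordinates),
                     population = unname(pc$pop_of),
                     round(pc$coordinates, 6)), "pca_coordinates.tsv")
      tsv(data.frame(component = seq_len(k),
                     eigenvalue = pc$eigenvalues[1:k],
                     var_frac_total = pc$var_frac_total[1:k],
                     var_frac_top10 = pc$var_frac_top10[1:k]),
          "pca_variance.tsv")
      info <- list(snps_structure = n_snps(sp), thin_gap_bp = gap)
      if (!is.null(st$K)) {
        km <- kmeans_on_pcs(pc, K = st$K, n_pcs = n_pcs, seed = seed)
        tsv(data.frame(population = rownames(km$fractions),
                       round(km$fractions, 4)), "kmeans_fractions.tsv")
        info$K <- st$K
      }
      done("structure", info)
    }, error = function(e) fail("structure", conditionMessage(e)))
  }

  ## AIMs
  if (!is.null(config$aims)) {
    ai <- config$aims
    tryCatch({
      rows <- list()
      for (pair in ai$pairs) {
        ap <- select_aims(panel, pair[1], pair[2],
                          min_gap_bp = if (is.null(ai$min_gap_bp)) 500000 else ai$min_gap_bp,
                          target_mcc = if (is.null(ai$target_mcc)) 1.0 else ai$target_mcc,
                          max_snps = if (is.null(ai$max_snps)) 200 else ai$max_snps)
        rows[[paste(pair, collapse = "_")]] <- data.frame(
          popA = pair[1], popB = pair[2],
          rank = seq_along(ap$snps), snp_id = ap$snps,
          snp_fst = round(ap$snp_fst, 6),
          mcc = round(ap$mcc_trajectory, 4)
        )
      }
      tsv(do.call(rbind, rows), "aim_panels.tsv")
      sizes <- vapply(rows, nrow, integer(1))
      done("aims", list(panel_sizes = as.list(sizes)))
    }, error = function(e) fail("aims", conditionMessage(e)))
  }

  ## LD / Ne / divergence dating
  if (!is.null(config$ld)) {
    ld <- config$ld
    if (!panel$phased) {
      fail("ld", "panel is not phased; LD stages skipped")
    } else tryCatch({
      pops <- if (is.null(ld$populations)) populations(panel) else ld$populations
      trajs <- list()
      all_rows <- list()
      for (p in pops) {
        bins <- bin_r2(panel, p,
                       c_min_cM = if (is.null(ld$c_min_cM)) 0.001 else ld$c_min_cM,
                       c_max_cM = if (is.null(ld$c_max_cM)) 2.5 else ld$c_max_cM,
                       width_cM = if (is.null(ld$width_cM)) 0.001 else ld$width_cM)
        tr <- ne_trajectory(bins, p)
        trajs[[p]] <- tr
        all_rows[[p]] <- tr[!is.na(tr$Ne), ]
      }
      tsv(do.call(rbind, all_rows), "ne_trajectories.tsv")
      info <- list(populations = pops)
      if (!is.null(ld$pairs)) {
        rng <- if (is.null(ld$interpop_range_cM)) c(0.01, 0.25) else ld$interpop_range_cM
        ypg <- if (is.null(ld$years_per_generation)) 25 else ld$years_per_generation
        drows <- lapply(ld$pairs, function(pair) {
          ne <- interpop_ne(trajs[[pair[1]]], trajs[[pair[2]]], c_range = rng)
          fst <- pairwise_fst(panel, pair[1], pair[2])$fst
          dv <- divergence_time(pair, fst, ne, years_per_generation = ypg)
          data.frame(popA = pair[1], popB = pair[2], fst = dv$fst,
                     Ne_interpop = dv$Ne_interpop,
                     T_F_generations = dv$T_F_generations,
                     T_F_years = dv$T_F_years)
        })
        tsv(do.call(rbind, drows), "divergence_times.tsv")
      }
      done("ld", info)
    }, error = function(e) fail("ld", conditionMessage(e)))
  }

  ## D / f3 tests
  if (!is.null(config$fstats)) {
    fs <- config$fstats
    tryCatch({
      fr <- allele_frequencies(panel)
      nb <- if (is.null(fs$n_blocks)) 500 else fs$n_blocks
      if (!is.null(fs$d_tests)) {
        rows <- lapply(fs$d_tests, function(q) {
          r <- d_stat(fr, q[1], q[2], q[3], q[4], n_blocks = nb)
          data.frame(popW = q[1], popA = q[2], popY = q[3], popZ = q[4],
                     D = r$value, Z = r$Z, significant = r$significant)
        })
        tsv(do.call(rbind, rows), "d_tests.tsv")
      }
      if (!is.null(fs$f3_tests)) {
        rows <- lapply(fs$f3_tests, function(q) {
          r <- f3_stat(fr, q[1], q[2], q[3], n_blocks = nb)
          data.frame(popC = q[1], popA = q[2], popB = q[3],
                     f3 = r$value, Z = r$Z, significant = r$significant)
        })
        tsv(do.call(rbind, rows), "f3_tests.tsv")
      }
      done("fstats", list(n_blocks = nb))
    }, error = function(e) fail("fstats", conditionMessage(e)))
  }

  ## F4 regression
  if (!is.null(config$f4reg)) {
    fg <- config$f4reg
    tryCatch({
      fr <- allele_frequencies(panel)
      nb <- if (is.null(fg$n_blocks)) 500 else fg$n_blocks
      reg <- f4_ratio_regression(fr, fg$O, fg$A, fg$B, fg$targets, n_blocks = nb)
      tsv(data.frame(target = reg$targets,
                     F4_B_O_X_A = reg$points$x, F4_A_O_X_B = reg$points$y,
                     alpha = reg$alphas, alpha_se = reg$alpha_se,
                     clamped = reg$clamped),
          "f4_regression.tsv")
      done("f4reg", list(intercept_l = reg$intercept_l, slope = reg$slope,
                         r_squared = reg$r_squared))
    }, error = function(e) fail("f4reg", conditionMessage(e)))
  }

  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
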