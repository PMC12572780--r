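#' Pipeline configuration
#'
#' Collects every threshold the pipeline uses so that a run is fully
#' determined by (config, inputs, seed). With no input paths the
#' simulator supplies the dataset (`preset = "paper-like"`).
#'
#' @param preset `"paper-like"` to simulate the default planted-supergene
#'   dataset; ignored when `vcf` is given.
#' @param vcf,gff3,samples,microsats optional input file paths.
#' @param sim a [sim_config()] overriding the preset's simulator settings.
#' @param fst_window FST scan window size, bp.
#' @param pca_window rolling-PCA window size, bp.
#' @param percentile genome-wide window-FST percentile defining the scan
#'   threshold. The paper-like preset uses 80: the planted region spans
#'   ~13 percent of the desk-scale genome's windows, so the threshold
#'   percentile must sit below the non-region fraction of windows; on a
#'   genome-scale dataset (region ~4 percent of windows) 95 is the
#'   conventional choice.
#' @param max_gap_windows gap tolerance in run detection.
#' @param min_span minimum supergene span, bp (default 10 x fst_window).
#' @param min_gq_site,min_dp,max_missing_frac variant filters, see
#'   [filter_variants()].
#' @param morph_lo,morph_hi morph cut-offs in mm, see [classify_morph()].
#' @param dunn_adjust p-adjustment for the Dunn post hoc test.
#' @param matriline_exact_limit see [min_matrilines()].
#' @param seed master RNG seed.
#' @param out_dir output directory (`NULL`: nothing written).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = "paper-like", vcf = NULL, gff3 = NULL,
                            samples = NULL, microsats = NULL, sim = NULL,
                            fst_window = 10000, pca_window = 50000,
                            percentile = NULL, max_gap_windows = 2,
                            min_span = NULL, min_gq_site = 20, min_dp = 3,
                            max_missing_frac = 0.6, morph_lo = 1.04,
                            morph_hi = 1.08, dunn_adjust = "holm",
                            matriline_exact_limit = 9, seed = 1,
                            out_dir = NULL) {
  if (is.null(percentile)) {
    percentile <- if (is.null(vcf) && identical(preset, "paper-like")) 80 else 95
  }
  structure(
    list(preset = preset, vcf = vcf, gff3 = gff3, samples = samples,
         microsats = microsats, sim = sim, fst_window = fst_window,
         pca_window = pca_window, percentile = percentile,
         max_gap_windows = max_gap_windows,
         min_span = if (is.null(min_span)) 10 * fst_window else min_span,
         min_gq_site = min_gq_site, min_dp = min_dp,
         max_missing_frac = max_missing_frac, morph_lo = morph_lo,
         morph_hi = morph_hi, dunn_adjust = dunn_adjust,
         matriline_exact_limit = matriline_exact_limit, seed = seed,
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full supergene pipeline
#'
#' simulate/load -> filter -> FST scan -> supergene detection -> rolling
#' PCA -> genotype assignment -> diagnostic SNPs -> phenotype and colony
#' associations -> matriline estimation. Writes stage TSVs and a JSON
#' report when `cfg$out_dir` is set; the report is identical for
#' identical (cfg, inputs, seed).
#'
#' @param cfg a [pipeline_config()].
#' @return the run report (a list), invisibly the same as written to
#'   `report.json`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log_lines <- c(
    sprintf("fst_window=%d pca_window=%d percentile=%g", cfg$fst_window,
            cfg$pca_window, cfg$percentile),
    sprintf("max_gap_windows=%d min_span=%d", cfg$max_gap_windows,
            cfg$min_span),
    sprintf("filters: minQ=%g minDP=%g max_missing=%g", cfg$min_gq_site,
            cfg$min_dp, cfg$max_missing_frac),
    sprintf("morph cut-offs: lo=%g hi=%g mm", cfg$morph_lo, cfg$morph_hi),
    sprintf("seed=%d", cfg$seed)
  )

  dat <- .stage("input", {
    if (!is.null(cfg$vcf)) {
      list(
        gm = read_vcf(cfg$vcf),
        gene_set = if (!is.null(cfg$gff3)) read_gff3(cfg$gff3),
        samples = if (!is.null(cfg$samples)) read_samples(cfg$samples),
        microsats = if (!is.null(cfg$microsats))
          utils::read.delim(cfg$microsats, stringsAsFactors = FALSE),
        truth = NULL
      )
    } else {
      sim <- if (is.null(cfg$sim)) sim_config() else cfg$sim
      simulate_dataset(sim, seed = cfg$seed)
    }
  })

  gm <- .stage("filter", filter_variants(dat$gm, cfg$min_gq_site, cfg$min_dp,
                                         cfg$max_missing_frac))

  fst <- .stage("fst_scan", {
    ph <- dat$samples[!is.na(dat$samples$head_width_mm), ]
    morph <- classify_morph(ph$head_width_mm, cfg$morph_lo, cfg$morph_hi)
    grp <- stats::setNames(morph, ph$sample_id)
    grp <- grp[grp %in% c("macrogyne", "microgyne")]
    if (length(unique(grp)) < 2) stop("need both macrogyne and microgyne samples")
    windowed_fst(gm, grp, window_size = cfg$fst_window)
  })
  threshold <- .stage("threshold", fst_percentile_threshold(fst, cfg$percentile))
  call <- .stage("detect", detect_supergene(fst, threshold,
                                            cfg$max_gap_windows, cfg$min_span))
  if (!call$found) stop("pipeline stage 'detect' failed: no supergene call")
  log_lines <- c(log_lines, sprintf("fst threshold (p%g) = %.4f",
                                    cfg$percentile, threshold))

  pca <- .stage("pca", rolling_pca(gm, call$chrom, cfg$pca_window))
  assignment <- .stage("assign", assign_genotypes(gm, call, pca))
  dat$samples$genotype_class <-
    assignment$samples$class[match(dat$samples$sample_id,
                                   assignment$samples$sample_id)]

  diag <- .stage("diagnostics", {
    ab <- ab_het_sites(gm, assignment, call$chrom, call$start, call$end)
    fixed <- fixed_diff_sites(gm, assignment, ab)
    counts <- NULL
    if (!is.null(dat$gene_set)) {
      counts <- rank_candidate_genes(
        cds_diagnostic_counts(gm, fixed, longest_isoform(dat$gene_set))
      )
    }
    list(ab = ab, fixed = fixed, gene_counts = counts)
  })

  assoc <- .stage("associations", {
    ph <- dat$samples[!is.na(dat$samples$genotype_class) &
                        !is.na(dat$samples$head_width_mm), ]
    groups <- split(ph$head_width_mm, ph$genotype_class)
    kw <- kruskal_wallis(groups)
    dunn <- dunn_posthoc(groups, cfg$dunn_adjust)
    colony <- colony_genotype_association(dat$samples)
    list(kw = kw, dunn = dunn, colony = colony)
  })

  matr <- .stage("matrilines", {
    if (is.null(dat$microsats)) return(NULL)
    mono <- estimate_matrilines(dat$microsats, "monandry",
                                cfg$matriline_exact_limit)
    poly <- estimate_matrilines(dat$microsats, "polyandry",
                                cfg$matriline_exact_limit)
    queens <- dat$samples[dat$samples$caste == "queen" &
                            !is.na(dat$samples$colony_id), ]
    col_class <- vapply(split(queens$genotype_class, queens$colony_id),
                        function(cl) if (any(cl == "AA")) "AA" else "non_AA",
                        character(1))
    common <- intersect(mono$colony_id, names(col_class))
    m <- mono[match(common, mono$colony_id), ]
    assoc_m <- matriline_genotype_association(m$n_matrilines,
                                              unname(col_class[common]))
    list(monandry = mono, polyandry = poly, association = assoc_m)
  })

  report <- list(
    seed = cfg$seed,
    thresholds = list(fst_window = cfg$fst_window,
                      pca_window = cfg$pca_window,
                      percentile = cfg$percentile, fst_threshold = threshold,
                      morph_lo = cfg$morph_lo, morph_hi = cfg$morph_hi),
    supergene = list(chrom = call$chrom, start = call$start, end = call$end,
                     n_windows = call$n_windows),
    genotype_classes = as.list(table(assignment$samples$class)),
    assignment_validated = assignment$validated,
    n_ab_het_sites = length(diag$ab),
    n_fixed_diff_sites = length(diag$fixed),
    top_genes = if (!is.null(diag$gene_counts))
      utils::head(diag$gene_counts[c("gene_id", "n_diagnostic")], 5),
    kruskal_wallis = assoc$kw,
    dunn = assoc$dunn,
    fisher_colony = list(table = assoc$colony$table, p = assoc$colony$p),
    fisher_matriline = if (!is.null(matr))
      list(table = matr$association$table, p = matr$association$p),
    log = log_lines
  )

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_window_table(fst, file.path(cfg$out_dir, "fst_windows.tsv"))
    pc <- cbind(pca$windows, as.data.frame(pca$scores))
    write_window_table(pc, file.path(cfg$out_dir, "pca_windows.tsv"))
    utils::write.table(assignment$samples,
                       file.path(cfg$out_dir, "genotype_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(diag$fixed)) {
      ds <- gm$sites[diag$fixed, ]
      ds$ab_all_het <- TRUE
      ds$fixed_opposite <- TRUE
      utils::write.table(ds, file.path(cfg$out_dir, "diagnostic_sites.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(diag$gene_counts)) {
      utils::write.table(diag$gene_counts,
                         file.path(cfg$out_dir, "gene_counts.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(matr)) {
      utils::write.table(merge(matr$monandry, matr$polyandry,
                               by = "colony_id",
                               suffixes = c("_monandry", "_polyandry")),
                         file.path(cfg$out_dir, "matrilines.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(report)
}
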