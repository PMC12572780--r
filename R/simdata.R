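#' Configuration for the synthetic supergene dataset
#'
#' Builds the configuration object consumed by the simulator. The defaults
#' emulate, at desk scale, a genome carrying one non-recombining divergent
#' haplotype block (a supergene) with three genotype classes AA/AB/BB,
#' class-dependent queen head widths, monogyne/polygyne colony structure
#' and 5-locus haplodiploid microsatellite families.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param snp_density expected SNPs per bp.
#' @param supergene list(chrom, start, end): planted non-recombining region
#'   (1-based inclusive bp).
#' @param fixed_diff_fraction fraction `d` of supergene SNPs that are fixed
#'   0-vs-1 differences between the A and B haplotype pools, in (0, 1).
#' @param n_founders founder haplotypes per pool.
#' @param switch_rate background founder-mosaic switch rate per bp; makes
#'   background LD decay with distance.
#' @param class_freqs named frequencies of the AA/AB/BB classes (sum to 1).
#' @param n_samples number of queens/gynes in the cohort.
#' @param pheno_mean named per-class head-width means (mm).
#' @param pheno_sd head-width standard deviation (mm).
#' @param colony_plan list(n_monogyne, n_polygyne, polygyne_queens
#'   (integer vector the per-colony queen number is drawn from), p_serial
#'   (probability a monogyne colony carries a second, replacement-queen
#'   matriline), workers_per_colony).
#' @param n_loci microsatellite loci.
#' @param alleles_per_locus alleles per microsatellite locus.
#' @param allele_freqs optional list of per-locus allele frequency vectors;
#'   default uniform.
#' @param dropout_rate,false_allele_rate microsatellite genotyping error
#'   rates (per heterozygous call / per allele).
#' @param depth_mean mean per-call sequencing depth (Poisson).
#' @param qual_range range site QUAL values are drawn from.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2,
                       chrom_length = 10e6,
                       snp_density = 1 / 500,
                       supergene = list(chrom = 1, start = 2000001, end = 4700000),
                       fixed_diff_fraction = 0.5,
                       n_founders = 8,
                       switch_rate = 1e-6,
                       class_freqs = c(AA = 1 / 3, AB = 1 / 3, BB = 1 / 3),
                       n_samples = 60,
                       pheno_mean = c(AA = 1.20, AB = 1.05, BB = 0.98),
                       pheno_sd = 0.03,
                       colony_plan = list(n_monogyne = 20, n_polygyne = 11,
                                          polygyne_queens = 2:4, p_serial = 0.1,
                                          workers_per_colony = 8),
                       n_loci = 5,
                       alleles_per_locus = 8,
                       allele_freqs = NULL,
                       dropout_rate = 0,
                       false_allele_rate = 0,
                       depth_mean = 18,
                       qual_range = c(30, 60)) {
  if (fixed_diff_fraction <= 0 || fixed_diff_fraction >= 1) {
    stop("fixed_diff_fraction must be in (0, 1)")
  }
  if (supergene$chrom > n_chromosomes ||
      supergene$start < 1 || supergene$end > chrom_length ||
      supergene$end <= supergene$start) {
    stop("supergene region must lie inside its chromosome")
  }
  if (abs(sum(class_freqs) - 1) > 1e-8) stop("class_freqs must sum to 1")
  if (is.null(allele_freqs)) {
    allele_freqs <- replicate(n_loci,
                              rep(1 / alleles_per_locus, alleles_per_locus),
                              simplify = FALSE)
  }
  cfg <- list(
    n_chromosomes = n_chromosomes, chrom_length = chrom_length,
    snp_density = snp_density, supergene = supergene,
    fixed_diff_fraction = fixed_diff_fraction, n_founders = n_founders,
    switch_rate = switch_rate, class_freqs = class_freqs,
    n_samples = n_samples, pheno_mean = pheno_mean, pheno_sd = pheno_sd,
    colony_plan = colony_plan, n_loci = n_loci,
    alleles_per_locus = alleles_per_locus, allele_freqs = allele_freqs,
    dropout_rate = dropout_rate, false_allele_rate = false_allele_rate,
    depth_mean = depth_mean, qual_range = qual_range
  )
  class(cfg) <- "sim_config"
  cfg
}

# ancestral allele frequency spectrum, conditioned away from fixation:
# Beta(0.5, 0.5) resampled into [0.05, 0.95]
.draw_site_freqs <- function(n) {
  q <- stats::rbeta(n, 0.5, 0.5)
  bad <- q < 0.05 | q > 0.95
  while (any(bad)) {
    q[bad] <- stats::rbeta(sum(bad), 0.5, 0.5)
    bad <- q < 0.05 | q > 0.95
  }
  q
}

.random_alleles <- function(n) {
  nuc <- c("A", "C", "G", "T")
  ref <- sample(nuc, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nuc, r), 1), character(1))
  list(ref = ref, alt = unname(alt))
}

#' Simulate the founder haplotype pools and site list
#'
#' Generates SNP positions per chromosome, a background founder pool, and
#' two divergent founder pools A and B for the planted supergene interval.
#' A fraction `fixed_diff_fraction` of interval SNPs are fixed 0-vs-1
#' between the pools (A carries the reference allele); the remaining
#' interval SNPs are shared ancestral polymorphisms planted at the same
#' allele count in both pools. The supergene interval itself is fully
#' non-recombining: an interval haplotype copies a single pool founder.
#'
#' @param cfg a [sim_config()].
#' @param seed integer RNG seed.
#' @return a list of class `hap_model` with elements `sites` (data.frame
#'   with chrom, pos, ref, alt, category), `founders_bg` (per-chromosome
#'   founder allele matrices), `pool_A`/`pool_B` (founder matrices over the
#'   interval sites) and `interval_idx` (global site indices of the
#'   interval).
#' @export
simulate_haplotypes <- function(cfg, seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  n_snp <- round(cfg$chrom_length * cfg$snp_density)
  sites_l <- vector("list", cfg$n_chromosomes)
  founders_bg <- vector("list", cfg$n_chromosomes)
  pool_A <- pool_B <- NULL
  interval_idx <- integer(0)
  offset <- 0L
  for (ch in seq_len(cfg$n_chromosomes)) {
    pos <- sort(sample.int(cfg$chrom_length, n_snp))
    al <- .random_alleles(n_snp)
    category <- rep("background", n_snp)
    in_iv <- ch == cfg$supergene$chrom &
      pos >= cfg$supergene$start & pos <= cfg$supergene$end
    if (ch == cfg$supergene$chrom && !any(in_iv)) {
      stop("supergene interval contains zero SNPs")
    }
    # background founders, redrawn until polymorphic among founders
    q <- .draw_site_freqs(n_snp)
    F_bg <- matrix(stats::rbinom(cfg$n_founders * n_snp, 1, rep(q, each = cfg$n_founders)),
                   nrow = cfg$n_founders)
    mono <- which(colSums(F_bg) %in% c(0L, cfg$n_founders))
    while (length(mono)) {
      qm <- .draw_site_freqs(length(mono))
      F_bg[, mono] <- stats::rbinom(cfg$n_founders * length(mono), 1,
                                    rep(qm, each = cfg$n_founders))
      mono <- mono[colSums(F_bg[, mono, drop = FALSE]) %in% c(0L, cfg$n_founders)]
    }
    if (any(in_iv)) {
      iv <- which(in_iv)
      n_iv <- length(iv)
      fixed <- stats::runif(n_iv) < cfg$fixed_diff_fraction
      category[iv] <- ifelse(fixed, "fixed_difference", "shared_polymorphic")
      pool_A <- matrix(0L, nrow = cfg$n_founders, ncol = n_iv)
      pool_B <- matrix(0L, nrow = cfg$n_founders, ncol = n_iv)
      # fixed differences: pool A reference, pool B alternative
      pool_B[, fixed] <- 1L
      # shared polymorphism: same ancestral allele count k in both pools
      # (balanced retained polymorphism), k drawn from an SFS-like
      # spectrum skewed to low frequency; this calibrates the observed
      # het of the region to ~60 percent in AB and ~15 percent in
      # homozygotes at the default d = 0.5
      n_sh <- sum(!fixed)
      if (n_sh) {
        kk <- seq_len(cfg$n_founders - 1)
        w <- (1 / kk + 1 / (cfg$n_founders - kk))^2
        k <- sample(kk, n_sh, replace = TRUE, prob = w)
        sh_cols <- which(!fixed)
        for (j in seq_len(n_sh)) {
          pool_A[sample.int(cfg$n_founders, k[j]), sh_cols[j]] <- 1L
          pool_B[sample.int(cfg$n_founders, k[j]), sh_cols[j]] <- 1L
        }
      }
      interval_idx <- offset + iv
    }
    sites_l[[ch]] <- data.frame(
      chrom = paste0("chr", ch), pos = pos, ref = al$ref, alt = al$alt,
      category = category, stringsAsFactors = FALSE
    )
    founders_bg[[ch]] <- F_bg
    offset <- offset + n_snp
  }
  structure(
    list(cfg = cfg, sites = do.call(rbind, sites_l),
         founders_bg = founders_bg, pool_A = pool_A, pool_B = pool_B,
         interval_idx = interval_idx),
    class = "hap_model"
  )
}

# one haplotype for one chromosome: background founder mosaic; on the
# supergene chromosome, interval sites copy a single founder of `pool`
# ("A"/"B") -- the interval is inherited as an unrecombined unit.
.draw_chrom_haplotype <- function(model, ch) {
  cfg <- model$cfg
  pos <- model$sites$pos[model$sites$chrom == paste0("chr", ch)]
  n <- length(pos)
  n_switch <- stats::rpois(1, cfg$switch_rate * cfg$chrom_length)
  breaks <- sort(stats::runif(n_switch, 1, cfg$chrom_length))
  seg <- findInterval(pos, breaks) + 1L
  fid <- sample.int(cfg$n_founders, n_switch + 1L, replace = TRUE)
  hap <- model$founders_bg[[ch]][cbind(fid[seg], seq_len(n))]
  hap
}

.draw_haplotype_pair <- function(model, class) {
  cfg <- model$cfg
  pools <- switch(class, AA = c("A", "A"), AB = c("A", "B"), BB = c("B", "B"))
  haps <- vector("list", 2)
  for (h in 1:2) {
    full <- unlist(lapply(seq_len(cfg$n_chromosomes),
                          function(ch) .draw_chrom_haplotype(model, ch)))
    pool <- if (pools[h] == "A") model$pool_A else model$pool_B
    founder <- sample.int(cfg$n_founders, 1)
    full[model$interval_idx] <- pool[founder, ]
    haps[[h]] <- full
  }
  haps
}

.quota_classes <- function(freqs, n) {
  # largest-remainder allocation so realized class counts match the
  # configured frequencies exactly (the study-condition cohort is 20/20/20)
  base <- floor(freqs * n)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(freqs * n - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  sample(rep(names(freqs), base))
}

#' Simulate a cohort of genotyped queens/gynes
#'
#' Draws per-sample supergene classes from the configured class
#' frequencies (realized exactly via largest-remainder quota), builds each
#' sample's two haplotypes (AA: two pool-A, AB: one of each, BB: two
#' pool-B interval haplotypes on a founder-mosaic background) and a
#' class-dependent head width (truncated normal, reported to 0.01 mm).
#'
#' @param cfg a [sim_config()].
#' @param seed integer RNG seed.
#' @return list with `gm` (a [genotype_matrix()]), `samples` (phenotype
#'   table), `truth` (supergene interval, per-sample class, per-site
#'   category) and the underlying `hap_model`.
#' @export
simulate_cohort <- function(cfg, seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_samples < 3) stop("n_samples must be >= 3")
  model <- simulate_haplotypes(cfg, seed)
  set.seed(seed + 1L)
  n <- cfg$n_samples
  classes <- .quota_classes(cfg$class_freqs, n)
  ids <- sprintf("S%03d", seq_len(n))
  n_site <- nrow(model$sites)
  calls <- matrix(NA_integer_, nrow = n, ncol = n_site)
  for (i in seq_len(n)) {
    hp <- .draw_haplotype_pair(model, classes[i])
    calls[i, ] <- hp[[1]] + hp[[2]]
  }
  widths <- stats::rnorm(n, cfg$pheno_mean[classes], cfg$pheno_sd)
  while (any(widths <= 0)) {
    r <- widths <= 0
    widths[r] <- stats::rnorm(sum(r), cfg$pheno_mean[classes[r]], cfg$pheno_sd)
  }
  widths <- round(widths, 2)
  depths <- matrix(stats::rpois(n * n_site, cfg$depth_mean), nrow = n)
  qual <- round(stats::runif(n_site, cfg$qual_range[1], cfg$qual_range[2]), 1)
  sites <- model$sites[c("chrom", "pos", "ref", "alt")]
  sites$qual <- qual
  gm <- genotype_matrix(ids, sites, calls, depths)
  samples <- data.frame(
    sample_id = ids, head_width_mm = widths, colony_id = NA_character_,
    queen_count = NA_integer_, caste = "gyne",
    genotype_class = NA_character_, stringsAsFactors = FALSE
  )
  truth <- list(
    supergene = list(chrom = paste0("chr", cfg$supergene$chrom),
                     start = cfg$supergene$start, end = cfg$supergene$end),
    class = stats::setNames(classes, ids),
    site_category = model$sites$category
  )
  list(gm = gm, samples = samples, truth = truth, model = model)
}

#' Simulate colony structure on top of a cohort
#'
#' Monogyne colonies receive one AA queen each; with probability
#' `p_serial` a second (unsampled, replacement) AA mother also contributes
#' workers, emulating serial polygyny. Polygyne colonies receive k >= 2
#' AB/BB queens. Workers are haplodiploid offspring of one mother and one
#' haploid father whose supergene haplotype is drawn at the pool
#' frequencies; the truth records every worker's matriline.
#'
#' @param cfg a [sim_config()].
#' @param cohort result of [simulate_cohort()].
#' @param seed integer RNG seed.
#' @return list with `samples` (cohort table updated with colony
#'   assignments), `workers` (worker table) and `truth_workers`
#'   (matriline/parentage truth per worker).
#' @export
simulate_colonies <- function(cfg, cohort, seed) {
  set.seed(seed)
  plan <- cfg$colony_plan
  classes <- cohort$truth$class
  aa_ids <- sample(names(classes)[classes == "AA"])
  other_ids <- sample(names(classes)[classes != "AA"])
  if (plan$n_monogyne > length(aa_ids)) {
    stop("colony plan requests more AA queens than simulated")
  }
  samples <- cohort$samples
  rownames(samples) <- samples$sample_id
  colonies <- list()
  ci <- 0L
  # haplotype frequency of A among fathers = population A-haplotype freq
  fA <- cfg$class_freqs[["AA"]] + cfg$class_freqs[["AB"]] / 2
  for (k in seq_len(plan$n_monogyne)) {
    ci <- ci + 1L
    cid <- sprintf("C%02d", ci)
    q <- aa_ids[k]
    samples[q, c("colony_id", "queen_count", "caste")] <-
      list(cid, 1L, "queen")
    serial <- stats::runif(1) < plan$p_serial
    mothers <- data.frame(
      mother_id = c(q, if (serial) paste0(cid, "_Mx")),
      mother_class = c("AA", if (serial) "AA"),
      sampled = c(TRUE, if (serial) FALSE),
      stringsAsFactors = FALSE
    )
    colonies[[cid]] <- list(type = "monogyne", mothers = mothers)
  }
  # queens per polygyne colony, capped so the non-AA pool is never exhausted
  nq_all <- sample(rep(plan$polygyne_queens, 2), plan$n_polygyne, replace = TRUE)
  if (2L * plan$n_polygyne > length(other_ids)) {
    stop("not enough non-AA samples for the polygyne plan")
  }
  while (sum(nq_all) > length(other_ids)) {
    j <- which.max(nq_all)
    nq_all[j] <- nq_all[j] - 1L
  }
  oi <- 0L
  for (k in seq_len(plan$n_polygyne)) {
    ci <- ci + 1L
    cid <- sprintf("C%02d", ci)
    nq <- nq_all[k]
    qs <- other_ids[oi + seq_len(nq)]
    oi <- oi + nq
    for (q in qs) {
      samples[q, c("colony_id", "queen_count", "caste")] <-
        list(cid, as.integer(nq), "queen")
    }
    colonies[[cid]] <- list(
      type = "polygyne",
      mothers = data.frame(mother_id = qs,
                           mother_class = unname(classes[qs]),
                           sampled = TRUE, stringsAsFactors = FALSE)
    )
  }
  workers <- list()
  truth_workers <- list()
  wi <- 0L
  for (cid in names(colonies)) {
    col <- colonies[[cid]]
    m <- col$mothers
    m$father_hap <- ifelse(stats::runif(nrow(m)) < fA, "A", "B")
    # each contributing mother seeds at least one worker
    nm <- nrow(m)
    assign <- c(seq_len(nm),
                sample.int(nm, plan$workers_per_colony - nm, replace = TRUE))
    assign <- sample(assign)
    for (w in seq_len(plan$workers_per_colony)) {
      wi <- wi + 1L
      wid <- sprintf("W%04d", wi)
      mi <- assign[w]
      mother_haps <- strsplit(m$mother_class[mi], "")[[1]]
      wclass <- paste(sort(c(sample(mother_haps, 1), m$father_hap[mi])),
                      collapse = "")
      workers[[wi]] <- data.frame(
        worker_id = wid, colony_id = cid, caste = "worker",
        stringsAsFactors = FALSE
      )
      truth_workers[[wi]] <- data.frame(
        worker_id = wid, colony_id = cid,
        matriline_id = paste0(cid, "_M", mi),
        mother_id = m$mother_id[mi], mother_class = m$mother_class[mi],
        father_hap = m$father_hap[mi], worker_class = wclass,
        stringsAsFactors = FALSE
      )
    }
  }
  list(
    samples = samples,
    workers = do.call(rbind, workers),
    truth_workers = do.call(rbind, truth_workers),
    colony_types = vapply(colonies, `[[`, "", "type")
  )
}

#' Simulate worker microsatellite genotypes
#'
#' Each matriline has a diploid mother (two draws from the configured
#' per-locus allele frequencies) and one haploid father; a worker inherits
#' one maternal allele and the paternal allele at every locus. Allelic
#' dropout turns a heterozygous call into an apparent homozygote at the
#' stated rate; a false allele substitutes a random other allele.
#'
#' @param cfg a [sim_config()].
#' @param colonies result of [simulate_colonies()].
#' @param seed integer RNG seed.
#' @return list with `genotypes` (worker x (2 x n_loci) allele table) and
#'   `parents` (true parental genotypes per matriline).
#' @export
simulate_microsatellites <- function(cfg, colonies, seed) {
  set.seed(seed)
  if ((cfg$dropout_rate > 0 || cfg$false_allele_rate > 0) &&
      any(vapply(cfg$allele_freqs, length, 1L) < 2)) {
    stop("error rates > 0 require >= 2 alleles per locus")
  }
  tw <- colonies$truth_workers
  mats <- unique(tw[c("matriline_id")])
  allele_labels <- lapply(cfg$allele_freqs,
                          function(f) 100L + 2L * seq_along(f))
  parents <- list()
  for (mid in mats$matriline_id) {
    mom <- vapply(seq_len(cfg$n_loci), function(l) {
      sample(allele_labels[[l]], 2, replace = TRUE,
             prob = cfg$allele_freqs[[l]])
    }, integer(2))
    dad <- vapply(seq_len(cfg$n_loci), function(l) {
      sample(allele_labels[[l]], 1, prob = cfg$allele_freqs[[l]])
    }, integer(1))
    parents[[mid]] <- list(mother = mom, father = dad)
  }
  out <- matrix(NA_integer_, nrow = nrow(tw), ncol = 2L * cfg$n_loci)
  for (i in seq_len(nrow(tw))) {
    par <- parents[[tw$matriline_id[i]]]
    for (l in seq_len(cfg$n_loci)) {
      a <- c(par$mother[sample.int(2, 1), l], par$father[l])
      if (cfg$false_allele_rate > 0) {
        for (j in 1:2) {
          if (stats::runif(1) < cfg$false_allele_rate) {
            a[j] <- sample(setdiff(allele_labels[[l]], a[j]), 1)
          }
        }
      }
      if (a[1] != a[2] && cfg$dropout_rate > 0 &&
          stats::runif(1) < cfg$dropout_rate) {
        a <- rep(a[sample.int(2, 1)], 2)
      }
      out[i, 2L * l - 1:0] <- sort(a)
    }
  }
  colnames(out) <- paste0("L", rep(seq_len(cfg$n_loci), each = 2), c("_a", "_b"))
  genotypes <- cbind(tw[c("worker_id", "colony_id")], as.data.frame(out))
  list(genotypes = genotypes, parents = parents)
}

#' Simulate a gene annotation over the synthetic genome
#'
#' Tiles genes every ~50 kb along each chromosome; each gene carries 1-3
#' isoforms of 2-5 CDS exons. Returns both a `gene_set` and the truth
#' table naming each gene's longest isoform.
#'
#' @param cfg a [sim_config()].
#' @param seed integer RNG seed.
#' @return list with `gene_set` and `truth_longest` (gene_id ->
#'   transcript_id).
#' @export
simulate_genes <- function(cfg, seed) {
  set.seed(seed)
  genes <- transcripts <- cds <- list()
  gi <- 0L
  for (ch in seq_len(cfg$n_chromosomes)) {
    tile_starts <- seq(1, cfg$chrom_length - 50000 + 1, by = 50000)
    for (ts in tile_starts) {
      gi <- gi + 1L
      gene_id <- sprintf("gene%05d", gi)
      strand <- sample(c("+", "-"), 1)
      g_start <- ts + 2000
      g_end <- ts + 48000
      n_iso <- sample.int(3, 1)
      for (k in seq_len(n_iso)) {
        tx_id <- sprintf("%s.t%d", gene_id, k)
        n_ex <- sample(2:5, 1)
        # non-overlapping exons inside the gene span
        bounds <- sort(sample(seq(g_start, g_end, by = 50), 2 * n_ex))
        ex_start <- bounds[seq(1, 2 * n_ex, by = 2)]
        ex_end <- bounds[seq(2, 2 * n_ex, by = 2)] - 1L
        transcripts[[length(transcripts) + 1L]] <-
          data.frame(transcript_id = tx_id, gene_id = gene_id,
                     stringsAsFactors = FALSE)
        cds[[length(cds) + 1L]] <-
          data.frame(transcript_id = tx_id, start = ex_start, end = ex_end,
                     stringsAsFactors = FALSE)
      }
      genes[[gi]] <- data.frame(gene_id = gene_id,
                                chrom = paste0("chr", ch), strand = strand,
                                stringsAsFactors = FALSE)
    }
  }
  gs <- structure(
    list(genes = do.call(rbind, genes),
         transcripts = do.call(rbind, transcripts),
         cds = do.call(rbind, cds)),
    class = "gene_set"
  )
  # truth: longest isoform per gene by summed CDS length, ties by id
  len <- tapply(gs$cds$end - gs$cds$start + 1L, gs$cds$transcript_id, sum)
  tx <- gs$transcripts
  tx$len <- as.integer(len[tx$transcript_id])
  truth_longest <- vapply(split(tx, tx$gene_id), function(d) {
    d <- d[order(-d$len, d$transcript_id), ]
    d$transcript_id[1]
  }, character(1))
  list(gene_set = gs, truth_longest = truth_longest)
}

#' Write a gene set as GFF3
#'
#' @param gs a `gene_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(gs, path) {
  stopifnot(inherits(gs, "gene_set"))
  tx_span <- lapply(split(gs$cds, gs$cds$transcript_id),
                    function(d) c(min(d$start), max(d$end)))
  lines <- c("##gff-version 3")
  for (g in seq_len(nrow(gs$genes))) {
    gid <- gs$genes$gene_id[g]
    chrom <- gs$genes$chrom[g]
    strand <- gs$genes$strand[g]
    txs <- gs$transcripts$transcript_id[gs$transcripts$gene_id == gid]
    spans <- do.call(rbind, tx_span[txs])
    lines <- c(lines, paste(chrom, "sim", "gene", min(spans[, 1]),
                            max(spans[, 2]), ".", strand, ".",
                            paste0("ID=", gid), sep = "\t"))
    for (tx in txs) {
      sp <- tx_span[[tx]]
      lines <- c(lines, paste(chrom, "sim", "mRNA", sp[1], sp[2], ".",
                              strand, ".",
                              paste0("ID=", tx, ";Parent=", gid), sep = "\t"))
      d <- gs$cds[gs$cds$transcript_id == tx, ]
      lines <- c(lines, paste(chrom, "sim", "CDS", d$start, d$end, ".",
                              strand, "0",
                              paste0("ID=cds-", tx, ";Parent=", tx), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a complete dataset bundle
#'
#' Runs the cohort, colony, microsatellite and gene-annotation simulators
#' from one master seed (stage seeds are drawn from it) and optionally
#' writes the standard-format files (VCF, GFF3, TSV tables, truth JSON).
#'
#' @param cfg a [sim_config()].
#' @param seed master integer RNG seed.
#' @param out_dir optional directory to write `genotypes.vcf`,
#'   `annotation.gff3`, `samples.tsv`, `workers.tsv`, `microsats.tsv` and
#'   `truth.json` into.
#' @return list with `gm`, `samples`, `workers`, `microsats`, `gene_set`,
#'   `truth` (including worker/matriline and per-gene truth).
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = 1, out_dir = NULL) {
  set.seed(seed)
  ss <- sample.int(.Machine$integer.max - 1L, 4)
  cohort <- simulate_cohort(cfg, ss[1])
  colonies <- simulate_colonies(cfg, cohort, ss[2])
  micro <- simulate_microsatellites(cfg, colonies, ss[3])
  ann <- simulate_genes(cfg, ss[4])
  truth <- cohort$truth
  truth$workers <- colonies$truth_workers
  truth$colony_types <- colonies$colony_types
  truth$longest_isoform <- ann$truth_longest
  truth$fixed_cds_counts <- .truth_cds_counts(cohort$gm, truth, ann)
  out <- list(
    gm = cohort$gm, samples = colonies$samples, workers = colonies$workers,
    microsats = micro$genotypes, gene_set = ann$gene_set, truth = truth
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_vcf(out$gm, file.path(out_dir, "genotypes.vcf"),
              contig_lengths = stats::setNames(
                rep(cfg$chrom_length, cfg$n_chromosomes),
                paste0("chr", seq_len(cfg$n_chromosomes))))
    write_gff3(out$gene_set, file.path(out_dir, "annotation.gff3"))
    utils::write.table(out$samples, file.path(out_dir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$workers, file.path(out_dir, "workers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$microsats, file.path(out_dir, "microsats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

# independent truth tally: planted fixed-difference sites inside each
# gene's longest-isoform CDS, by direct interval arithmetic
.truth_cds_counts <- function(gm, truth, ann) {
  fixed <- which(truth$site_category == "fixed_difference")
  pos <- gm$sites$pos[fixed]
  chrom <- gm$sites$chrom[fixed]
  gs <- ann$gene_set
  counts <- integer(nrow(gs$genes))
  names(counts) <- gs$genes$gene_id
  for (g in seq_len(nrow(gs$genes))) {
    gid <- gs$genes$gene_id[g]
    if (gs$genes$chrom[g] != truth$supergene$chrom) next
    tx <- truth$longest_isoform[[gid]]
    d <- gs$cds[gs$cds$transcript_id == tx, ]
    on_ch <- pos[chrom == gs$genes$chrom[g]]
    n <- 0L
    for (e in seq_len(nrow(d))) {
      n <- n + sum(on_ch >= d$start[e] & on_ch <= d$end[e])
    }
    counts[g] <- n
  }
  counts
}
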