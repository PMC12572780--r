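# In-code fixtures shared across test files.

# small genotype matrix built directly from a call matrix
make_gm <- function(calls, chrom = "chr1", pos = NULL, qual = 50,
                    depths = NULL, ref = "A", alt = "G") {
  n_site <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(n_site) * 100L
  genotype_matrix(
    sample_ids = sprintf("s%02d", seq_len(nrow(calls))),
    sites = data.frame(chrom = chrom, pos = pos,
                       ref = rep_len(ref, n_site), alt = rep_len(alt, n_site),
                       qual = rep_len(qual, n_site)),
    calls = calls, depths = depths
  )
}

# desk-scale simulator configuration: one small chromosome, planted region
small_cfg <- function(...) {
  args <- list(
    n_chromosomes = 1, chrom_length = 500000,
    supergene = list(chrom = 1, start = 100001, end = 300000),
    n_samples = 30,
    colony_plan = list(n_monogyne = 6, n_polygyne = 3,
                       polygyne_queens = 2:3, p_serial = 0,
                       workers_per_colony = 6)
  )
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

# plain-text VCF fixture written to a temp file; returns the path
write_vcf_fixture <- function(lines) {
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  path
}

vcf_header <- function(samples = c("s1", "s2")) {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

# microsatellite genotypes for one haplodiploid family: diploid mother,
# haploid father, n workers; returns workers x (2*n_loci) matrix
make_family <- function(mother, father, n_workers) {
  n_loci <- length(father)
  out <- matrix(NA_integer_, n_workers, 2 * n_loci)
  for (w in seq_len(n_workers)) {
    for (l in seq_len(n_loci)) {
      pair <- sort(c(mother[sample.int(2, 1), l], father[l]))
      out[w, c(2 * l - 1, 2 * l)] <- pair
    }
  }
  out
}

# random parental genotypes for a family at n_loci loci with n_alleles
random_parents <- function(n_loci = 5, n_alleles = 7) {
  list(
    mother = matrix(sample.int(n_alleles, 2 * n_loci, replace = TRUE),
                    nrow = 2),
    father = sample.int(n_alleles, n_loci, replace = TRUE)
  )
}
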