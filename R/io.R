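#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses a VCF v4.x file (plain text or gzipped) and returns the biallelic
#' SNP records as a [genotype_matrix()]. Multi-allelic records, indels and
#' other non-SNP records are dropped (with a message giving counts), which
#' matches the usual `--min-alleles 2 --max-alleles 2` site filter applied
#' before a genome scan. Unparseable genotypes and `./.` become `NA`.
#' Phased separators (`|`) are treated as unphased.
#'
#' @param path path to a VCF file.
#' @return a `genotype_matrix`; per-call `DP` is attached as `depths` when
#'   present in the FORMAT field.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE)),
    error = function(e) stop("malformed VCF (", conditionMessage(e), ")")
  )
  if (ncol(v@gt) < 2) stop("VCF contains zero samples")
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_in <- nrow(fix)
  if (n_in == 0) stop("VCF contains zero records")
  is_snp <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T") &
    !grepl(",", fix$ALT, fixed = TRUE)
  is_snp[is.na(is_snp)] <- FALSE
  if (sum(!is_snp) > 0) {
    message("read_vcf: dropped ", sum(!is_snp),
            " non-biallelic-SNP record(s) of ", n_in)
  }
  keep <- which(is_snp)
  if (length(keep) == 0) stop("no biallelic SNP records in VCF")

  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  samples <- colnames(v@gt)[-1]
  calls <- matrix(NA_integer_, nrow = length(samples), ncol = length(keep),
                  dimnames = list(samples, NULL))
  g <- gsub("|", "/", t(gt), fixed = TRUE)
  calls[g == "0/0"] <- 0L
  calls[g %in% c("0/1", "1/0")] <- 1L
  calls[g == "1/1"] <- 2L

  depths <- NULL
  has_dp <- any(grepl("(^|:)DP(:|$)", v@gt[keep, 1]))
  if (has_dp) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[keep, , drop = FALSE]
    depths <- t(dp)
    storage.mode(depths) <- "integer"
  }
  qual <- suppressWarnings(as.numeric(fix$QUAL[keep]))
  sites <- data.frame(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep],
    alt = fix$ALT[keep],
    qual = qual,
    stringsAsFactors = FALSE
  )
  genotype_matrix(samples, sites, calls, depths)
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits a minimal plain-text VCF with GT (and DP when depths are present).
#' `read_vcf(write_vcf(gm))` reproduces the calls exactly.
#'
#' @param gm a `genotype_matrix`.
#' @param path output path.
#' @param contig_lengths optional named integer vector (chromosome lengths)
#'   used to emit `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, contig_lengths = NULL) {
  has_dp <- !is.null(gm$depths)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=supergenescan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (has_dp) {
    hdr <- c(hdr, '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  }
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", gm$sample_ids), collapse = "\t"))
  gt_str <- matrix(".", nrow = nrow(gm$calls), ncol = ncol(gm$calls))
  gt_str[] <- c("0/0", "0/1", "1/1")[gm$calls + 1L]
  gt_str[is.na(gm$calls)] <- "./."
  if (has_dp) {
    dp <- gm$depths
    dp_str <- ifelse(is.na(dp), ".", as.character(dp))
    gt_str[] <- paste(gt_str, dp_str, sep = ":")
  }
  qual <- ifelse(is.na(gm$sites$qual), ".", format(gm$sites$qual, trim = TRUE))
  body <- paste(
    gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref, gm$sites$alt,
    qual, "PASS", ".", if (has_dp) "GT:DP" else "GT",
    apply(gt_str, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Apply the study's variant filters to a genotype matrix
#'
#' Reproduces vcftools-style filtering: per-genotype depth masking is
#' applied first (`--minDP`), then sites failing the site-quality threshold
#' (`--minQ`) are dropped, then sites whose called fraction falls below
#' `max_missing_frac` are dropped (`--max-missing 0.6` keeps sites with at
#' least 60 percent called genotypes). Only biallelic SNP sites enter a
#' `genotype_matrix` in the first place, so no further site-type filtering
#' is needed. The operation is idempotent.
#'
#' @param gm a `genotype_matrix`.
#' @param min_gq_site minimum site QUAL; sites with `qual` below it are
#'   dropped (sites with `NA` qual are kept).
#' @param min_dp minimum per-genotype depth; calls below it become `NA`.
#'   Ignored when `gm` carries no depths.
#' @param max_missing_frac minimum fraction of called genotypes a site must
#'   retain, in [0, 1] (vcftools `--max-missing` semantics).
#' @return the filtered `genotype_matrix`.
#' @export
filter_variants <- function(gm, min_gq_site = 20, min_dp = 3,
                            max_missing_frac = 0.6) {
  stopifnot(min_gq_site >= 0, min_dp >= 0)
  if (max_missing_frac < 0 || max_missing_frac > 1) {
    stop("max_missing_frac must be in [0, 1]")
  }
  calls <- gm$calls
  if (!is.null(gm$depths)) {
    calls[!is.na(gm$depths) & gm$depths < min_dp] <- NA_integer_
  }
  called_frac <- colMeans(!is.na(calls))
  keep_qual <- is.na(gm$sites$qual) | gm$sites$qual >= min_gq_site
  keep <- which(keep_qual & called_frac >= max_missing_frac)
  genotype_matrix(
    gm$sample_ids,
    gm$sites[keep, , drop = FALSE],
    calls[, keep, drop = FALSE],
    if (!is.null(gm$depths)) gm$depths[, keep, drop = FALSE]
  )
}

#' Read a GFF3 gene annotation into a gene set
#'
#' Reads `gene`, `mRNA` and `CDS` features and their Parent links. The
#' result is a `gene_set`: a list with `genes` (gene_id, chrom, strand),
#' `transcripts` (transcript_id, gene_id) and `cds` (transcript_id, start,
#' end; 1-based closed intervals).
#'
#' @param path path to a GFF3 file.
#' @return an object of class `gene_set`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- vapply(
    as.list(gr$Parent),
    function(p) if (length(p)) as.character(p)[1] else NA_character_,
    character(1)
  )
  gi <- typ == "gene"
  mi <- typ == "mRNA"
  ci <- typ == "CDS"
  genes <- data.frame(
    gene_id = ids[gi],
    chrom = as.character(GenomicRanges::seqnames(gr)[gi]),
    strand = as.character(GenomicRanges::strand(gr)[gi]),
    stringsAsFactors = FALSE
  )
  transcripts <- data.frame(
    transcript_id = ids[mi],
    gene_id = parents[mi],
    stringsAsFactors = FALSE
  )
  if (anyNA(transcripts$gene_id) ||
      !all(transcripts$gene_id %in% genes$gene_id)) {
    stop("mRNA without parent gene in GFF3")
  }
  cds <- data.frame(
    transcript_id = parents[ci],
    start = GenomicRanges::start(gr)[ci],
    end = GenomicRanges::end(gr)[ci],
    stringsAsFactors = FALSE
  )
  if (anyNA(cds$transcript_id) ||
      !all(cds$transcript_id %in% transcripts$transcript_id)) {
    stop("CDS without parent transcript in GFF3")
  }
  structure(list(genes = genes, transcripts = transcripts, cds = cds),
            class = "gene_set")
}

#' Keep the longest isoform of each gene
#'
#' Retains for every gene the single transcript maximizing summed CDS
#' length; ties are broken by the lexicographically smallest transcript id.
#' This mirrors the usual annotation-preprocessing step before counting
#' coding SNPs per gene.
#'
#' @param gs a `gene_set`.
#' @return a `gene_set` with exactly one transcript per gene.
#' @export
longest_isoform <- function(gs) {
  stopifnot(inherits(gs, "gene_set"))
  len <- tapply(gs$cds$end - gs$cds$start + 1L, gs$cds$transcript_id, sum)
  tx <- gs$transcripts
  tx$cds_len <- as.integer(len[tx$transcript_id])
  tx$cds_len[is.na(tx$cds_len)] <- 0L
  ord <- order(tx$gene_id, -tx$cds_len, tx$transcript_id)
  tx <- tx[ord, ]
  keep_tx <- tx$transcript_id[!duplicated(tx$gene_id)]
  structure(
    list(
      genes = gs$genes,
      transcripts = gs$transcripts[gs$transcripts$transcript_id %in% keep_tx, ,
                                   drop = FALSE],
      cds = gs$cds[gs$cds$transcript_id %in% keep_tx, , drop = FALSE]
    ),
    class = "gene_set"
  )
}

#' Read a per-sample phenotype/colony table
#'
#' Expects a TSV with columns `sample_id`, `head_width_mm`, `colony_id`,
#' `queen_count`, `caste` (and optionally `genotype_class`). Head widths
#' must be positive numbers when present; queen counts must be consistent
#' within a colony.
#'
#' @param path path to a TSV file.
#' @return a data.frame.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("sample table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, sep = "\t")
  required <- c("sample_id", "head_width_mm", "colony_id", "queen_count", "caste")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("sample table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tab$sample_id)) stop("duplicated sample id in sample table")
  hw <- tab$head_width_mm
  if (is.character(hw)) {
    hw_num <- suppressWarnings(as.numeric(hw))
    if (any(!is.na(hw) & hw != "" & is.na(hw_num))) {
      stop("non-numeric head width in sample table")
    }
    tab$head_width_mm <- hw_num
  }
  if (any(tab$head_width_mm <= 0, na.rm = TRUE)) stop("head width must be > 0")
  qc <- tapply(tab$queen_count, tab$colony_id,
               function(x) length(unique(x[!is.na(x)])))
  if (any(qc > 1, na.rm = TRUE)) {
    stop("inconsistent queen count within a colony")
  }
  tab
}

#' Write / read a window-statistics table
#'
#' Window tables are plain TSV with `chrom`, `start`, `end` (1-based
#' inclusive) followed by statistic columns; numeric values are written
#' with full precision.
#'
#' @param rows data.frame of window statistics.
#' @param path output path.
#' @return `path` invisibly (`write_window_table`); a data.frame
#'   (`read_window_table`).
#' @export
write_window_table <- function(rows, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(rows)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_table
#' @export
read_window_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
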