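#' Sites heterozygous in every AB individual
#'
#' Returns the region sites at which every AB-assigned sample is called
#' and heterozygous. The "all" is strict: a missing call in any AB sample
#' excludes the site.
#'
#' @param gm a [genotype_matrix()].
#' @param assignment a `genotype_assignment` (or a named class vector).
#' @param chrom,start,end region (1-based inclusive).
#' @return integer vector of site indices into `gm`.
#' @export
ab_het_sites <- function(gm, assignment, chrom, start = 1, end = Inf) {
  cls <- .class_vector(gm, assignment)
  ab <- which(cls == "AB")
  if (!length(ab)) stop("no AB samples")
  idx <- sites_in_region(gm, chrom, start, end)
  calls <- gm$calls[ab, idx, drop = FALSE]
  keep <- colSums(calls == 1L & !is.na(calls)) == length(ab)
  idx[keep]
}

#' Sites fixed for opposite homozygotes between AA and BB
#'
#' Keeps candidate sites where all non-missing AA calls are one
#' homozygote, all non-missing BB calls are the opposite homozygote, and
#' each group has at least one non-missing call. This is exactly the set
#' where the per-site Weir-Cockerham theta between the two groups equals
#' 1 (the "FST = 1" filter).
#'
#' @param gm a [genotype_matrix()].
#' @param assignment a `genotype_assignment` (or a named class vector).
#' @param candidate_sites integer vector of site indices to filter
#'   (typically from [ab_het_sites()]).
#' @return integer vector of site indices.
#' @export
fixed_diff_sites <- function(gm, assignment, candidate_sites) {
  if (!length(candidate_sites)) stop("empty candidate site set")
  cls <- .class_vector(gm, assignment)
  aa <- which(cls == "AA")
  bb <- which(cls == "BB")
  if (!length(aa) || !length(bb)) stop("need >= 1 AA and >= 1 BB sample")
  ca <- gm$calls[aa, candidate_sites, drop = FALSE]
  cb <- gm$calls[bb, candidate_sites, drop = FALSE]
  n_aa <- colSums(!is.na(ca))
  n_bb <- colSums(!is.na(cb))
  aa_ref <- colSums(ca == 0L, na.rm = TRUE) == n_aa
  aa_alt <- colSums(ca == 2L, na.rm = TRUE) == n_aa
  bb_ref <- colSums(cb == 0L, na.rm = TRUE) == n_bb
  bb_alt <- colSums(cb == 2L, na.rm = TRUE) == n_bb
  keep <- n_aa > 0 & n_bb > 0 & ((aa_ref & bb_alt) | (aa_alt & bb_ref))
  candidate_sites[keep]
}

.class_vector <- function(gm, assignment) {
  if (inherits(assignment, "genotype_assignment")) {
    cls <- assignment$samples$class[match(gm$sample_ids,
                                          assignment$samples$sample_id)]
  } else {
    cls <- unname(assignment[gm$sample_ids])
  }
  cls
}

#' Count diagnostic SNPs per gene within coding sequence
#'
#' Each site is assigned to every gene whose retained-isoform CDS contains
#' its position (1-based inclusive interval test, so a site at a CDS
#' boundary counts). The gene set must hold one isoform per gene (apply
#' [longest_isoform()] first). Gene order in the result preserves genomic
#' order.
#'
#' @param gm a [genotype_matrix()].
#' @param sites integer vector of site indices (diagnostic SNPs).
#' @param gs a `gene_set` reduced to one isoform per gene.
#' @return data.frame: gene_id, chrom, start, end (gene CDS span),
#'   n_diagnostic.
#' @export
cds_diagnostic_counts <- function(gm, sites, gs) {
  stopifnot(inherits(gs, "gene_set"))
  if (anyDuplicated(gs$transcripts$gene_id)) {
    stop("gene set has multiple isoforms per gene; apply longest_isoform()")
  }
  cds <- merge(gs$cds, gs$transcripts, by = "transcript_id")
  cds <- merge(cds, gs$genes, by = "gene_id")
  span <- do.call(rbind, lapply(split(cds, cds$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
               start = min(d$start), end = max(d$end),
               stringsAsFactors = FALSE)
  }))
  span <- span[order(span$chrom, span$start, span$gene_id), ]
  counts <- integer(nrow(span))
  names(counts) <- span$gene_id
  if (length(sites)) {
    snp_gr <- GenomicRanges::GRanges(
      gm$sites$chrom[sites],
      IRanges::IRanges(gm$sites$pos[sites], width = 1)
    )
    cds_gr <- GenomicRanges::GRanges(
      cds$chrom, IRanges::IRanges(cds$start, cds$end), gene_id = cds$gene_id
    )
    ov <- GenomicRanges::findOverlaps(snp_gr, cds_gr)
    if (length(ov)) {
      hit_genes <- cds_gr$gene_id[S4Vectors::subjectHits(ov)]
      # a site in two CDS exons of the same gene counts once
      uniq <- unique(data.frame(site = S4Vectors::queryHits(ov),
                                gene = hit_genes))
      tb <- table(uniq$gene)
      counts[names(tb)] <- as.integer(tb)
    }
  }
  span$n_diagnostic <- unname(counts)
  rownames(span) <- NULL
  span
}

#' Rank candidate genes by diagnostic-SNP content
#'
#' Descending by diagnostic-SNP count; ties broken by genomic position,
#' then gene id.
#'
#' @param counts data.frame from [cds_diagnostic_counts()].
#' @return the same data.frame, reordered.
#' @export
rank_candidate_genes <- function(counts) {
  ord <- order(-counts$n_diagnostic, counts$chrom, counts$start,
               counts$gene_id)
  out <- counts[ord, ]
  rownames(out) <- NULL
  out
}
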