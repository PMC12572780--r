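#' Construct a genotype matrix
#'
#' The central container of the package: diploid biallelic SNP calls for a
#' set of samples. Calls are coded as allele dosages of the alternative
#' allele: 0 = homozygous reference (0/0), 1 = heterozygous (0/1),
#' 2 = homozygous alternative (1/1), `NA` = missing (./.).
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param sites data.frame with columns `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`, `qual` (site quality; `NA` allowed). Positions must be
#'   strictly increasing within each chromosome.
#' @param calls integer matrix, samples x sites, values in {0, 1, 2, NA}.
#' @param depths optional integer matrix of per-call read depths, same
#'   dimensions as `calls`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sample_ids, sites, calls, depths = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  required <- c("chrom", "pos", "ref", "alt", "qual")
  if (!all(required %in% names(sites))) {
    stop("sites must have columns: ", paste(required, collapse = ", "))
  }
  sites <- as.data.frame(sites)[required]
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != length(sample_ids) || ncol(calls) != nrow(sites)) {
    stop("calls must be length(sample_ids) x nrow(sites)")
  }
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) stop("calls must be 0, 1, 2 or NA")
  # strictly increasing positions within each chromosome
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (length(p) > 1 && any(diff(p) <= 0)) {
      stop("positions not strictly increasing on chromosome ", ch)
    }
  }
  if (!is.null(depths)) {
    depths <- as.matrix(depths)
    storage.mode(depths) <- "integer"
    if (!all(dim(depths) == dim(calls))) stop("depths dimensions must match calls")
    if (any(depths < 0, na.rm = TRUE)) stop("depths must be non-negative")
  }
  dimnames(calls) <- list(sample_ids, NULL)
  if (!is.null(depths)) dimnames(depths) <- list(sample_ids, NULL)
  structure(
    list(sample_ids = sample_ids, sites = sites, calls = calls, depths = depths),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      nrow(x$sites), "sites on",
      length(unique(x$sites$chrom)), "chromosome(s)\n")
  cat(sprintf("  missing call fraction: %.4f\n", mean(is.na(x$calls))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of samples / sites
#' @param gm a `genotype_matrix`.
#' @return integer count.
#' @export
n_samples <- function(gm) length(gm$sample_ids)

#' @rdname n_samples
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' Subset a genotype matrix by site index and/or sample id
#'
#' Order of retained sites and samples always follows the order of the
#' index vectors as given; readers and filters never permute.
#'
#' @param gm a `genotype_matrix`.
#' @param site_idx integer vector of site column indices (default all).
#' @param samples character vector of sample ids (default all).
#' @return a `genotype_matrix`.
#' @export
subset_gm <- function(gm, site_idx = NULL, samples = NULL) {
  if (is.null(site_idx)) site_idx <- seq_len(n_sites(gm))
  if (is.null(samples)) samples <- gm$sample_ids
  si <- match(samples, gm$sample_ids)
  if (anyNA(si)) stop("unknown sample id(s): ", paste(samples[is.na(si)], collapse = ", "))
  genotype_matrix(
    sample_ids = gm$sample_ids[si],
    sites = gm$sites[site_idx, , drop = FALSE],
    calls = gm$calls[si, site_idx, drop = FALSE],
    depths = if (!is.null(gm$depths)) gm$depths[si, site_idx, drop = FALSE]
  )
}

#' Site indices falling in a genomic region
#'
#' @param gm a `genotype_matrix`.
#' @param chrom chromosome identifier.
#' @param start,end 1-based inclusive bounds.
#' @return integer vector of site indices.
#' @export
sites_in_region <- function(gm, chrom, start, end) {
  which(gm$sites$chrom == chrom & gm$sites$pos >= start & gm$sites$pos <= end)
}
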