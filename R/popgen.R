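#' Weir-Cockerham variance components at one site
#'
#' Computes the Weir & Cockerham (1984) variance components for a single
#' biallelic site from per-population diploid genotype counts, and the
#' estimator theta = a / (a + b + c). This is the per-site quantity that
#' vcftools' `--weir-fst-pop` accumulates. Theta may be negative (it is an
#' unbiased-component ratio, not a parameter) and is reported unclamped;
#' at a site monomorphic across all populations theta is undefined and
#' returned as `NaN`.
#'
#' @param counts matrix (or data.frame) with one row per population and
#'   columns `hom_ref`, `het`, `hom_alt` of genotype counts.
#' @return list with `a`, `b`, `c`, `theta`.
#' @export
wc_fst_site <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) stop("need >= 2 populations")
  n_i <- rowSums(counts)
  if (any(n_i == 0)) stop("a population has zero called genotypes")
  comp <- .wc_components(
    n = n_i,
    p = (counts[, 3] * 2 + counts[, 2]) / (2 * n_i),
    h = counts[, 2] / n_i
  )
  comp
}

# vectorised Weir-Cockerham components over sites.
# n, p, h: population x site matrices of sample sizes (called diploids),
# alt allele frequencies and observed het fractions.
.wc_components_mat <- function(n, p, h) {
  r <- nrow(n)
  nbar <- colMeans(n)
  nsum <- colSums(n)
  nc <- (nsum - colSums(n^2) / nsum) / (r - 1)
  pbar <- colSums(n * p) / nsum
  s2 <- colSums(n * (p - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(n * h) / nsum
  inner <- pbar * (1 - pbar) - ((r - 1) / r) * s2
  a <- (nbar / nc) * (s2 - (inner - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  theta <- a / (a + b + cc)
  # monomorphic across all populations: estimator undefined
  mono <- (pbar == 0 | pbar == 1) & hbar == 0
  theta[mono] <- NaN
  list(a = a, b = b, c = cc, theta = theta)
}

.wc_components <- function(n, p, h) {
  m <- .wc_components_mat(cbind(n), cbind(p), cbind(h))
  list(a = unname(m$a[1]), b = unname(m$b[1]), c = unname(m$c[1]),
       theta = unname(m$theta[1]))
}

# per-site n/p/h matrices for a grouping of the samples of gm
.group_site_stats <- function(gm, groups) {
  groups <- as.factor(groups)
  lv <- levels(droplevels(groups))
  n <- p <- h <- matrix(0, nrow = length(lv), ncol = n_sites(gm))
  for (k in seq_along(lv)) {
    calls <- gm$calls[which(groups == lv[k]), , drop = FALSE]
    nk <- colSums(!is.na(calls))
    n[k, ] <- nk
    p[k, ] <- colSums(calls, na.rm = TRUE) / (2 * nk)
    h[k, ] <- colSums(calls == 1L, na.rm = TRUE) / nk
  }
  list(n = n, p = p, h = h)
}

#' Windowed Weir-Cockerham FST scan
#'
#' Tiles each chromosome with non-overlapping windows (step defaults to
#' the window size) and reports per window the vcftools-style "weighted"
#' FST (ratio of summed numerators a to summed denominators a+b+c over the
#' window's informative sites) and the mean of per-site theta values.
#' Windows with no informative site carry `NaN`.
#'
#' @param gm a [genotype_matrix()].
#' @param groups named vector (names = sample ids) or vector aligned with
#'   `gm$sample_ids` giving each grouped sample's population; samples with
#'   `NA` are excluded.
#' @param window_size window size in bp.
#' @param step step in bp (default `window_size`: non-overlapping tiling).
#' @return data.frame: chrom, start, end (1-based inclusive), n_sites,
#'   fst_weighted, fst_mean.
#' @export
windowed_fst <- function(gm, groups, window_size = 10000, step = window_size) {
  if (window_size <= 0) stop("window_size must be > 0")
  if (!is.null(names(groups))) {
    unknown <- setdiff(names(groups), gm$sample_ids)
    if (length(unknown)) stop("unknown sample id(s): ",
                              paste(unknown, collapse = ", "))
    g <- rep(NA_character_, n_samples(gm))
    g[match(names(groups), gm$sample_ids)] <- as.character(groups)
    groups <- g
  }
  keep <- which(!is.na(groups))
  if (length(unique(groups[keep])) < 2) stop("need >= 2 groups")
  sub <- subset_gm(gm, samples = gm$sample_ids[keep])
  st <- .group_site_stats(sub, groups[keep])
  # sites where some group has zero calls are uninformative
  ok <- colSums(st$n == 0) == 0
  comp <- .wc_components_mat(st$n[, ok, drop = FALSE],
                             st$p[, ok, drop = FALSE],
                             st$h[, ok, drop = FALSE])
  site_chrom <- gm$sites$chrom[ok]
  site_pos <- gm$sites$pos[ok]
  num <- unname(comp$a)
  den <- unname(comp$a + comp$b + comp$c)
  theta <- unname(comp$theta)
  out <- list()
  for (ch in unique(gm$sites$chrom)) {
    max_pos <- max(gm$sites$pos[gm$sites$chrom == ch])
    starts <- seq(1, max_pos, by = step)
    idx <- which(site_chrom == ch)
    win_of <- findInterval(site_pos[idx], starts)
    n_win <- length(starts)
    n_site_w <- tabulate(win_of, nbins = n_win)
    agg <- function(v, f = identity) {
      out <- numeric(n_win)
      use <- is.finite(v)
      if (any(use)) {
        s <- rowsum(f(v[use]), win_of[use])
        out[as.integer(rownames(s))] <- s
      }
      out
    }
    sum_num <- agg(num[idx])
    sum_den <- agg(den[idx])
    n_theta <- agg(theta[idx], function(x) rep(1, length(x)))
    mean_theta <- ifelse(n_theta > 0, agg(theta[idx]) / n_theta, NaN)
    fst_w <- ifelse(sum_den > 0, sum_num / sum_den, NaN)
    out[[ch]] <- data.frame(
      chrom = ch, start = starts, end = starts + window_size - 1,
      n_sites = n_site_w, fst_weighted = fst_w, fst_mean = mean_theta,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Genome-wide percentile threshold of window FST values
#'
#' The empirical percentile of the finite `fst_weighted` values, using
#' linear interpolation between order statistics (R's default quantile
#' definition, type 7). This is the rule behind "the 95th percentile" used
#' to highlight differentiated windows in genome scans.
#'
#' @param stats data.frame from [windowed_fst()].
#' @param pct percentile in (0, 100).
#' @return the threshold value.
#' @export
fst_percentile_threshold <- function(stats, pct = 95) {
  if (pct <= 0 || pct >= 100) stop("pct must be in (0, 100)")
  v <- stats$fst_weighted
  v <- v[is.finite(v)]
  if (!length(v)) stop("no finite window FST values")
  unname(stats::quantile(v, pct / 100, type = 7))
}

#' Observed heterozygosity fraction of a sample in a region
#'
#' Heterozygous calls divided by non-missing calls within the region (the
#' per-individual quantity behind vcftools `--het`, restricted to a
#' region).
#'
#' @param gm a [genotype_matrix()].
#' @param sample sample id.
#' @param chrom,start,end region (1-based inclusive); `start`/`end`
#'   default to the whole chromosome.
#' @return proportion in [0, 1].
#' @export
obs_het_fraction <- function(gm, sample, chrom, start = 1, end = Inf) {
  i <- match(sample, gm$sample_ids)
  if (is.na(i)) stop("unknown sample: ", sample)
  idx <- sites_in_region(gm, chrom, start, end)
  calls <- gm$calls[i, idx]
  called <- sum(!is.na(calls))
  if (called == 0) stop("zero called sites for sample in region")
  sum(calls == 1L, na.rm = TRUE) / called
}

#' Composite LD r-squared between two sites
#'
#' Squared Pearson correlation of genotype dosages (0/1/2) over samples
#' called at both sites: the phase-free composite-LD convention for
#' unphased genotypes. Symmetric in its arguments and invariant to ref/alt
#' relabeling.
#'
#' @param gm a [genotype_matrix()].
#' @param i,j site indices.
#' @return r-squared in [0, 1]; `NaN` when either site is monomorphic
#'   among the jointly called samples.
#' @export
ld_r2 <- function(gm, i, j) {
  x <- gm$calls[, i]
  y <- gm$calls[, j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) stop("fewer than 2 jointly called samples")
  if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) return(NaN)
  stats::cor(x[ok], y[ok])^2
}

#' Distance-binned LD decay within a region
#'
#' Computes r-squared for all pairs of region sites (passing a minor
#' allele frequency filter) separated by at most `max_dist` bp, and
#' averages them within contiguous distance bins `[lo, hi)`.
#'
#' @param gm a [genotype_matrix()].
#' @param samples sample ids to use (default all).
#' @param chrom,start,end region (1-based inclusive).
#' @param maf_min minimum minor allele frequency.
#' @param max_dist maximum pair distance in bp.
#' @param bin_width distance bin width in bp.
#' @return data.frame: bin_lo, bin_hi, mean_r2, n_pairs.
#' @export
ld_decay <- function(gm, samples = NULL, chrom, start = 1, end = Inf,
                     maf_min = 0.05, max_dist = 300000, bin_width = 10000) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (is.null(samples)) samples <- gm$sample_ids
  sub <- subset_gm(gm, sites_in_region(gm, chrom, start, end), samples)
  dos <- sub$calls
  p <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- which(!is.na(maf) & maf >= maf_min)
  if (length(keep) < 2) stop("fewer than 2 sites pass the MAF filter")
  dos <- dos[, keep, drop = FALSE]
  pos <- sub$sites$pos[keep]
  n_bins <- ceiling(max_dist / bin_width)
  sum_r2 <- n_pairs <- numeric(n_bins)
  # blockwise banded correlation: only pairs within max_dist are computed
  block <- 512L
  m <- length(pos)
  use_pairwise <- anyNA(dos)
  for (s0 in seq(1, m, by = block)) {
    s1 <- min(s0 + block - 1L, m)
    jmax <- s1
    while (jmax < m && pos[jmax + 1L] - pos[s1] <= max_dist) jmax <- jmax + 1L
    cols <- s0:jmax
    cmat <- if (use_pairwise) {
      suppressWarnings(stats::cor(dos[, s0:s1, drop = FALSE],
                                  dos[, cols, drop = FALSE],
                                  use = "pairwise.complete.obs"))
    } else {
      stats::cor(dos[, s0:s1, drop = FALSE], dos[, cols, drop = FALSE])
    }
    for (ii in s0:s1) {
      jj <- cols[cols > ii]
      if (!length(jj)) next
      d <- pos[jj] - pos[ii]
      sel <- which(d <= max_dist)
      if (!length(sel)) next
      r2 <- cmat[ii - s0 + 1L, match(jj[sel], cols)]^2
      b <- pmin(d[sel] %/% bin_width + 1L, n_bins)
      fin <- is.finite(r2)
      if (!any(fin)) next
      tb <- tapply(r2[fin], b[fin], sum)
      bi <- as.integer(names(tb))
      sum_r2[bi] <- sum_r2[bi] + tb
      n_pairs[bi] <- n_pairs[bi] + tabulate(b[fin], nbins = n_bins)[bi]
    }
  }
  data.frame(
    bin_lo = (seq_len(n_bins) - 1) * bin_width,
    bin_hi = seq_len(n_bins) * bin_width,
    mean_r2 = ifelse(n_pairs > 0, sum_r2 / n_pairs, NaN),
    n_pairs = n_pairs
  )
}

#' Slope of mean r-squared against distance
#'
#' Ordinary least-squares slope of per-bin mean r-squared on bin midpoint,
#' over populated bins. Used to contrast the flat LD profile inside a
#' non-recombining region with the decaying background.
#'
#' @param bins data.frame from [ld_decay()].
#' @return slope in r-squared units per bp.
#' @export
ld_decay_slope <- function(bins) {
  b <- bins[bins$n_pairs > 0 & is.finite(bins$mean_r2), ]
  if (nrow(b) < 2) stop("need >= 2 populated bins")
  mid <- (b$bin_lo + b$bin_hi) / 2
  unname(stats::coef(stats::lm(b$mean_r2 ~ mid))[2])
}

#' Kimura two-parameter (K80) nucleotide distance
#'
#' With P the transition proportion and Q the transversion proportion over
#' comparable sites, d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q). Sites
#' with a non-ACGT character in either sequence are excluded. When the log
#' argument is non-positive the distance is saturated and returned as
#' `NA` with `saturated = TRUE`.
#'
#' @param seq1,seq2 equal-length nucleotide character strings (or
#'   character vectors of single bases).
#' @return list with `distance`, `P`, `Q`, `n_sites`, `saturated`.
#' @export
k80_distance <- function(seq1, seq2) {
  s1 <- toupper(if (length(seq1) == 1) strsplit(seq1, "")[[1]] else seq1)
  s2 <- toupper(if (length(seq2) == 1) strsplit(seq2, "")[[1]] else seq2)
  if (length(s1) != length(s2)) stop("sequence length mismatch")
  nuc <- c("A", "C", "G", "T")
  ok <- s1 %in% nuc & s2 %in% nuc
  n <- sum(ok)
  if (n == 0) stop("zero comparable sites")
  a <- s1[ok]
  b <- s2[ok]
  purine <- function(x) x %in% c("A", "G")
  diff <- a != b
  transition <- diff & (purine(a) == purine(b))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(list(distance = NA_real_, P = P, Q = Q, n_sites = n,
                saturated = TRUE))
  }
  list(distance = -0.5 * log(w1) - 0.25 * log(w2), P = P, Q = Q,
       n_sites = n, saturated = FALSE)
}
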