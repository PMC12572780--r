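#' Rolling-window PCA along a chromosome
#'
#' For each non-overlapping window: builds the genotype-dosage matrix,
#' imputes missing cells with the site mean, centers sites and scales them
#' by sqrt(2p(1-p)) (the usual variance standardization for genotype
#' PCA), and extracts PC1 by singular value decomposition. Because a PCA
#' sign is arbitrary per window, each window's sign is oriented to
#' maximize the correlation of its sample scores with the previous
#' informative window; in the first informative window the
#' lexicographically smallest sample id gets a non-negative score. Windows
#' with fewer than 2 polymorphic sites are emitted with `NA` scores.
#'
#' @param gm a [genotype_matrix()].
#' @param chrom chromosome to scan.
#' @param window_size window size in bp.
#' @param standardize scale dosages by sqrt(2p(1-p)) (default) or only
#'   center them.
#' @return list of class `pca_windows`: `windows` (data.frame chrom,
#'   start, end, n_sites, pc1_var_frac, informative) and `scores` (window
#'   x sample matrix of PC1 scores).
#' @export
rolling_pca <- function(gm, chrom, window_size = 50000, standardize = TRUE) {
  if (!chrom %in% gm$sites$chrom) stop("unknown chromosome: ", chrom)
  pos_all <- gm$sites$pos[gm$sites$chrom == chrom]
  starts <- seq(1, max(pos_all), by = window_size)
  n_win <- length(starts)
  n <- n_samples(gm)
  scores <- matrix(NA_real_, nrow = n_win, ncol = n,
                   dimnames = list(NULL, gm$sample_ids))
  info <- data.frame(
    chrom = chrom, start = starts, end = starts + window_size - 1,
    n_sites = 0L, pc1_var_frac = NA_real_, informative = FALSE,
    stringsAsFactors = FALSE
  )
  first_sample <- order(gm$sample_ids)[1]
  prev <- NULL
  for (w in seq_len(n_win)) {
    idx <- sites_in_region(gm, chrom, starts[w], starts[w] + window_size - 1)
    if (!length(idx)) next
    dos <- gm$calls[, idx, drop = FALSE]
    storage.mode(dos) <- "double"
    p <- colMeans(dos, na.rm = TRUE) / 2
    poly <- which(!is.na(p) & p > 0 & p < 1)
    info$n_sites[w] <- length(idx)
    if (length(poly) < 2) next
    dos <- dos[, poly, drop = FALSE]
    p <- p[poly]
    # impute missing with the site mean, center, standardize
    for (j in which(colSums(is.na(dos)) > 0)) {
      dos[is.na(dos[, j]), j] <- 2 * p[j]
    }
    x <- sweep(dos, 2, 2 * p)
    if (standardize) x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
    sv <- svd(x, nu = 1, nv = 0)
    if (sv$d[1] <= .Machine$double.eps * 10) next  # degenerate window
    sc <- sv$u[, 1] * sv$d[1]
    flip <- if (is.null(prev)) {
      sc[first_sample] < 0
    } else {
      sum(sc * prev) < 0
    }
    if (flip) sc <- -sc
    scores[w, ] <- sc
    info$pc1_var_frac[w] <- sv$d[1]^2 / sum(sv$d^2)
    info$informative[w] <- TRUE
    prev <- sc
  }
  structure(list(windows = info, scores = scores), class = "pca_windows")
}

#' Detect a supergene interval from a window FST scan
#'
#' A candidate is a maximal run of windows with `fst_weighted` above the
#' threshold, allowing at most `max_gap_windows` consecutive
#' below-threshold or uninformative windows inside the run. The longest
#' candidate whose span reaches `min_span` bp is returned, its interval
#' being [first window start, last window end]. Processing order of
#' chromosomes does not affect the result.
#'
#' With `refine = TRUE` (the default) the winning run's bounds are then
#' trimmed: edge windows whose FST is below half the median FST of the
#' run's supporting windows are removed from both ends, so that isolated
#' background windows chained to the run through the gap tolerance do not
#' stretch the reported interval.
#'
#' @param fst_windows data.frame from [windowed_fst()].
#' @param threshold FST threshold (e.g. from
#'   [fst_percentile_threshold()]).
#' @param max_gap_windows gap tolerance inside a run.
#' @param min_span minimum interval span in bp.
#' @param refine trim run edges below half the run-median FST.
#' @return list of class `supergene_call`: `found`, `chrom`, `start`,
#'   `end`, `n_windows` (supporting above-threshold windows),
#'   `threshold`. When no candidate reaches `min_span`, `found` is
#'   `FALSE` (an explicit no-call).
#' @export
detect_supergene <- function(fst_windows, threshold, max_gap_windows = 2,
                             min_span = NULL, refine = TRUE) {
  if (is.null(min_span)) {
    min_span <- 10 * (fst_windows$end[1] - fst_windows$start[1] + 1)
  }
  best <- NULL
  for (ch in sort(unique(fst_windows$chrom))) {
    w <- fst_windows[fst_windows$chrom == ch, ]
    w <- w[order(w$start), ]
    hit <- which(is.finite(w$fst_weighted) & w$fst_weighted > threshold)
    if (!length(hit)) next
    run_start <- hit[1]
    run_end <- hit[1]
    runs <- list()
    for (i in hit[-1]) {
      if (i - run_end - 1 <= max_gap_windows) {
        run_end <- i
      } else {
        runs[[length(runs) + 1]] <- c(run_start, run_end)
        run_start <- run_end <- i
      }
    }
    runs[[length(runs) + 1]] <- c(run_start, run_end)
    for (r in runs) {
      if (refine) {
        sup <- hit[hit >= r[1] & hit <= r[2]]
        edge_min <- stats::median(w$fst_weighted[sup]) / 2
        strong <- sup[w$fst_weighted[sup] >= edge_min]
        if (!length(strong)) next
        r <- range(strong)
      }
      span <- w$end[r[2]] - w$start[r[1]] + 1
      supp <- sum(hit >= r[1] & hit <= r[2])
      if (span >= min_span && (is.null(best) || span > best$span)) {
        best <- list(chrom = ch, start = w$start[r[1]], end = w$end[r[2]],
                     span = span, n_windows = supp)
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(found = FALSE, threshold = threshold),
                     class = "supergene_call"))
  }
  structure(
    list(found = TRUE, chrom = best$chrom, start = best$start,
         end = best$end, n_windows = best$n_windows, threshold = threshold),
    class = "supergene_call"
  )
}

#' @export
print.supergene_call <- function(x, ...) {
  if (!x$found) {
    cat("supergene_call: no region reached the minimum span (no-call)\n")
  } else {
    cat(sprintf("supergene_call: %s:%d-%d (%.2f Mb, %d supporting windows, threshold %.3f)\n",
                x$chrom, x$start, x$end, (x$end - x$start + 1) / 1e6,
                x$n_windows, x$threshold))
  }
  invisible(x)
}

# deterministic 1-D k-means, centers seeded at min / median / max
.cluster_scores_1d <- function(v) {
  centers <- matrix(c(min(v), stats::median(v), max(v)))
  km <- tryCatch(
    stats::kmeans(v, centers = centers, iter.max = 100),
    error = function(e) NULL,
    warning = function(w) NULL
  )
  if (is.null(km) || any(km$size == 0)) {
    # middle center starved: the scores support only two clusters
    km2 <- stats::kmeans(v, centers = matrix(c(min(v), max(v))),
                         iter.max = 100)
    ord <- order(km2$centers)
    cl <- match(km2$cluster, ord)
    cl[cl == 2] <- 3L  # keep outer-cluster coding 1/3
    return(list(cluster = cl, merged = TRUE))
  }
  ord <- order(km$centers)
  cl <- match(km$cluster, ord)  # 1 = lowest-center cluster
  cent <- sort(as.vector(km$centers))
  # degenerate two-cluster structure: one adjacent center gap is tiny
  gaps <- diff(cent)
  merged <- FALSE
  if (min(gaps) < 0.25 * max(gaps)) {
    merged <- TRUE
    if (gaps[1] < gaps[2]) {
      cl[cl == 2] <- 1
      cl[cl == 3] <- 2
    } else {
      cl[cl == 3] <- 2
    }
  }
  list(cluster = cl, merged = merged)
}

#' Assign supergene genotypes AA / AB / BB
#'
#' Samples are placed by their mean PC1 score over the informative PCA
#' windows inside the region, split into three one-dimensional k-means
#' clusters (deterministically seeded at the minimum, median and maximum
#' score). The middle cluster is labeled AB. The outer clusters are
#' polarized by majority genotype at the AB-heterozygous sites: the
#' cluster that is mostly homozygous-reference is AA, the mostly
#' homozygous-alternative one is BB. The assignment is validated by
#' requiring the AB class to have the highest mean observed-heterozygosity
#' fraction in the region; on failure the assignment is flagged.
#'
#' @param gm a [genotype_matrix()].
#' @param region list(chrom, start, end) or a `supergene_call`.
#' @param pca result of [rolling_pca()] on the region's chromosome.
#' @return list of class `genotype_assignment`: `samples` (data.frame
#'   sample_id, class, mean_pc1, het_fraction), `ab_sites` (site indices
#'   used for polarization), `validated`, `warnings`.
#' @export
assign_genotypes <- function(gm, region, pca) {
  if (inherits(region, "supergene_call")) {
    if (!region$found) stop("cannot assign genotypes from a no-call region")
    region <- list(chrom = region$chrom, start = region$start, end = region$end)
  }
  win <- pca$windows
  in_reg <- which(win$chrom == region$chrom & win$informative &
                    win$start <= region$end & win$end >= region$start)
  if (!length(in_reg)) stop("region overlaps no informative PCA window")
  mean_pc1 <- colMeans(pca$scores[in_reg, , drop = FALSE])
  if (length(unique(mean_pc1)) < 3) {
    stop("fewer than 3 distinct PC1 score values; cannot form 3 clusters")
  }
  clu <- .cluster_scores_1d(mean_pc1)
  warnings <- character(0)
  het <- vapply(gm$sample_ids, function(s)
    obs_het_fraction(gm, s, region$chrom, region$start, region$end), 0)
  if (clu$merged) {
    warnings <- c(warnings,
                  "only 2 score clusters supported; no third class forced")
    # two clusters: the one with higher mean het is AB, the other is
    # polarized AA/BB by majority call below
    cl <- clu$cluster
    het_by <- tapply(het, cl, mean)
    ab_cl <- as.integer(names(which.max(het_by)))
    lab <- rep(NA_character_, length(cl))
    lab[cl == ab_cl] <- "AB"
    other <- setdiff(unique(cl), ab_cl)
    cl3 <- ifelse(cl == ab_cl, 2L, ifelse(cl == other[1], 1L, 3L))
  } else {
    cl3 <- clu$cluster
    lab <- c(NA, "AB", NA)[cl3]
  }
  # polarize outer clusters at AB-heterozygous sites
  reg_idx <- sites_in_region(gm, region$chrom, region$start, region$end)
  ab_samples <- which(lab == "AB")
  ab_calls <- gm$calls[ab_samples, reg_idx, drop = FALSE]
  all_het <- colSums(ab_calls == 1L & !is.na(ab_calls)) == length(ab_samples)
  ab_sites <- reg_idx[all_het]
  if (!length(ab_sites)) {
    warnings <- c(warnings, "no AB-heterozygous sites; outer clusters polarized by PC1 order")
  }
  for (k in c(1L, 3L)) {
    members <- which(cl3 == k & is.na(lab))
    if (!length(members)) next
    if (length(ab_sites)) {
      calls <- gm$calls[members, ab_sites, drop = FALSE]
      n_ref <- sum(calls == 0L, na.rm = TRUE)
      n_alt <- sum(calls == 2L, na.rm = TRUE)
      lab[members] <- if (n_ref >= n_alt) "AA" else "BB"
    } else {
      lab[members] <- if (k == 1L) "AA" else "BB"
    }
  }
  # both outer clusters must not have received the same label
  if (!clu$merged && length(unique(lab)) < 3) {
    warnings <- c(warnings, "outer clusters polarized to the same label")
  }
  validated <- TRUE
  het_by_class <- tapply(het, lab, mean)
  if (!("AB" %in% names(het_by_class)) ||
      which.max(het_by_class) != match("AB", names(het_by_class))) {
    validated <- FALSE
    warnings <- c(warnings,
                  "validation failed: AB class does not have the highest mean het fraction")
  }
  structure(
    list(
      samples = data.frame(sample_id = gm$sample_ids, class = lab,
                           mean_pc1 = unname(mean_pc1),
                           het_fraction = unname(het),
                           stringsAsFactors = FALSE),
      ab_sites = ab_sites, validated = validated, warnings = warnings,
      region = region
    ),
    class = "genotype_assignment"
  )
}

#' @export
print.genotype_assignment <- function(x, ...) {
  cat("genotype_assignment:",
      paste(names(table(x$samples$class)), table(x$samples$class),
            sep = "=", collapse = ", "),
      if (x$validated) "(validated)" else "(VALIDATION FAILED)", "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Genotype count profile at AB-heterozygous sites
#'
#' Counts hom-ref / het / hom-alt cells per assigned class over all
#' (sample, site) cells of the AB-heterozygous site set; the AB column is
#' all-heterozygous by construction of that site set.
#'
#' @param gm a [genotype_matrix()].
#' @param assignment a `genotype_assignment`.
#' @return matrix: rows hom_ref/het/hom_alt, one column per class.
#' @export
genotype_count_profile <- function(gm, assignment) {
  sites <- assignment$ab_sites
  if (!length(sites)) stop("empty AB-heterozygous site set")
  classes <- sort(unique(stats::na.omit(assignment$samples$class)))
  out <- sapply(classes, function(cl) {
    rows <- which(assignment$samples$class == cl)
    calls <- gm$calls[rows, sites, drop = FALSE]
    c(hom_ref = sum(calls == 0L, na.rm = TRUE),
      het = sum(calls == 1L, na.rm = TRUE),
      hom_alt = sum(calls == 2L, na.rm = TRUE))
  })
  out
}
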