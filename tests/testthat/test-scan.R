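# shared small simulated dataset with planted truth
scan_dat <- simulate_cohort(small_cfg(), seed = 101)
scan_pca <- rolling_pca(scan_dat$gm, "chr1", window_size = 50000)
scan_region <- scan_dat$truth$supergene

test_that("rolling_pca is deterministic and emits degenerate windows empty", {
  again <- rolling_pca(scan_dat$gm, "chr1", window_size = 50000)
  expect_identical(scan_pca$scores, again$scores)
  expect_identical(scan_pca$windows, again$windows)
  # constant window: all samples identical -> no informative PC1
  calls <- matrix(1L, nrow = 5, ncol = 4)
  gm <- make_gm(calls, pos = c(10L, 20L, 30L, 40L))
  p <- rolling_pca(gm, "chr1", window_size = 1000)
  expect_false(any(p$windows$informative))
  expect_true(all(is.na(p$scores)))
  expect_error(rolling_pca(gm, "chrX"), "unknown chromosome")
})

test_that("PC1 separates the three classes with AB in the middle everywhere", {
  cls <- scan_dat$truth$class[colnames(scan_pca$scores)]
  reg_win <- which(scan_pca$windows$informative &
                     scan_pca$windows$start >= scan_region$start &
                     scan_pca$windows$end <= scan_region$end)
  expect_gt(length(reg_win), 1)
  for (w in reg_win) {
    m <- tapply(scan_pca$scores[w, ], cls, mean)
    expect_true(m[["AB"]] > min(m[["AA"]], m[["BB"]]) &&
                  m[["AB"]] < max(m[["AA"]], m[["BB"]]))
  }
})

test_that("duplicating every sample preserves the score structure", {
  gm <- scan_dat$gm
  gm2 <- genotype_matrix(
    c(gm$sample_ids, paste0(gm$sample_ids, "_dup")),
    gm$sites, rbind(gm$calls, gm$calls)
  )
  p2 <- rolling_pca(gm2, "chr1", window_size = 50000)
  w <- which(scan_pca$windows$informative & p2$windows$informative)[1]
  a <- scan_pca$scores[w, gm$sample_ids]
  b <- p2$scores[w, gm$sample_ids]
  expect_gt(abs(cor(a, b)), 0.9999)
})

test_that("detect_supergene finds runs, honours gaps and min_span", {
  w <- data.frame(
    chrom = "chr1", start = seq(1, 91, by = 10), end = seq(10, 100, by = 10),
    n_sites = 5,
    fst_weighted = c(0.1, 0.8, 0.1, 0.1, 0.9, 0.85, 0.1, 0.1, 0.1, 0.1)
  )
  # single above-threshold window with min_span <= window size
  one <- detect_supergene(w[1:3, ], 0.5, max_gap_windows = 0, min_span = 10)
  expect_true(one$found)
  expect_equal(c(one$start, one$end), c(11, 20))
  # gap of 2 bridges windows 2..6
  run <- detect_supergene(w, 0.5, max_gap_windows = 2, min_span = 30,
                          refine = FALSE)
  expect_equal(c(run$start, run$end), c(11, 60))
  expect_equal(run$n_windows, 3)
  # no window above threshold: explicit no-call
  none <- detect_supergene(w, 0.95, min_span = 10)
  expect_false(none$found)
  # min_span unattainable: no-call
  short <- detect_supergene(w[1:3, ], 0.5, min_span = 50)
  expect_false(short$found)
})

test_that("detection is invariant to chromosome row order", {
  w1 <- data.frame(chrom = "chr1", start = seq(1, 91, by = 10),
                   end = seq(10, 100, by = 10), n_sites = 5,
                   fst_weighted = c(0.1, 0.1, 0.8, 0.9, 0.8, 0.8, 0.1,
                                    0.1, 0.1, 0.1))
  w2 <- data.frame(chrom = "chr2", start = seq(1, 91, by = 10),
                   end = seq(10, 100, by = 10), n_sites = 5,
                   fst_weighted = 0.05)
  a <- detect_supergene(rbind(w1, w2), 0.5, min_span = 30)
  b <- detect_supergene(rbind(w2, w1)[sample(20), ], 0.5, min_span = 30)
  expect_equal(a, b)
  expect_equal(a$chrom, "chr1")
})

test_that("edge refinement trims weak windows chained through gaps", {
  w <- data.frame(
    chrom = "chr1", start = seq(1, 111, by = 10),
    end = seq(10, 120, by = 10), n_sites = 5,
    fst_weighted = c(0.05, 0.2, 0.8, 0.9, 0.85, 0.8, 0.9, 0.85, 0.8, 0.9,
                     0.2, 0.05)
  )
  # threshold 0.15: the weak flanking windows (0.2) join the run, but sit
  # below half the run median (~0.85/2) and are trimmed by refinement
  call <- detect_supergene(w, 0.15, max_gap_windows = 2, min_span = 30)
  expect_equal(c(call$start, call$end), c(21, 100))
  raw <- detect_supergene(w, 0.15, max_gap_windows = 2, min_span = 30,
                          refine = FALSE)
  expect_lt(call$end - call$start, raw$end - raw$start)
})

test_that("genotype assignment recovers the planted classes exactly", {
  asg <- assign_genotypes(scan_dat$gm, scan_region, scan_pca)
  truth <- scan_dat$truth$class[asg$samples$sample_id]
  expect_true(asg$validated)
  expect_equal(asg$samples$class, unname(truth))
  expect_equal(oracle_ari(asg$samples$class, truth), 1)
  # AB has the highest mean het fraction by validation
  het <- tapply(asg$samples$het_fraction, asg$samples$class, mean)
  expect_equal(names(which.max(het)), "AB")
})

test_that("assignment is invariant to sample order", {
  perm <- sample(n_samples(scan_dat$gm))
  gm2 <- subset_gm(scan_dat$gm, samples = scan_dat$gm$sample_ids[perm])
  pca2 <- rolling_pca(gm2, "chr1", window_size = 50000)
  asg1 <- assign_genotypes(scan_dat$gm, scan_region, scan_pca)
  asg2 <- assign_genotypes(gm2, scan_region, pca2)
  m <- match(asg1$samples$sample_id, asg2$samples$sample_id)
  expect_equal(asg1$samples$class, asg2$samples$class[m])
})

test_that("ref/alt relabeling at every site swaps AA and BB exactly", {
  gm <- scan_dat$gm
  flipped <- genotype_matrix(
    gm$sample_ids,
    data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos,
               ref = gm$sites$alt, alt = gm$sites$ref,
               qual = gm$sites$qual),
    2L - gm$calls
  )
  pca_f <- rolling_pca(flipped, "chr1", window_size = 50000)
  asg <- assign_genotypes(gm, scan_region, scan_pca)
  asg_f <- assign_genotypes(flipped, scan_region, pca_f)
  swap <- c(AA = "BB", AB = "AB", BB = "AA")
  expect_equal(asg_f$samples$class, unname(swap[asg$samples$class]))
})

test_that("two-class regions yield two clusters with a warning, not a forced third", {
  cfg <- small_cfg(n_samples = 20,
                   class_freqs = c(AA = 0.5, AB = 0, BB = 0.5))
  dat <- simulate_cohort(cfg, seed = 55)
  pca <- rolling_pca(dat$gm, "chr1", window_size = 50000)
  asg <- assign_genotypes(dat$gm, dat$truth$supergene, pca)
  expect_true(any(grepl("2 score clusters", asg$warnings)))
  expect_lte(length(unique(asg$samples$class)), 2)
})

test_that("assignment rejects degenerate score sets", {
  calls <- matrix(1L, nrow = 4, ncol = 6)
  calls[1, ] <- 0L
  gm <- make_gm(calls, pos = seq(100L, 600L, by = 100L))
  p <- rolling_pca(gm, "chr1", window_size = 10000)
  # all informative scores identical within machine precision is impossible
  # here, but a region with no informative window must error
  expect_error(
    assign_genotypes(gm, list(chrom = "chr1", start = 100000, end = 200000), p),
    "no informative"
  )
})

test_that("genotype count profile is all-het for AB and majority-correct", {
  asg <- assign_genotypes(scan_dat$gm, scan_region, scan_pca)
  prof <- genotype_count_profile(scan_dat$gm, asg)
  expect_equal(prof["hom_ref", "AB"] + prof["hom_alt", "AB"], 0)
  expect_gt(prof["hom_ref", "AA"] / sum(prof[, "AA"]), 0.9)
  expect_gt(prof["hom_alt", "BB"] / sum(prof[, "BB"]), 0.9)
  # single-sample class: counts equal that sample's calls
  keep <- c(which(asg$samples$class == "AA")[1],
            which(asg$samples$class == "AB"),
            which(asg$samples$class == "BB"))
  gm_sub <- subset_gm(scan_dat$gm, samples = scan_dat$gm$sample_ids[keep])
  pca_sub <- rolling_pca(gm_sub, "chr1", window_size = 50000)
  cls_sub <- asg$samples$class[keep]
  asg_sub <- list(samples = data.frame(sample_id = gm_sub$sample_ids,
                                       class = cls_sub),
                  ab_sites = asg$ab_sites)
  class(asg_sub) <- "genotype_assignment"
  prof_sub <- genotype_count_profile(gm_sub, asg_sub)
  one_aa <- gm_sub$calls[1, asg$ab_sites]
  expect_equal(unname(prof_sub["hom_ref", "AA"]), sum(one_aa == 0L))
  expect_equal(unname(prof_sub["het", "AA"]), sum(one_aa == 1L))
})
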