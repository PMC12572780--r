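test_that("wc_fst_site handles the canonical cases", {
  # fixed difference between populations
  fixed <- wc_fst_site(rbind(c(5, 0, 0), c(0, 0, 5)))
  expect_equal(fixed$theta, 1)
  # identical genotype counts: no among-population variance
  same <- wc_fst_site(rbind(c(2, 2, 2), c(2, 2, 2)))
  expect_lte(same$theta, 0)
  # hand-evaluated components for pop1 (0/0,0/1,1/1), pop2 (0/0,0/0,0/1)
  mixed <- wc_fst_site(rbind(c(1, 1, 1), c(2, 1, 0)))
  expect_equal(mixed$a, 0, tolerance = 1e-12)
  expect_equal(mixed$b, 1 / 12, tolerance = 1e-12)
  expect_equal(mixed$c, 1 / 6, tolerance = 1e-12)
  expect_equal(mixed$theta, 0, tolerance = 1e-12)
  # monomorphic across all populations is undefined
  expect_true(is.nan(wc_fst_site(rbind(c(3, 0, 0), c(4, 0, 0)))$theta))
  expect_error(wc_fst_site(rbind(c(0, 0, 0), c(1, 1, 1))), "zero called")
  expect_error(wc_fst_site(rbind(c(1, 1, 1))), ">= 2 populations")
})

test_that("wc_fst_site agrees with the step-by-step oracle on random sites", {
  set.seed(404)
  for (rep in 1:50) {
    r <- sample(2:4, 1)
    counts <- matrix(sample(0:6, 3 * r, replace = TRUE), nrow = r)
    while (any(rowSums(counts) == 0)) {
      counts <- matrix(sample(0:6, 3 * r, replace = TRUE), nrow = r)
    }
    got <- wc_fst_site(counts)
    want <- oracle_wc_theta(asplit(counts, 1))
    expect_equal(got$a, want$a, tolerance = 1e-10)
    expect_equal(got$b, want$b, tolerance = 1e-10)
    expect_equal(got$c, want$c, tolerance = 1e-10)
    if (is.finite(want$theta)) {
      expect_equal(got$theta, want$theta, tolerance = 1e-10)
    }
  }
})

test_that("windowed_fst reduces to wc_fst_site for single-site windows", {
  calls <- rbind(c(0L, 2L), c(1L, 2L), c(2L, 0L),
                 c(0L, 0L), c(0L, 1L), c(1L, 0L))
  gm <- make_gm(calls, pos = c(500L, 25000L))
  grp <- setNames(rep(c("p1", "p2"), each = 3), gm$sample_ids)
  w <- windowed_fst(gm, grp, window_size = 10000)
  s1 <- wc_fst_site(rbind(c(1, 1, 1), c(2, 1, 0)))
  expect_equal(w$fst_weighted[1], s1$a / (s1$a + s1$b + s1$c))
  expect_equal(w$fst_mean[1], s1$theta)
  expect_equal(w$n_sites, c(1L, 0L, 1L))
  expect_true(is.nan(w$fst_weighted[2]))
})

test_that("windowed_fst is invariant to sample order and validates input", {
  dat <- simulate_cohort(small_cfg(n_samples = 12), seed = 5)
  grp <- setNames(rep(c("x", "y"), 6), dat$gm$sample_ids)
  w1 <- windowed_fst(dat$gm, grp)
  perm <- sample(n_samples(dat$gm))
  gm2 <- subset_gm(dat$gm, samples = dat$gm$sample_ids[perm])
  w2 <- windowed_fst(gm2, grp)
  expect_equal(w1, w2)
  expect_error(windowed_fst(dat$gm, c(nope = "x")), "unknown sample")
  expect_error(windowed_fst(dat$gm, grp, window_size = 0), "> 0")
})

test_that("a fixed-difference-only window has weighted FST 1", {
  calls <- rbind(c(0L, 0L), c(0L, 0L), c(2L, 2L), c(2L, 2L))
  gm <- make_gm(calls, pos = c(100L, 200L))
  grp <- setNames(c("p1", "p1", "p2", "p2"), gm$sample_ids)
  w <- windowed_fst(gm, grp, window_size = 10000)
  expect_equal(w$fst_weighted, 1)
})

test_that("percentile threshold uses linear interpolation", {
  st <- data.frame(fst_weighted = seq(0, 1, by = 0.1))
  expect_equal(fst_percentile_threshold(st, 95), 0.95)
  expect_equal(fst_percentile_threshold(data.frame(fst_weighted = rep(0.3, 7)), 95),
               0.3)
  st$fst_weighted[3] <- NaN  # ignored
  expect_equal(fst_percentile_threshold(st, 50),
               median(st$fst_weighted, na.rm = TRUE))
  expect_error(fst_percentile_threshold(st, 0), "in \\(0, 100\\)")
  expect_error(fst_percentile_threshold(st, 100), "in \\(0, 100\\)")
})

test_that("the percentile threshold separates background from region windows", {
  dat <- simulate_cohort(small_cfg(), seed = 47)
  cls <- dat$truth$class[dat$gm$sample_ids]
  grp <- setNames(cls[cls != "AB"], names(cls)[cls != "AB"])
  w <- windowed_fst(dat$gm, grp)
  tr <- dat$truth$supergene
  in_iv <- w$start >= tr$start & w$end <= tr$end
  th <- fst_percentile_threshold(w, 80)
  # nearly all background windows sit below the threshold, region above
  expect_gte(mean(w$fst_weighted[!in_iv] < th, na.rm = TRUE), 0.95)
  expect_gt(median(w$fst_weighted[in_iv], na.rm = TRUE), 0.6)
  expect_lt(median(w$fst_weighted[!in_iv], na.rm = TRUE), 0.1)
})

test_that("obs_het_fraction counts het among called genotypes", {
  gm <- make_gm(rbind(c(1L, 1L, 1L, 1L), c(0L, 1L, 2L, NA)))
  expect_equal(obs_het_fraction(gm, "s01", "chr1"), 1)
  expect_equal(obs_het_fraction(gm, "s02", "chr1"), 1 / 3)
  gm_na <- make_gm(rbind(c(NA, NA), c(0L, 1L)))
  expect_error(obs_het_fraction(gm_na, "s01", "chr1"), "zero called")
  expect_error(obs_het_fraction(gm, "sX", "chr1"), "unknown sample")
})

test_that("ld_r2 follows the composite dosage-correlation convention", {
  gm <- make_gm(rbind(c(0L, 0L, 2L), c(1L, 1L, 1L), c(2L, 2L, 0L),
                      c(0L, 0L, 2L)))
  expect_equal(ld_r2(gm, 1, 2), 1)          # identical dosages
  expect_equal(ld_r2(gm, 1, 3), 1)          # perfect negative correlation
  expect_equal(ld_r2(gm, 1, 2), ld_r2(gm, 2, 1))
  mono <- make_gm(rbind(c(0L, 0L), c(1L, 0L), c(2L, 0L)))
  expect_true(is.nan(ld_r2(mono, 1, 2)))
  # ref/alt relabeling (dosage 2 - x) leaves r2 unchanged
  set.seed(8)
  calls <- matrix(sample(0:2, 40, replace = TRUE), nrow = 8)
  gm2 <- make_gm(calls)
  gm_flip <- make_gm(2L - calls)
  for (j in 2:5) expect_equal(ld_r2(gm2, 1, j), ld_r2(gm_flip, 1, j))
})

test_that("ld_r2 equals a first-principles covariance computation", {
  set.seed(99)
  for (rep in 1:20) {
    calls <- matrix(sample(c(0:2, NA), 30, replace = TRUE,
                           prob = c(0.3, 0.3, 0.3, 0.1)), nrow = 10)
    gm <- make_gm(calls)
    x <- calls[, 1]; y <- calls[, 2]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2 || var(x[ok]) == 0 || var(y[ok]) == 0) next
    xo <- x[ok] - mean(x[ok]); yo <- y[ok] - mean(y[ok])
    brute <- (sum(xo * yo))^2 / (sum(xo^2) * sum(yo^2))
    expect_equal(ld_r2(gm, 1, 2), brute, tolerance = 1e-12)
  }
})

test_that("ld_decay bins pairs by distance", {
  gm <- make_gm(rbind(c(0L, 0L), c(1L, 1L), c(2L, 2L), c(0L, 1L)),
                pos = c(1000L, 26000L))
  bins <- ld_decay(gm, chrom = "chr1", maf_min = 0, bin_width = 10000)
  populated <- bins[bins$n_pairs > 0, ]
  expect_equal(nrow(populated), 1)
  expect_equal(populated$bin_lo, 20000)
  expect_equal(populated$mean_r2, ld_r2(gm, 1, 2))
  # duplicated columns: every populated bin averages exactly 1
  dup <- make_gm(matrix(rep(c(0L, 1L, 2L, 1L, 0L), 6), nrow = 5),
                 pos = c(10L, 5000L, 22000L, 31000L, 44000L, 60000L))
  b2 <- ld_decay(dup, chrom = "chr1", maf_min = 0, bin_width = 10000)
  expect_equal(b2$mean_r2[b2$n_pairs > 0],
               rep(1, sum(b2$n_pairs > 0)), tolerance = 1e-12)
  expect_error(ld_decay(gm, chrom = "chr1", bin_width = 0), "> 0")
})

test_that("k80 distance matches its closed form and flags saturation", {
  expect_equal(k80_distance("ACGT", "ACGT")$distance, 0)
  # 100 sites, 10 transitions, 5 transversions: P = 0.10, Q = 0.05
  base <- rep("A", 100)
  other <- base
  other[1:10] <- "G"          # transitions A->G
  other[11:15] <- "C"         # transversions A->C
  got <- k80_distance(base, other)
  expect_equal(got$P, 0.10)
  expect_equal(got$Q, 0.05)
  expect_equal(round(got$distance, 4), 0.1702)
  expect_equal(got$distance, -0.5 * log(1 - 0.2 - 0.05) - 0.25 * log(1 - 0.1))
  # saturation: 1 - 2P - Q <= 0
  sat <- k80_distance(rep("A", 10), c(rep("G", 5), rep("A", 4), "C"))
  expect_true(sat$saturated)
  expect_true(is.na(sat$distance))
  # non-ACGT sites excluded
  expect_equal(k80_distance("ACNT", "ACNA")$n_sites, 3)
  expect_error(k80_distance("ACG", "AC"), "length mismatch")
  expect_error(k80_distance("NNN", "NNN"), "zero comparable")
})

test_that("k80 distance agrees with ape on random sequences", {
  skip_if_not_installed("ape")
  set.seed(7)
  for (rep in 1:10) {
    s1 <- sample(c("a", "c", "g", "t"), 500, replace = TRUE)
    s2 <- s1
    mut <- sample(500, 60)
    s2[mut] <- sample(c("a", "c", "g", "t"), 60, replace = TRUE)
    d_ape <- ape::dist.dna(ape::as.DNAbin(rbind(s1, s2)), model = "K80")
    expect_equal(k80_distance(s1, s2)$distance, as.numeric(d_ape),
                 tolerance = 1e-12)
  }
})

test_that("k80 distance is monotone in P at fixed Q within its domain", {
  d <- sapply(1:20, function(k) {
    s1 <- rep("A", 100)
    s2 <- rep("A", 100)
    s2[seq_len(k)] <- "G"
    k80_distance(s1, s2)$distance
  })
  expect_true(all(diff(d) > 0))
  expect_true(all(d > 0))
})
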