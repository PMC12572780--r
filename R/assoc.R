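#' Classify queen morph from head width
#'
#' Head width above `hi` mm is a macrogyne, below `lo` a microgyne, and
#' the closed interval [lo, hi] an intermediate. The default cut-offs
#' (1.04 and 1.08 mm) bracket the traditional single 1.06 mm cut-off used
#' for queen-size-dimorphic Myrmica.
#'
#' @param width head width(s) in mm; must be positive.
#' @param lo,hi the two cut-offs in mm.
#' @return character vector: "macrogyne", "intermediate" or "microgyne".
#' @export
classify_morph <- function(width, lo = 1.04, hi = 1.08) {
  if (any(width <= 0, na.rm = TRUE)) stop("head width must be positive")
  out <- ifelse(width > hi, "macrogyne",
                ifelse(width < lo, "microgyne", "intermediate"))
  out[is.na(width)] <- NA_character_
  out
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Tie-corrected H statistic with df = number of groups - 1 and a
#' chi-square upper-tail p-value. When all values are equal H = 0 and
#' p = 1.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(vapply(groups, length, 1L) == 0)) stop("a group is empty")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (length(unique(x)) == 1) {
    return(list(H = 0, df = length(groups) - 1, p = 1))
  }
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Dunn's post hoc test for pairwise group comparisons
#'
#' For groups i and j with mean ranks in the pooled ranking,
#' z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))
#' where T = sum over tied values of (t^3 - t). Two-sided normal
#' p-values, adjusted across all pairs (Holm by default;
#' Benjamini-Hochberg via `adjust = "BH"`).
#'
#' @param groups named list of numeric vectors.
#' @param adjust p-adjustment method, `"holm"` or `"BH"`.
#' @return data.frame: group1, group2, z, p_raw, p_adj.
#' @export
dunn_posthoc <- function(groups, adjust = c("holm", "BH")) {
  adjust <- match.arg(adjust)
  if (length(groups) < 2) stop("need >= 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  sizes <- vapply(groups, length, 1L)
  g <- rep(names(groups), sizes)
  N <- length(x)
  rk <- rank(x)
  mean_rank <- tapply(rk, g, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties)
  var_base <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(var_base * (1 / sizes[[i]] + 1 / sizes[[j]]))
    z <- if (se > 0) (mean_rank[[i]] - mean_rank[[j]]) / se else 0
    z
  })
  p_raw <- 2 * stats::pnorm(-abs(res))
  data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ], z = unname(res),
    p_raw = unname(p_raw),
    p_adj = unname(stats::p.adjust(p_raw, method = adjust)),
    stringsAsFactors = FALSE
  )
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric two-sided p-value by the point-probability rule:
#' the sum of the probabilities of all tables with the observed margins
#' whose probability does not exceed the observed table's (up to a
#' 1 + 1e-7 relative tolerance) - the convention of standard statistical
#' environments.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return the two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2))) stop("table must be 2x2")
  if (any(m < 0) || any(m != round(m))) stop("cells must be non-negative integers")
  if (sum(m) == 0) stop("all-zero table")
  stats::fisher.test(m)$p.value
}

#' Colony-level association between social type and supergene genotype
#'
#' Classifies colonies as single- or multiple-queen from the observed
#' queen count, scores a colony AA when any resident queen is AA (non-AA
#' otherwise), and tests the 2x2 colony-type x genotype-class table with
#' a two-sided Fisher exact test.
#'
#' @param samples data.frame with at least `colony_id`, `caste`,
#'   `queen_count`, `genotype_class`; only rows with caste "queen" are
#'   used.
#' @return list with `table` (2x2) and `p`.
#' @export
colony_genotype_association <- function(samples) {
  q <- samples[samples$caste == "queen" & !is.na(samples$colony_id), ]
  if (anyNA(q$genotype_class)) stop("every queen needs a genotype class")
  if (any(q$queen_count < 1)) stop("colony with zero queens")
  per_col <- lapply(split(q, q$colony_id), function(d) {
    data.frame(
      type = if (d$queen_count[1] == 1) "single_queen" else "multiple_queen",
      aa = any(d$genotype_class == "AA"),
      stringsAsFactors = FALSE
    )
  })
  pc <- do.call(rbind, per_col)
  tab <- matrix(
    c(sum(pc$type == "single_queen" & pc$aa),
      sum(pc$type == "single_queen" & !pc$aa),
      sum(pc$type == "multiple_queen" & pc$aa),
      sum(pc$type == "multiple_queen" & !pc$aa)),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("single_queen", "multiple_queen"), c("AA", "non_AA"))
  )
  list(table = tab, p = fisher_exact_2x2(tab))
}

#' Association between matriline count and supergene genotype
#'
#' Tests the 2x2 table of colony genotype class (AA vs non-AA) against
#' matriline count (1 vs more than 1) with a two-sided Fisher exact test.
#'
#' @param n_matrilines integer vector of estimated matriline counts, one
#'   per colony.
#' @param colony_class character vector, "AA" or anything else (treated
#'   as non-AA), aligned with `n_matrilines`.
#' @return list with `table` (2x2) and `p`.
#' @export
matriline_genotype_association <- function(n_matrilines, colony_class) {
  if (length(n_matrilines) != length(colony_class)) {
    stop("inputs must have equal length")
  }
  if (length(n_matrilines) < 2) stop("need >= 2 colonies")
  if (any(n_matrilines < 1)) stop("matriline count must be >= 1")
  aa <- colony_class == "AA"
  single <- n_matrilines == 1
  tab <- matrix(
    c(sum(aa & single), sum(aa & !single),
      sum(!aa & single), sum(!aa & !single)),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("AA", "non_AA"), c("one_matriline", "multiple_matrilines"))
  )
  list(table = tab, p = fisher_exact_2x2(tab))
}
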