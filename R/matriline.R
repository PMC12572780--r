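#' Is a set of workers consistent with one matriline?
#'
#' Haplodiploid family rules. Under monandry the workers must, at every
#' locus with data, be explainable as offspring of one diploid mother
#' (m1, m2) and one haploid father f: every worker's unordered allele
#' pair is {f, m} with m in {m1, m2}. Under polyandry (one mother, any
#' number of fathers) every worker must only carry at least one maternal
#' allele: there must exist (m1, m2) intersecting every worker's pair.
#' Missing data at a locus never falsifies a family.
#'
#' @param geno integer matrix, workers x (2 x n_loci): columns 2l-1, 2l
#'   are the unordered allele pair at locus l; `NA` = missing.
#' @param mode `"monandry"` or `"polyandry"`.
#' @return `TRUE` or `FALSE`.
#' @export
family_consistent <- function(geno, mode = c("monandry", "polyandry")) {
  mode <- match.arg(mode)
  geno <- as.matrix(geno)
  if (nrow(geno) == 0) stop("need >= 1 worker")
  n_loci <- ncol(geno) / 2
  if (n_loci < 1 || ncol(geno) %% 2 != 0) stop("no loci")
  for (l in seq_len(n_loci)) {
    pairs <- geno[, c(2 * l - 1, 2 * l), drop = FALSE]
    pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
    if (nrow(pairs) == 0) next
    if (!.locus_consistent(pairs, mode)) return(FALSE)
  }
  TRUE
}

.locus_consistent <- function(pairs, mode) {
  alleles <- sort(unique(as.vector(pairs)))
  if (mode == "monandry") {
    for (f in alleles) {
      has_f <- pairs[, 1] == f | pairs[, 2] == f
      if (!all(has_f)) next
      # maternal allele is determined given the father: the non-f allele,
      # or f itself for an {f, f} homozygote
      maternal <- ifelse(pairs[, 1] == f, pairs[, 2], pairs[, 1])
      if (length(unique(maternal)) <= 2) return(TRUE)
    }
    FALSE
  } else {
    for (i in seq_along(alleles)) {
      for (j in i:length(alleles)) {
        mm <- c(alleles[i], alleles[j])
        if (all(pairs[, 1] %in% mm | pairs[, 2] %in% mm)) return(TRUE)
      }
    }
    FALSE
  }
}

#' Minimum number of matrilines explaining a colony's workers
#'
#' Parsimony criterion: the smallest number of blocks partitioning the
#' colony's workers such that each block is [family_consistent()]. For
#' colonies of at most `exact_limit` workers the minimum is found by an
#' exact branch-and-bound search over set partitions; larger colonies use
#' a deterministic greedy heuristic (seed each block with the unassigned
#' worker that has the fewest pairwise-compatible peers, grow while
#' consistent), whose result is an upper bound on the exact minimum.
#'
#' @param geno integer matrix, workers x (2 x n_loci), as in
#'   [family_consistent()]; row names are worker ids.
#' @param mode `"monandry"` or `"polyandry"`.
#' @param exact_limit largest colony size for the exact search.
#' @return list of class `matriline_partition`: `blocks` (list of row
#'   index vectors), `n_matrilines`, `mode`, `method`.
#' @export
min_matrilines <- function(geno, mode = c("monandry", "polyandry"),
                           exact_limit = 9) {
  mode <- match.arg(mode)
  geno <- as.matrix(geno)
  n <- nrow(geno)
  if (n == 0) stop("need >= 1 worker")
  if (n <= exact_limit) {
    blocks <- .exact_partition(geno, mode)
    method <- "exact"
  } else {
    blocks <- .greedy_partition(geno, mode)
    method <- "greedy"
  }
  structure(
    list(blocks = blocks, n_matrilines = length(blocks), mode = mode,
         method = method),
    class = "matriline_partition"
  )
}

.exact_partition <- function(geno, mode) {
  n <- nrow(geno)
  best <- list(blocks = lapply(seq_len(n), identity))  # singletons always valid
  best_k <- n
  recurse <- function(i, blocks) {
    if (length(blocks) >= best_k) return()  # cannot improve
    if (i > n) {
      best_k <<- length(blocks)
      best$blocks <<- blocks
      return()
    }
    for (b in seq_along(blocks)) {
      cand <- c(blocks[[b]], i)
      if (family_consistent(geno[cand, , drop = FALSE], mode)) {
        nb <- blocks
        nb[[b]] <- cand
        recurse(i + 1, nb)
      }
    }
    recurse(i + 1, c(blocks, list(i)))
  }
  recurse(2L, list(1L))
  best$blocks
}

.greedy_partition <- function(geno, mode) {
  n <- nrow(geno)
  unassigned <- seq_len(n)
  # pairwise compatibility counts for seeding
  compat <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- family_consistent(geno[c(i, j), , drop = FALSE], mode)
      compat[i, j] <- compat[j, i] <- ok
    }
  }
  blocks <- list()
  while (length(unassigned)) {
    deg <- rowSums(compat[unassigned, unassigned, drop = FALSE])
    seed <- unassigned[which.min(deg)]  # ties: first index
    block <- seed
    unassigned <- setdiff(unassigned, seed)
    for (w in unassigned) {
      cand <- c(block, w)
      if (family_consistent(geno[cand, , drop = FALSE], mode)) block <- cand
    }
    unassigned <- setdiff(unassigned, block)
    blocks[[length(blocks) + 1]] <- block
  }
  blocks
}

#' Estimate matriline counts for every colony in a microsatellite table
#'
#' @param microsats data.frame with `worker_id`, `colony_id` and paired
#'   allele columns (`L1_a`, `L1_b`, ...), as produced by
#'   [simulate_microsatellites()] or read from TSV.
#' @param mode `"monandry"` or `"polyandry"`.
#' @param exact_limit see [min_matrilines()].
#' @return data.frame: colony_id, n_matrilines, method.
#' @export
estimate_matrilines <- function(microsats, mode = c("monandry", "polyandry"),
                                exact_limit = 9) {
  mode <- match.arg(mode)
  allele_cols <- setdiff(names(microsats), c("worker_id", "colony_id"))
  out <- lapply(split(microsats, microsats$colony_id), function(d) {
    geno <- as.matrix(d[allele_cols])
    rownames(geno) <- d$worker_id
    part <- min_matrilines(geno, mode, exact_limit)
    data.frame(colony_id = d$colony_id[1],
               n_matrilines = part$n_matrilines, method = part$method,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
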