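#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: the observed genotype table's conditional
#' probability given the allele counts is compared against tables obtained
#' by randomly re-pairing the observed alleles. The p-value is
#' `(1 + #{permuted tables with probability <= observed}) / (1 + n_mc)`.
#' Used to drop loci that deviate from HWE before any likelihood is
#' computed (the locus-exclusion policy applies p < 0.05 per population).
#'
#' @param dataset A [genotype_dataset()].
#' @param locus Locus id.
#' @param n_mc Number of Monte-Carlo permutations (default 10000).
#' @param seed RNG seed (required for determinism).
#' @param population Optional population id to subset on.
#' @return The Monte-Carlo p-value. A monomorphic locus returns 1 with a
#'   warning.
#' @export
hwe_test <- function(dataset, locus, n_mc = 10000L, seed, population = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (!locus %in% dataset$loci) stop("unknown locus: ", locus, call. = FALSE)
  if (!is.null(population))
    dataset <- subset_individuals(
      dataset, !is.na(dataset$meta$population) &
        dataset$meta$population == population)
  g <- dataset$calls[, paste0(locus, c("_1", "_2")), drop = FALSE]
  g <- g[!is.na(g[, 1]), , drop = FALSE]
  alleles <- c(g[, 1], g[, 2])
  if (length(unique(alleles)) < 2L) {
    warning("locus ", locus, " is monomorphic; HWE p set to 1")
    return(1)
  }
  if (nrow(g) < 5L)
    stop("need >= 5 typed individuals at locus ", locus, call. = FALSE)
  set.seed(as.integer(seed))
  # log conditional probability up to a constant: only the genotype-count
  # factorials and the heterozygote count vary across re-pairings
  K <- max(alleles) + 1
  score <- function(a1, a2) {
    lo <- pmin(a1, a2); hi <- pmax(a1, a2)
    counts <- rle(sort(lo * K + hi))$lengths
    sum(lo != hi) * log(2) - sum(lgamma(counts + 1))
  }
  obs <- score(g[, 1], g[, 2])
  n2 <- length(alleles)
  hits <- 0L
  for (i in seq_len(n_mc)) {
    perm <- sample(alleles, n2)
    half <- n2 %/% 2L
    if (score(perm[seq_len(half)], perm[half + seq_len(half)]) <= obs + 1e-12)
      hits <- hits + 1L
  }
  (1 + hits) / (1 + n_mc)
}

#' HWE-based locus exclusion
#'
#' Runs [hwe_test()] on every locus and returns those with p below `alpha`,
#' plus any locus explicitly flagged error-prone.
#'
#' @param dataset A [genotype_dataset()].
#' @param alpha Exclusion level (default 0.05).
#' @param n_mc,seed Passed to [hwe_test()].
#' @param flagged Character vector of loci to exclude regardless (e.g. a
#'   marker known to be prone to genotyping error).
#' @param population Optional population id.
#' @return Character vector of locus ids to exclude.
#' @export
hwe_exclusions <- function(dataset, alpha = 0.05, n_mc = 2000L, seed = 1L,
                           flagged = character(), population = NULL) {
  ps <- vapply(seq_along(dataset$loci), function(i) {
    suppressWarnings(hwe_test(dataset, dataset$loci[i], n_mc = n_mc,
                              seed = derive_seed(seed, i),
                              population = population))
  }, numeric(1))
  union(dataset$loci[ps < alpha], intersect(flagged, dataset$loci))
}

#' Drop loci from a dataset
#'
#' @param dataset A [genotype_dataset()].
#' @param loci Locus ids to remove.
#' @return A `genotype_dataset` without those loci.
#' @export
drop_loci <- function(dataset, loci) {
  keep <- setdiff(dataset$loci, loci)
  if (!length(keep)) stop("no loci left after exclusion", call. = FALSE)
  cols <- as.vector(rbind(paste0(keep, "_1"), paste0(keep, "_2")))
  genotype_dataset(dataset$calls[, cols, drop = FALSE], dataset$meta)
}
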