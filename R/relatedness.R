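#' Queller-Goodnight pairwise relatedness
#'
#' The symmetric (ratio-of-sums) multilocus estimator. For locus `l` with
#' genotypes `gx = (a,b)`, `gy = (c,d)` and reference frequencies `p`:
#' \deqn{num_l(x|y) = 0.5(\delta_{ac}+\delta_{ad}+\delta_{bc}+\delta_{bd}) - p_a - p_b}
#' \deqn{den_l(x) = 1 + \delta_{ab} - p_a - p_b}
#' and
#' \deqn{r = \frac{\sum_l num_l(x|y) + \sum_l num_l(y|x)}{\sum_l den_l(x) + \sum_l den_l(y)}.}
#' Loci missing in either individual are skipped. Expected values are 0.5
#' for parent-offspring and full sibs, 0.25 for half sibs, 0 for unrelated
#' pairs; individual estimates range roughly over \[-1, 1\].
#'
#' @param gx,gy Genotypes: numeric matrices, loci in rows (rownames = locus
#'   ids), 2 columns; `NA` rows are missing calls. See
#'   [individual_genotype()].
#' @param freqs An [allele_freq_block()].
#' @param variant `"symmetric"` (default; one ratio of pooled sums over
#'   both reference directions) or `"directional-mean"` (average of the
#'   two directional ratios), offered for sensitivity analyses.
#' @return Scalar relatedness estimate `r`. Errors if no locus is typed in
#'   both individuals or the denominator sum is zero (all loci
#'   uninformative).
#' @export
qg_relatedness <- function(gx, gy, freqs,
                           variant = c("symmetric", "directional-mean")) {
  variant <- match.arg(variant)
  stopifnot(inherits(freqs, "allele_freq_block"))
  loci <- intersect(rownames(gx), names(freqs))
  num_xy <- 0; num_yx <- 0; den_x <- 0; den_y <- 0; used <- 0L
  for (l in loci) {
    x <- gx[l, ]; y <- gy[l, ]
    if (anyNA(x) || anyNA(y)) next
    p <- freqs[[l]]
    px <- sum(freq_lookup(p, x)); py <- sum(freq_lookup(p, y))
    share <- sum(outer(x, y, "=="))
    num_xy <- num_xy + 0.5 * share - px
    num_yx <- num_yx + 0.5 * share - py
    den_x <- den_x + 1 + (x[1] == x[2]) - px
    den_y <- den_y + 1 + (y[1] == y[2]) - py
    used <- used + 1L
  }
  if (used == 0L) stop("no locus typed in both individuals", call. = FALSE)
  if (variant == "symmetric") {
    den <- den_x + den_y
    if (abs(den) < 1e-9)        # exact zero up to float summation order
      stop("all loci uninformative: QG denominator is zero", call. = FALSE)
    unname((num_xy + num_yx) / den)
  } else {
    if (abs(den_x) < 1e-9 || abs(den_y) < 1e-9)
      stop("all loci uninformative: QG denominator is zero", call. = FALSE)
    unname((num_xy / den_x + num_yx / den_y) / 2)
  }
}

#' Pairwise relatedness matrix for a dataset
#'
#' Vectorised computation of [qg_relatedness()] between every pair of
#' individuals. `NA` where a pair shares no typed locus or the denominator
#' vanishes.
#'
#' @param dataset A [genotype_dataset()].
#' @param freqs An [allele_freq_block()].
#' @param variant See [qg_relatedness()].
#' @return Symmetric numeric matrix with `NA` diagonal, dimnames = ids.
#' @export
relatedness_matrix <- function(dataset, freqs,
                               variant = c("symmetric",
                                           "directional-mean")) {
  variant <- match.arg(variant)
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(freqs, "allele_freq_block"))
  n <- n_individuals(dataset)
  NR <- matrix(0, n, n); DR <- matrix(0, n, n)
  for (l in intersect(dataset$loci, names(freqs))) {
    g <- dataset$calls[, paste0(l, c("_1", "_2")), drop = FALSE]
    ok <- !is.na(g[, 1])
    if (sum(ok) < 2) next
    p <- freqs[[l]]
    a <- g[ok, 1]; b <- g[ok, 2]
    psum <- freq_lookup(p, a) + freq_lookup(p, b)
    S <- outer(a, a, "==") + outer(a, b, "==") +
      outer(b, a, "==") + outer(b, b, "==")
    deni <- 1 + (a == b) - psum
    ones <- rep(1, length(a))
    idx <- which(ok)
    # row-direction numerator/denominator; the transposes give the other
    NR[idx, idx] <- NR[idx, idx] + 0.5 * S - outer(psum, ones)
    DR[idx, idx] <- DR[idx, idx] + outer(deni, ones)
  }
  if (variant == "symmetric") {
    N <- NR + t(NR); D <- DR + t(DR)
    r <- N / D
    r[abs(D) < 1e-9] <- NA
  } else {
    M <- NR / DR
    M[abs(DR) < 1e-9] <- NA
    r <- (M + t(M)) / 2
  }
  diag(r) <- NA
  dimnames(r) <- list(dataset$meta$id, dataset$meta$id)
  r
}

# Batched QG relatedness over simulated dyads.
# a1,b1,a2,b2: n x L matrices of allele labels (columns = loci of `freqs`).
qg_relatedness_batch <- function(a1, b1, a2, b2, freqs) {
  n <- nrow(a1)
  num <- numeric(n); den <- numeric(n)
  loci <- names(freqs)
  for (j in seq_along(loci)) {
    p <- freqs[[loci[j]]]
    x1 <- a1[, j]; y1 <- b1[, j]; x2 <- a2[, j]; y2 <- b2[, j]
    px <- freq_lookup(p, x1) + freq_lookup(p, y1)
    py <- freq_lookup(p, x2) + freq_lookup(p, y2)
    share <- (x1 == x2) + (x1 == y2) + (y1 == x2) + (y1 == y2)
    num <- num + share - px - py
    den <- den + (1 + (x1 == y1) - px) + (1 + (x2 == y2) - py)
  }
  num / den
}
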