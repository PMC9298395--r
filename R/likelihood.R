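#' Relationship hypotheses as k-coefficients
#'
#' A relationship hypothesis is the triple `(k0, k1, k2)` of probabilities
#' that a dyad shares 0, 1 or 2 alleles identical by descent at a locus.
#' Presets: unrelated `U = (1,0,0)`, half sib `HS = (0.5,0.5,0)`, full sib
#' `FS = (0.25,0.5,0.25)`, parent-offspring `PO = (0,1,0)`.
#'
#' @param label One of `"U"`, `"HS"`, `"FS"`, `"PO"`, or `NULL` to supply
#'   coefficients directly.
#' @param k0,k1,k2 Custom coefficients (must sum to 1).
#' @return An object of class `k_coefficients`.
#' @examples
#' kin_hypothesis("FS")
#' kin_hypothesis(k0 = 0.5, k1 = 0.5, k2 = 0, label = "custom-HS")
#' @export
kin_hypothesis <- function(label = NULL, k0 = NULL, k1 = NULL, k2 = NULL) {
  presets <- list(U  = c(1, 0, 0), HS = c(0.5, 0.5, 0),
                  FS = c(0.25, 0.5, 0.25), PO = c(0, 1, 0))
  if (is.null(k0)) {
    if (is.null(label) || !label %in% names(presets))
      stop("label must be one of U, HS, FS, PO (or supply k0,k1,k2)",
           call. = FALSE)
    k <- presets[[label]]
  } else {
    k <- c(k0, k1, k2)
    if (abs(sum(k) - 1) > 1e-9 || any(k < 0))
      stop("k-coefficients must be nonnegative and sum to 1", call. = FALSE)
    label <- label %||% "custom"
  }
  structure(list(k0 = k[1], k1 = k[2], k2 = k[3], label = label),
            class = "k_coefficients")
}

#' @export
print.k_coefficients <- function(x, ...) {
  cat(sprintf("%s: k = (%.3g, %.3g, %.3g)\n", x$label, x$k0, x$k1, x$k2))
  invisible(x)
}

# HWE genotype probability, T1 (one allele IBD) and T2 (both IBD) kernels,
# vectorised over dyads at one locus. p1,q1 = alleles of gx; p2,q2 of gy.
locus_likelihood_terms <- function(a1, b1, a2, b2, p) {
  pa1 <- freq_lookup(p, a1); pb1 <- freq_lookup(p, b1)
  pa2 <- freq_lookup(p, a2); pb2 <- freq_lookup(p, b2)
  Pgx <- ifelse(a1 == b1, pa1 * pa1, 2 * pa1 * pb1)
  Pgy <- ifelse(a2 == b2, pa2 * pa2, 2 * pa2 * pb2)
  # T(z): transmission probability of gy given IBD allele z
  Tz <- function(z, pz) {
    het <- a2 != b2
    ifelse(het,
           (z == a2) * pb2 + (z == b2) * pa2,
           (z == a2) * pa2)
  }
  T1 <- 0.5 * (Tz(a1, pa1) + Tz(b1, pb1))
  T2 <- as.numeric((a1 == a2 & b1 == b2) | (a1 == b2 & b1 == a2))
  list(Pgx = Pgx, Pgy = Pgy, T1 = T1, T2 = T2)
}

#' Dyad log-likelihood under a relationship hypothesis
#'
#' Per locus, `L = P(gx) * (k0 P(gy) + k1 T1(gy|gx) + k2 T2(gy|gx))`, where
#' `P` is the HWE genotype probability, `T1` averages over which allele of
#' `gx` is identical by descent, and `T2` indicates genotype identity as
#' unordered pairs. Returns the sum of per-locus log-likelihoods over loci
#' typed in both individuals. A genotype pair impossible under the
#' hypothesis (e.g. no shared allele under parent-offspring) yields `-Inf`,
#' which loses every likelihood comparison but is never used in further
#' arithmetic.
#'
#' @param gx,gy Genotypes as loci x 2 matrices (see
#'   [individual_genotype()]).
#' @param k A [kin_hypothesis()].
#' @param freqs An [allele_freq_block()].
#' @return Scalar log-likelihood (possibly `-Inf`).
#' @export
dyad_log_likelihood <- function(gx, gy, k, freqs) {
  stopifnot(inherits(k, "k_coefficients"), inherits(freqs, "allele_freq_block"))
  loci <- intersect(rownames(gx), names(freqs))
  ll <- 0
  used <- 0L
  for (l in loci) {
    x <- gx[l, ]; y <- gy[l, ]
    if (anyNA(x) || anyNA(y)) next
    tm <- locus_likelihood_terms(x[1], x[2], y[1], y[2], freqs[[l]])
    L <- tm$Pgx * (k$k0 * tm$Pgy + k$k1 * tm$T1 + k$k2 * tm$T2)
    ll <- ll + log(L)
    used <- used + 1L
  }
  if (used == 0L) stop("no locus typed in both individuals", call. = FALSE)
  ll
}

# vectorised log-likelihood over a dyad batch (n x L allele matrices)
dyad_log_likelihood_batch <- function(a1, b1, a2, b2, k, freqs) {
  ll <- numeric(nrow(a1))
  loci <- names(freqs)
  for (j in seq_along(loci)) {
    tm <- locus_likelihood_terms(a1[, j], b1[, j], a2[, j], b2[, j],
                                 freqs[[loci[j]]])
    ll <- ll + log(tm$Pgx * (k$k0 * tm$Pgy + k$k1 * tm$T1 + k$k2 * tm$T2))
  }
  ll
}

#' Simulate genotype dyads under a relationship hypothesis
#'
#' The first genotype of each pair is an HWE draw from `freqs`; the second
#' shares 0/1/2 alleles identical by descent with probabilities
#' `(k0, k1, k2)`, drawn independently per locus (unlinked loci). This is
#' the null/alternative generator behind every simulated significance
#' level in the pipeline.
#'
#' @param hypothesis A [kin_hypothesis()].
#' @param n Number of dyads.
#' @param freqs An [allele_freq_block()].
#' @param seed RNG seed.
#' @return A `dyad_batch`: list of four n x L allele matrices `a1, b1, a2,
#'   b2` (columns = loci). Use [dyad_pair()] to extract pair `i` in the
#'   loci x 2 matrix form.
#' @export
simulate_dyads <- function(hypothesis, n, freqs, seed) {
  stopifnot(inherits(hypothesis, "k_coefficients"),
            inherits(freqs, "allele_freq_block"), n >= 1)
  set.seed(as.integer(seed))
  L <- length(freqs)
  a1 <- b1 <- a2 <- b2 <- matrix(NA_character_, n, L,
                                 dimnames = list(NULL, names(freqs)))
  for (j in seq_len(L)) {
    p <- freqs[[j]]
    lab <- names(p)
    a1[, j] <- sample(lab, n, TRUE, p)
    b1[, j] <- sample(lab, n, TRUE, p)
    ibd <- sample(0:2, n, TRUE,
                  c(hypothesis$k0, hypothesis$k1, hypothesis$k2))
    c2 <- sample(lab, n, TRUE, p)
    d2 <- sample(lab, n, TRUE, p)
    # one allele IBD: copy a random allele of gx into a random slot of gy
    pick_first <- stats::runif(n) < 0.5
    ibd_allele <- ifelse(pick_first, a1[, j], b1[, j])
    into_first <- stats::runif(n) < 0.5
    one <- ibd == 1
    c2[one & into_first] <- ibd_allele[one & into_first]
    d2[one & !into_first] <- ibd_allele[one & !into_first]
    two <- ibd == 2
    c2[two] <- a1[two, j]; d2[two] <- b1[two, j]
    a2[, j] <- c2; b2[, j] <- d2
  }
  structure(list(a1 = a1, b1 = b1, a2 = a2, b2 = b2,
                 loci = names(freqs), hypothesis = hypothesis$label),
            class = "dyad_batch")
}

#' Extract one simulated dyad
#'
#' @param batch A `dyad_batch` from [simulate_dyads()].
#' @param i Pair index.
#' @return List with `gx` and `gy`, each a loci x 2 matrix.
#' @export
dyad_pair <- function(batch, i) {
  gx <- cbind(batch$a1[i, ], batch$b1[i, ])
  gy <- cbind(batch$a2[i, ], batch$b2[i, ])
  rownames(gx) <- rownames(gy) <- batch$loci
  list(gx = gx, gy = gy)
}

#' Null distribution of the log-likelihood ratio
#'
#' Simulates `n` dyads under the null hypothesis and returns the sampled
#' log-likelihood ratios `logL(primary) - logL(null)`. Computing this once
#' and passing it to [classify_dyad()] via `null_dist` amortises the
#' simulation across many dyads tested against the same hypothesis pair
#' and frequency block.
#'
#' @param primary,null [kin_hypothesis()] objects.
#' @param freqs An [allele_freq_block()].
#' @param n Number of simulated null dyads.
#' @param seed RNG seed.
#' @return Numeric vector of length `n` (may contain `-Inf`).
#' @export
null_lambda_distribution <- function(primary, null, freqs, n = 10000L, seed) {
  sim <- simulate_dyads(null, n, freqs, seed)
  dyad_log_likelihood_batch(sim$a1, sim$b1, sim$a2, sim$b2, primary, freqs) -
    dyad_log_likelihood_batch(sim$a1, sim$b1, sim$a2, sim$b2, null, freqs)
}

#' Likelihood-ratio classification of a dyad
#'
#' Tests a primary relationship hypothesis against a null (typically
#' unrelatedness). The observed ratio `Lambda = logL(primary) - logL(null)`
#' is compared to ratios of dyads simulated under the null:
#' `p = (1 + #{Lambda' >= Lambda}) / (1 + n_null)`; the dyad is significant
#' at `p <= alpha`. If the primary hypothesis is impossible for the
#' observed genotypes (`logL = -Inf`) it is rejected outright (`p = 1`).
#'
#' @param gx,gy Genotypes as loci x 2 matrices.
#' @param primary,null [kin_hypothesis()] objects.
#' @param freqs An [allele_freq_block()].
#' @param n_null Null-simulation size (>= 1000 recommended).
#' @param alpha Significance level.
#' @param seed RNG seed (used only when `null_dist` is not supplied).
#' @param null_dist Optional precomputed [null_lambda_distribution()].
#' @return List with `lambda`, `p_value`, `significant`, `logl_primary`,
#'   `logl_null`.
#' @export
classify_dyad <- function(gx, gy, primary, null, freqs,
                          n_null = 10000L, alpha = 0.05, seed = 1L,
                          null_dist = NULL) {
  lp <- dyad_log_likelihood(gx, gy, primary, freqs)
  ln <- dyad_log_likelihood(gx, gy, null, freqs)
  if (!is.finite(lp)) {
    return(list(lambda = -Inf, p_value = 1, significant = FALSE,
                logl_primary = lp, logl_null = ln))
  }
  lambda <- lp - ln
  if (is.null(null_dist))
    null_dist <- null_lambda_distribution(primary, null, freqs,
                                          n = n_null, seed = seed)
  p <- (1 + sum(null_dist >= lambda)) / (1 + length(null_dist))
  list(lambda = lambda, p_value = p, significant = p <= alpha,
       logl_primary = lp, logl_null = ln)
}
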