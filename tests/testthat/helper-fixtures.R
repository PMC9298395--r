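# shared fixture builders and independent oracles

uniform_block <- function(n_loci = 10, n_alleles = 10) {
  allele_freq_block(stats::setNames(
    lapply(seq_len(n_loci), function(i)
      stats::setNames(rep(1 / n_alleles, n_alleles),
                      as.character(seq_len(n_alleles)))),
    sprintf("L%02d", seq_len(n_loci))))
}

random_block <- function(n_loci = 2, n_alleles = 3, seed = 1) {
  set.seed(seed)
  allele_freq_block(stats::setNames(
    lapply(seq_len(n_loci), function(i) {
      x <- stats::rgamma(n_alleles, 2) + 0.05
      stats::setNames(x / sum(x), as.character(seq_len(n_alleles)))
    }),
    sprintf("L%02d", seq_len(n_loci))))
}

# random genotype matrix (loci x 2) under HWE at `freqs`
random_genotype <- function(freqs) {
  g <- t(vapply(freqs, function(p)
    sample(as.numeric(names(p)), 2, TRUE, p), numeric(2)))
  rownames(g) <- names(freqs)
  g
}

# draw a founder genotype as a flat vector (2 values per locus)
founder_vec <- function(freqs) {
  unlist(lapply(freqs, function(p)
    sample(as.numeric(names(p)), 2, TRUE, p)))
}

# Mendelian offspring of two flat genotype vectors
mendel_vec <- function(m, f) {
  L <- length(m) / 2
  o <- numeric(2 * L)
  for (j in seq_len(L)) {
    o[2 * j - 1] <- m[2 * j - sample(0:1, 1)]
    o[2 * j] <- f[2 * j - sample(0:1, 1)]
  }
  o
}

# dataset of full-sib families (list of sizes) plus n_unrelated singletons
family_dataset <- function(freqs, fam_sizes, n_unrelated = 0, group = "G1",
                           seed = 1) {
  set.seed(seed)
  rows <- list(); fam_id <- integer()
  for (k in seq_along(fam_sizes)) {
    m <- founder_vec(freqs); f <- founder_vec(freqs)
    for (i in seq_len(fam_sizes[k])) {
      rows[[length(rows) + 1L]] <- mendel_vec(m, f)
      fam_id <- c(fam_id, k)
    }
  }
  for (i in seq_len(n_unrelated)) {
    rows[[length(rows) + 1L]] <- founder_vec(freqs)
    fam_id <- c(fam_id, NA)
  }
  calls <- do.call(rbind, rows)
  loci <- names(freqs)
  colnames(calls) <- as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2")))
  meta <- data.frame(id = sprintf("i%03d", seq_len(nrow(calls))),
                     group = group, stringsAsFactors = FALSE)
  list(dataset = genotype_dataset(calls, meta), family = fam_id)
}

# --- independent oracles -------------------------------------------------

# Queller-Goodnight estimator coded directly from the per-locus definition,
# looping over reference directions explicitly (kept independent of the
# package's vectorised path)
qg_oracle <- function(gx, gy, freqs) {
  num <- 0; den <- 0
  for (l in rownames(gx)) {
    x <- gx[l, ]; y <- gy[l, ]
    if (anyNA(x) || anyNA(y)) next
    p <- freqs[[l]]
    pv <- function(a) unname(p[as.character(a)])
    d <- function(a, b) as.numeric(a == b)
    num_xy <- 0.5 * (d(x[1], y[1]) + d(x[1], y[2]) +
                       d(x[2], y[1]) + d(x[2], y[2])) - pv(x[1]) - pv(x[2])
    num_yx <- 0.5 * (d(y[1], x[1]) + d(y[1], x[2]) +
                       d(y[2], x[1]) + d(y[2], x[2])) - pv(y[1]) - pv(y[2])
    den_x <- 1 + d(x[1], x[2]) - pv(x[1]) - pv(x[2])
    den_y <- 1 + d(y[1], y[2]) - pv(y[1]) - pv(y[2])
    num <- num + num_xy + num_yx
    den <- den + den_x + den_y
  }
  if (abs(den) < 1e-9) return(NaN)   # uninformative (degenerate) instance
  num / den
}

# dyad likelihood by brute-force enumeration: for each locus sum over IBD
# states and, within state 1, over which gx allele is shared and which
# allele completes gy (full enumeration over the allele set)
loglik_oracle <- function(gx, gy, k, freqs) {
  ll <- 0
  for (l in rownames(gx)) {
    x <- gx[l, ]; y <- gy[l, ]
    if (anyNA(x) || anyNA(y)) next
    p <- freqs[[l]]
    pv <- function(a) unname(p[as.character(a)])
    hwe <- function(g) if (g[1] == g[2]) pv(g[1])^2 else 2 * pv(g[1]) * pv(g[2])
    same_unordered <- function(a, b)
      (a[1] == b[1] && a[2] == b[2]) || (a[1] == b[2] && a[2] == b[1])
    # state 1: gy = unordered {z, w}, z a random allele of gx, w ~ p
    p1 <- 0
    for (zi in 1:2) for (w in names(p)) {
      cand <- c(x[zi], as.numeric(w))
      if (same_unordered(cand, y)) p1 <- p1 + 0.5 * unname(p[w])
    }
    p2 <- as.numeric(same_unordered(x, y))
    L <- hwe(x) * (k$k0 * hwe(y) + k$k1 * p1 + k$k2 * p2)
    ll <- ll + log(L)
  }
  ll
}

# fixed-step Simpson integration of 1/g(s) (quadrature oracle)
simpson_age <- function(sl, model, steps = 1e5) {
  f <- function(s) 1 / (model$alpha + model$beta * log(s))
  h <- (sl - model$s0) / steps
  s <- model$s0 + h * (0:steps)
  w <- c(1, rep(c(4, 2), length.out = steps - 1), 1)
  sum(w * f(s)) * h / 3
}
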