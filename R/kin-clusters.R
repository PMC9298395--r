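#' Partition a social group into kin clusters
#'
#' Greedy likelihood-ratio agglomeration: every member starts as a
#' singleton; the cluster pair with the highest mean pairwise full-sib
#' versus unrelated likelihood ratio (geometric mean, i.e. mean log-ratio,
#' robust to the ratio's heavy right tail) is merged while that mean
#' exceeds `merge_threshold` (ties broken by lexicographically smallest
#' member id). Afterwards each member of a multi-member cluster is
#' re-validated by [classify_dyad()] against a representative (the member
#' with the highest mean within-cluster ratio) under the PO, FS and HS
#' hypotheses; members significant under none are demoted to singletons —
#' an individual misplaced by the greedy step is thereby filtered out as a
#' non-relative.
#'
#' @param dataset A [genotype_dataset()] holding one social group's
#'   members (use [subset_individuals()]).
#' @param freqs An [allele_freq_block()].
#' @param merge_threshold Minimum mean FS-vs-U likelihood ratio to merge
#'   (default 1: merge only if full sibship is on average better supported
#'   than unrelatedness).
#' @param alpha Significance level for the demotion check.
#' @param n_null Null-simulation size shared across the demotion checks.
#' @param seed RNG seed for the null simulations.
#' @return A `kin_partition`: list with `assignment` (named integer vector
#'   id -> cluster) and `clusters` (list of id vectors).
#' @export
split_kin_groups <- function(dataset, freqs, merge_threshold = 1,
                             alpha = 0.05, n_null = 2000L, seed = 1L) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  ids <- dataset$meta$id
  n <- length(ids)
  if (n == 1L)
    return(structure(list(assignment = stats::setNames(1L, ids),
                          clusters = list(ids)), class = "kin_partition"))
  hyp <- lapply(c(PO = "PO", FS = "FS", HS = "HS", U = "U"), kin_hypothesis)
  ll <- pairwise_loglik(dataset, freqs, hyp[c("FS", "U")])
  # geometric-mean ratio: mean log-LR is robust to the estimator's heavy
  # right tail, which otherwise lets a few lucky cross-family dyads drive
  # arithmetic-mean merges
  LR <- ll$FS - ll$U                # n x n log-ratios, NA diagonal
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1L) break
    best <- NULL; best_val <- log(merge_threshold)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      m <- mean(LR[clusters[[i]], clusters[[j]]])
      tie_key <- min(ids[c(clusters[[i]], clusters[[j]])])
      if (m > best_val ||
          (!is.null(best) && m == best_val && tie_key < best$key)) {
        best <- list(i = i, j = j, key = tie_key); best_val <- m
      }
    }
    if (is.null(best)) break
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  # demotion pass: validate members against the cluster representative
  nulls <- lapply(c(PO = "PO", FS = "FS", HS = "HS"), function(h) {
    null_lambda_distribution(hyp[[h]], hyp$U, freqs, n = n_null,
                             seed = derive_seed(seed, match(h, c("PO", "FS", "HS"))))
  })
  demoted <- integer()
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    if (length(cl) < 2L) next
    mean_lr <- vapply(cl, function(i) mean(LR[i, setdiff(cl, i)]), numeric(1))
    rep_i <- cl[order(-mean_lr, ids[cl])][1]
    gr <- individual_genotype(dataset, rep_i)
    for (i in setdiff(cl, rep_i)) {
      gi <- individual_genotype(dataset, i)
      ok <- any(vapply(c("PO", "FS", "HS"), function(h) {
        classify_dyad(gr, gi, hyp[[h]], hyp$U, freqs, alpha = alpha,
                      null_dist = nulls[[h]])$significant
      }, logical(1)))
      if (!ok) demoted <- c(demoted, i)
    }
  }
  if (length(demoted)) {
    clusters <- lapply(clusters, setdiff, y = demoted)
    clusters <- c(clusters[lengths(clusters) > 0L], as.list(demoted))
  }
  assignment <- integer(n)
  for (k in seq_along(clusters)) assignment[clusters[[k]]] <- k
  structure(list(assignment = stats::setNames(assignment, ids),
                 clusters = lapply(clusters, function(cl) ids[sort(cl)])),
            class = "kin_partition")
}

#' @export
print.kin_partition <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("kin_partition: %d members in %d clusters (sizes %s)\n",
              length(x$assignment), length(x$clusters),
              paste(sort(sizes, decreasing = TRUE), collapse = ",")))
  invisible(x)
}

# all-pairs log-likelihood matrices for a set of hypotheses
pairwise_loglik <- function(dataset, freqs, hypotheses) {
  n <- n_individuals(dataset)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  L <- length(freqs)
  idx <- function(i, col) dataset$calls[i, paste0(names(freqs), col)]
  a1 <- matrix(idx(pr[, 1], "_1"), ncol = L)
  b1 <- matrix(idx(pr[, 1], "_2"), ncol = L)
  a2 <- matrix(idx(pr[, 2], "_1"), ncol = L)
  b2 <- matrix(idx(pr[, 2], "_2"), ncol = L)
  out <- lapply(hypotheses, function(k) {
    v <- dyad_log_likelihood_batch_na(a1, b1, a2, b2, k, freqs)
    m <- matrix(NA_real_, n, n)
    m[pr] <- v; m[pr[, 2:1, drop = FALSE]] <- v
    m
  })
  out
}

# batch log-likelihood tolerating missing calls (locus skipped per dyad)
dyad_log_likelihood_batch_na <- function(a1, b1, a2, b2, k, freqs) {
  ll <- numeric(nrow(a1))
  loci <- names(freqs)
  for (j in seq_along(loci)) {
    ok <- !(is.na(a1[, j]) | is.na(a2[, j]))
    if (!any(ok)) next
    tm <- locus_likelihood_terms(a1[ok, j], b1[ok, j], a2[ok, j], b2[ok, j],
                                 freqs[[loci[j]]])
    ll[ok] <- ll[ok] +
      log(tm$Pgx * (k$k0 * tm$Pgy + k$k1 * tm$T1 + k$k2 * tm$T2))
  }
  ll
}

#' Dyad table with relatedness and per-hypothesis likelihoods
#'
#' Builds the pipeline's dyad records for all pairs (optionally only pairs
#' within the same social group): Queller-Goodnight `r`, loci used, log
#' likelihoods under PO/FS/HS/U, the best-supported label, and the
#' simulated p-value of the best non-null hypothesis against U.
#'
#' @param dataset A [genotype_dataset()].
#' @param freqs An [allele_freq_block()].
#' @param within_groups If TRUE (default), only same-group pairs.
#' @param alpha Significance level.
#' @param n_null Shared null-simulation size.
#' @param seed RNG seed.
#' @param qg_variant See [qg_relatedness()].
#' @return Data frame with columns `id1,id2,r,loci_used,logl_po,logl_fs,
#'   logl_hs,logl_u,best,p_value,significant`.
#' @export
dyad_table <- function(dataset, freqs, within_groups = TRUE,
                       alpha = 0.05, n_null = 2000L, seed = 1L,
                       qg_variant = "symmetric") {
  stopifnot(inherits(dataset, "genotype_dataset"))
  n <- n_individuals(dataset)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  if (within_groups) {
    grp <- dataset$meta$group
    keep <- !is.na(grp[pr[, 1]]) & grp[pr[, 1]] == grp[pr[, 2]]
    pr <- pr[keep, , drop = FALSE]
  }
  hyp <- lapply(c(PO = "PO", FS = "FS", HS = "HS", U = "U"), kin_hypothesis)
  L <- length(freqs)
  a1 <- matrix(dataset$calls[pr[, 1], paste0(names(freqs), "_1")], ncol = L)
  b1 <- matrix(dataset$calls[pr[, 1], paste0(names(freqs), "_2")], ncol = L)
  a2 <- matrix(dataset$calls[pr[, 2], paste0(names(freqs), "_1")], ncol = L)
  b2 <- matrix(dataset$calls[pr[, 2], paste0(names(freqs), "_2")], ncol = L)
  lls <- lapply(hyp, function(k)
    dyad_log_likelihood_batch_na(a1, b1, a2, b2, k, freqs))
  rmat <- relatedness_matrix(dataset, freqs, variant = qg_variant)
  loci_used <- rowSums(!(is.na(a1) | is.na(a2)))
  nulls <- lapply(c(PO = "PO", FS = "FS", HS = "HS"), function(h) {
    null_lambda_distribution(hyp[[h]], hyp$U, freqs, n = n_null,
                             seed = derive_seed(seed, match(h, c("PO", "FS", "HS"))))
  })
  labs <- c("PO", "FS", "HS", "U")
  llm <- cbind(lls$PO, lls$FS, lls$HS, lls$U)
  best <- labs[max.col(llm, ties.method = "last")]
  p <- rep(NA_real_, nrow(pr)); sig <- rep(FALSE, nrow(pr))
  for (i in seq_len(nrow(pr))) {
    if (best[i] == "U") { p[i] <- 1; next }
    lam <- llm[i, match(best[i], labs)] - lls$U[i]
    nd <- nulls[[best[i]]]
    p[i] <- (1 + sum(nd >= lam)) / (1 + length(nd))
    sig[i] <- p[i] <= alpha
  }
  data.frame(id1 = dataset$meta$id[pr[, 1]], id2 = dataset$meta$id[pr[, 2]],
             r = rmat[pr], loci_used = loci_used,
             logl_po = lls$PO, logl_fs = lls$FS, logl_hs = lls$HS,
             logl_u = lls$U, best = best, p_value = p, significant = sig,
             stringsAsFactors = FALSE)
}
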