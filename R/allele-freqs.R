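#' Allele frequency block
#'
#' Per-locus allele frequency vectors used as the reference distribution for
#' every relatedness estimate and likelihood in the pipeline. Construct via
#' [estimate_allele_frequencies()], [read_allele_frequencies()], or directly
#' from a named list.
#'
#' @param freqs Named list; one numeric vector per locus, names = allele
#'   labels, summing to 1.
#' @param provenance `"naive"`, `"corrected"` or `"external"`.
#' @return An `allele_freq_block`.
#' @export
allele_freq_block <- function(freqs, provenance = "external") {
  stopifnot(is.list(freqs), length(freqs) >= 1)
  for (l in names(freqs)) {
    p <- freqs[[l]]
    if (is.null(names(p)) || any(p <= 0) ||
        abs(sum(p) - 1) > 1e-9)
      stop("locus ", l, ": frequencies must be named, positive, sum to 1",
           call. = FALSE)
  }
  structure(freqs, class = "allele_freq_block", provenance = provenance)
}

#' @export
print.allele_freq_block <- function(x, ...) {
  cat(sprintf("allele_freq_block (%s): %d loci, %s alleles/locus\n",
              attr(x, "provenance"), length(x),
              paste(range(lengths(x)), collapse = "-")))
  invisible(x)
}

# p[allele] lookup with hard error on alleles unknown to the block
freq_lookup <- function(p, alleles) {
  out <- p[match(as.character(alleles), names(p))]
  if (anyNA(out) && !all(is.na(alleles))) {
    bad <- is.na(out) & !is.na(alleles)
    if (any(bad))
      stop("allele(s) absent from frequency block: ",
           paste(unique(alleles[bad]), collapse = ", "), call. = FALSE)
  }
  unname(out)
}

#' Estimate allele frequencies from a genotype dataset
#'
#' `method = "naive"` counts alleles over non-missing calls. `method =
#' "corrected"` applies the relatedness correction: individuals are
#' iteratively down-weighted by `1/(1 + mean pairwise r to all others)` and
#' frequencies re-estimated until the largest frequency change falls below
#' `tol` (or `max_iter` passes). With many relatives in the sample, naive
#' counting over-represents family alleles; the reweighting shrinks that
#' bias toward the founder frequencies.
#'
#' Frequencies are floored at `1/(2N + 1)` (N = individuals used) and
#' renormalized, so no likelihood ever hits log(0) on a rare allele.
#'
#' @param dataset A [genotype_dataset()].
#' @param method `"naive"` or `"corrected"`.
#' @param population Optional population id to subset on.
#' @param floor Apply the rare-allele floor (default TRUE).
#' @param tol,max_iter Convergence controls for the corrected method.
#' @return An `allele_freq_block` with matching provenance.
#' @export
estimate_allele_frequencies <- function(dataset,
                                        method = c("naive", "corrected"),
                                        population = NULL,
                                        floor = TRUE,
                                        tol = 1e-6, max_iter = 20L) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (!is.null(population)) {
    keep <- !is.na(dataset$meta$population) &
      dataset$meta$population == population
    if (!any(keep)) stop("no individuals in population ", population,
                         call. = FALSE)
    dataset <- subset_individuals(dataset, keep)
  }
  n <- n_individuals(dataset)
  w <- rep(1, n)
  est <- function(w) {
    out <- vector("list", length(dataset$loci))
    names(out) <- dataset$loci
    for (l in dataset$loci) {
      g <- dataset$calls[, paste0(l, c("_1", "_2")), drop = FALSE]
      ok <- !is.na(g[, 1])
      if (!any(ok))
        stop("locus ", l, " has zero non-missing calls", call. = FALSE)
      lab <- as.character(c(g[ok, 1], g[ok, 2]))
      ww <- rep(w[ok], 2L)
      tab <- tapply(ww, lab, sum)
      p <- stats::setNames(as.numeric(tab), names(tab))
      p <- p / sum(p)
      out[[l]] <- p[order(as.numeric(names(p)))]
    }
    out
  }
  p_cur <- est(w)
  if (method == "corrected") {
    for (it in seq_len(max_iter)) {
      blk <- allele_freq_block(lapply(p_cur, floor_freqs, n = n),
                               provenance = "corrected")
      rmat <- relatedness_matrix(dataset, blk)
      mean_r <- rowMeans(rmat, na.rm = TRUE)
      mean_r[is.nan(mean_r)] <- 0
      w_new <- 1 / (1 + pmax(mean_r, -0.9))
      p_new <- est(w_new)
      delta <- max(mapply(function(a, b) max(abs(a - b)), p_new, p_cur))
      p_cur <- p_new
      if (delta < tol) break
    }
  }
  if (floor) p_cur <- lapply(p_cur, floor_freqs, n = n)
  allele_freq_block(p_cur, provenance = method)
}

# raise frequencies below 1/(2N+1) to the floor, renormalize
floor_freqs <- function(p, n) {
  pmin_val <- 1 / (2 * n + 1)
  p <- pmax(p, pmin_val)
  p / sum(p)
}

#' Read / write an allele-frequency block as CSV
#'
#' CSV columns: `locus,allele,freq`.
#'
#' @param path File path.
#' @return [read_allele_frequencies()]: an `allele_freq_block` (provenance
#'   `"external"`); [write_allele_frequencies()]: `path`, invisibly.
#' @export
read_allele_frequencies <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("locus", "allele", "freq") %in% colnames(df)))
  freqs <- lapply(split(df, df$locus), function(d) {
    stats::setNames(d$freq, as.character(d$allele))
  })
  allele_freq_block(freqs[unique(df$locus)], provenance = "external")
}

#' @param x An `allele_freq_block`.
#' @rdname read_allele_frequencies
#' @export
write_allele_frequencies <- function(x, path) {
  stopifnot(inherits(x, "allele_freq_block"))
  df <- do.call(rbind, lapply(names(x), function(l) {
    data.frame(locus = l, allele = names(x[[l]]), freq = unname(x[[l]]),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
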