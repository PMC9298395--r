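#' Pairwise parentage assignment under Mendelian and age constraints
#'
#' Every adult (size at or above the sex-specific maturity size) is tested
#' as a candidate parent of every smaller member of the same group. A
#' candidate mismatches at a locus when the two genotypes share no allele;
#' a candidate is age-feasible when its back-calculated size at the
#' potential offspring's estimated birth day — via the growth model — is at
#' least `min_parent_size_at_spawning` (default 31.0 mm, the size a fish
#' reaches roughly 210 days ahead of a newborn). An assignment is accepted
#' when `mismatch_count <= max_mismatch` and age-feasible; per offspring at
#' most one father and one mother are accepted (fewest mismatches, then
#' highest PO-vs-U likelihood ratio; an exact tie leaves both reported but
#' none accepted, with a warning). Mothers and fathers are assigned
#' pairwise and independently — joint consistency is not enforced.
#'
#' @param dataset A [genotype_dataset()] (statuses/sexes/sizes in `meta`).
#' @param freqs An [allele_freq_block()].
#' @param max_mismatch Maximum tolerated mismatching loci (default 1).
#' @param growth A [growth_model()] for back-calculating sizes.
#' @param min_parent_size_at_spawning Minimum parental size (mm) at the
#'   offspring's birth day.
#' @param maturity_sizes Named vector `c(male=, female=)`, mm; candidates
#'   below it (today) are not considered adults.
#' @return Data frame of class `parentage` with columns
#'   `offspring,parent,sex_role,mismatches,age_feasible,lr_po_u,accepted`.
#' @export
assign_parentage <- function(dataset, freqs, max_mismatch = 1L,
                             growth = growth_model(),
                             min_parent_size_at_spawning = 31,
                             maturity_sizes = c(male = 32.5, female = 31.5)) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(freqs, "allele_freq_block"))
  meta <- dataset$meta
  if (is.null(meta$sl_mm)) stop("parentage needs sl_mm metadata", call. = FALSE)
  age <- rep(NA_real_, nrow(meta))
  ok_sl <- !is.na(meta$sl_mm) & meta$sl_mm >= growth$s0 &
    meta$sl_mm < growth$s_inf
  age[ok_sl] <- age_from_size(meta$sl_mm[ok_sl], growth)
  # feasibility shortcut: parent >= s_min at spawning  <=>  age gap >= age(s_min)
  min_gap <- age_from_size(min_parent_size_at_spawning, growth)
  hyp_po <- kin_hypothesis("PO"); hyp_u <- kin_hypothesis("U")
  rows <- list()
  for (g in unique(stats::na.omit(meta$group))) {
    gi <- which(!is.na(meta$group) & meta$group == g)
    gi <- gi[order(meta$id[gi])]                 # candidate-order invariance
    for (ci in gi) {
      sex <- meta$sex[ci]
      if (is.na(sex) || !sex %in% c("M", "F")) next
      mat <- if (sex == "M") maturity_sizes[["male"]] else maturity_sizes[["female"]]
      if (is.na(meta$sl_mm[ci]) || meta$sl_mm[ci] < mat) next
      gc <- individual_genotype(dataset, ci)
      for (oi in gi) {
        if (oi == ci) next
        if (is.na(meta$sl_mm[oi]) || meta$sl_mm[oi] >= meta$sl_mm[ci]) next
        go <- individual_genotype(dataset, oi)
        mm <- count_mismatches(gc, go)
        feas <- !is.na(age[ci]) && !is.na(age[oi]) &&
          (age[ci] - age[oi]) >= min_gap
        lr <- tryCatch(
          dyad_log_likelihood(gc, go, hyp_po, freqs) -
            dyad_log_likelihood(gc, go, hyp_u, freqs),
          error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          offspring = meta$id[oi], parent = meta$id[ci],
          sex_role = if (sex == "M") "father" else "mother",
          mismatches = mm, age_feasible = feas, lr_po_u = lr,
          accepted = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(offspring = character(), parent = character(),
               sex_role = character(), mismatches = integer(),
               age_feasible = logical(), lr_po_u = numeric(),
               accepted = logical(), stringsAsFactors = FALSE)
  # acceptance: best candidate per offspring and role
  for (o in unique(out$offspring)) for (role in c("father", "mother")) {
    sel <- which(out$offspring == o & out$sex_role == role &
                   out$mismatches <= max_mismatch & out$age_feasible)
    if (!length(sel)) next
    sc <- out[sel, ]
    ord <- order(sc$mismatches, -ifelse(is.finite(sc$lr_po_u), sc$lr_po_u, -Inf))
    if (length(sel) > 1L) {
      t1 <- sc[ord[1], ]; t2 <- sc[ord[2], ]
      tied <- t1$mismatches == t2$mismatches &&
        isTRUE(abs(t1$lr_po_u - t2$lr_po_u) < 1e-9)
      if (tied) {
        warning("offspring ", o, ": equal-score ", role,
                " candidates; none accepted")
        next
      }
    }
    out$accepted[sel[ord[1]]] <- TRUE
  }
  class(out) <- c("parentage", class(out))
  out
}

# loci where two genotypes share no allele (missing loci skipped)
count_mismatches <- function(g1, g2) {
  ok <- !is.na(g1[, 1]) & !is.na(g2[, 1])
  if (!any(ok)) return(0L)
  share <- g1[ok, 1] == g2[ok, 1] | g1[ok, 1] == g2[ok, 2] |
    g1[ok, 2] == g2[ok, 1] | g1[ok, 2] == g2[ok, 2]
  sum(!share)
}
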