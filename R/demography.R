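#' Immigrant classification within a social group
#'
#' An individual with at least one significant *ancestral or lateral* kin
#' link inside its group — an accepted parent, or co-membership in a kin
#' cluster with someone other than its own accepted offspring — is a
#' `non-immigrant`. Own descendants are not evidence of philopatry: an
#' immigrant breeder that has reproduced still arrived from outside. Otherwise its genotype is unique within the group:
#' it is an `immigrant` when the group holds both an older and a younger
#' kin group to compare against (a cluster of >= 2 members whose oldest
#' member is older than the focal, and one whose youngest member is
#' younger), and a `possible immigrant` when it does not — rapid breeder
#' turnover may then have obscured philopatry. Singletons do not count as
#' kin groups. A missing focal age conservatively yields
#' `possible immigrant` with a warning.
#'
#' @param id Focal individual id.
#' @param partition A `kin_partition` for the group (see
#'   [split_kin_groups()]).
#' @param parentage A [assign_parentage()] table (accepted rows used).
#' @param ages Named numeric vector id -> age (days) covering the group.
#' @param kin_links Optional data frame `id1,id2,best,significant` of
#'   within-group dyad classifications (from [dyad_table()]); when given,
#'   lateral kin means a significant FS/HS partner, which separates true
#'   siblings from own descendants more sharply than cluster co-membership
#'   (the fallback when `NULL`).
#' @return One of `"non-immigrant"`, `"possible immigrant"`, `"immigrant"`.
#' @export
classify_immigrant <- function(id, partition, parentage, ages,
                               kin_links = NULL) {
  stopifnot(inherits(partition, "kin_partition"))
  members <- names(partition$assignment)
  if (!id %in% members) stop("id not in partition: ", id, call. = FALSE)
  acc <- parentage[parentage$accepted, , drop = FALSE]
  has_parent <- any(acc$offspring == id & acc$parent %in% members)
  # plausible descendants: Mendel-compatible, age-feasible candidate rows
  # with the focal as parent (acceptance may have failed on a tie, but the
  # member is still no evidence of the focal's own philopatry)
  own_offspring <- parentage$offspring[parentage$parent == id &
                                         parentage$age_feasible &
                                         parentage$mismatches <= 1]
  cl_id <- partition$assignment[[id]]
  lateral <- names(partition$assignment)[partition$assignment == cl_id]
  lateral_kin <- setdiff(lateral, c(id, own_offspring))
  if (!is.null(kin_links) && length(lateral_kin)) {
    # the partition chains mates together through their shared offspring,
    # so demand direct genetic evidence: the focal-partner dyad itself must
    # be significant; partners best-labelled parent-offspring and younger
    # than the focal are presumed descendants, not siblings (older PO
    # partners are presumed parents and do attest philopatry)
    lk <- kin_links[kin_links$id1 == id | kin_links$id2 == id, , drop = FALSE]
    lk$partner <- ifelse(lk$id1 == id, lk$id2, lk$id1)
    direct <- lk$partner[lk$significant &
                           !(lk$best == "PO" &
                               !is.na(ages[lk$partner]) & !is.na(ages[id]) &
                               ages[lk$partner] < ages[id])]
    lateral_kin <- intersect(lateral_kin, direct)
  }
  if (has_parent || length(lateral_kin)) return("non-immigrant")
  if (is.na(ages[id])) {
    warning("no age for ", id, "; classified possible immigrant")
    return("possible immigrant")
  }
  kin_groups <- Filter(function(cl) length(cl) >= 2L && !id %in% cl,
                       partition$clusters)
  if (length(kin_groups)) {
    older <- any(vapply(kin_groups,
                        function(cl) max(ages[cl], na.rm = TRUE) > ages[id],
                        logical(1)))
    younger <- any(vapply(kin_groups,
                          function(cl) min(ages[cl], na.rm = TRUE) < ages[id],
                          logical(1)))
    if (older && younger) return("immigrant")
  }
  "possible immigrant"
}

#' Detect breeding-territory inheritance
#'
#' A breeder is flagged as having inherited its position when its group
#' still contains either its accepted other-sex parent, or a significant
#' full- or half-sib partner of similar age (absolute estimated age
#' difference at most `similar_age_window` days). Matrilineal inheritance
#' (MLI) for breeder females, patrilineal (PLI) for breeder males; either
#' way a minimum estimate, since dead or departed relatives make
#' inheritance undetectable.
#'
#' @param id Breeder id.
#' @param meta Metadata data frame of the breeder's group.
#' @param parentage Parentage table (accepted rows used).
#' @param kin_links Data frame `id1,id2,best,significant` of within-group
#'   dyad classifications (e.g. from [dyad_table()]).
#' @param ages Named numeric vector id -> age (days).
#' @param similar_age_window Days (default 90).
#' @return List with `inherited` (flag) and `label` (`"MLI"`, `"PLI"` or
#'   `NA`).
#' @export
detect_inheritance <- function(id, meta, parentage, kin_links, ages,
                               similar_age_window = 90) {
  row <- meta[meta$id == id, , drop = FALSE]
  if (!nrow(row) || !row$status %in% c("breeder male", "breeder female"))
    stop("detect_inheritance applies to breeders only: ", id, call. = FALSE)
  label <- if (row$status == "breeder female") "MLI" else "PLI"
  other_sex <- if (row$status == "breeder female") "M" else "F"
  acc <- parentage[parentage$accepted, , drop = FALSE]
  parents <- acc$parent[acc$offspring == id]
  parent_here <- any(parents %in% meta$id &
                       meta$sex[match(parents, meta$id)] == other_sex,
                     na.rm = TRUE)
  sibs <- kin_links[kin_links$significant & kin_links$best %in% c("FS", "HS") &
                      (kin_links$id1 == id | kin_links$id2 == id), ,
                    drop = FALSE]
  partner <- unique(ifelse(sibs$id1 == id, sibs$id2, sibs$id1))
  sib_similar <- FALSE
  if (length(partner) && !is.na(ages[id])) {
    dif <- abs(ages[partner] - ages[id])
    sib_similar <- any(!is.na(dif) & dif <= similar_age_window)
  }
  inherited <- parent_here || sib_similar
  list(inherited = inherited, label = if (inherited) label else NA_character_)
}

#' Breeder tenure from group-member ages
#'
#' Minimum tenure = estimated age of the oldest group member the breeder
#' produced (zero if none); maximum = age of the next older non-immigrant
#' group member *not* produced by the breeder. Tenure is the mean of the
#' two bounds; with no qualifying older non-immigrant the estimate is
#' censored (open-ended) at the minimum.
#'
#' @param id Breeder id.
#' @param meta Metadata data frame of the breeder's group.
#' @param parentage Parentage table (accepted rows used).
#' @param immigrant_class Named character vector id -> class for the group.
#' @param ages Named numeric vector id -> age (days).
#' @return List `t_min`, `t_max` (NA if censored), `tenure`, `censored`.
#' @export
estimate_tenure <- function(id, meta, parentage, immigrant_class, ages) {
  acc <- parentage[parentage$accepted, , drop = FALSE]
  own <- unique(acc$offspring[acc$parent == id])
  own <- intersect(own, meta$id)
  t_min <- if (length(own)) max(ages[own], na.rm = TRUE) else 0
  others <- setdiff(meta$id, c(id, own))
  cand <- others[immigrant_class[others] == "non-immigrant" &
                   !is.na(ages[others]) & ages[others] > t_min]
  if (length(cand)) {
    t_max <- min(ages[cand])
    list(t_min = t_min, t_max = t_max, tenure = mean(c(t_min, t_max)),
         censored = FALSE)
  } else {
    list(t_min = t_min, t_max = NA_real_, tenure = t_min, censored = TRUE)
  }
}

#' Per-group demographic reconstruction
#'
#' Runs the full within-group reconstruction for every social group: ages
#' from the growth model, kin-cluster partition, immigrant classification,
#' inheritance detection for breeders, and tenure estimation. This is the
#' threefold use of the kinship reconstruction - inheritance, tenure,
#' immigration - assembled into one report.
#'
#' @param dataset A [genotype_dataset()].
#' @param freqs An [allele_freq_block()].
#' @param growth A [growth_model()].
#' @param parentage Optional precomputed [assign_parentage()] table;
#'   computed if `NULL`.
#' @param alpha,n_null,seed Classification controls (see
#'   [classify_dyad()]).
#' @param merge_threshold Passed to [split_kin_groups()].
#' @param similar_age_window Days, for [detect_inheritance()].
#' @return Data frame, one row per group member:
#'   `id,group,subgroup,status,sex,sl_mm,age_days,kin_cluster,
#'   immigrant_class,inherited,inheritance_label,tenure_min,tenure_max,
#'   tenure_mean,censored`.
#' @export
demography_report <- function(dataset, freqs, growth = growth_model(),
                              parentage = NULL, alpha = 0.05,
                              n_null = 2000L, seed = 1L,
                              merge_threshold = 1,
                              similar_age_window = 90) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  meta <- dataset$meta
  ages <- rep(NA_real_, nrow(meta))
  ok <- !is.na(meta$sl_mm) & meta$sl_mm >= growth$s0 & meta$sl_mm < growth$s_inf
  ages[ok] <- age_from_size(meta$sl_mm[ok], growth)
  names(ages) <- meta$id
  if (is.null(parentage))
    parentage <- assign_parentage(dataset, freqs, growth = growth)
  out <- list()
  groups <- unique(stats::na.omit(meta$group))
  for (gn in seq_along(groups)) {
    g <- groups[gn]
    sub <- subset_individuals(dataset, !is.na(meta$group) & meta$group == g)
    part <- split_kin_groups(sub, freqs, merge_threshold = merge_threshold,
                             alpha = alpha, n_null = n_null,
                             seed = derive_seed(seed, gn))
    links <- dyad_table(sub, freqs, within_groups = FALSE, alpha = alpha,
                        n_null = n_null, seed = derive_seed(seed, gn))
    cls <- vapply(sub$meta$id, function(i)
      suppressWarnings(classify_immigrant(i, part, parentage, ages,
                                          kin_links = links)),
      character(1))
    df <- data.frame(
      id = sub$meta$id, group = g, subgroup = sub$meta$subgroup,
      status = sub$meta$status, sex = sub$meta$sex, sl_mm = sub$meta$sl_mm,
      age_days = unname(ages[sub$meta$id]),
      kin_cluster = paste0(g, ".", unname(part$assignment[sub$meta$id])),
      immigrant_class = unname(cls),
      inherited = NA, inheritance_label = NA_character_,
      tenure_min = NA_real_, tenure_max = NA_real_, tenure_mean = NA_real_,
      censored = NA, stringsAsFactors = FALSE)
    br <- which(df$status %in% c("breeder male", "breeder female"))
    for (i in br) {
      inh <- detect_inheritance(df$id[i], sub$meta, parentage, links, ages,
                                similar_age_window = similar_age_window)
      ten <- estimate_tenure(df$id[i], sub$meta, parentage, cls, ages)
      df$inherited[i] <- inh$inherited
      df$inheritance_label[i] <- inh$label
      df$tenure_min[i] <- ten$t_min
      df$tenure_max[i] <- ten$t_max
      df$tenure_mean[i] <- ten$tenure
      df$censored[i] <- ten$censored
    }
    out[[length(out) + 1L]] <- df
  }
  do.call(rbind, out)
}
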