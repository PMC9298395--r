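#' Immigration and reproductive-skew summary tables
#'
#' Builds the two study-style summary tables from a demographic report and
#' a parentage table: an immigration table (counts of non-immigrants,
#' possible immigrants and assured immigrants per status and sex) and a
#' reproductive-skew table (per status and sex: number of producers,
#' offspring produced inside the focal's own subgroup vs. other subgroups
#' of the same group, and the eligible-member denominators under the
#' minimum age-gap rule).
#'
#' @param demog A [demography_report()] data frame.
#' @param parentage An [assign_parentage()] table.
#' @param min_age_gap Minimum producer-offspring age difference, days
#'   (default 210; equivalent to the producer being ~31 mm at spawning).
#' @param mature_sizes Named vector `c(male=, female=)`, mm: non-breeder
#'   focals below it are excluded from the skew table (default 43.5/38.5).
#' @return List with data frames `immigration` (columns `status_sex,
#'   non_immigrant, possible_immigrant, immigrant, pct_immigrant`) and
#'   `skew` (columns `status_sex, producers, produced_subgroup,
#'   produced_other, members_subgroup, members_other`).
#' @export
summarize_structure <- function(demog, parentage, min_age_gap = 210,
                                mature_sizes = c(male = 43.5, female = 38.5)) {
  list(immigration = immigration_table(demog),
       skew = skew_table(demog, parentage, min_age_gap = min_age_gap,
                         mature_sizes = mature_sizes))
}

status_sex_label <- function(status, sex) {
  sx <- ifelse(is.na(sex) | !sex %in% c("M", "F"), "unknown",
               ifelse(sex == "M", "male", "female"))
  ifelse(status %in% c("breeder male", "breeder female"), status,
         paste(status, sx))
}

immigration_table <- function(demog) {
  lab <- status_sex_label(demog$status, demog$sex)
  keep <- demog$status != "offspring"
  tab <- table(lab[keep],
               factor(demog$immigrant_class[keep],
                      c("non-immigrant", "possible immigrant", "immigrant")))
  out <- data.frame(status_sex = rownames(tab),
                    non_immigrant = as.integer(tab[, 1]),
                    possible_immigrant = as.integer(tab[, 2]),
                    immigrant = as.integer(tab[, 3]),
                    stringsAsFactors = FALSE)
  tot <- rowSums(out[, 2:4])
  out$pct_immigrant <- round(100 * out$immigrant / tot, 1)
  out
}

#' Shares derived from an immigration-count table
#'
#' Percentage of group members (independents excluded) that are assured
#' immigrants, and that carry a unique genotype (possible + assured).
#'
#' @param tbl Data frame with columns `status_sex, non_immigrant,
#'   possible_immigrant, immigrant` (e.g. from [summarize_structure()] or
#'   a printed-count CSV).
#' @return List `pct_immigrant`, `pct_unique` (percent, 1 decimal scale).
#' @export
immigration_shares <- function(tbl) {
  keep <- !grepl("^independent", tbl$status_sex) &
    !grepl("^Total", tbl$status_sex, ignore.case = TRUE)
  tot <- sum(tbl$non_immigrant[keep] + tbl$possible_immigrant[keep] +
               tbl$immigrant[keep])
  list(pct_immigrant = 100 * sum(tbl$immigrant[keep]) / tot,
       pct_unique = 100 * sum(tbl$possible_immigrant[keep] +
                                tbl$immigrant[keep]) / tot)
}

skew_table <- function(demog, parentage, min_age_gap = 210,
                       mature_sizes = c(male = 43.5, female = 38.5)) {
  acc <- parentage[parentage$accepted, , drop = FALSE]
  demog$status_sex <- status_sex_label(demog$status, demog$sex)
  rows_for <- c("breeder male", "breeder female", "helper male",
                "helper female", "independent male", "independent female")
  idx <- stats::setNames(seq_len(nrow(demog)), demog$id)
  out <- lapply(rows_for, function(lab) {
    f <- demog$status_sex == lab
    if (!grepl("^breeder", lab)) {
      thr <- if (grepl("male$", lab) && !grepl("female$", lab))
        mature_sizes[["male"]] else mature_sizes[["female"]]
      f <- f & !is.na(demog$sl_mm) & demog$sl_mm >= thr
    }
    focals <- demog$id[f]
    ps <- po <- ms <- mo <- 0L
    producers <- 0L
    for (id in focals) {
      i <- idx[[id]]
      own <- acc$offspring[acc$parent == id]
      own <- own[own %in% names(idx)]
      j <- idx[own]
      same_sg <- !is.na(demog$subgroup[j]) &
        demog$subgroup[j] == demog$subgroup[i]
      ps <- ps + sum(same_sg); po <- po + sum(!same_sg)
      if (length(own)) producers <- producers + 1L
      grp <- demog$group == demog$group[i] & demog$id != id
      gap_ok <- grp & !is.na(demog$age_days) & !is.na(demog$age_days[i]) &
        (demog$age_days[i] - demog$age_days) >= min_age_gap
      in_sg <- !is.na(demog$subgroup) &
        demog$subgroup == demog$subgroup[i]
      ms <- ms + sum(gap_ok & in_sg)
      mo <- mo + sum(gap_ok & !in_sg)
    }
    data.frame(status_sex = lab, producers = producers,
               produced_subgroup = ps, produced_other = po,
               members_subgroup = ms, members_other = mo,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Shares derived from a reproductive-skew table
#'
#' Helper-male share of detected paternities and helper-female share of
#' detected maternities (percent).
#'
#' @param tbl Data frame with columns `status_sex, produced_subgroup,
#'   produced_other`.
#' @return List `pct_helper_paternity`, `pct_helper_maternity`,
#'   `n_paternities`, `n_maternities`.
#' @export
parentage_shares <- function(tbl) {
  prod <- tbl$produced_subgroup + tbl$produced_other
  male <- grepl(" male$|^breeder male$", tbl$status_sex)
  female <- grepl(" female$|^breeder female$", tbl$status_sex)
  n_pat <- sum(prod[male]); n_mat <- sum(prod[female])
  list(pct_helper_paternity =
         100 * sum(prod[tbl$status_sex == "helper male"]) / n_pat,
       pct_helper_maternity =
         100 * sum(prod[tbl$status_sex == "helper female"]) / n_mat,
       n_paternities = n_pat, n_maternities = n_mat)
}

#' Own-subgroup vs other-subgroup 2x2 table for one status row
#'
#' Builds the `[[produced_own, not_produced_own], [produced_other,
#' not_produced_other]]` table used in the chi-square comparisons of
#' reproductive skew.
#'
#' @param tbl A skew table (see [summarize_structure()]).
#' @param status_sex Row label, e.g. `"breeder male"`.
#' @return 2x2 integer matrix.
#' @export
skew_2x2 <- function(tbl, status_sex) {
  r <- tbl[tbl$status_sex == status_sex, , drop = FALSE]
  if (!nrow(r)) stop("no row ", status_sex, call. = FALSE)
  matrix(c(r$produced_subgroup, r$members_subgroup - r$produced_subgroup,
           r$produced_other, r$members_other - r$produced_other),
         2, 2, byrow = TRUE,
         dimnames = list(c("own subgroup", "other subgroup"),
                         c("produced", "not produced")))
}
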