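#' Configuration for the social-group simulator
#'
#' Defaults describe the stated world the simulator emulates: 30-45
#' polygynous groups of 1-4 female subgroups with up to 15 helpers each,
#' 10-13 microsatellite loci, roughly 17% of recruits arriving as outside
#' immigrants, reproductive skew toward the dominant pair, and breeder
#' turnover on a ~190-260 day median tenure scale.
#'
#' @param n_groups Number of polygynous groups (default 40).
#' @param subgroups_per_group Integer range `c(min, max)` (default 1-4).
#' @param helpers_per_subgroup Integer range (default 0-15).
#' @param n_loci Number of microsatellite loci (default 10).
#' @param alleles_per_locus Integer range (default 12-24: the study's
#'   markers carried a long rare-allele tail, with ~20% of alleles private
#'   to a single group).
#' @param founder_freq_concentration Dirichlet concentration for founder
#'   allele frequencies (default 1 = uniform simplex).
#' @param sim_days Simulated span, days (default 720).
#' @param breeding_interval Days between broods / hazard steps (default 60).
#' @param male_tenure_median,female_tenure_median Median breeder tenures,
#'   days (defaults 257.5 and 191.5, the field estimates).
#' @param p_inherit_male,p_inherit_female Probability a vacated breeder
#'   slot is filled from within the group (defaults 11/33 and 31/60, the
#'   observed inheritance fractions).
#' @param p_helper_immigrant Per-recruitment probability a new helper is an
#'   outside immigrant (default 0.17, calibrated to the observed standing
#'   fraction; the field study reports no per-event rate).
#' @param p_helper_paternity,p_helper_maternity Per-brood probability a
#'   mature helper sires/produces the brood (defaults 0.20 and 0.07,
#'   matching the detected helper shares of paternity/maternity).
#' @param genotyping_error_rate,missing_rate Error-injection defaults
#'   (both 0; see [inject_errors()]).
#' @param growth_params Numeric `c(alpha, beta, s0)` for the shared
#'   [growth_model()].
#' @param maturity_sizes Named `c(male=, female=)` mm at gonadal maturity
#'   (defaults 32.5 / 31.5, dissection benchmarks).
#' @param seed RNG seed; all stochastic draws flow from it.
#' @return A validated `simulation_config`.
#' @export
simulation_config <- function(n_groups = 40L,
                              subgroups_per_group = c(1L, 4L),
                              helpers_per_subgroup = c(0L, 15L),
                              n_loci = 10L,
                              alleles_per_locus = c(12L, 24L),
                              founder_freq_concentration = 1,
                              sim_days = 720,
                              breeding_interval = 60,
                              male_tenure_median = 257.5,
                              female_tenure_median = 191.5,
                              p_inherit_male = 11 / 33,
                              p_inherit_female = 31 / 60,
                              p_helper_immigrant = 0.17,
                              p_helper_paternity = 0.20,
                              p_helper_maternity = 0.07,
                              genotyping_error_rate = 0,
                              missing_rate = 0,
                              growth_params = c(alpha = 0.38, beta = -0.087,
                                                s0 = 6.5),
                              maturity_sizes = c(male = 32.5, female = 31.5),
                              seed = 1L) {
  cfg <- list(n_groups = as.integer(n_groups),
              subgroups_per_group = assert_range(subgroups_per_group,
                                                 "subgroups_per_group"),
              helpers_per_subgroup = assert_range(helpers_per_subgroup,
                                                  "helpers_per_subgroup"),
              n_loci = as.integer(n_loci),
              alleles_per_locus = assert_range(alleles_per_locus,
                                               "alleles_per_locus"),
              founder_freq_concentration = founder_freq_concentration,
              sim_days = sim_days, breeding_interval = breeding_interval,
              male_tenure_median = male_tenure_median,
              female_tenure_median = female_tenure_median,
              p_inherit_male = p_inherit_male,
              p_inherit_female = p_inherit_female,
              p_helper_immigrant = p_helper_immigrant,
              p_helper_paternity = p_helper_paternity,
              p_helper_maternity = p_helper_maternity,
              genotyping_error_rate = genotyping_error_rate,
              missing_rate = missing_rate,
              growth_params = growth_params,
              maturity_sizes = maturity_sizes,
              seed = as.integer(seed))
  for (p in c("p_inherit_male", "p_inherit_female", "p_helper_immigrant",
              "p_helper_paternity", "p_helper_maternity",
              "genotyping_error_rate", "missing_rate"))
    assert_prob(cfg[[p]], p)
  if (!(cfg$sim_days > cfg$breeding_interval && cfg$breeding_interval > 0))
    stop("need sim_days > breeding_interval > 0", call. = FALSE)
  if (cfg$n_groups < 1L || cfg$subgroups_per_group[1] < 1L)
    stop("expected group size is zero: need >= 1 group with >= 1 subgroup",
         call. = FALSE)
  if (cfg$founder_freq_concentration <= 0)
    stop("founder_freq_concentration must be > 0", call. = FALSE)
  gm <- growth_model(growth_params[[1]], growth_params[[2]], growth_params[[3]])
  if (any(maturity_sizes >= gm$s_inf))
    stop(sprintf("maturity size exceeds asymptotic size (%.1f mm)", gm$s_inf),
         call. = FALSE)
  cfg$growth <- gm
  structure(cfg, class = "simulation_config")
}

#' Forward-simulate a polygynous cooperative population
#'
#' Each group starts with a founding breeder male and one breeder female
#' per subgroup (genotypes drawn in HWE from Dirichlet founder
#' frequencies). Time advances on the breeding-interval grid: breeders end
#' tenure with a geometric per-interval hazard calibrated so the median
#' tenure matches the configured medians; a vacated slot is filled from
#' within (largest mature same-sex member, an inheritance event) with the
#' configured probability, else by a new immigrant. Each subgroup draws a
#' target helper count and its recruits are spread over brood dates: each
#' recruit is an outside immigrant with `p_helper_immigrant`, otherwise a
#' natal brood member with Mendelian genotype from the current breeders
#' (with per-brood helper paternity/maternity at the configured rates).
#' Sizes follow the shared growth model deterministically from age; the
#' emitted dataset is the snapshot at `sim_days` (members below 15 mm are
#' `offspring`, a small fraction of mature helpers are relabelled
#' `independent`). Genotyping error and missingness, if configured, are
#' applied by [inject_errors()] after the truth tables are frozen.
#'
#' @param config A [simulation_config()].
#' @return List with `dataset` (a [genotype_dataset()]), `truth` (class
#'   `truth_tables`: `pedigree`, `immigrants`, `tenure`, `inheritance`,
#'   `group_history` data frames), and `founder_freqs` (an
#'   [allele_freq_block()]).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  gm <- config$growth
  age_cap <- age_from_size(gm$s_inf - 0.5, gm)
  sl_of <- function(age) size_at_age(pmin(age, age_cap), gm)
  mat_m <- config$maturity_sizes[["male"]]
  mat_f <- config$maturity_sizes[["female"]]
  # founder allele frequencies: Dirichlet per locus
  loci <- sprintf("L%02d", seq_len(config$n_loci))
  freqs <- lapply(loci, function(l) {
    K <- sample(seq(config$alleles_per_locus[1], config$alleles_per_locus[2]), 1)
    x <- stats::rgamma(K, config$founder_freq_concentration)
    stats::setNames(x / sum(x), as.character(seq_len(K)))
  })
  names(freqs) <- loci
  fblock <- allele_freq_block(freqs, provenance = "external")

  ind <- new.env(parent = emptyenv())   # id -> individual record (hashed)
  geno <- new.env(parent = emptyenv())  # id -> numeric vector length 2*n_loci
  memb <- vector("list", config$n_groups)  # per-group present-member ids
  all_ids <- character(0)
  hist <- list()       # group history events
  n_id <- 0L
  hwe_draw <- function() {
    unlist(lapply(freqs, function(p)
      sample(as.numeric(names(p)), 2, TRUE, p)))
  }
  mendel <- function(gm_, gf_) {
    L <- length(loci)
    out <- numeric(2 * L)
    pick <- function(pair) pair[sample.int(2, 1)]
    for (j in seq_len(L)) {
      out[2 * j - 1] <- pick(gm_[c(2 * j - 1, 2 * j)])
      out[2 * j] <- pick(gf_[c(2 * j - 1, 2 * j)])
    }
    out
  }
  add_ind <- function(g, sg, sex, natal, day, age_at_entry, role,
                      mother = NA, father = NA, founder = FALSE,
                      origin = if (natal) "natal" else "immigrant_helper") {
    n_id <<- n_id + 1L
    id <- sprintf("G%02d_I%04d", g, n_id)
    geno[[id]] <- if (natal) mendel(geno[[mother]], geno[[father]])
    else hwe_draw()
    ind[[id]] <- list(id = id, group = g, subgroup = sg, sex = sex,
                      natal = natal, birth_day = if (natal) day else NA,
                      arrival_day = day, arrival_age = age_at_entry,
                      mother = mother, father = father, role = role,
                      founder = founder, origin = origin, present = TRUE,
                      tenure_start = if (role %in% c("bm", "bf")) day else NA,
                      tenure_end = NA, inherited = NA)
    memb[[g]] <<- c(memb[[g]], id)
    all_ids <<- c(all_ids, id)
    id
  }
  age_at <- function(id, day) {
    r <- ind[[id]]
    if (r$natal) day - r$birth_day else r$arrival_age + (day - r$arrival_day)
  }
  size_at <- function(id, day) sl_of(age_at(id, day))

  brood_days <- seq(config$breeding_interval, config$sim_days,
                    by = config$breeding_interval)
  p_end_m <- 1 - 2^(-config$breeding_interval / config$male_tenure_median)
  p_end_f <- 1 - 2^(-config$breeding_interval / config$female_tenure_median)
  tenure_rows <- list()
  close_tenure <- function(id, day, censored) {
    r <- ind[[id]]
    tenure_rows[[length(tenure_rows) + 1L]] <<- data.frame(
      id = id, sex = r$sex, start_day = r$tenure_start,
      end_day = if (censored) NA_real_ else day, censored = censored,
      inherited = r$inherited, stringsAsFactors = FALSE)
  }

  groups <- vector("list", config$n_groups)
  for (g in seq_len(config$n_groups)) {
    n_sub <- sample(seq(config$subgroups_per_group[1],
                        config$subgroups_per_group[2]), 1)
    sgs <- sprintf("G%02d.S%d", g, seq_len(n_sub))
    bm_sl <- stats::runif(1, mat_m + 12, min(gm$s_inf - 12, mat_m + 32))
    bm <- add_ind(g, sgs[1], "M", FALSE, 0, age_from_size(bm_sl, gm),
                  "bm", founder = TRUE, origin = "founder")
    ind[[bm]]$inherited <- FALSE
    bf <- character(n_sub)
    for (s in seq_len(n_sub)) {
      bf_sl <- stats::runif(1, mat_f + 7, mat_f + 19)
      bf[s] <- add_ind(g, sgs[s], "F", FALSE, 0,
                       age_from_size(bf_sl, gm), "bf", founder = TRUE,
                       origin = "founder")
      ind[[bf[s]]]$inherited <- FALSE
    }
    # recruitment schedule: target helpers per subgroup spread over broods
    sched <- lapply(seq_len(n_sub), function(s) {
      Tn <- sample(seq(config$helpers_per_subgroup[1],
                       config$helpers_per_subgroup[2]), 1)
      if (Tn == 0) return(integer(0))
      sort(sample(brood_days, Tn, replace = TRUE))
    })
    groups[[g]] <- list(g = g, sgs = sgs, bm = bm, bf = bf, sched = sched)
  }

  members_of <- function(g) memb[[g]]
  for (d in brood_days) {
    for (gr in groups) {
      g <- gr$g
      # --- breeder turnover; a slot may sit vacant until an heir matures ---
      fill_slot <- function(sex, p_inherit, sg) {
        mat_sl <- if (sex == "M") mat_m else mat_f
        inherit <- stats::runif(1) < p_inherit
        pool <- members_of(g)
        pool <- pool[vapply(pool, function(i)
          ind[[i]]$sex == sex && !ind[[i]]$role %in% c("bm", "bf") &&
            size_at(i, d) >= mat_sl, logical(1))]
        if (inherit) {
          if (!length(pool)) return(NA_character_)   # wait for an heir
          sz <- vapply(pool, size_at, numeric(1), day = d)
          heir <- pool[order(-sz, pool)][1]
          ind[[heir]]$role <- if (sex == "M") "bm" else "bf"
          ind[[heir]]$subgroup <- sg
          ind[[heir]]$tenure_start <- d
          ind[[heir]]$inherited <- TRUE
          hist[[length(hist) + 1L]] <<- data.frame(
            day = d, event = "inheritance", id = heir, group = g,
            stringsAsFactors = FALSE)
          heir
        } else {
          sl_new <- stats::runif(1, mat_sl + 7, mat_sl + 22)
          nb <- add_ind(g, sg, sex, FALSE, d, age_from_size(sl_new, gm),
                        if (sex == "M") "bm" else "bf",
                        origin = "immigrant_breeder")
          ind[[nb]]$inherited <- FALSE
          hist[[length(hist) + 1L]] <<- data.frame(
            day = d, event = "takeover", id = nb, group = g,
            stringsAsFactors = FALSE)
          nb
        }
      }
      turnover <- function(slot_id, sex, p_end, p_inherit, sg) {
        if (!is.na(slot_id)) {
          if (stats::runif(1) >= p_end) return(slot_id)
          ind[[slot_id]]$present <- FALSE
          memb[[g]] <<- setdiff(memb[[g]], slot_id)
          close_tenure(slot_id, d, censored = FALSE)
          hist[[length(hist) + 1L]] <<- data.frame(
            day = d, event = "tenure_end", id = slot_id, group = g,
            stringsAsFactors = FALSE)
        }
        fill_slot(sex, p_inherit, sg)
      }
      gr$bm <- turnover(gr$bm, "M", p_end_m, config$p_inherit_male, gr$sgs[1])
      for (s in seq_along(gr$bf))
        gr$bf[s] <- turnover(gr$bf[s], "F", p_end_f,
                             config$p_inherit_female, gr$sgs[s])
      # --- recruitment / broods ---
      for (s in seq_along(gr$sgs)) {
        n_rec <- sum(gr$sched[[s]] == d)
        if (!n_rec) next
        imm <- stats::runif(n_rec) < config$p_helper_immigrant
        n_natal <- sum(!imm)
        # natal broods need both a sitting dam and sire
        if (n_natal && (is.na(gr$bm) || is.na(gr$bf[s]))) n_natal <- 0L
        if (n_natal) {
          mem <- members_of(g)
          sire <- gr$bm
          helpers_m <- mem[vapply(mem, function(i)
            ind[[i]]$sex == "M" && !ind[[i]]$role %in% c("bm", "bf") &&
              size_at(i, d) >= mat_m, logical(1))]
          if (length(helpers_m) &&
              stats::runif(1) < config$p_helper_paternity)
            sire <- sample(helpers_m, 1)
          dam <- gr$bf[s]
          helpers_f <- mem[vapply(mem, function(i)
            ind[[i]]$sex == "F" && !ind[[i]]$role %in% c("bm", "bf") &&
              ind[[i]]$subgroup == gr$sgs[s] &&
              size_at(i, d) >= mat_f, logical(1))]
          if (length(helpers_f) &&
              stats::runif(1) < config$p_helper_maternity)
            dam <- sample(helpers_f, 1)
          for (b in seq_len(n_natal)) {
            sex <- sample(c("M", "F"), 1)
            add_ind(g, gr$sgs[s], sex, TRUE, d, 0, "helper",
                    mother = dam, father = sire)
          }
        }
        for (b in seq_len(sum(imm))) {
          sex <- sample(c("M", "F"), 1)
          sl_arr <- stats::runif(1, 16, 34)
          add_ind(g, gr$sgs[s], sex, FALSE, d,
                  age_from_size(sl_arr, gm), "helper")
        }
      }
      groups[[g]] <- gr
    }
  }
  # close tenures of breeders still in place (censored at sim_days)
  for (gr in groups) {
    for (b in c(gr$bm, gr$bf))
      if (!is.na(b)) close_tenure(b, config$sim_days, censored = TRUE)
  }

  # --- snapshot ---
  present <- all_ids[vapply(all_ids, function(i) ind[[i]]$present,
                            logical(1))]
  meta_rows <- lapply(present, function(i) {
    r <- ind[[i]]
    age <- age_at(i, config$sim_days)
    sl <- sl_of(age)
    status <- if (r$role == "bm") "breeder male"
    else if (r$role == "bf") "breeder female"
    else if (sl < 15) "offspring" else "helper"
    sex <- r$sex
    data.frame(id = i, population = "P1", group = sprintf("G%02d", r$group),
               subgroup = r$subgroup, status = status, sex = sex,
               sl_mm = round(sl, 1), age_true = age,
               stringsAsFactors = FALSE)
  })
  meta <- do.call(rbind, meta_rows)
  # independents: a small fraction of mature helpers left their subgroup
  hl <- which(meta$status == "helper" & meta$sl_mm >= min(mat_m, mat_f))
  if (length(hl)) {
    indep <- hl[stats::runif(length(hl)) < 0.05]
    meta$status[indep] <- "independent"
  }
  # unknown-sex observations among helpers (field sexing fails on some)
  hl2 <- which(meta$status %in% c("helper", "offspring"))
  usex <- hl2[stats::runif(length(hl2)) < 0.08]
  meta$sex[usex] <- "U"
  # behaviour counts (workload ingredients), single-10min protocol
  nb <- nrow(meta)
  meta$def_conspecific <- stats::rpois(nb, 3)
  meta$def_heterospecific <- stats::rpois(nb, 2)
  meta$chamber_visits <- stats::rpois(nb, 2)
  meta$maintenance <- stats::rpois(nb, 1.5)
  meta$protocol <- "single-10min"
  calls <- do.call(rbind, mget(meta$id, envir = geno))
  colnames(calls) <- as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2")))
  age_true <- stats::setNames(meta$age_true, meta$id)
  meta$age_true <- NULL
  dataset <- genotype_dataset(calls, meta)

  ped <- do.call(rbind, lapply(all_ids, function(i) {
    r <- ind[[i]]
    if (!r$natal) return(NULL)
    data.frame(offspring = i, mother = r$mother, father = r$father,
               birth_day = r$birth_day, stringsAsFactors = FALSE)
  }))
  imm_tab <- do.call(rbind, lapply(all_ids, function(i) {
    r <- ind[[i]]
    data.frame(id = i,
               class_true = if (r$natal) "philopatric" else "immigrant",
               founder = r$founder, origin = r$origin,
               stringsAsFactors = FALSE)
  }))
  truth <- structure(list(
    pedigree = ped %||% data.frame(),
    immigrants = imm_tab,
    tenure = do.call(rbind, tenure_rows),
    group_history = if (length(hist)) do.call(rbind, hist) else
      data.frame(day = numeric(), event = character(), id = character(),
                 group = integer()),
    age_true = age_true), class = "truth_tables")

  if (config$genotyping_error_rate > 0 || config$missing_rate > 0)
    dataset <- inject_errors(dataset, config$genotyping_error_rate,
                             config$missing_rate,
                             seed = derive_seed(config$seed, 999L))
  list(dataset = dataset, truth = truth, founder_freqs = fblock)
}

#' @export
print.truth_tables <- function(x, ...) {
  cat(sprintf(
    "truth_tables: %d pedigree rows, %d individuals, %d tenure records\n",
    nrow(x$pedigree), nrow(x$immigrants), nrow(x$tenure)))
  invisible(x)
}

#' Inject genotyping error and missingness
#'
#' Each allele call is independently replaced by a random allele (drawn
#' with the dataset's naive frequencies) with probability `error_rate`;
#' each locus call is set missing with probability `missing_rate`. Truth
#' tables are untouched by construction. Rates `(0, 0)` return the
#' dataset unchanged.
#'
#' @param dataset A [genotype_dataset()].
#' @param error_rate Per-allele replacement probability.
#' @param missing_rate Per-locus-call missingness probability.
#' @param seed RNG seed.
#' @return A `genotype_dataset` with perturbed calls.
#' @export
inject_errors <- function(dataset, error_rate, missing_rate, seed = 1L) {
  assert_prob(error_rate, "error_rate")
  assert_prob(missing_rate, "missing_rate")
  if (error_rate == 0 && missing_rate == 0) return(dataset)
  set.seed(as.integer(seed))
  calls <- dataset$calls
  if (error_rate > 0) {
    freqs <- estimate_allele_frequencies(dataset, "naive", floor = FALSE)
    for (l in dataset$loci) {
      p <- freqs[[l]]
      for (col in paste0(l, c("_1", "_2"))) {
        hit <- !is.na(calls[, col]) & stats::runif(nrow(calls)) < error_rate
        if (any(hit))
          calls[hit, col] <- sample(as.numeric(names(p)), sum(hit), TRUE, p)
      }
    }
  }
  if (missing_rate > 0) {
    for (l in dataset$loci) {
      drop <- stats::runif(nrow(calls)) < missing_rate
      calls[drop, paste0(l, c("_1", "_2"))] <- NA
    }
  }
  genotype_dataset(calls, dataset$meta)
}

#' Write simulator truth tables as CSV
#'
#' Emits `pedigree.csv`, `immigrants.csv` and `tenure.csv` into `dir`.
#'
#' @param truth A `truth_tables` object from [simulate_population()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth_tables <- function(truth, dir) {
  stopifnot(inherits(truth, "truth_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(truth$pedigree, file.path(dir, "pedigree.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$immigrants, file.path(dir, "immigrants.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$tenure, file.path(dir, "tenure.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a flat key-value simulation config file
#'
#' Accepts a minimal TOML/YAML-style file of `key = value` or
#' `key: value` lines (ranges and vectors comma-separated); unknown keys
#' error. Values are passed to [simulation_config()].
#'
#' @param path File path.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*[:=]\\s*")
  args <- list()
  for (p in kv) {
    if (length(p) != 2L) stop("malformed config line: ", paste(p, collapse = ""),
                              call. = FALSE)
    val <- as.numeric(strsplit(p[2], ",")[[1]])
    args[[p[1]]] <- if (length(val) == 1L) val else val
  }
  known <- names(formals(simulation_config))
  bad <- setdiff(names(args), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(simulation_config, args)
}
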