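#' Pipeline configuration
#'
#' Exactly one input mode: either `simulation` (a [simulation_config()])
#' or `input_csv` (path to a genotype table in the pipeline CSV dialect).
#' All thresholds of the downstream stages are collected here; the seed is
#' mandatory because classification, partitioning and the bootstrap are
#' all simulation-based.
#'
#' @param simulation Optional [simulation_config()].
#' @param input_csv Optional path to a genotype CSV.
#' @param freq_file Optional external allele-frequency block CSV
#'   (overrides `freq_method`).
#' @param qg_variant `"symmetric"` (default) or `"directional-mean"`; see
#'   [qg_relatedness()].
#' @param freq_method `"corrected"` (default) or `"naive"`.
#' @param locus_exclusions Character vector of loci to drop up front
#'   (error-prone markers).
#' @param hwe_alpha HWE exclusion level per population (default 0.05).
#' @param alpha,n_null Dyad-classification controls.
#' @param n_reps Bootstrap repetitions for the category comparisons.
#' @param max_mismatch,min_parent_size_at_spawning,maturity_sizes,
#'   similar_age_window,merge_threshold Stage thresholds (see the
#'   respective functions).
#' @param growth_params `c(alpha, beta, s0)` for the growth model.
#' @param seed Master seed.
#' @param out_dir Output directory for the report bundle.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, input_csv = NULL,
                            freq_file = NULL,
                            qg_variant = c("symmetric", "directional-mean"),
                            freq_method = c("corrected", "naive"),
                            locus_exclusions = character(),
                            hwe_alpha = 0.05,
                            alpha = 0.05, n_null = 2000L, n_reps = 100L,
                            max_mismatch = 1L,
                            min_parent_size_at_spawning = 31,
                            maturity_sizes = c(male = 32.5, female = 31.5),
                            similar_age_window = 90,
                            merge_threshold = 1,
                            growth_params = c(0.38, -0.087, 6.5),
                            seed = 1L, out_dir = tempfile("kinrecon_run_")) {
  if (is.null(simulation) == is.null(input_csv))
    stop("exactly one input mode: `simulation` or `input_csv`", call. = FALSE)
  structure(list(simulation = simulation, input_csv = input_csv,
                 freq_file = freq_file,
                 qg_variant = match.arg(qg_variant),
                 freq_method = match.arg(freq_method),
                 locus_exclusions = locus_exclusions,
                 hwe_alpha = hwe_alpha, alpha = alpha,
                 n_null = as.integer(n_null), n_reps = as.integer(n_reps),
                 max_mismatch = as.integer(max_mismatch),
                 min_parent_size_at_spawning = min_parent_size_at_spawning,
                 maturity_sizes = maturity_sizes,
                 similar_age_window = similar_age_window,
                 merge_threshold = merge_threshold,
                 growth_params = growth_params,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full reconstruction pipeline
#'
#' simulate/load -> locus filtering -> allele frequencies -> dyad table ->
#' kinship partition + parentage -> demographic reconstruction ->
#' summaries and category comparisons. Writes a report bundle (CSV
#' artifacts plus a JSON manifest) into `config$out_dir`; identical
#' config and seed reproduce an identical bundle.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with all in-memory artifacts
#'   (`dataset, freqs, dyads, parentage, demography, summaries,
#'   comparisons, truth`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_line <- function(...) if (!quiet) message(sprintf(...))
  gm <- growth_model(config$growth_params[[1]], config$growth_params[[2]],
                     config$growth_params[[3]])
  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- simulate_population(config$simulation)
    dataset <- sim$dataset; truth <- sim$truth
    log_line("stage simulate: %d individuals, %d loci",
             n_individuals(dataset), length(dataset$loci))
  } else {
    dataset <- read_genotypes(config$input_csv, "csv")
    log_line("stage load: %d individuals, %d loci from %s",
             n_individuals(dataset), length(dataset$loci), config$input_csv)
  }
  excl <- config$locus_exclusions
  if (config$hwe_alpha > 0)       # hwe_alpha = 0 disables the HWE screen
    excl <- union(excl, hwe_exclusions(dataset, alpha = config$hwe_alpha,
                                       seed = derive_seed(config$seed, 11L)))
  if (length(excl)) {
    log_line("stage filter: dropping loci %s", paste(excl, collapse = ", "))
    dataset <- drop_loci(dataset, excl)
  }
  freqs <- if (!is.null(config$freq_file)) {
    read_allele_frequencies(config$freq_file)
  } else {
    estimate_allele_frequencies(dataset, config$freq_method)
  }
  log_line("stage frequencies: %s block over %d loci",
           attr(freqs, "provenance"), length(freqs))
  dyads <- dyad_table(dataset, freqs, within_groups = TRUE,
                      alpha = config$alpha, n_null = config$n_null,
                      seed = derive_seed(config$seed, 21L),
                      qg_variant = config$qg_variant)
  log_line("stage relatedness: %d within-group dyads", nrow(dyads))
  parentage <- assign_parentage(
    dataset, freqs, max_mismatch = config$max_mismatch, growth = gm,
    min_parent_size_at_spawning = config$min_parent_size_at_spawning,
    maturity_sizes = config$maturity_sizes)
  log_line("stage parentage: %d accepted of %d candidate pairs",
           sum(parentage$accepted), nrow(parentage))
  demog <- demography_report(dataset, freqs, growth = gm,
                             parentage = parentage, alpha = config$alpha,
                             n_null = config$n_null,
                             seed = derive_seed(config$seed, 31L),
                             merge_threshold = config$merge_threshold,
                             similar_age_window = config$similar_age_window)
  log_line("stage demography: %d members reconstructed", nrow(demog))
  summaries <- summarize_structure(demog, parentage)
  comparisons <- tryCatch(
    relatedness_category_comparisons(dataset, demog, freqs,
                                     n_reps = config$n_reps,
                                     alpha = config$alpha,
                                     seed = derive_seed(config$seed, 41L)),
    error = function(e) {
      log_line("stage comparisons skipped: %s", conditionMessage(e))
      NULL
    })
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, f) utils::write.csv(
    x, file.path(config$out_dir, f), row.names = FALSE)
  wcsv(dyads, "dyads.csv")
  wcsv(parentage, "parentage.csv")
  wcsv(demog, "demography.csv")
  wcsv(summaries$immigration, "immigration.csv")
  wcsv(summaries$skew, "skew.csv")
  if (!is.null(comparisons)) wcsv(comparisons, "comparisons.csv")
  if (!is.null(truth)) write_truth_tables(truth, file.path(config$out_dir,
                                                           "truth"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("kinrecon")),
    seed = config$seed,
    config = config[setdiff(names(config), c("simulation", "out_dir"))],
    simulation = if (!is.null(config$simulation))
      unclass(config$simulation)[setdiff(names(config$simulation), "growth")],
    n_individuals = n_individuals(dataset),
    loci = dataset$loci, excluded_loci = excl)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_line("bundle written to %s", config$out_dir)
  invisible(list(dataset = dataset, freqs = freqs, dyads = dyads,
                 parentage = parentage, demography = demog,
                 summaries = summaries, comparisons = comparisons,
                 truth = truth, out_dir = config$out_dir))
}

#' Category-labelled relatedness comparison per social status
#'
#' For each focal status, every dyad pairing a focal individual with any
#' other individual is labelled `subgroup` (same subgroup), `group` (same
#' group, different subgroup) or `non-group`, and the three categories are
#' compared by [bootstrap_category_comparison()].
#'
#' @param dataset A [genotype_dataset()].
#' @param demog A [demography_report()] (for subgroup labels).
#' @param freqs An [allele_freq_block()].
#' @param statuses Focal statuses to analyse.
#' @param n_reps,alpha,seed Passed to the bootstrap.
#' @return Data frame with a `status` column plus the comparison fields.
#' @export
relatedness_category_comparisons <- function(dataset, demog, freqs,
                                             statuses = c("breeder male",
                                                          "breeder female",
                                                          "helper"),
                                             n_reps = 100L, alpha = 0.05,
                                             seed = 1L) {
  rmat <- relatedness_matrix(dataset, freqs)
  meta <- dataset$meta
  out <- list()
  for (st in statuses) {
    foc <- which(meta$status == st)
    if (!length(foc)) next
    vals <- numeric(0); cats <- character(0)
    for (i in foc) {
      js <- seq_len(nrow(meta))[-i]
      same_g <- !is.na(meta$group[js]) & !is.na(meta$group[i]) &
        meta$group[js] == meta$group[i]
      same_sg <- same_g & !is.na(meta$subgroup[js]) &
        !is.na(meta$subgroup[i]) & meta$subgroup[js] == meta$subgroup[i]
      cat_i <- ifelse(same_sg, "subgroup",
                      ifelse(same_g, "group", "non-group"))
      vals <- c(vals, rmat[i, js]); cats <- c(cats, cat_i)
    }
    ok <- !is.na(vals)
    if (length(unique(cats[ok])) < 2) next
    cmp <- bootstrap_category_comparison(vals[ok], cats[ok],
                                         n_reps = n_reps, alpha = alpha,
                                         seed = seed)
    cmp$status <- st
    out[[length(out) + 1L]] <- as.data.frame(cmp)
  }
  if (!length(out)) stop("no status had >= 2 dyad categories", call. = FALSE)
  do.call(rbind, out)
}
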