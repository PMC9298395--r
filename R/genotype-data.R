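#' Genotype dataset container
#'
#' The pipeline's universal input: diploid co-dominant allele calls per
#' individual and locus, plus the social metadata (population, group,
#' subgroup, status, sex, standard length, optional behaviour counts).
#'
#' Allele calls are stored as a numeric matrix with two columns per locus
#' (`<locus>_1`, `<locus>_2`); `NA` marks a missing call (both columns of a
#' locus are set `NA` if either allele is unscored). Allele labels are
#' integers, typically microsatellite fragment sizes.
#'
#' @param calls Numeric matrix, one row per individual, columns
#'   `<locus>_1, <locus>_2, ...`.
#' @param meta Data frame with at least column `id`; recognised columns are
#'   `population`, `group`, `subgroup`, `status`, `sex`, `sl_mm`; any
#'   further columns (behaviour counts, protocol tags) are carried along.
#' @return An object of class `genotype_dataset` with fields `meta`,
#'   `calls`, `loci`.
#' @export
genotype_dataset <- function(calls, meta) {
  calls <- as.matrix(calls)
  if (ncol(calls) %% 2L != 0L)
    stop("allele column count must be even (two columns per locus)",
         call. = FALSE)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (is.null(meta$id)) stop("meta must contain an `id` column", call. = FALSE)
  meta$id <- as.character(meta$id)
  if (anyDuplicated(meta$id))
    stop("duplicate individual ids: ",
         paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "),
         call. = FALSE)
  if (nrow(calls) != nrow(meta))
    stop("calls and meta disagree on the number of individuals", call. = FALSE)
  for (col in c("population", "group", "subgroup", "status", "sex"))
    if (is.null(meta[[col]])) meta[[col]] <- NA_character_
  bad <- setdiff(unique(stats::na.omit(meta$status)), status_levels())
  if (length(bad))
    stop("unknown status label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(meta$sl_mm) && any(!is.na(meta$sl_mm) & meta$sl_mm <= 0))
    stop("sl_mm must be > 0 where present", call. = FALSE)
  # a subgroup id must belong to exactly one group
  sg <- unique(meta[!is.na(meta$subgroup), c("group", "subgroup")])
  if (anyDuplicated(sg$subgroup))
    stop("subgroup id mapped to more than one group: ",
         paste(unique(sg$subgroup[duplicated(sg$subgroup)]), collapse = ", "),
         call. = FALSE)
  loci <- unique(sub("_[12]$", "", colnames(calls)))
  expected <- as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2")))
  if (!identical(colnames(calls), expected))
    stop("call columns must come in <locus>_1, <locus>_2 pairs", call. = FALSE)
  # standardise half-missing calls to fully missing
  for (l in loci) {
    cc <- calls[, paste0(l, c("_1", "_2")), drop = FALSE]
    miss <- is.na(cc[, 1]) | is.na(cc[, 2])
    calls[miss, paste0(l, c("_1", "_2"))] <- NA
  }
  rownames(calls) <- meta$id
  structure(list(meta = meta, calls = calls, loci = loci),
            class = "genotype_dataset")
}

status_levels <- function() {
  c("breeder male", "breeder female", "helper", "offspring", "independent")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d individuals x %d loci\n",
              nrow(x$meta), length(x$loci)))
  st <- table(x$meta$status, useNA = "ifany")
  cat("  status:", paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n")
  invisible(x)
}

#' Number of individuals / loci
#' @param x A `genotype_dataset`.
#' @rdname genotype_dataset
#' @export
n_individuals <- function(x) nrow(x$meta)

#' Subset a genotype dataset by individual
#'
#' @param x A `genotype_dataset`.
#' @param ids Character ids or logical/integer index into individuals.
#' @return A `genotype_dataset` restricted to the selected individuals.
#' @export
subset_individuals <- function(x, ids) {
  stopifnot(inherits(x, "genotype_dataset"))
  idx <- if (is.character(ids)) match(ids, x$meta$id) else seq_len(nrow(x$meta))[ids]
  if (anyNA(idx)) stop("unknown individual id(s)", call. = FALSE)
  genotype_dataset(x$calls[idx, , drop = FALSE], x$meta[idx, , drop = FALSE])
}

#' Extract one individual's genotype as a loci x 2 matrix
#'
#' @param x A `genotype_dataset`.
#' @param id Individual id (or row index).
#' @return Numeric matrix, `length(loci)` rows, 2 columns, rownames = loci.
#' @export
individual_genotype <- function(x, id) {
  i <- if (is.character(id)) match(id, x$meta$id) else id
  if (is.na(i)) stop("unknown individual id: ", id, call. = FALSE)
  m <- matrix(x$calls[i, ], ncol = 2, byrow = TRUE,
              dimnames = list(x$loci, c("a1", "a2")))
  m
}

#' Read a genotype table
#'
#' Two dialects are supported. The pipeline CSV has header
#' `id,population,group,subgroup,status,sex,sl_mm,<locus>_1,<locus>_2,...`
#' (metadata columns beyond `id` optional; extra non-locus columns such as
#' behaviour counts are kept in `meta`); allele code `0` means missing.
#' GenePop files (4- or 6-digit alleles) use `0000`/`000000` for missing;
#' `Pop` blocks become populations `pop1`, `pop2`, ... and the text before
#' the comma is the individual id.
#'
#' @param path File path.
#' @param format `"csv"` or `"genepop"`.
#' @return A [genotype_dataset()].
#' @export
read_genotypes <- function(path, format = c("csv", "genepop")) {
  format <- match.arg(format)
  if (format == "csv") read_genotypes_csv(path) else read_genepop(path)
}

read_genotypes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cn <- colnames(df)
  is_allele <- grepl("_[12]$", cn) & !cn %in% c("sl_mm")
  # locus columns are those ending _1/_2 whose stem appears with both suffixes
  stems <- sub("_[12]$", "", cn[is_allele])
  loci <- unique(stems[duplicated(stems) | rev(duplicated(rev(stems)))])
  allele_cols <- as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2")))
  if (!all(allele_cols %in% cn))
    stop("malformed locus columns in ", path, call. = FALSE)
  calls <- as.matrix(df[, allele_cols, drop = FALSE])
  storage.mode(calls) <- "double"
  calls[calls == 0] <- NA
  meta <- df[, setdiff(cn, allele_cols), drop = FALSE]
  genotype_dataset(calls, meta)
}

read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("not a GenePop file: ", path, call. = FALSE)
  body <- lines[-1]                      # first line is the title
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(pop_idx)) stop("GenePop file has no Pop line", call. = FALSE)
  locus_lines <- body[seq_len(pop_idx[1] - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  ids <- character(); pops <- character(); rows <- list()
  pop_no <- 0L
  for (ln in body[-seq_len(pop_idx[1] - 1L)]) {
    if (grepl("^\\s*pop\\s*$", ln, ignore.case = TRUE)) {
      pop_no <- pop_no + 1L
      next
    }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2L) stop("malformed GenePop record: ", ln, call. = FALSE)
    id <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(codes) != length(loci))
      stop("GenePop record has ", length(codes), " loci, expected ",
           length(loci), ": ", id, call. = FALSE)
    w <- nchar(codes[1]) / 2
    a1 <- as.numeric(substr(codes, 1, w))
    a2 <- as.numeric(substr(codes, w + 1, 2 * w))
    g <- as.vector(rbind(a1, a2))
    g[g == 0] <- NA
    ids <- c(ids, id); pops <- c(pops, paste0("pop", pop_no))
    rows[[length(rows) + 1L]] <- g
  }
  calls <- do.call(rbind, rows)
  colnames(calls) <- as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2")))
  genotype_dataset(calls, data.frame(id = ids, population = pops,
                                     stringsAsFactors = FALSE))
}

#' Write a genotype dataset in the pipeline CSV dialect
#'
#' Missing calls are written as `0`. `write_genotypes()` followed by
#' [read_genotypes()] is an identity round trip.
#'
#' @param x A `genotype_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path) {
  stopifnot(inherits(x, "genotype_dataset"))
  calls <- x$calls
  calls[is.na(calls)] <- 0
  lead <- intersect(c("id", "population", "group", "subgroup", "status",
                      "sex", "sl_mm"), colnames(x$meta))
  extra <- setdiff(colnames(x$meta), lead)
  df <- cbind(x$meta[, c(lead, extra), drop = FALSE], as.data.frame(calls))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
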