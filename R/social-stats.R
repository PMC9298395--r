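#' Composite workload from behavioural counts
#'
#' Sums territory-defence (conspecific and heterospecific), breeding-
#' chamber-visit and maintenance counts into a single workload score.
#' Under the `single-10min` protocol the counts of the one observation are
#' summed directly. Under `triple-15min` the three observation totals are
#' averaged and multiplied by 2/3, putting them on the 10-minute scale.
#' The result is rounded half-up to the nearest integer (so count models
#' can be fitted downstream).
#'
#' @param counts For `single-10min`: numeric vector of behaviour counts.
#'   For `triple-15min`: numeric vector of the three per-observation
#'   totals, or a 3-row matrix of per-observation behaviour counts.
#' @param protocol `"single-10min"` or `"triple-15min"`.
#' @return Nonnegative integer workload.
#' @examples
#' workload_composite(c(2, 1, 3, 0), "single-10min")   # 6
#' workload_composite(c(6, 9, 12), "triple-15min")     # mean 9 * 2/3 = 6
#' @export
workload_composite <- function(counts,
                               protocol = c("single-10min", "triple-15min")) {
  protocol <- match.arg(protocol)
  if (any(is.na(counts)) || any(counts < 0))
    stop("behaviour counts must be nonnegative", call. = FALSE)
  w <- if (protocol == "single-10min") {
    sum(counts)
  } else {
    totals <- if (is.matrix(counts)) rowSums(counts) else counts
    if (length(totals) != 3L)
      stop("triple-15min protocol expects three observations", call. = FALSE)
    mean(totals) * 2 / 3
  }
  as.integer(round_half_up(w))
}

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction (matching the worked comparisons of produced
#' vs. not-produced group members); p from the chi-square distribution
#' with 1 df.
#'
#' @param tab 2x2 numeric matrix (or length-4 vector, filled by row).
#' @return List `statistic`, `df`, `p_value`.
#' @export
chi_square_2x2 <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(tab, 2, 2, byrow = TRUE)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0)) stop("cell counts must be >= 0", call. = FALSE)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0))
    stop("zero row margin (row ", which(rs == 0)[1], ")", call. = FALSE)
  if (any(cs == 0))
    stop("zero column margin (column ", which(cs == 0)[1], ")", call. = FALSE)
  E <- outer(rs, cs) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' One-sample t test (raw sample or printed moments)
#'
#' `t = (mean - mu0) / (sd / sqrt(n))`, `df = n - 1`, two-sided p. Accepts
#' either the raw sample or summary moments, so printed tables can be
#' re-tested.
#'
#' @param x Numeric sample (optional if moments given).
#' @param mean,sd,n Summary moments (ignored when `x` is supplied).
#' @param mu0 Null mean (default 0).
#' @return List `t`, `df`, `p_value`.
#' @export
one_sample_t <- function(x = NULL, mean = NULL, sd = NULL, n = NULL,
                         mu0 = 0) {
  if (!is.null(x)) {
    n <- length(x); mean <- base::mean(x); sd <- stats::sd(x)
  }
  if (is.null(mean) || is.null(sd) || is.null(n))
    stop("supply a sample or (mean, sd, n)", call. = FALSE)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (sd <= 0) stop("sd must be > 0", call. = FALSE)
  t <- (mean - mu0) / (sd / sqrt(n))
  list(t = t, df = n - 1,
       p_value = 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE))
}

#' Dunnett's C pairwise confidence intervals
#'
#' Post hoc comparison that does not assume equal variances. For groups i
#' and j with sample variances `s2`, sizes `n` and studentized-range
#' quantiles `q_i = q(alpha; k, n_i - 1)`:
#' \deqn{hw = \sqrt{(v_i + v_j)/2}\;\frac{q_i v_i + q_j v_j}{v_i + v_j}, \quad v = s^2/n}
#' and the interval is `(mean_i - mean_j) +/- hw`. Quantiles come from the
#' studentized-range distribution (`qtukey`). Both groups having zero
#' variance degenerates to a width-0 interval with a warning.
#'
#' @param samples Named list of numeric vectors (k >= 2, each n >= 2).
#' @param alpha Family-wise level (default 0.05).
#' @return Data frame `cat_i,cat_j,mean_diff,lower,upper,significant`
#'   (significant = interval excludes 0).
#' @export
dunnett_c <- function(samples, alpha = 0.05) {
  k <- length(samples)
  stopifnot(k >= 2, all(lengths(samples) >= 2))
  if (is.null(names(samples))) names(samples) <- paste0("g", seq_len(k))
  m <- vapply(samples, mean, numeric(1))
  v <- vapply(samples, stats::var, numeric(1)) / lengths(samples)
  qv <- vapply(lengths(samples) - 1, function(df)
    qtukey_safe(1 - alpha, k, df), numeric(1))
  pairs <- utils::combn(k, 2)
  out <- lapply(seq_len(ncol(pairs)), function(c2) {
    i <- pairs[1, c2]; j <- pairs[2, c2]
    if (v[i] + v[j] == 0) {
      warning("both groups have zero variance: degenerate CI")
      hw <- 0
    } else {
      hw <- sqrt((v[i] + v[j]) / 2) * (qv[i] * v[i] + qv[j] * v[j]) /
        (v[i] + v[j])
    }
    d <- m[i] - m[j]
    data.frame(cat_i = names(samples)[i], cat_j = names(samples)[j],
               mean_diff = d, lower = d - hw, upper = d + hw,
               significant = (d - hw) > 0 | (d + hw) < 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# studentized-range quantile; qtukey()'s numerical integration fails at
# df = 1, where a fixed-seed Monte-Carlo estimate stands in (cached)
.qtukey_cache <- new.env(parent = emptyenv())
qtukey_safe <- function(p, k, df) {
  q <- suppressWarnings(stats::qtukey(p, k, df))
  if (is.finite(q)) return(q)
  key <- sprintf("%g_%d_%d", p, k, df)
  if (!is.null(.qtukey_cache[[key]])) return(.qtukey_cache[[key]])
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(20231L)
  n_mc <- 2e5
  x <- matrix(stats::rnorm(n_mc * k), n_mc, k)
  rng <- (apply(x, 1, max) - apply(x, 1, min)) /
    sqrt(stats::rchisq(n_mc, df) / df)
  q <- unname(stats::quantile(rng, p))
  .qtukey_cache[[key]] <- q
  q
}

#' Bootstrap ANOVA with averaged Dunnett's C intervals
#'
#' The study's resampling scheme: the category-labelled value table is
#' resampled with replacement to its original size `n_reps` times
#' (unstratified); each replicate gets a one-way ANOVA across categories
#' and Dunnett's C intervals for every category pair. The ANOVA p-value
#' and the interval bounds are averaged over replicates, and a pair is
#' significant when the *averaged* interval excludes zero. A replicate
#' that loses a category (or leaves one with a single row) is redrawn and
#' logged.
#'
#' @param values Numeric response (e.g. pairwise relatedness).
#' @param category Category label per value (>= 2 categories, each with
#'   >= 2 rows).
#' @param n_reps Bootstrap repetitions (default 100).
#' @param alpha Level for the Dunnett's C intervals.
#' @param seed RNG seed.
#' @return Data frame of class `category_comparison`:
#'   `cat_i,cat_j,mean_diff,avg_p,avg_lo,avg_hi,significant,n_reps`, with
#'   attribute `redraws` = number of redrawn replicates.
#' @export
bootstrap_category_comparison <- function(values, category, n_reps = 100L,
                                          alpha = 0.05, seed = 1L) {
  stopifnot(length(values) == length(category))
  ok <- !is.na(values) & !is.na(category)
  values <- values[ok]; category <- as.character(category[ok])
  cats <- sort(unique(category))
  if (length(cats) < 2L || any(table(category) < 2))
    stop("need >= 2 categories with >= 2 values each", call. = FALSE)
  set.seed(as.integer(seed))
  n <- length(values)
  acc <- NULL; pvals <- numeric(0); redraws <- 0L
  rep_done <- 0L
  while (rep_done < n_reps) {
    idx <- sample.int(n, n, replace = TRUE)
    vb <- values[idx]; cb <- category[idx]
    if (!all(cats %in% cb) || any(table(factor(cb, cats)) < 2)) {
      redraws <- redraws + 1L
      next
    }
    p_anova <- stats::anova(stats::lm(vb ~ factor(cb)))$`Pr(>F)`[1]
    dc <- dunnett_c(split(vb, factor(cb, cats)), alpha = alpha)
    rep_done <- rep_done + 1L
    pvals <- c(pvals, p_anova)
    if (is.null(acc)) {
      acc <- dc[, c("cat_i", "cat_j")]
      acc$mean_diff <- dc$mean_diff; acc$lo <- dc$lower; acc$hi <- dc$upper
    } else {
      acc$mean_diff <- acc$mean_diff + dc$mean_diff
      acc$lo <- acc$lo + dc$lower; acc$hi <- acc$hi + dc$upper
    }
  }
  out <- data.frame(cat_i = acc$cat_i, cat_j = acc$cat_j,
                    mean_diff = acc$mean_diff / n_reps,
                    avg_p = mean(pvals),
                    avg_lo = acc$lo / n_reps, avg_hi = acc$hi / n_reps,
                    stringsAsFactors = FALSE)
  out$significant <- out$avg_lo > 0 | out$avg_hi < 0
  out$n_reps <- n_reps
  attr(out, "redraws") <- redraws
  class(out) <- c("category_comparison", class(out))
  out
}

#' Gehan-Wilcoxon (generalized Wilcoxon) two-sample survival comparison
#'
#' Weighted log-rank test with weight equal to the number at risk
#' (Gehan-Breslow), the classical Kaplan-Meier life-table comparison for
#' two strata: at each distinct event time the observed minus expected
#' events in stratum 1 are weighted by the risk-set size, with the usual
#' hypergeometric variance; the statistic is chi-square with 1 df. Scale
#' changes of the times leave the statistic untouched (rank test).
#'
#' @param time Observation times (e.g. tenure, days).
#' @param event 1/TRUE = event observed, 0/FALSE = censored.
#' @param group Two-level stratum label (e.g. breeder sex).
#' @return List `statistic`, `p_value`, `medians` (KM median per stratum).
#' @export
km_gehan <- function(time, event, group) {
  event <- as.integer(event)
  group <- as.character(group)
  lev <- sort(unique(group))
  if (length(lev) != 2L) stop("exactly two strata required", call. = FALSE)
  if (any(tapply(event, group, sum) == 0))
    stop("each stratum needs >= 1 observed event", call. = FALSE)
  tt <- sort(unique(time[event == 1]))
  U <- 0; V <- 0
  for (t in tt) {
    at_risk <- time >= t
    n_tot <- sum(at_risk)
    n1 <- sum(at_risk & group == lev[1])
    d_tot <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == lev[1])
    if (n_tot < 2) next
    e1 <- d_tot * n1 / n_tot
    var1 <- d_tot * (n1 / n_tot) * (1 - n1 / n_tot) *
      (n_tot - d_tot) / (n_tot - 1)
    U <- U + n_tot * (d1 - e1)
    V <- V + n_tot^2 * var1
  }
  stat <- if (V > 0) U^2 / V else 0
  medians <- vapply(lev, function(g) km_median(time[group == g],
                                               event[group == g]),
                    numeric(1))
  list(statistic = stat,
       p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
       medians = medians)
}

# Kaplan-Meier median (first time S(t) <= 0.5); NA if never reached
km_median <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  s <- 1
  for (t in unique(time[event == 1])) {
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n)
    if (s <= 0.5) return(t)
  }
  NA_real_
}
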