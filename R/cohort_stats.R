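## Cohort evaluation statistics: descriptive table summaries, the exact
## (full-enumeration) Wilcoxon signed-rank test, and reader-rating tallies.
## The per-volunteer tables of the bundled 10-subject 3-T study ship as
## plain CSV fixtures under inst/extdata/.

#' Mean and sample standard deviation
#'
#' @param values Numeric vector; the standard deviation (n-1 denominator)
#'   needs at least 2 values.
#' @return Named numeric vector `c(mean = , sd = )`.
#' @examples
#' descriptive(cohort_t1_table()$gm_t1)  # 1442.8, 179.7
#' @export
descriptive <- function(values) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    abort_data("`values` must be finite numbers")
  }
  if (length(values) < 2L) {
    abort_data("need at least 2 values for a sample standard deviation")
  }
  c(mean = mean(values), sd = sd(values))
}

## Exact null distribution of the positive-rank sum V: counts of each
## achievable 2*V value over all 2^n sign assignments, by subset-sum
## doubling over the (doubled, hence integer even with midranks) ranks.
signed_rank_counts <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (r in ranks2) {
    g <- f
    g[(r + 1):(total + 1)] <- g[(r + 1):(total + 1)] + f[1:(total + 1 - r)]
    f <- g
  }
  f  # f[s + 1] = number of sign assignments with 2*V = s
}

#' Exact Wilcoxon signed-rank test by full enumeration
#'
#' Paired two-sided test. Zero differences are dropped, absolute
#' differences are ranked with midranks for ties, and the exact null
#' distribution of the positive-rank sum is obtained by enumerating all
#' `2^n` sign assignments (n <= 20).  The reported statistic is the
#' smaller of the positive- and negative-rank sums; the two-sided p-value
#' is `2 * min(P(V <= v), P(V >= v))` capped at 1, where `v` is the
#' observed positive-rank sum — the classical exact convention (n = 10
#' with all differences one-signed gives p = 2/1024).
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return Object of class `asl_wilcoxon_result`: `w_statistic` (smaller
#'   signed-rank sum), `n_effective` (pairs after dropping zeros) and
#'   `p_two_sided`.
#' @examples
#' tab <- cohort_rcbf_table()
#' wilcoxon_signed_rank_exact(tab$rcbf_regular, tab$rcbf_adaptive)
#' @export
wilcoxon_signed_rank_exact <- function(x, y) {
  if (length(x) != length(y)) abort_data("`x` and `y` must have equal length")
  if (!length(x)) abort_data("need at least one pair")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort_data("inputs must be finite")
  }
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) abort_data("all paired differences are zero")
  if (n > 20L) abort_param("exact enumeration supported for n_effective <= 20")
  r <- rank(abs(d))                       # midranks for ties
  ranks2 <- as.integer(round(2 * r))      # doubled ranks are integers
  v2 <- sum(ranks2[d > 0])                # observed 2*V
  counts <- signed_rank_counts(ranks2)
  tot <- 2^n
  p_le <- sum(counts[seq_len(v2 + 1)]) / tot
  p_ge <- sum(counts[(v2 + 1):length(counts)]) / tot
  p <- min(1, 2 * min(p_le, p_ge))
  vpos <- v2 / 2
  vneg <- sum(r) - vpos
  structure(list(w_statistic = min(vpos, vneg), n_effective = n,
                 p_two_sided = p,
                 v_positive = vpos, v_negative = vneg),
            class = "asl_wilcoxon_result")
}

#' @export
print.asl_wilcoxon_result <- function(x, ...) {
  cat(sprintf("Exact Wilcoxon signed-rank: W = %g (n = %d), two-sided p = %.5g\n",
              x$w_statistic, x$n_effective, x$p_two_sided))
  invisible(x)
}

#' Tally reader ratings per reader and category
#'
#' Sums 3-point ratings (-1 = original better, 0 = equal, 1 = modified
#' better) over cases, per reader and category — the "Sum" row of a
#' reader-study table.
#'
#' @param table Data frame with columns `case`, `reader`, `category`,
#'   `rating`; ratings must be -1, 0 or 1.
#' @return Data frame with columns `reader`, `category`, `sum`, ordered by
#'   category (noise, cortical_structures, artifacts) then reader.
#' @examples
#' tally_ratings(reader_ratings_table())
#' @export
tally_ratings <- function(table) {
  req <- c("case", "reader", "category", "rating")
  if (!is.data.frame(table) || !all(req %in% names(table)) || !nrow(table)) {
    abort_data("ratings table must be a non-empty data frame with columns case, reader, category, rating")
  }
  if (!all(table$rating %in% c(-1L, 0L, 1L))) {
    abort_data("ratings must be -1, 0 or 1")
  }
  agg <- stats::aggregate(rating ~ reader + category, data = table, FUN = sum)
  names(agg)[names(agg) == "rating"] <- "sum"
  cat_order <- c("noise", "cortical_structures", "artifacts")
  lev <- c(intersect(cat_order, unique(agg$category)),
           setdiff(unique(agg$category), cat_order))
  agg <- agg[order(match(agg$category, lev), agg$reader), c("reader", "category", "sum")]
  rownames(agg) <- NULL
  agg
}

extdata_csv <- function(name) {
  path <- system.file("extdata", name, package = "aslbs", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Bundled per-volunteer whole-brain tissue T1 table
#'
#' Mean gray matter, white matter and CSF T1 relaxation times (ms) of 10
#' healthy volunteers measured at 3 T with the two-flip-angle method.
#' CSF values may be inaccurate due to the long relaxation times.
#'
#' @return Data frame with columns `volunteer`, `gm_t1`, `wm_t1`, `csf_t1`.
#' @export
cohort_t1_table <- function() extdata_csv("cohort_t1.csv")

#' Bundled per-volunteer relative CBF table
#'
#' Mean gray matter rCBF (arbitrary units) of the same 10 volunteers,
#' measured once with the routine fixed background suppression timing
#' (`rcbf_regular`) and once with the individually adapted timing
#' (`rcbf_adaptive`).
#'
#' @return Data frame with columns `volunteer`, `rcbf_regular`,
#'   `rcbf_adaptive`.
#' @export
cohort_rcbf_table <- function() extdata_csv("cohort_rcbf.csv")

#' Bundled blinded reader ratings
#'
#' Two neuroradiologists rated fixed-vs-adapted image pairs on a 3-point
#' scale (-1 original better, 0 equal, 1 modified better) in three
#' categories: amount of noise, visualization of cortical structures,
#' severity of artifacts.
#'
#' @return Long-format data frame with columns `case`, `reader`,
#'   `category`, `rating` (60 rows: 10 cases x 2 readers x 3 categories).
#' @export
reader_ratings_table <- function() extdata_csv("reader_ratings.csv")
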