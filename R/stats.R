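## Isoform length statistics and expression-timing classification.

#' One-sample Wilcoxon signed-rank test
#'
#' Tests whether `values` are symmetrically distributed around `reference`.
#' Zero differences are dropped (the Wilcoxon convention) and tied absolute
#' differences receive averaged ranks. For `n <= 25` informative differences
#' the null distribution of the positive-rank sum is computed exactly over
#' all 2^n sign assignments (via a generating-function convolution on doubled
#' ranks, which handles half-integer averaged ranks exactly); larger samples
#' use the normal approximation with continuity and tie corrections. The
#' P-value is two-sided.
#'
#' @param values Numeric vector (>= 1 value).
#' @param reference Null location.
#' @return List with `statistic` (positive-rank sum V), `p_value`, `n_used`
#'   (non-zero differences), `method` (`"exact"` or `"normal"`), and
#'   `all_zero` (TRUE when every difference is zero, in which case p = 1).
#' @export
wilcoxon_signed_rank <- function(values, reference = 0) {
  if (length(values) < 1) stop_meiutr("need at least one value")
  d <- values - reference
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, p_value = 1, n_used = 0L,
                method = "degenerate", all_zero = TRUE))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25) {
    w <- as.integer(round(2 * r))  # doubled ranks are integers even with ties
    # distribution of the doubled positive-rank sum over 2^n sign choices
    f <- c(1, numeric(sum(w)))
    for (wi in w) {
      shifted <- c(numeric(wi), f[seq_len(length(f) - wi)])
      f <- f + shifted
    }
    f <- f / 2^n
    v2 <- as.integer(round(2 * v))
    p_le <- sum(f[seq_len(v2 + 1L)])
    p_ge <- sum(f[(v2 + 1L):length(f)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal"
  }
  list(statistic = v, p_value = p, n_used = n, method = method, all_zero = FALSE)
}

#' Length summary of called mUTRs against a mitotic reference
#'
#' Computes the median, range and fold change of segment lengths for one side
#' relative to the published mitotic UTR median (68 bp for 5' UTRs, 91 bp for
#' 3' UTRs by default), plus a one-sample Wilcoxon signed-rank test of the
#' lengths against that reference. The fold change is reported to one
#' decimal, matching the conventional reporting precision.
#'
#' @param calls mUTR call tibble with `side` and `length` columns (e.g. from
#'   [call_mutrs()]), or any tibble with those columns.
#' @param side `"5p"` or `"3p"`.
#' @param reference_median Mitotic reference median length in bp; defaults to
#'   68 (5') / 91 (3').
#' @return One-row tibble: `side`, `n`, `median_bp`, `min_bp`, `max_bp`,
#'   `reference_median`, `fold_change`, `wilcoxon_stat`, `wilcoxon_p`.
#' @export
length_summary <- function(calls, side = c("5p", "3p"), reference_median = NULL) {
  side <- match.arg(side)
  reference_median <- reference_median %||% c("5p" = 68, "3p" = 91)[[side]]
  lengths <- calls$length[calls$side == side]
  if (length(lengths) == 0) stop_meiutr("no calls of side %s", side)
  wx <- wilcoxon_signed_rank(lengths, reference_median)
  tibble(
    side = side,
    n = length(lengths),
    median_bp = median(lengths),
    min_bp = min(lengths),
    max_bp = max(lengths),
    reference_median = reference_median,
    fold_change = round(median(lengths) / reference_median, 1),
    wilcoxon_stat = wx$statistic,
    wilcoxon_p = wx$p_value
  )
}

#' Classify expression timing of sporulation-induced rows
#'
#' Assigns early/middle/late classes from the diploid SPII 1-12 h profile:
#' the peak hour is the argmax (smallest hour on ties) and the class follows
#' the staggered meiotic induction windows — early for peaks at 1-4 h, middle
#' 5-8 h, late 9-12 h (boundaries configurable). The score is the peak value
#' minus the median SPII value; a zero score marks a flat, low-confidence
#' profile.
#'
#' @param expr An [expression_set()] with diploid SPII 1-12 h samples.
#' @param ids Row ids to classify (default: all rows).
#' @param boundaries Inclusive upper hour of the early and middle windows.
#' @return Tibble `segment_id`, `class`, `peak_spii_hour`, `score`,
#'   `low_confidence`.
#' @export
classify_timing <- function(expr, ids = NULL, boundaries = c(early = 4, middle = 8)) {
  samples <- expr$samples
  spii <- samples$strain == "MATa/alpha" & samples$medium == "SPII"
  if (!setequal(unique(samples$timepoint[spii]), 1:12)) {
    stop_meiutr("SPII 1-12 h diploid samples required for timing classification")
  }
  values <- expr$values
  if (!is.null(ids)) {
    absent <- setdiff(ids, values$id)
    if (length(absent)) stop_meiutr("expression rows missing: %s", paste(absent, collapse = ","))
    values <- values[match(ids, values$id), ]
  }
  m <- as.matrix(values[, samples$id[spii], drop = FALSE])
  hour <- samples$timepoint[spii]
  # average replicates per hour, order 1..12
  prof <- t(apply(m, 1, function(v) tapply(v, factor(hour, levels = 1:12), mean)))
  peak <- apply(prof, 1, which.max)  # smallest hour on ties
  score <- prof[cbind(seq_len(nrow(prof)), peak)] - apply(prof, 1, median)
  tibble(
    segment_id = values$id,
    class = dplyr::case_when(
      peak <= boundaries[["early"]] ~ "early",
      peak <= boundaries[["middle"]] ~ "middle",
      TRUE ~ "late"
    ),
    peak_spii_hour = as.integer(peak),
    score = as.numeric(score),
    low_confidence = score <= 0
  )
}

#' Percentage reporter for motif-containing fractions
#'
#' Reports `n_with / n_total` as a whole-number percentage, the convention
#' used when quoting the fraction of UTRs containing a motif (e.g. 21 of 92
#' is reported as 23%).
#'
#' @param n_with,n_total Counts with `0 <= n_with <= n_total`, `n_total > 0`.
#' @return Integer percentage.
#' @export
motif_percent <- function(n_with, n_total) {
  if (any(n_total <= 0) || any(n_with < 0) || any(n_with > n_total)) {
    stop_meiutr("need 0 <= n_with <= n_total with n_total > 0")
  }
  as.integer(round(100 * n_with / n_total))
}
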