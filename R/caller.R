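## The mUTR annotation procedure: filter unannotated segments, keep those
## expressed above background only in sporulating cells, assign them to an
## adjacent ORF (< 100 bp from the TSS or terminator), and select segments
## whose expression does NOT correlate significantly with the cognate ORF
## across the averaged YPD/YPA/SPII condition profile (Pearson cc on 14
## values, t with 12 df, Benjamini-Hochberg adjusted, keep p_adjusted > alpha).

#' Configuration for the mUTR caller
#'
#' @param tau Log2 background threshold; a value counts as expressed when
#'   strictly above `tau`.
#' @param max_gap Maximal distance (bp, exclusive) between a segment and the
#'   TSS/terminator anchor of its cognate ORF.
#' @param min_spii_timepoints_above_tau Minimum number of diploid SPII samples
#'   above `tau` for a segment to count as sporulation-specific; guards
#'   against single-sample noise.
#' @param alpha Adjusted-P threshold: candidates are *selected* when their
#'   adjusted correlation P-value exceeds `alpha` (non-significant
#'   correlation with the cognate ORF).
#' @param require_orf_expressed_in Which mitotic growth condition the cognate
#'   ORF must be expressed in: `"either"` (YPD or YPA), `"YPD"` or `"YPA"`.
#' @param overlap_tolerance Same-strand overlap (bp) with an annotated feature
#'   tolerated before a segment is discarded; 0 means any overlap excludes.
#' @return A `caller_config` list.
#' @export
caller_config <- function(tau = 6, max_gap = 100L,
                          min_spii_timepoints_above_tau = 2L,
                          alpha = 0.05,
                          require_orf_expressed_in = c("either", "YPD", "YPA"),
                          overlap_tolerance = 0L) {
  require_orf_expressed_in <- match.arg(require_orf_expressed_in)
  if (max_gap <= 0) stop_meiutr("max_gap must be > 0")
  if (alpha <= 0 || alpha > 1) stop_meiutr("alpha must be in (0,1]")
  structure(list(tau = tau, max_gap = as.integer(max_gap),
                 min_spii_timepoints_above_tau = as.integer(min_spii_timepoints_above_tau),
                 alpha = alpha,
                 require_orf_expressed_in = require_orf_expressed_in,
                 overlap_tolerance = as.integer(overlap_tolerance)),
            class = "caller_config")
}

as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand
  )
}

#' Drop segments overlapping annotated features
#'
#' Removes segments with same-strand overlap (beyond `overlap_tolerance` bp)
#' with any known-class feature: protein-coding genes, snoRNAs, rRNAs, tRNAs,
#' SUTs, CUTs or MUTs. Opposite-strand overlap never excludes. Features of
#' class `"other"` are ignored.
#'
#' @param segments Segment tibble.
#' @param genes Annotation tibble (see [read_annotation()]).
#' @param cfg A [caller_config()].
#' @return The retained subset of `segments`.
#' @export
filter_unannotated <- function(segments, genes, cfg = caller_config()) {
  if (nrow(segments) == 0) return(segments)
  genes <- filter(genes, .data$class %in% KNOWN_CLASSES)
  if (nrow(genes) == 0) return(segments)
  hits <- GenomicRanges::findOverlaps(
    as_granges0(segments), as_granges0(genes),
    minoverlap = cfg$overlap_tolerance + 1L,
    ignore.strand = FALSE
  )
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop)) segments[-drop, ] else segments
}

#' Flag sporulation-specific expression rows
#'
#' A row is sporulation-specific when its value is strictly above `tau` in at
#' least `min_spii_timepoints_above_tau` diploid (MATa/alpha) SPII samples AND
#' at or below `tau` in every mitotic sample (the MATa synchronized course,
#' diploid YPD and YPA) and every MATalpha/alpha starvation control.
#'
#' @param expr An [expression_set()] covering the full sample design.
#' @param cfg A [caller_config()].
#' @param ids Row ids to evaluate (default: all rows).
#' @return Tibble with `id`, `n_spii_above` and logical `sporulation_specific`.
#' @export
sporulation_specific <- function(expr, cfg = caller_config(), ids = NULL) {
  samples <- expr$samples
  cls <- sample_classes(samples)
  need <- c("mitotic_sync", "dip_ypd", "dip_ypa", "dip_spii", "alpha_control")
  missing <- setdiff(need, unique(cls))
  if (length(missing)) {
    stop_meiutr("sample design incomplete; missing classes: %s",
                paste(missing, collapse = ", "))
  }
  values <- expr$values
  if (!is.null(ids)) {
    absent <- setdiff(ids, values$id)
    if (length(absent)) stop_meiutr("expression rows missing: %s", paste(absent, collapse = ","))
    values <- values[match(ids, values$id), ]
  }
  m <- as.matrix(values[, samples$id, drop = FALSE])
  spii <- cls == "dip_spii"
  n_above <- rowSums(m[, spii, drop = FALSE] > cfg$tau)
  clean <- rowSums(m[, !spii, drop = FALSE] > cfg$tau) == 0
  tibble(id = values$id,
         n_spii_above = as.integer(n_above),
         sporulation_specific = n_above >= cfg$min_spii_timepoints_above_tau & clean)
}

# Candidate (gene, side, gap) combinations for one segment against
# same-chromosome, same-strand ORFs. The gap counts bases strictly between
# the segment boundary and the anchor; a segment abutting or overlapping the
# anchor has gap 0 provided it does not extend past the opposite ORF boundary.
candidate_assignments <- function(seg, genes) {
  g <- filter(genes, .data$class == "ORF",
              .data$chrom == seg$chrom, .data$strand == seg$strand)
  if (nrow(g) == 0) return(NULL)
  plus <- g$strand == "+"
  cand5 <- tibble(
    gene_id = g$gene_id, side = "5p",
    gap = ifelse(plus, g$tss - seg$end, seg$start - g$tss),
    on_side = ifelse(plus, seg$start < g$tss, seg$end > g$tss),
    within = ifelse(plus, seg$end <= g$end, seg$start >= g$start)
  )
  cand3 <- tibble(
    gene_id = g$gene_id, side = "3p",
    gap = ifelse(plus, seg$start - g$terminator, g$terminator - seg$end),
    on_side = ifelse(plus, seg$end > g$terminator, seg$start < g$terminator),
    within = ifelse(plus, seg$start >= g$start, seg$end <= g$end)
  )
  cand <- bind_rows(cand5, cand3) |>
    mutate(gap = pmax(0L, as.integer(.data$gap))) |>
    filter(.data$on_side, .data$within)
  cand
}

#' Assign segments to cognate genes by anchor proximity
#'
#' A segment qualifies as a potential 5' UTR of a same-strand gene when it
#' lies on the gene-upstream side of the TSS at a gap below `max_gap`, and as
#' a potential 3' UTR when it lies downstream of the terminator likewise.
#' Among multiple qualifying genes the smallest gap wins; ties are broken by
#' lexicographic gene id, then 5' before 3'.
#'
#' @param segments Segment tibble.
#' @param genes Annotation tibble.
#' @param cfg A [caller_config()].
#' @return Tibble `segment_id`, `gene_id`, `side` (`"5p"`/`"3p"`), `gap`;
#'   unassignable segments are absent.
#' @export
assign_to_gene <- function(segments, genes, cfg = caller_config()) {
  out <- purrr::map(seq_len(nrow(segments)), function(i) {
    seg <- segments[i, ]
    cand <- candidate_assignments(seg, genes)
    if (is.null(cand)) return(NULL)
    cand <- filter(cand, .data$gap < cfg$max_gap)
    if (nrow(cand) == 0) return(NULL)
    cand <- arrange(cand, .data$gap, .data$gene_id, dplyr::desc(.data$side))
    tibble(segment_id = seg$segment_id,
           gene_id = cand$gene_id[1], side = cand$side[1], gap = cand$gap[1])
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(segment_id = character(), gene_id = character(),
                  side = character(), gap = integer()))
  }
  out
}

#' Correlate segment and ORF expression over the condition design
#'
#' Pearson product-moment correlation over the 14 averaged condition values
#' (YPD, YPA, SPII 1-12 h of the MATa/alpha diploid). Under the null the
#' statistic `t = cc * sqrt(df / (1 - cc^2))` follows a t distribution with
#' `df = 12`; the two-sided tail gives the raw P-value. A zero-variance row
#' makes cc undefined; such pairs are reported as cc = 0 with p = 1 and
#' flagged `degenerate`.
#'
#' @param pairs Tibble with columns `segment_id`, `gene_id`.
#' @param expr An [expression_set()].
#' @return `pairs` with `cc`, `n`, `df`, `t_stat`, `p_raw`, `degenerate`.
#' @export
correlate_expression <- function(pairs, expr) {
  if (nrow(pairs) == 0) {
    return(mutate(pairs, cc = numeric(0), n = integer(0), df = integer(0),
                  t_stat = numeric(0), p_raw = numeric(0), degenerate = logical(0)))
  }
  prof <- condition_profile(expr, unique(c(pairs$segment_id, pairs$gene_id)))
  n <- ncol(prof)
  if (n != 14) stop_meiutr("correlation design contract violated: %d conditions, expected 14", n)
  df <- n - 2L
  res <- purrr::map(seq_len(nrow(pairs)), function(i) {
    x <- prof[pairs$segment_id[i], ]
    y <- prof[pairs$gene_id[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(tibble(cc = 0, t_stat = 0, p_raw = 1, degenerate = TRUE))
    }
    cc <- cor(x, y)
    t_stat <- cc * sqrt(df / max(1 - cc^2, .Machine$double.eps))
    tibble(cc = cc, t_stat = t_stat,
           p_raw = 2 * pt(-abs(t_stat), df = df), degenerate = FALSE)
  })
  bind_cols(pairs, bind_rows(res)) |>
    mutate(n = n, df = df, .before = "t_stat")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of raw P-values in `[0, 1]`.
#' @return Adjusted P-values in the input order, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_meiutr("P-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

empty_calls <- function() {
  tibble(segment_id = character(), gene_id = character(), side = character(),
         gap = integer(), chrom = character(), strand = character(),
         start = integer(), end = integer(), length = integer(),
         cc = numeric(), n = integer(), df = integer(), t_stat = numeric(),
         p_raw = numeric(), p_adjusted = numeric(), degenerate = logical())
}

#' Call meiotic UTR extensions from expression segments
#'
#' Runs the full annotation procedure: (1) discard segments overlapping
#' annotated features; (2) keep segments expressed above background only in
#' sporulating diploid samples; (3) assign each survivor to a cognate ORF
#' within `max_gap` of its TSS (5') or terminator (3'), requiring the ORF to
#' be expressed in mitotic growth; (4) correlate each candidate with its ORF
#' over the 14 averaged conditions; (5) adjust all candidate P-values jointly
#' (Benjamini-Hochberg) and select candidates with `p_adjusted > alpha`, i.e.
#' segments *not* significantly correlated with their ORF. Selection by
#' non-significance inherits the procedure's known weakness (low power favours
#' selection); degenerate zero-variance correlations are flagged.
#'
#' @param segments Segment tibble.
#' @param genes Annotation tibble.
#' @param expr An [expression_set()] covering the full sample design.
#' @param cfg A [caller_config()].
#' @return A tibble of class `mutr_calls` (one row per called mUTR with
#'   coordinates, gap, correlation statistics and adjusted P), carrying the
#'   full candidate report in `attr(, "report")` with a per-candidate
#'   `status` column.
#' @export
call_mutrs <- function(segments, genes, expr, cfg = caller_config()) {
  finish <- function(calls, report) {
    calls <- arrange(calls, .data$chrom, .data$start, .data$segment_id)
    structure(calls, report = report, cfg = cfg,
              class = c("mutr_calls", class(calls)))
  }
  if (nrow(segments) == 0) return(finish(empty_calls(), empty_calls()))
  filt <- filter_unannotated(segments, genes, cfg)
  if (nrow(filt) == 0) return(finish(empty_calls(), empty_calls()))
  spor <- sporulation_specific(expr, cfg, ids = filt$segment_id)
  keep <- filt[spor$sporulation_specific[match(filt$segment_id, spor$id)], ]
  if (nrow(keep) == 0) return(finish(empty_calls(), empty_calls()))
  assigned <- assign_to_gene(keep, genes, cfg)
  if (nrow(assigned) == 0) return(finish(empty_calls(), empty_calls()))

  # cognate ORF must itself be expressed during mitotic growth
  prof <- condition_profile(expr, unique(assigned$gene_id))
  orf_ok <- switch(cfg$require_orf_expressed_in,
    either = prof[, "YPD"] > cfg$tau | prof[, "YPA"] > cfg$tau,
    YPD = prof[, "YPD"] > cfg$tau,
    YPA = prof[, "YPA"] > cfg$tau)
  assigned <- assigned[orf_ok[assigned$gene_id], ]
  if (nrow(assigned) == 0) return(finish(empty_calls(), empty_calls()))

  cand <- correlate_expression(assigned, expr) |>
    mutate(p_adjusted = bh_adjust(.data$p_raw))
  cand <- left_join(cand,
                    select(segments, "segment_id", "chrom", "strand", "start", "end"),
                    by = "segment_id") |>
    mutate(length = .data$end - .data$start,
           status = ifelse(.data$p_adjusted > cfg$alpha, "called", "correlated"))
  calls <- cand |>
    filter(.data$status == "called") |>
    select("segment_id", "gene_id", "side", "gap", "chrom", "strand",
           "start", "end", "length", "cc", "n", "df", "t_stat",
           "p_raw", "p_adjusted", "degenerate")
  finish(calls, cand)
}

#' @export
print.mutr_calls <- function(x, ...) {
  cat(sprintf("<mutr_calls> %d called (%d 5', %d 3') of %d candidates\n",
              nrow(x), sum(x$side == "5p"), sum(x$side == "3p"),
              nrow(attr(x, "report"))))
  NextMethod()
}

#' Candidate-level report for a set of mUTR calls
#'
#' @param x An object of class `mutr_calls`.
#' @param ... Unused.
#' @return One row per correlated candidate (called or rejected), with
#'   coordinates, correlation statistics and a `status` column.
#' @method tidy mutr_calls
#' @export
tidy.mutr_calls <- function(x, ...) {
  as_tibble(attr(x, "report"))
}

#' One-row summary of a set of mUTR calls
#'
#' @param x An object of class `mutr_calls`.
#' @param ... Unused.
#' @method glance mutr_calls
#' @export
glance.mutr_calls <- function(x, ...) {
  tibble(n_candidates = nrow(attr(x, "report")),
         n_called = nrow(x),
         n_5p = sum(x$side == "5p"),
         n_3p = sum(x$side == "3p"),
         n_degenerate = sum(x$degenerate))
}
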