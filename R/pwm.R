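## Information-weighted position weight matrix engine.
##
## Scoring follows the MATCH convention used throughout the TRANSFAC
## ecosystem: per-column frequencies f(i,b) (with pseudocount), information
## weights I(i) = sum_b f(i,b) ln(4 f(i,b)), window score
## S(w) = sum_i I(i) f(i, w_i), and min-max normalisation to the matrix score
## similarity MSS = (S - S_min)/(S_max - S_min). The core score similarity CSS
## is the same quantity restricted to the 5 consecutive most informative
## columns. The natural log is used; normalisation cancels the base.

new_pwm <- function(id, counts, pseudocount) {
  L <- ncol(counts)
  n <- colSums(counts)
  freq <- sweep(counts + pseudocount, 2, n + 4 * pseudocount, "/")
  # 0 * log(0) := 0 for pseudocount-free zero cells
  info <- apply(freq, 2, function(f) {
    terms <- ifelse(f > 0, f * log(4 * f), 0)
    sum(terms)
  })
  weights <- sweep(freq, 2, info, "*")
  core_len <- min(5L, L)
  core_sums <- vapply(seq_len(L - core_len + 1L),
                      function(i) sum(info[i:(i + core_len - 1L)]), numeric(1))
  core_start <- which.max(core_sums)  # leftmost on ties
  structure(
    list(id = id, length = L, counts = counts, freq = freq, info = info,
         weights = weights,
         col_min = apply(weights, 2, min),
         col_max = apply(weights, 2, max),
         core = seq.int(core_start, core_start + core_len - 1L),
         pseudocount = pseudocount),
    class = "meiutr_pwm"
  )
}

#' Build a position weight matrix from aligned binding sites
#'
#' Counts each base per column, applies a pseudocount, and derives
#' information weights and the 5-column core (the window of consecutive
#' columns with maximal summed information; leftmost on ties).
#'
#' @param sites Character vector of equal-length ACGT sequences (>= 1).
#' @param pseudocount Pseudocount added to every cell (default 0.25); avoids
#'   minus-infinite log weights for zero-count cells.
#' @param id Matrix identifier.
#' @return A `meiutr_pwm` object.
#' @export
build_pwm <- function(sites, pseudocount = 0.25, id = "pwm") {
  if (length(sites) < 1) stop_meiutr("need at least one binding site")
  sites <- toupper(sites)
  check_bases(sites, "binding site")
  L <- unique(nchar(sites))
  if (length(L) != 1) stop_meiutr("binding sites must have equal length")
  chars <- do.call(rbind, strsplit(sites, ""))
  counts <- vapply(seq_len(L), function(j) {
    tabulate(match(chars[, j], DNA_BASES), nbins = 4)
  }, numeric(4))
  rownames(counts) <- DNA_BASES
  new_pwm(id, counts, pseudocount)
}

#' Build a position weight matrix from a count matrix
#'
#' @param counts 4 x L numeric matrix with rows A,C,G,T (e.g. from
#'   [read_transfac()]); all counts >= 0 and each column sum > 0.
#' @inheritParams build_pwm
#' @return A `meiutr_pwm` object.
#' @export
pwm_from_counts <- function(counts, pseudocount = 0.25, id = "pwm") {
  if (!is.matrix(counts) || nrow(counts) != 4) stop_meiutr("counts must be a 4 x L matrix")
  if (is.null(rownames(counts))) rownames(counts) <- DNA_BASES
  counts <- counts[DNA_BASES, , drop = FALSE]
  if (any(counts < 0) || any(colSums(counts) <= 0)) {
    stop_meiutr("counts must be >= 0 with positive column sums")
  }
  new_pwm(id, counts, pseudocount)
}

#' The packaged synthetic URS1 matrix
#'
#' A consensus-derived stand-in for proprietary URS1 matrices: built from the
#' classical Ume6 target consensus TAGCCGCCGA with 7 observations of the
#' consensus base and 1 of every other base per column (a mildly degenerate
#' logo). With default scan thresholds, a single substitution outside the core
#' still passes while a core substitution does not. The same matrix ships as
#' `inst/extdata/urs1_synthetic.transfac`.
#'
#' @inheritParams build_pwm
#' @return A `meiutr_pwm` of length 10.
#' @export
urs1_pwm <- function(pseudocount = 0.25) {
  bases <- strsplit(URS1_CONSENSUS, "")[[1]]
  counts <- matrix(1, 4, length(bases), dimnames = list(DNA_BASES, NULL))
  counts[cbind(match(bases, DNA_BASES), seq_along(bases))] <- 7
  pwm_from_counts(counts, pseudocount = pseudocount, id = "URS1_synthetic")
}

#' @export
print.meiutr_pwm <- function(x, ...) {
  consensus <- paste(DNA_BASES[apply(x$freq, 2, which.max)], collapse = "")
  cat(sprintf("<meiutr_pwm> %s: length %d, core %d-%d, consensus %s\n",
              x$id, x$length, min(x$core), max(x$core), consensus))
  invisible(x)
}

#' @rdname tidy.meiutr_pwm
#' @method tidy meiutr_pwm
#' @export
tidy.meiutr_pwm <- function(x, ...) {
  tibble(
    motif = x$id,
    position = rep(seq_len(x$length), each = 4),
    base = rep(DNA_BASES, x$length),
    count = as.vector(x$counts),
    freq = as.vector(x$freq),
    info = rep(x$info, each = 4),
    core = rep(seq_len(x$length) %in% x$core, each = 4)
  )
}

#' Tidy a position weight matrix
#'
#' @param x A `meiutr_pwm`.
#' @param ... Unused.
#' @return One row per (position, base) with counts, frequencies, column
#'   information and core membership.
#' @name tidy.meiutr_pwm
NULL

word_index <- function(word) {
  idx <- match(strsplit(toupper(word), "")[[1]], DNA_BASES)
  if (anyNA(idx)) stop_meiutr("word contains non-ACGT characters: %s", word)
  idx
}

score_raw <- function(pwm, idx, positions) {
  sum(pwm$weights[cbind(idx[positions], positions)])
}

normalise_score <- function(s, smin, smax) {
  if (smax - smin <= 0) return(1)  # all-uniform matrix: every word is maximal
  (s - smin) / (smax - smin)
}

#' Score one sequence window against a PWM
#'
#' Returns the min-max-normalised matrix score similarity (MSS) over all
#' columns and the core score similarity (CSS) over the 5 most informative
#' consecutive columns; both lie in `[0, 1]`.
#'
#' @param pwm A `meiutr_pwm`.
#' @param word ACGT string of exactly the matrix length.
#' @return Named numeric vector `c(mss, css)`.
#' @export
score_window <- function(pwm, word) {
  idx <- word_index(word)
  if (length(idx) != pwm$length) {
    stop_meiutr("word length %d != matrix length %d", length(idx), pwm$length)
  }
  all_pos <- seq_len(pwm$length)
  mss <- normalise_score(score_raw(pwm, idx, all_pos),
                         sum(pwm$col_min), sum(pwm$col_max))
  css <- normalise_score(score_raw(pwm, idx, pwm$core),
                         sum(pwm$col_min[pwm$core]), sum(pwm$col_max[pwm$core]))
  c(mss = mss, css = css)
}

scan_one_strand <- function(pwm, seq, min_css, min_mss) {
  n <- nchar(seq)
  L <- pwm$length
  if (n < L) return(NULL)
  idx <- match(strsplit(seq, "")[[1]], DNA_BASES)
  if (anyNA(idx)) stop_meiutr("sequence contains non-ACGT characters")
  n_win <- n - L + 1L
  # L x n_win matrix of weighted frequencies, summed per window
  s <- numeric(n_win)
  for (i in seq_len(L)) {
    s <- s + pwm$weights[cbind(idx[i:(i + n_win - 1L)], i)]
  }
  sc <- numeric(n_win)
  for (i in pwm$core) {
    sc <- sc + pwm$weights[cbind(idx[i:(i + n_win - 1L)], i)]
  }
  rng_all <- c(sum(pwm$col_min), sum(pwm$col_max))
  rng_core <- c(sum(pwm$col_min[pwm$core]), sum(pwm$col_max[pwm$core]))
  mss <- vapply(s, normalise_score, numeric(1), rng_all[1], rng_all[2])
  css <- vapply(sc, normalise_score, numeric(1), rng_core[1], rng_core[2])
  keep <- css >= min_css & mss >= min_mss
  if (!any(keep)) return(NULL)
  off <- which(keep) - 1L
  tibble(offset = off,
         word = substring(seq, off + 1L, off + L),
         mss = mss[keep], css = css[keep])
}

#' Scan sequences for motif matches on both strands
#'
#' Evaluates every window of the forward sequence and of its reverse
#' complement; a hit requires `css >= min_css` and `mss >= min_mss` (the
#' conventional URS1 cut-offs of 0.9 and 0.7 are the defaults). Minus-strand
#' hits are reported at their forward-strand offset. Hits are ordered by
#' sequence, then offset, then strand (`+` before `-`).
#'
#' @param pwm A `meiutr_pwm`.
#' @param seqs Named character vector of ACGT sequences (or a tibble with
#'   columns `seq_id` and `seq`, or a [Biostrings::DNAStringSet]).
#' @param min_css,min_mss Core / matrix score similarity thresholds.
#' @return Tibble with columns `seq_id`, `offset` (0-based, forward
#'   coordinates), `strand`, `word` (as matched, i.e. reverse-complemented for
#'   minus-strand hits), `mss`, `css`.
#' @export
scan_pwm <- function(pwm, seqs, min_css = 0.9, min_mss = 0.7) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- setNames(as.character(seqs), names(seqs))
  if (is.data.frame(seqs)) seqs <- setNames(seqs$seq, seqs$seq_id)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%03d", seq_along(seqs))
  hits <- purrr::imap(seqs, function(s, id) {
    s <- toupper(s)
    n <- nchar(s)
    fwd <- scan_one_strand(pwm, s, min_css, min_mss)
    out <- list()
    if (!is.null(fwd)) out$f <- mutate(fwd, strand = "+")
    if (n >= pwm$length) {
      rev <- scan_one_strand(pwm, revcomp(s), min_css, min_mss)
      if (!is.null(rev)) {
        rev$offset <- n - pwm$length - rev$offset
        out$r <- mutate(rev, strand = "-")
      }
    }
    if (!length(out)) return(NULL)
    mutate(bind_rows(out), seq_id = id)
  })
  hits <- bind_rows(hits)
  if (nrow(hits) == 0) {
    return(tibble(seq_id = character(), offset = integer(), strand = character(),
                  word = character(), mss = numeric(), css = numeric()))
  }
  hits |>
    select("seq_id", "offset", "strand", "word", "mss", "css") |>
    arrange(.data$seq_id, .data$offset, .data$strand)
}
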