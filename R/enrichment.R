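## Motif enrichment of a target promoter set against the background of
## cognate-ORF promoters: a likelihood-ratio permutation statistic and a
## count-based one-sided exact test.

new_enrichment <- function(motif, statistic_observed, null_mean, null_sd,
                           n_permutations, p_value, method,
                           target_n, background_n,
                           target_hits = NA_integer_, background_hits = NA_integer_,
                           flags = character(0)) {
  structure(
    list(motif = motif, statistic_observed = statistic_observed,
         null_mean = null_mean, null_sd = null_sd,
         n_permutations = n_permutations, p_value = p_value, method = method,
         target_n = target_n, background_n = background_n,
         target_hits = target_hits, background_hits = background_hits,
         flags = flags),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %s (%s): p = %.4g (targets %d vs background %d)\n",
              x$motif, x$method, x$p_value, x$target_n, x$background_n))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(motif = x$motif, method = x$method,
         statistic_observed = x$statistic_observed,
         null_mean = x$null_mean, null_sd = x$null_sd,
         n_permutations = x$n_permutations, p_value = x$p_value,
         target_n = x$target_n, background_n = x$background_n,
         target_hits = x$target_hits, background_hits = x$background_hits)
}

#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(motif = x$motif, method = x$method, p_value = x$p_value,
         enriched_at_0.01 = x$p_value <= 0.01)
}

#' Exact count-based motif enrichment
#'
#' One-sided hypergeometric test for over-representation of motif-containing
#' sequences in the target set relative to the background set.
#'
#' @param target_hits,target_n Motif-containing and total target sequences.
#' @param background_hits,background_n Likewise for the background.
#' @param motif Motif identifier for reporting.
#' @return An `enrichment_result` with `method = "fisher"`.
#' @export
fisher_enrichment <- function(target_hits, target_n, background_hits, background_n,
                              motif = "motif") {
  counts <- c(target_hits, target_n, background_hits, background_n)
  if (any(counts < 0)) stop_meiutr("counts must be >= 0")
  if (target_hits > target_n || background_hits > background_n) {
    stop_meiutr("hits cannot exceed sequence counts")
  }
  white <- target_hits + background_hits
  black <- (target_n - target_hits) + (background_n - background_hits)
  p <- phyper(target_hits - 1, white, black, target_n, lower.tail = FALSE)
  new_enrichment(motif, statistic_observed = target_hits / max(target_n, 1),
                 null_mean = white * target_n / max(white + black, 1), null_sd = NA_real_,
                 n_permutations = 0L, p_value = p, method = "fisher",
                 target_n = target_n, background_n = background_n,
                 target_hits = as.integer(target_hits),
                 background_hits = as.integer(background_hits))
}

#' Per-sequence likelihood-ratio motif score
#'
#' For each sequence, the mean over all windows on both strands of the
#' likelihood ratio `prod_i f(i, w_i) / bg(w_i)` of the motif model against
#' an i.i.d. background (uniform 0.25 per base by default). Sequences shorter
#' than the motif score 0.
#'
#' @param pwm A `meiutr_pwm`.
#' @param seqs Character vector of ACGT sequences.
#' @param background Length-4 base frequencies (A,C,G,T) of the null model.
#' @return Numeric vector of per-sequence scores.
#' @export
sequence_scores <- function(pwm, seqs, background = rep(0.25, 4)) {
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-8) {
    stop_meiutr("background must be 4 base frequencies summing to 1")
  }
  log_lr <- log(pwm$freq) - log(background)  # 4 x L
  L <- pwm$length
  vapply(toupper(seqs), function(s) {
    n <- nchar(s)
    if (n < L) return(0)
    idx <- match(strsplit(s, "")[[1]], DNA_BASES)
    if (anyNA(idx)) stop_meiutr("sequence contains non-ACGT characters")
    ridx <- rev(5L - idx)  # reverse complement indices
    n_win <- n - L + 1L
    acc <- numeric(n_win); racc <- numeric(n_win)
    for (i in seq_len(L)) {
      acc <- acc + log_lr[cbind(idx[i:(i + n_win - 1L)], i)]
      racc <- racc + log_lr[cbind(ridx[i:(i + n_win - 1L)], i)]
    }
    mean(c(exp(acc), exp(racc)))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Permutation test of motif enrichment against a background set
#'
#' The observed statistic is the mean per-sequence likelihood-ratio score
#' (see [sequence_scores()]) over the target set. The null is built by
#' recomputing that statistic on `n_perm` random target-size subsets of the
#' background (drawn without replacement when the background is large enough,
#' otherwise with replacement, flagged). The P-value uses the add-one rule
#' `p = (1 + #(null >= observed)) / (1 + n_perm)`, so it is never exactly 0.
#' Deterministic given `seed`.
#'
#' @param pwm A `meiutr_pwm`.
#' @param target_seqs,background_seqs Non-empty character vectors of ACGT
#'   sequences (e.g. 100-bp promoter windows).
#' @param n_perm Number of permutations (>= 1; 999 by default).
#' @param seed Integer seed for the permutation draws.
#' @param background Base frequencies of the scoring null model.
#' @return An `enrichment_result` with `method = "permutation"`; sequence hit
#'   counts at the conventional scan thresholds are included for reporting.
#' @export
permutation_enrichment <- function(pwm, target_seqs, background_seqs,
                                   n_perm = 999, seed = 1L,
                                   background = rep(0.25, 4)) {
  if (length(target_seqs) == 0 || length(background_seqs) == 0) {
    stop_meiutr("target and background sets must be non-empty")
  }
  if (n_perm < 1) stop_meiutr("n_perm must be >= 1")
  t_scores <- sequence_scores(pwm, target_seqs, background)
  b_scores <- sequence_scores(pwm, background_seqs, background)
  observed <- mean(t_scores)
  nt <- length(target_seqs); nb <- length(background_seqs)
  flags <- character(0)
  replace <- nb < nt
  if (replace) flags <- "background_smaller_than_target_sampled_with_replacement"
  null <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      mean(b_scores[sample.int(nb, nt, replace = replace)])
    }, numeric(1))
  })
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  hits <- function(seqs) {
    h <- scan_pwm(pwm, setNames(seqs, sprintf("s%06d", seq_along(seqs))))
    length(unique(h$seq_id))
  }
  new_enrichment(pwm$id, statistic_observed = observed,
                 null_mean = mean(null), null_sd = stats::sd(null),
                 n_permutations = as.integer(n_perm), p_value = p,
                 method = "permutation", target_n = nt, background_n = nb,
                 target_hits = hits(target_seqs),
                 background_hits = hits(background_seqs), flags = flags)
}

#' Null-distribution plot for a permutation enrichment result
#'
#' @param object An `enrichment_result` from [permutation_enrichment()].
#' @param ... Unused.
#' @return A ggplot: the null mean/sd band and the observed statistic.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- tibble(x = c(object$null_mean - object$null_sd,
                     object$null_mean + object$null_sd))
  ggplot2::ggplot() +
    ggplot2::geom_rect(ggplot2::aes(xmin = df$x[1], xmax = df$x[2],
                                    ymin = 0, ymax = 1), alpha = 0.3) +
    ggplot2::geom_vline(xintercept = object$null_mean, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$statistic_observed, colour = "red") +
    ggplot2::labs(x = "mean likelihood-ratio score",
                  title = sprintf("%s: observed vs permutation null (p = %.3g)",
                                  object$motif, object$p_value)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.title.y = ggplot2::element_blank())
}
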