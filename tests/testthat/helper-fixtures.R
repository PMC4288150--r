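# Shared fixtures: a small simulated dataset reused across test files, plus
# independent oracle implementations kept deliberately naive.

small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_chromosomes = 1, chrom_length = 60000,
             n_genes = 18, n_planted_5p_mutrs = 5, n_planted_3p_mutrs = 4,
             n_decoy_segments = 8, ...)
}

shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(small_cfg())
    cache
  }
})

# Brute-force Benjamini-Hochberg step-up: adj_i = min over j with p_j >= p_i
# (in sorted order) of m * p_(j) / j, capped at 1.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min(m * ranked[i:m] / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive signed-rank null: enumerate all 2^n sign assignments.
wilcoxon_brute <- function(values, reference) {
  d <- values - reference
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  list(statistic = v_obs, p_value = min(1, 2 * min(p_le, p_ge)))
}

# Direct evaluation of the information-weighted similarity scores.
mss_css_naive <- function(pwm, word) {
  idx <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
  score <- function(pos) {
    s <- sum(sapply(pos, function(i) pwm$info[i] * pwm$freq[idx[i], i]))
    smin <- sum(sapply(pos, function(i) min(pwm$info[i] * pwm$freq[, i])))
    smax <- sum(sapply(pos, function(i) max(pwm$info[i] * pwm$freq[, i])))
    if (smax - smin <= 0) 1 else (s - smin) / (smax - smin)
  }
  c(mss = score(seq_len(pwm$length)), css = score(pwm$core))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}
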