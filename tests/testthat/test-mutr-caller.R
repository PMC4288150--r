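# Toy annotation used by filtering/assignment tests: one + strand gene with
# TSS 1000 and a tRNA on the opposite strand.
toy_genes <- function() {
  tibble::tibble(
    gene_id = c("geneA", "trna1"),
    chrom = "chr1", strand = c("+", "-"),
    start = c(1000L, 500L), end = c(2000L, 580L),
    tss = c(1000L, 580L), terminator = c(2000L, 500L),
    class = c("ORF", "tRNA"))
}

test_that("annotation filtering is strand-aware with zero-overlap default", {
  segs <- tibble::tibble(
    segment_id = c("inside_orf", "opp_strand_trna", "same_strand_trna", "clear"),
    chrom = "chr1",
    strand = c("+", "+", "-", "+"),
    start = c(1200L, 510L, 510L, 3000L),
    end = c(1300L, 560L, 560L, 3100L))
  kept <- filter_unannotated(segs, toy_genes())
  expect_setequal(kept$segment_id, c("opp_strand_trna", "clear"))

  # no annotation features -> everything retained
  expect_equal(filter_unannotated(segs, toy_genes()[0, ]), segs)
  expect_equal(nrow(filter_unannotated(segs[0, ], toy_genes())), 0)
})

test_that("sporulation specificity applies the strict-threshold boundary rules", {
  samples <- sample_design()
  tau <- 6
  base <- rep(4, nrow(samples))
  mk <- function(...) {
    v <- base
    mods <- list(...)
    for (id in names(mods)) v[samples$id == id] <- mods[[id]]
    v
  }
  rows <- rbind(
    ok = mk(dip_spii_04h = 9, dip_spii_05h = 9),
    leaky = mk(dip_spii_04h = 9, dip_spii_05h = 9, dip_ypd = 9),
    boundary = rep(tau, nrow(samples)),          # equality everywhere: not above
    single = mk(dip_spii_04h = 9),               # only one SPII point above
    alpha_leak = mk(dip_spii_04h = 9, dip_spii_05h = 9, alpha_spii_08h = 9))
  values <- tibble::tibble(id = rownames(rows)) |>
    dplyr::bind_cols(tibble::as_tibble(stats::setNames(as.data.frame(rows), samples$id)))
  expr <- expression_set(values, samples)
  res <- sporulation_specific(expr, caller_config(tau = tau))
  expect_equal(res$sporulation_specific,
               c(TRUE, FALSE, FALSE, FALSE, FALSE), ignore_attr = TRUE)

  # missing sample classes fail loudly
  sub <- samples[samples$strain != "MATalpha/alpha", ]
  expr2 <- expression_set(values[c("id", sub$id)], sub)
  expect_error(sporulation_specific(expr2), "alpha_control")
})

test_that("gene assignment follows the gap convention and tie-breaks", {
  genes <- toy_genes()
  seg <- function(id, start, end, strand = "+") {
    tibble::tibble(segment_id = id, chrom = "chr1", strand = strand,
                   start = as.integer(start), end = as.integer(end))
  }
  # worked example: TSS 1000, segment [920, 995) -> 5p at gap 5
  a <- assign_to_gene(seg("s", 920, 995), genes)
  expect_equal(a$gene_id, "geneA")
  expect_equal(a$side, "5p")
  expect_equal(a$gap, 5L)

  # 150 bp away -> no assignment
  expect_equal(nrow(assign_to_gene(seg("s", 700, 850), genes)), 0)

  # abutting and TSS-overlapping segments get gap 0
  expect_equal(assign_to_gene(seg("s", 900, 1000), genes)$gap, 0L)
  expect_equal(assign_to_gene(seg("s", 900, 1050), genes)$gap, 0L)
  # ... but a segment extending past the opposite ORF boundary does not qualify
  expect_equal(nrow(assign_to_gene(seg("s", 900, 2100), genes)), 0)

  # downstream segment -> 3p off the terminator
  b <- assign_to_gene(seg("s", 2010, 2100), genes)
  expect_equal(b$side, "3p")
  expect_equal(b$gap, 10L)

  # two qualifying genes: smallest gap wins
  genes2 <- dplyr::bind_rows(
    toy_genes()[1, ],
    dplyr::mutate(toy_genes()[1, ], gene_id = "geneB", start = 600L, end = 900L,
                  tss = 600L, terminator = 900L))
  two <- assign_to_gene(seg("s", 930, 960), genes2)
  expect_equal(two$gene_id, "geneB")   # 3p gap 30 beats 5p gap 40
  expect_equal(two$side, "3p")

  # equal gaps: lexicographic gene id
  genes3 <- dplyr::bind_rows(
    toy_genes()[1, ],
    dplyr::mutate(toy_genes()[1, ], gene_id = "geneAB", start = 800L, end = 900L,
                  tss = 800L, terminator = 900L))
  tie <- assign_to_gene(seg("s", 910, 990), genes3)
  expect_equal(tie$gap, 10L)
  expect_equal(tie$gene_id, "geneA")
})

test_that("correlation matches the closed-form t-tail with 12 df", {
  sim <- shared_sim()
  pairs <- tibble::tibble(
    segment_id = sim$truth$segment_id[sim$truth$role == "planted"][1:4],
    gene_id = sim$truth$gene_id[sim$truth$role == "planted"][1:4])
  res <- correlate_expression(pairs, sim$expr)
  expect_true(all(res$n == 14))
  expect_true(all(res$df == 12))
  prof <- meiutr:::condition_profile(sim$expr, unique(unlist(pairs)))
  for (i in seq_len(nrow(res))) {
    cc <- cor(prof[pairs$segment_id[i], ], prof[pairs$gene_id[i], ])
    t_oracle <- cc * sqrt(12 / (1 - cc^2))
    p_oracle <- 2 * (1 - pt(abs(t_oracle), df = 12))
    expect_equal(res$cc[i], cc, tolerance = 1e-12)
    expect_equal(res$p_raw[i], p_oracle, tolerance = 1e-12)
  }

  # identical non-constant rows: cc = 1, p -> 0
  seg1 <- pairs$segment_id[1]
  self <- correlate_expression(
    tibble::tibble(segment_id = seg1, gene_id = seg1), sim$expr)
  expect_equal(self$cc, 1)
  expect_lt(self$p_raw, 1e-12)

  # degenerate constant row -> cc 0, p 1, flagged
  vals <- sim$expr$values
  vals[1, -1] <- 5
  flat <- expression_set(vals, sim$expr$samples)
  deg <- correlate_expression(
    tibble::tibble(segment_id = vals$id[1], gene_id = pairs$gene_id[1]), flat)
  expect_true(deg$degenerate)
  expect_equal(deg$cc, 0)
  expect_equal(deg$p_raw, 1)
})

test_that("BH adjustment equals the brute-force step-up on short vectors", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               bh_brute(c(0.01, 0.02, 0.03, 0.04)))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(42)
  for (n in 1:6) {
    for (rep in 1:50) {
      p <- runif(n)
      expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
    }
  }
})

test_that("the full caller recovers planted truth and rejects decoys", {
  sim <- shared_sim()
  cfg <- caller_config(tau = small_cfg()$background_threshold_tau)
  calls <- call_mutrs(sim$segments, sim$genes, sim$expr, cfg)
  planted <- dplyr::filter(sim$truth, role == "planted")
  expect_gte(mean(planted$segment_id %in% calls$segment_id), 0.8)
  decoys <- sim$truth$segment_id[sim$truth$role != "planted"]
  expect_false(any(decoys %in% calls$segment_id))
  hit <- dplyr::inner_join(as_tibble(calls), planted,
                           by = "segment_id", suffix = c("", ".truth"))
  expect_equal(hit$gene_id, hit$gene_id.truth)
  expect_equal(hit$side, hit$side.truth)
  expect_true(all(calls$gap < cfg$max_gap))
  expect_true(all(calls$p_adjusted > cfg$alpha))

  # empty input and boundary alpha semantics (p_adjusted > 1 is impossible)
  expect_equal(nrow(call_mutrs(sim$segments[0, ], sim$genes, sim$expr, cfg)), 0)
  cfg1 <- caller_config(tau = cfg$tau, alpha = 1)
  expect_equal(nrow(call_mutrs(sim$segments, sim$genes, sim$expr, cfg1)), 0)

  # permutation invariance of the input segment order (calls compared after
  # stripping the order-dependent candidate report)
  strip <- function(x) {
    attr(x, "report") <- NULL
    attr(x, "cfg") <- NULL
    as.data.frame(x)
  }
  shuffled <- sim$segments[rev(seq_len(nrow(sim$segments))), ]
  calls2 <- call_mutrs(shuffled, sim$genes, sim$expr, cfg)
  expect_equal(strip(calls2), strip(calls))
  expect_equal(dplyr::arrange(tidy(calls2), segment_id),
               dplyr::arrange(tidy(calls), segment_id))

  # selection is anti-monotone in |cc|: leave the segment untouched but give
  # its cognate ORF an SPII profile that exactly mirrors the segment's, so the
  # pair becomes perfectly correlated and falls out of the call set
  vic <- calls$segment_id[1]
  vic_gene <- calls$gene_id[1]
  vals <- sim$expr$values
  spii <- sim$expr$samples$strain == "MATa/alpha" & sim$expr$samples$medium == "SPII"
  seg_row <- as.numeric(vals[match(vic, vals$id), -1])
  orf_row <- as.numeric(vals[match(vic_gene, vals$id), -1])
  orf_row[spii] <- seg_row[spii] + 6
  vals[match(vic_gene, vals$id), -1] <- as.list(orf_row)
  calls3 <- call_mutrs(sim$segments, sim$genes,
                       expression_set(vals, sim$expr$samples), cfg)
  expect_false(vic %in% calls3$segment_id)

  expect_s3_class(tidy(calls), "tbl_df")
  expect_equal(glance(calls)$n_called, nrow(calls))
})
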