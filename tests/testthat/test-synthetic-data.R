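test_that("generation is deterministic and degenerate configs behave", {
  cfg <- small_cfg(seed = 11)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth, b$truth)
  expect_identical(a$expr$values, b$expr$values)

  # byte-identical files under a fixed seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(cfg, dir = d1); simulate_dataset(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }

  empty <- simulate_genome(sim_config(seed = 1, n_genes = 0,
                                      n_planted_5p_mutrs = 0,
                                      n_planted_3p_mutrs = 0,
                                      n_decoy_segments = 0))
  expect_equal(nrow(empty$genes), 0)
  expect_equal(length(empty$genome[[1]]), 60000)

  expect_error(simulate_genome(sim_config(n_genes = 100, chrom_length = 60000)),
               "infeasible")
  expect_error(sim_config(background_threshold_tau = 3), "expressed_level")
  expect_error(sim_config(urs1_plant_rate_target = 1.5), "rates")
})

test_that("planted URS1 sites are recoverable by exact search on both strands", {
  sim <- simulate_dataset(small_cfg(seed = 21))
  pr <- dplyr::filter(sim$promoters, planted)
  expect_gt(nrow(pr), 0)
  for (i in seq_len(nrow(pr))) {
    chrom <- as.character(sim$genome[[pr$chrom[i]]])
    found <- substr(chrom, pr$urs1_position[i] + 1,
                    pr$urs1_position[i] + nchar(pr$urs1_word[i]))
    expected <- if (pr$strand[i] == "+") pr$urs1_word[i] else
      meiutr:::revcomp(pr$urs1_word[i])
    expect_identical(found, expected)
    # plant lies within its 100-bp window
    expect_gte(pr$urs1_position[i], pr$window_start[i])
    expect_lte(pr$urs1_position[i] + 10, pr$window_end[i])
  }
  # truth rows propagate mutr-window plants
  tr <- dplyr::filter(sim$truth, urs1_planted)
  expect_true(all(tr$side == "5p"))
  expect_true(all(tr$gene_id %in% sim$genes$gene_id))
})

test_that("a plant rate of 1 with no mismatches puts the consensus in every target window", {
  cfg <- small_cfg(seed = 5, urs1_plant_rate_target = 1.0, urs1_mismatch_rate = 0)
  sim <- simulate_genome(cfg)
  tgt <- dplyr::filter(sim$promoters, kind == "mutr_upstream")
  expect_equal(nrow(tgt), cfg$n_planted_5p_mutrs)
  expect_true(all(tgt$planted))
  for (i in seq_len(nrow(tgt))) {
    win <- upstream_window(sim$genome, tgt$chrom[i], tgt$strand[i],
                           tgt$anchor[i], 100)
    expect_true(grepl("TAGCCGCCGA", win, fixed = TRUE))
  }
})

test_that("expression matrix matches the sample design and planted timing", {
  sim <- shared_sim()
  cfg <- small_cfg()
  expr <- sim$expr
  n_orf <- sum(sim$genes$class == "ORF")
  expect_equal(nrow(expr$values), nrow(sim$truth) + n_orf)
  expect_equal(nrow(expr$samples), 45)
  expect_equal(sum(expr$samples$strain == "MATa"), 28)

  tau <- cfg$background_threshold_tau
  windows <- list(early = 1:4, middle = 5:8, late = 9:12)
  spii <- expr$samples$strain == "MATa/alpha" & expr$samples$medium == "SPII"
  other <- !spii
  for (i in which(sim$truth$role == "planted")) {
    row <- as.numeric(expr$values[match(sim$truth$segment_id[i], expr$values$id),
                                  expr$samples$id])
    expect_true(all(row[other] <= tau))
    hours <- expr$samples$timepoint[spii]
    in_win <- hours %in% windows[[sim$truth$timing[i]]]
    expect_true(all(row[spii][in_win] > tau))
    expect_true(all(row[spii][!in_win] <= tau))
  }
})

test_that("zero noise collapses constitutive ORF rows to the expressed level", {
  cfg <- small_cfg(seed = 3, noise_sd = 0)
  sim <- simulate_dataset(cfg)
  hosts <- sim$truth$gene_id[sim$truth$role == "decoy_correlated"]
  plain <- setdiff(sim$genes$gene_id[sim$genes$class == "ORF"], hosts)
  rows <- as.matrix(sim$expr$values[match(plain, sim$expr$values$id),
                                    sim$expr$samples$id])
  expect_true(all(rows == cfg$expressed_level))
})

test_that("planted segments satisfy all selection criteria and decoys each fail one", {
  sim <- shared_sim()
  cfg <- caller_config(tau = small_cfg()$background_threshold_tau)
  filt <- filter_unannotated(sim$segments, sim$genes, cfg)
  spor <- sporulation_specific(sim$expr, cfg, ids = sim$segments$segment_id)
  assigned <- assign_to_gene(sim$segments, sim$genes, cfg)
  for (i in seq_len(nrow(sim$truth))) {
    id <- sim$truth$segment_id[i]
    role <- sim$truth$role[i]
    unannotated <- id %in% filt$segment_id
    sporulation <- spor$sporulation_specific[spor$id == id]
    near <- id %in% assigned$segment_id
    if (role == "planted") {
      expect_true(unannotated && sporulation && near, info = id)
      expect_equal(assigned$gene_id[assigned$segment_id == id],
                   sim$truth$gene_id[i])
      expect_equal(assigned$side[assigned$segment_id == id], sim$truth$side[i])
    } else {
      fails <- c(annotated = !unannotated, mitotic = !sporulation, far = !near)
      expected_fail <- switch(role,
        decoy_annotated = "annotated", decoy_mitotic = "mitotic",
        decoy_far = "far", decoy_correlated = NA)
      if (is.na(expected_fail)) {
        # correlated decoys pass these criteria; they must fall to the
        # correlation test instead
        expect_true(!any(fails), info = id)
        cres <- correlate_expression(
          tibble::tibble(segment_id = id, gene_id = sim$truth$gene_id[i]),
          sim$expr)
        expect_lt(cres$p_raw, 0.01)
      } else {
        expect_true(fails[[expected_fail]], info = id)
        expect_true(sum(fails) == 1, info = id)
      }
    }
  }
})

test_that("truth table round-trips through TSV", {
  sim <- shared_sim()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$truth))
  expect_equal(nrow(back), nrow(sim$truth))

  write_truth(sim$truth[0, ], path)
  expect_equal(nrow(read_truth(path)), 0)
  expect_error(write_truth(NULL, path), "NULL")
})
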