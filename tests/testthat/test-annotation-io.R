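test_that("GFF3 and BED coordinate conventions are honoured", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t101\t200\t.\t+\t.\tID=g1;class=ORF",
    "chr1\tx\tncRNA\t301\t350\t.\t-\t.\tID=n1;class=tRNA",
    "chr1\tx\tncRNA\t401\t450\t.\t+\t.\tID=n2;class=mystery"
  ), gff)
  ann <- read_annotation(gff)
  expect_equal(ann$start[ann$gene_id == "g1"], 100)
  expect_equal(ann$end[ann$gene_id == "g1"], 200)
  expect_equal(ann$tss[ann$gene_id == "g1"], 100)       # defaults to ORF 5' end
  expect_equal(ann$terminator[ann$gene_id == "g1"], 200)
  expect_equal(ann$class[ann$gene_id == "n2"], "other") # unknown class

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\ts1\t0\t+", bed)
  seg <- read_segments(bed)
  expect_equal(seg$start, 100)
  expect_equal(seg$end, 200)

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\ts1\t0\t+", "chr1\t5"), bad)
  expect_error(read_segments(bad), "line 2")
})

test_that("annotation and segment writers round-trip", {
  sim <- shared_sim()
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(sim$genes, gff)
  back <- read_annotation(gff)
  expect_equal(dplyr::arrange(back, gene_id), dplyr::arrange(sim$genes, gene_id))

  bed <- withr::local_tempfile(fileext = ".bed")
  write_segments(sim$segments, bed)
  expect_equal(read_segments(bed), sim$segments)
})

test_that("expression IO enforces the finite-value and sample-match contracts", {
  sim <- shared_sim()
  m <- withr::local_tempfile(fileext = ".tsv")
  s <- withr::local_tempfile(fileext = ".tsv")
  write_expression(sim$expr, m, s)
  back <- read_expression(m, s)
  expect_equal(back$values, sim$expr$values)
  expect_equal(back$samples, sim$expr$samples)

  # sample mismatch names the offender
  sheet <- sim$expr$samples
  sheet$id[1] <- "nonexistent_sample"
  s2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(sheet, s2)
  expect_error(read_expression(m, s2), "nonexistent_sample")

  # NA violates the finite-only contract
  vals <- sim$expr$values
  vals[2, 3] <- NA
  m2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(vals, m2)
  expect_error(read_expression(m2, s), "finite")
})

test_that("TRANSFAC parsing handles ordering, emptiness and malformed blocks", {
  # block built from 10 identical TAGCCGCCGA sites: one nonzero cell per column
  tf <- withr::local_tempfile(fileext = ".transfac")
  pwm10 <- build_pwm(rep("TAGCCGCCGA", 10), pseudocount = 0)
  write_transfac(list(URS1 = pwm10$counts), tf)
  rec <- read_transfac(tf)
  expect_named(rec, "URS1")
  expect_equal(colSums(rec$URS1 > 0), rep(1, 10), ignore_attr = TRUE)
  expect_equal(rec$URS1, pwm10$counts)

  # permuted P0 header is re-ordered to A,C,G,T
  tf2 <- withr::local_tempfile(fileext = ".transfac")
  writeLines(c("ID perm", "P0 T G C A",
               "01 9 0 1 0",   # T=9 C=1 -> A0 C1 G0 T9
               "02 0 8 0 2",   # A=2, G=8
               "//"), tf2)
  rec2 <- read_transfac(tf2)[["perm"]]
  expect_equal(rec2[, 1], c(A = 0, C = 1, G = 0, T = 9))
  expect_equal(rec2[, 2], c(A = 2, C = 0, G = 8, T = 0))

  empty <- withr::local_tempfile(fileext = ".transfac")
  writeLines(character(0), empty)
  expect_equal(length(read_transfac(empty)), 0)

  noterm <- withr::local_tempfile(fileext = ".transfac")
  writeLines(c("ID x", "P0 A C G T", "01 1 2 3 4"), noterm)
  expect_error(read_transfac(noterm), "//")

  badcell <- withr::local_tempfile(fileext = ".transfac")
  writeLines(c("ID x", "P0 A C G T", "01 1 q 3 4", "//"), badcell)
  expect_error(read_transfac(badcell), "non-numeric")

  # the shipped synthetic URS1 matrix equals the in-code constructor
  shipped <- read_transfac(system.file("extdata", "urs1_synthetic.transfac",
                                       package = "meiutr"))
  expect_equal(shipped$URS1_synthetic, urs1_pwm()$counts, ignore_attr = TRUE)
})

test_that("upstream windows are strand-aware, truncated and involutive", {
  genome <- Biostrings::DNAStringSet(c(chrA = paste(rep("ACGT", 50), collapse = "")))
  full <- as.character(genome[[1]])

  expect_equal(upstream_window(genome, "chrA", "+", 100, 100),
               substr(full, 1, 100))
  expect_equal(nchar(upstream_window(genome, "chrA", "+", 50, 100)), 50)
  expect_equal(nchar(upstream_window(genome, "chrA", "-", 180, 100)), 20)
  expect_equal(upstream_window(genome, "chrA", "+", 0, 10), "")
  expect_error(upstream_window(genome, "chrA", "+", 500, 10), "outside")
  expect_error(upstream_window(genome, "chrA", "+", 10, 0), "width")

  # minus-strand window is the reverse complement of the mirrored + extraction
  toy <- Biostrings::DNAStringSet(c(t = "ACGTACGTACGTACGTACGT"))
  minus <- upstream_window(toy, "t", "-", 8, 6)
  plus_region <- substr("ACGTACGTACGTACGTACGT", 9, 14)
  expect_equal(minus, meiutr:::revcomp(plus_region))
  expect_equal(meiutr:::revcomp(minus), plus_region)

  # vectorised version preserves rows
  tab <- tibble::tibble(id = c("a", "b"), chrom = "t",
                        strand = c("+", "-"), anchor = c(10, 10))
  out <- upstream_windows(tab, toy, width = 4)
  expect_equal(out$seq[1], substr("ACGTACGTACGTACGTACGT", 7, 10))
})

test_that("mUTR BED output encodes names and clamped scores", {
  calls <- tibble::tibble(
    chrom = "chr1", start = c(10L, 50L), end = c(30L, 80L), strand = "+",
    gene_id = c("g1", "g2"), side = c("5p", "3p"),
    timing = c("early", NA), p_adjusted = c(0.2, 1))
  path <- withr::local_tempfile(fileext = ".bed")
  write_mutr_bed(calls, path)
  lines <- readLines(path)
  f <- strsplit(lines, "\t")
  expect_equal(f[[1]][4], "g1|5p|early")
  expect_equal(f[[2]][4], "g2|3p|none")
  expect_equal(as.integer(f[[1]][5]), 800)
  expect_equal(as.integer(f[[2]][5]), 0)   # adjusted P = 1 -> score 0
  expect_equal(as.integer(f[[1]][2:3]), c(10L, 30L))  # half-open preserved

  write_mutr_bed(calls[0, ], path)
  expect_equal(length(readLines(path)), 0)
})
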