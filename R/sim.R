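## Synthetic miniature genome + expression generator with planted ground
## truth, emulating the study conditions the analysis assumes: constitutive
## ORF expression across a 45-sample design, sporulation-only UTR-extension
## segments with early/middle/late timing, decoy segments that each violate
## exactly one selection criterion, and URS1 sites planted into promoter
## windows at controlled rates.

TIMING_WINDOWS <- list(early = 1:4, middle = 5:8, late = 9:12)

#' Configuration of the synthetic dataset
#'
#' Defaults define the study conditions: a two-chromosome 60-kb-per-chromosome
#' genome carrying 40 non-overlapping genes, 10 planted 5' and 8 planted 3'
#' meiotic UTR segments, 12 decoy segments, and URS1 sites planted into the
#' 100-bp windows upstream of meiotic TSSs at a 0.66 rate (matching the
#' lenient observed URS1-containing fraction) versus 0.1 in background
#' promoters. Expression is log2-scale: constitutive level 10, background 4,
#' detection threshold tau 6, additive Gaussian noise sd 0.5.
#'
#' @param seed Integer RNG seed; the whole dataset is a pure function of the
#'   configuration.
#' @param n_chromosomes,chrom_length Genome shape.
#' @param n_genes Number of protein-coding genes (non-overlapping layout).
#' @param n_planted_5p_mutrs,n_planted_3p_mutrs Planted true mUTR counts.
#' @param n_decoy_segments Decoys cycling through four violation classes:
#'   expressed in mitosis, > 100 bp from any anchor, expression-correlated
#'   with the cognate ORF, or overlapping an annotated ncRNA.
#' @param timing_mix Named proportions over early/middle/late (sums to 1).
#' @param urs1_plant_rate_target,urs1_plant_rate_background Planting
#'   probabilities for meiotic-TSS windows and ORF-TSS windows.
#' @param urs1_mismatch_rate Probability that a planted site is a uniformly
#'   chosen single-substitution variant of the consensus rather than the
#'   literal TAGCCGCCGA, so both exact and near-exact sites occur.
#' @param background_level,expressed_level,noise_sd,background_threshold_tau
#'   Log2 expression parameters; must satisfy
#'   `expressed_level > tau > background_level`.
#' @param replicates Replicates per condition in the sample design.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 60000L,
                       n_genes = 40L,
                       n_planted_5p_mutrs = 10L,
                       n_planted_3p_mutrs = 8L,
                       n_decoy_segments = 12L,
                       timing_mix = c(early = 1/3, middle = 1/3, late = 1/3),
                       urs1_plant_rate_target = 0.66,
                       urs1_plant_rate_background = 0.1,
                       urs1_mismatch_rate = 0.3,
                       background_level = 4,
                       expressed_level = 10,
                       noise_sd = 0.5,
                       background_threshold_tau = 6,
                       replicates = 1L) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length), n_genes = as.integer(n_genes),
              n_planted_5p_mutrs = as.integer(n_planted_5p_mutrs),
              n_planted_3p_mutrs = as.integer(n_planted_3p_mutrs),
              n_decoy_segments = as.integer(n_decoy_segments),
              timing_mix = timing_mix,
              urs1_plant_rate_target = urs1_plant_rate_target,
              urs1_plant_rate_background = urs1_plant_rate_background,
              urs1_mismatch_rate = urs1_mismatch_rate,
              background_level = background_level,
              expressed_level = expressed_level,
              noise_sd = noise_sd,
              background_threshold_tau = background_threshold_tau,
              replicates = as.integer(replicates))
  counts <- c(cfg$n_chromosomes, cfg$chrom_length, cfg$n_genes,
              cfg$n_planted_5p_mutrs, cfg$n_planted_3p_mutrs, cfg$n_decoy_segments)
  if (any(counts < 0)) stop_meiutr("counts must be >= 0")
  rates <- c(cfg$urs1_plant_rate_target, cfg$urs1_plant_rate_background,
             cfg$urs1_mismatch_rate)
  if (any(rates < 0 | rates > 1)) stop_meiutr("rates must lie in [0, 1]")
  if (!(cfg$expressed_level > cfg$background_threshold_tau &&
        cfg$background_threshold_tau > cfg$background_level)) {
    stop_meiutr("need expressed_level > tau > background_level")
  }
  if (!setequal(names(cfg$timing_mix), c("early", "middle", "late")) ||
      abs(sum(cfg$timing_mix) - 1) > 1e-8) {
    stop_meiutr("timing_mix must be named early/middle/late proportions summing to 1")
  }
  if (cfg$noise_sd < 0) stop_meiutr("noise_sd must be >= 0")
  structure(cfg, class = "sim_config")
}

# One uniformly chosen single-substitution variant of the consensus.
mutate_consensus <- function(word) {
  pos <- sample.int(nchar(word), 1)
  old <- substr(word, pos, pos)
  new <- sample(setdiff(DNA_BASES, old), 1)
  substr(word, pos, pos) <- new
  word
}

# Deterministic non-overlapping gene layout: genes are distributed over
# chromosomes and each gene owns a fixed-pitch block with the ORF centred in
# it, leaving symmetric margins that accommodate UTR segments, gaps and the
# 100-bp promoter window. Fails explicitly when the packing is infeasible.
layout_genes <- function(cfg) {
  per_chrom <- rep(cfg$n_genes %/% cfg$n_chromosomes, cfg$n_chromosomes)
  extra <- cfg$n_genes %% cfg$n_chromosomes
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  rows <- list()
  gi <- 0L
  for (ci in seq_len(cfg$n_chromosomes)) {
    ng <- per_chrom[ci]
    if (ng == 0) next
    pitch <- cfg$chrom_length %/% ng
    if (pitch < 3000) {
      stop_meiutr("infeasible packing: %d genes on a %d-bp chromosome (pitch %d < 3000)",
                  ng, cfg$chrom_length, pitch)
    }
    for (k in seq_len(ng)) {
      gi <- gi + 1L
      block_start <- (k - 1L) * pitch
      orf_len <- sample(400:800, 1)
      orf_start <- block_start + (pitch - orf_len) %/% 2L
      strand <- sample(c("+", "-"), 1)
      rows[[gi]] <- tibble(
        gene_id = sprintf("gene%03d", gi),
        chrom = sprintf("chr%d", ci), strand = strand,
        start = orf_start, end = orf_start + orf_len,
        block_start = block_start, block_end = block_start + pitch
      )
    }
  }
  bind_rows(rows) |>
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end),
           terminator = ifelse(.data$strand == "+", .data$end, .data$start),
           class = "ORF")
}

# Segment flanking a gene at a given gap: kind "5p" upstream of the TSS,
# "3p" downstream of the terminator, in gene orientation.
flank_segment <- function(gene, kind, gap, len) {
  plus <- gene$strand == "+"
  if (kind == "5p") {
    if (plus) c(gene$tss - gap - len, gene$tss - gap)
    else c(gene$tss + gap, gene$tss + gap + len)
  } else {
    if (plus) c(gene$terminator + gap, gene$terminator + gap + len)
    else c(gene$terminator - gap - len, gene$terminator - gap)
  }
}

mutr_length <- function(n, median_bp, lo, hi) {
  pmin(hi, pmax(lo, round(stats::rlnorm(n, meanlog = log(median_bp), sdlog = 0.6))))
}

#' Generate the synthetic genome, annotation, segments and ground truth
#'
#' Lays out non-overlapping genes, plants true 5'/3' mUTR segments (length
#' distributions with medians 241 and 173 bp) and four classes of decoy
#' segments, writes URS1 consensus (or single-mismatch) sites into the 100-bp
#' windows upstream of meiotic TSSs and of ORF TSSs at the configured rates,
#' and emits a random genome sequence carrying those plants. Deterministic
#' given the configuration.
#'
#' @param cfg A [sim_config()].
#' @return List with `genome` ([Biostrings::DNAStringSet]), `genes`
#'   (annotation tibble incl. ncRNA decoy features), `segments`, `truth`
#'   (one row per segment: side, timing, role, URS1 plant), and `promoters`
#'   (one row per planted-window candidate with plant position and word).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_hosted <- cfg$n_planted_5p_mutrs + cfg$n_planted_3p_mutrs + cfg$n_decoy_segments
  if (cfg$n_genes > 0 && n_hosted > cfg$n_genes) {
    stop_meiutr("infeasible design: %d segments need host genes but only %d genes",
                n_hosted, cfg$n_genes)
  }
  withr::with_seed(cfg$seed, {
    chrom_names <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
    seqs <- setNames(
      vapply(chrom_names, function(ch)
        paste(sample(DNA_BASES, cfg$chrom_length, replace = TRUE), collapse = ""),
        character(1)),
      chrom_names)
    if (cfg$n_genes == 0) {
      empty_genes <- tibble(gene_id = character(), chrom = character(),
                            strand = character(), start = integer(), end = integer(),
                            tss = integer(), terminator = integer(), class = character())
      return(list(genome = Biostrings::DNAStringSet(seqs), genes = empty_genes,
                  segments = tibble(segment_id = character(), chrom = character(),
                                    strand = character(), start = integer(), end = integer()),
                  truth = empty_truth(), promoters = empty_promoters()))
    }
    genes <- layout_genes(cfg)

    ids <- sample(genes$gene_id)
    g5 <- ids[seq_len(cfg$n_planted_5p_mutrs)]
    g3 <- ids[cfg$n_planted_5p_mutrs + seq_len(cfg$n_planted_3p_mutrs)]
    decoy_hosts <- ids[cfg$n_planted_5p_mutrs + cfg$n_planted_3p_mutrs +
                         seq_len(cfg$n_decoy_segments)]
    decoy_types <- rep_len(c("mitotic", "far", "correlated", "annotated"),
                           cfg$n_decoy_segments)

    seg_rows <- list(); truth_rows <- list(); nc_rows <- list()
    si <- 0L
    add_segment <- function(gene, kind, gap, len, side, timing, role, expr_timing) {
      si <<- si + 1L
      pos <- flank_segment(gene, kind, gap, len)
      id <- sprintf("seg%03d", si)
      seg_rows[[si]] <<- tibble(segment_id = id, chrom = gene$chrom,
                                strand = gene$strand,
                                start = as.integer(pos[1]), end = as.integer(pos[2]))
      truth_rows[[si]] <<- tibble(segment_id = id, gene_id = gene$gene_id,
                                  side = side, timing = timing, role = role,
                                  expr_timing = expr_timing,
                                  urs1_planted = FALSE,
                                  urs1_position = NA_integer_,
                                  urs1_word = NA_character_)
      id
    }
    draw_timing <- function() {
      sample(names(cfg$timing_mix), 1, prob = cfg$timing_mix)
    }

    for (gid in g5) {
      gene <- genes[genes$gene_id == gid, ]
      tm <- draw_timing()
      add_segment(gene, "5p", sample(0:80, 1), mutr_length(1, 241, 56, 800),
                  "5p", tm, "planted", tm)
    }
    for (gid in g3) {
      gene <- genes[genes$gene_id == gid, ]
      tm <- draw_timing()
      add_segment(gene, "3p", sample(0:80, 1), mutr_length(1, 173, 57, 800),
                  "3p", tm, "planted", tm)
    }
    for (di in seq_along(decoy_hosts)) {
      gene <- genes[genes$gene_id == decoy_hosts[di], ]
      type <- decoy_types[di]
      len <- sample(100:400, 1)
      if (type == "mitotic") {
        add_segment(gene, "5p", sample(0:80, 1), len, "none", "none",
                    "decoy_mitotic", draw_timing())
      } else if (type == "far") {
        add_segment(gene, "5p", sample(150:300, 1), len, "none", "none",
                    "decoy_far", draw_timing())
      } else if (type == "correlated") {
        add_segment(gene, "5p", sample(0:80, 1), len, "none", "none",
                    "decoy_correlated", "none")
      } else {
        id <- add_segment(gene, "5p", sample(0:80, 1), max(len, 120L), "none", "none",
                          "decoy_annotated", draw_timing())
        seg <- seg_rows[[si]]
        nc_rows[[length(nc_rows) + 1]] <- tibble(
          gene_id = sprintf("nc%02d", length(nc_rows) + 1),
          chrom = seg$chrom, strand = seg$strand,
          start = seg$start + 10L, end = seg$start + 100L,
          tss = NA_integer_, terminator = NA_integer_,
          class = sample(c("snoRNA", "tRNA", "SUT", "CUT", "MUT"), 1)
        )
      }
    }
    segments <- bind_rows(seg_rows)
    truth <- bind_rows(truth_rows)

    # --- URS1 planting ---------------------------------------------------
    occupied <- list()  # per-chromosome planted intervals, to avoid collisions
    plant <- function(chrom, strand, win_start, win_end, rate) {
      if (runif(1) >= rate) return(NULL)
      word <- URS1_CONSENSUS
      if (runif(1) < cfg$urs1_mismatch_rate) word <- mutate_consensus(word)
      wlen <- nchar(word)
      for (try in 1:10) {
        pos <- win_start + sample.int(win_end - win_start - wlen + 1L, 1) - 1L
        prev <- occupied[[chrom]]
        clash <- !is.null(prev) && any(pos < prev[, 2] & pos + wlen > prev[, 1])
        if (!clash) {
          occupied[[chrom]] <<- rbind(prev, c(pos, pos + wlen))
          insert <- if (strand == "+") word else revcomp(word)
          substr(seqs[[chrom]], pos + 1L, pos + wlen) <<- insert
          return(list(position = pos, word = word))
        }
      }
      NULL
    }
    prom_rows <- list()
    add_promoter <- function(gene, anchor, kind, rate) {
      if (gene$strand == "+") {
        win <- c(anchor - 100L, anchor)
      } else {
        win <- c(anchor, anchor + 100L)
      }
      res <- plant(gene$chrom, gene$strand, win[1], win[2], rate)
      prom_rows[[length(prom_rows) + 1]] <<- tibble(
        gene_id = gene$gene_id, kind = kind, chrom = gene$chrom,
        strand = gene$strand, anchor = as.integer(anchor),
        window_start = as.integer(win[1]), window_end = as.integer(win[2]),
        planted = !is.null(res),
        urs1_position = if (is.null(res)) NA_integer_ else as.integer(res$position),
        urs1_word = if (is.null(res)) NA_character_ else res$word
      )
    }
    for (gid in g5) {
      gene <- genes[genes$gene_id == gid, ]
      seg <- segments[segments$segment_id ==
                        truth$segment_id[truth$gene_id == gid & truth$side == "5p"], ]
      anchor <- if (gene$strand == "+") seg$start else seg$end  # meiotic TSS
      add_promoter(gene, anchor, "mutr_upstream", cfg$urs1_plant_rate_target)
    }
    for (gid in genes$gene_id) {
      gene <- genes[genes$gene_id == gid, ]
      add_promoter(gene, gene$tss, "orf_upstream", cfg$urs1_plant_rate_background)
    }
    promoters <- bind_rows(prom_rows)

    # propagate mutr-window plants into the truth table
    tgt <- filter(promoters, .data$kind == "mutr_upstream", .data$planted)
    for (i in seq_len(nrow(tgt))) {
      j <- which(truth$gene_id == tgt$gene_id[i] & truth$side == "5p")
      truth$urs1_planted[j] <- TRUE
      truth$urs1_position[j] <- tgt$urs1_position[i]
      truth$urs1_word[j] <- tgt$urs1_word[i]
    }

    annotation <- bind_rows(
      select(genes, "gene_id", "chrom", "strand", "start", "end",
             "tss", "terminator", "class"),
      bind_rows(nc_rows) |>
        mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end),
               terminator = ifelse(.data$strand == "+", .data$end, .data$start))
    )
    list(genome = Biostrings::DNAStringSet(seqs), genes = annotation,
         segments = segments, truth = truth, promoters = promoters)
  })
}

empty_truth <- function() {
  tibble(segment_id = character(), gene_id = character(), side = character(),
         timing = character(), role = character(), expr_timing = character(),
         urs1_planted = logical(), urs1_position = integer(),
         urs1_word = character())
}

empty_promoters <- function() {
  tibble(gene_id = character(), kind = character(), chrom = character(),
         strand = character(), anchor = integer(), window_start = integer(),
         window_end = integer(), planted = logical(),
         urs1_position = integer(), urs1_word = character())
}

#' Generate the synthetic expression matrix
#'
#' ORF rows are expressed (around `expressed_level`, clamped above `tau`) in
#' all samples. Planted mUTR rows rise above `tau` only in diploid SPII
#' samples within their timing window (early 1-4 h, middle 5-8 h, late
#' 9-12 h), peaking at a random hour of that window, and stay below `tau`
#' (clamped) everywhere else. Each decoy row violates exactly one selection
#' criterion: `decoy_mitotic` is expressed in every sample; `decoy_far` and
#' `decoy_annotated` behave like true mUTRs (their defect lies in
#' coordinates/annotation); `decoy_correlated` tracks a deliberate SPII trend
#' that is also written into its host ORF, so segment and ORF correlate
#' across the condition design. Deterministic given the configuration.
#'
#' @param cfg A [sim_config()].
#' @param genes Annotation tibble from [simulate_genome()].
#' @param truth Truth tibble from [simulate_genome()].
#' @return An [expression_set()] with `nrow(truth) + n ORF` rows and
#'   `45 * replicates` samples.
#' @export
simulate_expression <- function(cfg, genes, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  bad <- setdiff(unique(c(truth$timing, truth$expr_timing)),
                 c(names(TIMING_WINDOWS), "none"))
  if (length(bad)) stop_meiutr("unknown timing label: %s", paste(bad, collapse = ","))
  samples <- sample_design(cfg$replicates)
  cls <- sample_classes(samples)
  spii <- cls == "dip_spii"
  hour <- samples$timepoint
  ns <- nrow(samples)
  tau <- cfg$background_threshold_tau

  withr::with_seed(cfg$seed + 1L, {
    bg_row <- function() pmin(cfg$background_level + rnorm(ns) * cfg$noise_sd, tau - 0.5)
    lift <- function(row, mask, level) {
      row[mask] <- pmax(level[mask] + rnorm(sum(mask)) * cfg$noise_sd, tau + 0.5)
      row
    }
    const_level <- rep(cfg$expressed_level, ns)
    corr_hosts <- truth$gene_id[truth$role == "decoy_correlated"]

    orf_genes <- filter(genes, .data$class == "ORF")
    orf_rows <- purrr::map(orf_genes$gene_id, function(gid) {
      level <- const_level
      if (gid %in% corr_hosts) {
        level[spii] <- cfg$expressed_level + 0.4 * hour[spii]
      }
      lift(bg_row(), rep(TRUE, ns), level)
    })

    seg_rows <- purrr::map(seq_len(nrow(truth)), function(i) {
      role <- truth$role[i]
      row <- bg_row()
      if (role == "decoy_mitotic") {
        return(lift(row, rep(TRUE, ns), const_level))
      }
      if (role == "decoy_correlated") {
        row[spii] <- cfg$background_level + 0.4 * hour[spii] + rnorm(sum(spii)) * cfg$noise_sd
        return(row)
      }
      window <- TIMING_WINDOWS[[truth$expr_timing[i]]]
      peak <- sample(window, 1)
      mask <- spii & hour %in% window
      level <- rep(0, ns)
      level[mask] <- cfg$expressed_level - 0.5 * abs(hour[mask] - peak)
      lift(row, mask, level)
    })

    mat <- do.call(rbind, c(seg_rows, orf_rows))
    if (is.null(mat)) mat <- matrix(numeric(0), nrow = 0, ncol = ns)
    values <- tibble(id = c(truth$segment_id, orf_genes$gene_id)) |>
      bind_cols(as_tibble(setNames(as.data.frame(mat), samples$id)))
    expression_set(values, samples)
  })
}

#' Generate a complete synthetic dataset (and optionally write it to disk)
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory; when given, writes `genome.fasta`,
#'   `annotation.gff3`, `segments.bed`, `expression.tsv`, `samples.tsv` and
#'   `truth.tsv` and records the paths in the result.
#' @return The [simulate_genome()] list extended with `expr` (an
#'   [expression_set()]) and, when written, `paths`.
#' @export
simulate_dataset <- function(cfg = sim_config(), dir = NULL) {
  sim <- simulate_genome(cfg)
  sim$expr <- simulate_expression(cfg, sim$genes, sim$truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      genome = file.path(dir, "genome.fasta"),
      annotation = file.path(dir, "annotation.gff3"),
      segments = file.path(dir, "segments.bed"),
      expression = file.path(dir, "expression.tsv"),
      samples = file.path(dir, "samples.tsv"),
      truth = file.path(dir, "truth.tsv")
    )
    write_genome(sim$genome, paths$genome)
    write_annotation(sim$genes, paths$annotation)
    write_segments(sim$segments, paths$segments)
    write_expression(sim$expr, paths$expression, paths$samples)
    write_truth(sim$truth, paths$truth)
    sim$paths <- paths
  }
  sim
}

#' Write / read the ground-truth table
#'
#' TSV with a header, one row per segment; round-trips losslessly.
#'
#' @param truth Truth tibble from [simulate_genome()].
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  if (is.null(truth)) stop_meiutr("truth must not be NULL")
  readr::write_tsv(truth, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop_meiutr("truth file not found: %s", path)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    segment_id = "c", gene_id = "c", side = "c", timing = "c",
                    role = "c", expr_timing = "c", urs1_planted = "l",
                    urs1_position = "i", urs1_word = "c"))
}
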