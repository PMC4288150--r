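## Orchestrated end-to-end run: simulate (or load) -> call mUTRs -> classify
## timing -> extract upstream windows -> scan -> enrichment -> length stats,
## with file outputs after every stage and a machine-readable JSON summary.

default_pipeline_config <- function() {
  list(
    out_dir = NULL,
    seed = 1L,
    inputs = NULL,     # NULL = simulate; else named paths (segments, annotation,
                       # expression, samples, genome)
    sim = list(),      # overrides for sim_config() when simulating
    caller = list(),   # overrides for caller_config()
    scan = list(min_css = 0.9, min_mss = 0.7),
    enrichment = list(method = "permutation", n_perm = 999),
    timing_boundaries = c(early = 4, middle = 8),
    upstream_width = 100
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_meiutr("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full mUTR discovery and motif-enrichment pipeline
#'
#' Executes simulate (or load) -> call mUTRs -> classify timing -> extract
#' 100-bp upstream windows of meiotic TSSs and of cognate ORF TSSs -> scan
#' for URS1 -> enrichment test -> length statistics, writing a BED of calls,
#' FASTA window sets, TSV tables for the candidate report, motif hits,
#' enrichment and length summaries, and a JSON run summary with the seed and
#' per-stage counts. Rerunning with an identical configuration reproduces
#' byte-identical outputs.
#'
#' @param config A named list overriding the defaults (see
#'   `meiutr:::default_pipeline_config()`), or the path of a YAML file with
#'   the same structure. `out_dir` is required. When `inputs` is `NULL` a
#'   synthetic dataset is generated from `sim` (seeded by `seed`); otherwise
#'   `inputs` must name existing `segments`, `annotation`, `expression`,
#'   `samples` and `genome` files, which are checked before any stage runs.
#' @return The run summary (list), invisibly also written to
#'   `summary.json` in `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  if (is.null(cfg$out_dir)) stop_meiutr("config must set out_dir")
  if (!is.null(cfg$inputs)) {
    need <- c("segments", "annotation", "expression", "samples", "genome")
    for (nm in need) {
      p <- cfg$inputs[[nm]]
      if (is.null(p) || !file.exists(p)) {
        stop_meiutr("missing input path for '%s': %s", nm, p %||% "<unset>")
      }
    }
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)

  truth <- NULL
  if (is.null(cfg$inputs)) {
    sim <- stage("simulate", {
      scfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
      simulate_dataset(scfg)
    })
    segments <- sim$segments; genes <- sim$genes; expr <- sim$expr
    genome <- sim$genome; truth <- sim$truth
    write_truth(truth, out("truth.tsv"))
  } else {
    segments <- stage("load", read_segments(cfg$inputs$segments))
    genes <- stage("load", read_annotation(cfg$inputs$annotation))
    expr <- stage("load", read_expression(cfg$inputs$expression, cfg$inputs$samples))
    genome <- stage("load", read_genome(cfg$inputs$genome))
  }

  ccfg <- do.call(caller_config, cfg$caller)
  calls <- stage("call-mutrs", call_mutrs(segments, genes, expr, ccfg))
  report <- tidy(calls)

  calls <- stage("classify-timing", {
    if (nrow(calls) > 0) {
      timing <- classify_timing(expr, ids = calls$segment_id,
                                boundaries = cfg$timing_boundaries)
      left_join(calls, select(timing, "segment_id", timing = "class",
                              "peak_spii_hour"),
                by = "segment_id")
    } else {
      mutate(calls, timing = character(0), peak_spii_hour = integer(0))
    }
  })
  write_mutr_bed(calls, out("mutr_calls.bed"))
  readr::write_tsv(report, out("mutr_report.tsv"), progress = FALSE)

  pwm <- urs1_pwm()
  windows <- stage("upstream-windows", {
    five <- filter(calls, .data$side == "5p")
    targets <- NULL; background <- NULL
    if (nrow(five) > 0) {
      targets <- five |>
        mutate(anchor = ifelse(.data$strand == "+", .data$start, .data$end)) |>
        select(id = "segment_id", "chrom", "strand", "anchor") |>
        upstream_windows(genome, width = cfg$upstream_width)
      background <- genes |>
        filter(.data$class == "ORF", .data$gene_id %in% five$gene_id) |>
        mutate(anchor = .data$tss) |>
        select(id = "gene_id", "chrom", "strand", "anchor") |>
        upstream_windows(genome, width = cfg$upstream_width)
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(setNames(targets$seq, targets$id)),
        out("target_windows.fasta"))
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(setNames(background$seq, background$id)),
        out("background_windows.fasta"))
    }
    list(targets = targets, background = background)
  })

  hits <- stage("scan-motifs", {
    if (is.null(windows$targets)) {
      scan_pwm(pwm, character(0))
    } else {
      scan_pwm(pwm, setNames(windows$targets$seq, windows$targets$id),
               min_css = cfg$scan$min_css, min_mss = cfg$scan$min_mss)
    }
  })
  readr::write_tsv(hits, out("motif_hits.tsv"), progress = FALSE)

  enr <- stage("enrich", {
    if (is.null(windows$targets)) NULL
    else if (cfg$enrichment$method == "permutation") {
      permutation_enrichment(pwm, windows$targets$seq, windows$background$seq,
                             n_perm = cfg$enrichment$n_perm, seed = cfg$seed)
    } else {
      bhits <- scan_pwm(pwm, setNames(windows$background$seq, windows$background$id),
                        min_css = cfg$scan$min_css, min_mss = cfg$scan$min_mss)
      fisher_enrichment(length(unique(hits$seq_id)), nrow(windows$targets),
                        length(unique(bhits$seq_id)), nrow(windows$background),
                        motif = pwm$id)
    }
  })
  if (!is.null(enr)) readr::write_tsv(tidy(enr), out("enrichment.tsv"), progress = FALSE)

  stats_tbl <- stage("stats", {
    purrr::map_dfr(c("5p", "3p"), function(s) {
      if (sum(calls$side == s) == 0) return(NULL)
      length_summary(calls, side = s)
    })
  })
  readr::write_tsv(stats_tbl, out("length_stats.tsv"), progress = FALSE)

  summary <- list(
    package_version = as.character(utils::packageVersion("meiutr")),
    seed = cfg$seed,
    simulated = is.null(cfg$inputs),
    n_segments = nrow(segments),
    n_candidates = nrow(report),
    n_called = nrow(calls),
    n_called_5p = sum(calls$side == "5p"),
    n_called_3p = sum(calls$side == "3p"),
    n_planted = if (is.null(truth)) NA else sum(truth$role == "planted"),
    n_target_windows = if (is.null(windows$targets)) 0 else nrow(windows$targets),
    n_windows_with_hit = length(unique(hits$seq_id)),
    enrichment_p = if (is.null(enr)) NA else enr$p_value,
    enrichment_method = if (is.null(enr)) NA else enr$method,
    outputs = list(calls = "mutr_calls.bed", report = "mutr_report.tsv",
                   hits = "motif_hits.tsv", stats = "length_stats.tsv")
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null")
  invisible(summary)
}
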