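## Readers/writers and the tabular data model.
##
## Internal coordinates are 0-based half-open everywhere; conversion to the
## 1-based closed convention of GFF3 (and back from BED, which is already
## half-open) happens only at file boundaries.

#' Read a genome FASTA file
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return A [Biostrings::DNAStringSet] named by the first whitespace-delimited
#'   token of each FASTA header.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop_meiutr("genome FASTA not found: %s", path)
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Write a genome FASTA file
#'
#' @param genome A named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

# Fail with the offending line number when a tab-separated interval file is
# malformed; rtracklayer's own errors do not localise the problem.
validate_column_count <- function(path, n_required, label) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "" || startsWith(ln, "#")) next
    nf <- length(strsplit(ln, "\t", fixed = TRUE)[[1]])
    if (nf < n_required) {
      stop_meiutr("malformed %s line %d in %s: %d field(s), expected >= %d",
                  label, i, path, nf, n_required)
    }
  }
  invisible(TRUE)
}

#' Read a gene/ncRNA annotation from GFF3
#'
#' Features of type `gene` (class `ORF`) and `ncRNA` (classes snoRNA, rRNA,
#' tRNA, SUT, CUT, MUT) are returned as one row each. GFF3 1-based closed
#' coordinates are converted to 0-based half-open. `tss` and `terminator`
#' attributes, when present, are taken verbatim as 0-based anchor coordinates
#' (this package's own GFF3 dialect); when absent they default to the
#' strand-appropriate ORF boundaries. Unknown classes are parsed as `"other"`.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `tss`, `terminator`, `class`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop_meiutr("annotation not found: %s", path)
  validate_column_count(path, 9, "GFF3")
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  tss = integer(), terminator = integer(), class = character()))
  }
  mc <- as.data.frame(S4Vectors::mcols(gr))
  cls <- if ("class" %in% names(mc)) as.character(mc$class) else rep(NA_character_, length(gr))
  cls[is.na(cls) | !(cls %in% KNOWN_CLASSES)] <- "other"
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop_meiutr("annotation features must carry an explicit +/- strand")
  }
  tss <- if ("tss" %in% names(mc)) suppressWarnings(as.integer(as.character(mc$tss))) else rep(NA_integer_, length(gr))
  term <- if ("terminator" %in% names(mc)) suppressWarnings(as.integer(as.character(mc$terminator))) else rep(NA_integer_, length(gr))
  tss <- ifelse(is.na(tss), ifelse(strand == "+", start0, end0), tss)
  term <- ifelse(is.na(term), ifelse(strand == "+", end0, start0), term)
  id <- if ("ID" %in% names(mc)) as.character(mc$ID) else sprintf("feature%04d", seq_along(gr))
  out <- tibble(
    gene_id = id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start = start0,
    end = end0,
    tss = as.integer(tss),
    terminator = as.integer(term),
    class = cls
  )
  validate_annotation(out)
  out
}

validate_annotation <- function(genes) {
  stopifnot(is.data.frame(genes))
  if (nrow(genes) == 0) return(invisible(genes))
  if (any(genes$start >= genes$end)) stop_meiutr("annotation has start >= end")
  plus <- genes$strand == "+"
  if (any(genes$tss[plus] > genes$terminator[plus]) ||
      any(genes$tss[!plus] < genes$terminator[!plus])) {
    stop_meiutr("tss/terminator orientation inconsistent with strand")
  }
  invisible(genes)
}

#' Write a gene/ncRNA annotation as GFF3
#'
#' Inverse of [read_annotation()]; `tss`/`terminator` are stored as attributes
#' in internal 0-based coordinates.
#'
#' @param genes Annotation tibble as returned by [read_annotation()].
#' @param path Output path.
#' @export
write_annotation <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  S4Vectors::mcols(gr)$type <- ifelse(genes$class == "ORF", "gene", "ncRNA")
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$class <- genes$class
  S4Vectors::mcols(gr)$tss <- genes$tss
  S4Vectors::mcols(gr)$terminator <- genes$terminator
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read expression segments from BED6 or GFF3
#'
#' Every segment must carry an explicit strand; BED intervals are already
#' 0-based half-open, GFF3 intervals are converted.
#'
#' @param path Path to a BED6 or GFF3 file (chosen by extension).
#' @return A tibble with columns `segment_id`, `chrom`, `strand`, `start`, `end`.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop_meiutr("segment file not found: %s", path)
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE)
  validate_column_count(path, if (is_gff) 9 else 6, if (is_gff) "GFF3" else "BED6")
  gr <- rtracklayer::import(path, format = if (is_gff) "gff3" else "bed")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop_meiutr("segments must carry an explicit +/- strand")
  }
  mc <- as.data.frame(S4Vectors::mcols(gr))
  id <- if ("name" %in% names(mc)) as.character(mc$name)
        else if ("ID" %in% names(mc)) as.character(mc$ID)
        else sprintf("seg%05d", seq_along(gr))
  tibble(
    segment_id = id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Write segments as BED6
#'
#' @param segments Segment tibble (`segment_id`, `chrom`, `strand`, `start`, `end`).
#' @param path Output path.
#' @export
write_segments <- function(segments, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   segments$chrom, segments$start, segments$end,
                   segments$segment_id, 0L, segments$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Bundle an expression table with its sample sheet
#'
#' @param values Tibble whose first column `id` names segments/genes and whose
#'   remaining columns are per-sample log2 expression values (all finite).
#' @param samples Sample sheet tibble with columns `id`, `strain`
#'   (`MATa`, `MATa/alpha`, `MATalpha/alpha`), `medium` (`YPD`, `YPA`, `SPII`,
#'   `sync`) and `timepoint` (minutes for the synchronized time course, hours
#'   otherwise).
#' @return An object of class `expression_set` (a two-element list).
#' @export
expression_set <- function(values, samples) {
  values <- as_tibble(values)
  samples <- as_tibble(samples)
  if (names(values)[1] != "id") stop_meiutr("first expression column must be 'id'")
  need <- c("id", "strain", "medium", "timepoint")
  if (!all(need %in% names(samples))) {
    stop_meiutr("sample sheet must have columns %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(samples$id)) stop_meiutr("duplicate sample ids in sample sheet")
  cols <- setdiff(names(values), "id")
  extra_cols <- setdiff(cols, samples$id)
  extra_samp <- setdiff(samples$id, cols)
  if (length(extra_cols) || length(extra_samp)) {
    stop_meiutr("expression columns and sample sheet disagree (matrix-only: %s; sheet-only: %s)",
                paste(extra_cols, collapse = ","), paste(extra_samp, collapse = ","))
  }
  vals <- as.matrix(values[cols])
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop_meiutr("expression values must all be finite numbers")
  }
  structure(list(values = values[c("id", samples$id)], samples = samples),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("<expression_set> %d rows x %d samples\n",
              nrow(x$values), nrow(x$samples)))
  invisible(x)
}

#' Read an expression matrix and sample sheet
#'
#' @param matrix_path TSV with a header; first column `id`, remaining columns
#'   one per sample id.
#' @param samplesheet_path TSV with columns `id`, `strain`, `medium`,
#'   `timepoint`.
#' @return An [expression_set()].
#' @export
read_expression <- function(matrix_path, samplesheet_path) {
  for (p in c(matrix_path, samplesheet_path)) {
    if (!file.exists(p)) stop_meiutr("expression input not found: %s", p)
  }
  values <- readr::read_tsv(matrix_path, show_col_types = FALSE, progress = FALSE)
  samples <- readr::read_tsv(samplesheet_path, show_col_types = FALSE, progress = FALSE)
  expression_set(values, samples)
}

#' Write an expression set to TSV
#'
#' @param expr An [expression_set()].
#' @param matrix_path,samplesheet_path Output paths.
#' @export
write_expression <- function(expr, matrix_path, samplesheet_path) {
  readr::write_tsv(expr$values, matrix_path, progress = FALSE)
  readr::write_tsv(expr$samples, samplesheet_path, progress = FALSE)
  invisible(matrix_path)
}

#' Read TRANSFAC-format count matrices
#'
#' Parses the standard TRANSFAC matrix dialect: an optional `ID`/`AC` line, a
#' `P0` (or `PO`) header giving the base column order, numbered count rows, and
#' a `//` block terminator. Columns are re-ordered to A,C,G,T regardless of the
#' header order.
#'
#' @param path Path to a TRANSFAC matrix file.
#' @return A named list of 4 x L count matrices (rows A,C,G,T); empty list for
#'   an empty file.
#' @export
read_transfac <- function(path) {
  if (!file.exists(path)) stop_meiutr("TRANSFAC file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  id <- NULL; order <- NULL; rows <- list(); in_block <- FALSE
  flush_block <- function() {
    if (!length(rows)) return(NULL)
    m <- do.call(rbind, rows)           # positions x 4, in header order
    colnames(m) <- order
    m <- t(m[, DNA_BASES, drop = FALSE])  # 4 x L, rows A,C,G,T
    rownames(m) <- DNA_BASES
    m
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "XX") || startsWith(ln, "CC") ||
        startsWith(ln, "BF") || startsWith(ln, "DE") || startsWith(ln, "NA ")) next
    if (grepl("^(AC|ID)\\s+", ln)) {
      in_block <- TRUE
      tok <- strsplit(ln, "\\s+")[[1]]
      if (is.null(id)) id <- tok[2] else id <- id %||% tok[2]
      if (grepl("^ID\\s+", ln)) id <- tok[2]
      next
    }
    if (grepl("^P[0O]\\s+", ln)) {
      in_block <- TRUE
      order <- toupper(strsplit(ln, "\\s+")[[1]][-1])
      if (!setequal(order, DNA_BASES)) {
        stop_meiutr("line %d: P0 header must list A,C,G,T (got '%s')", i, ln)
      }
      next
    }
    if (grepl("^[0-9]+\\s", ln)) {
      tok <- strsplit(ln, "\\s+")[[1]]
      if (length(tok) < 5) stop_meiutr("line %d: matrix row with < 4 counts", i)
      counts <- suppressWarnings(as.numeric(tok[2:5]))
      if (any(is.na(counts))) stop_meiutr("line %d: non-numeric count cell", i)
      rows[[length(rows) + 1]] <- counts
      next
    }
    if (startsWith(ln, "//")) {
      m <- flush_block()
      if (!is.null(m)) {
        out[[id %||% sprintf("matrix%d", length(out) + 1)]] <- m
      }
      id <- NULL; order <- NULL; rows <- list(); in_block <- FALSE
      next
    }
  }
  if (in_block || length(rows)) {
    stop_meiutr("TRANSFAC block not terminated by '//' in %s", path)
  }
  out
}

#' Write count matrices in TRANSFAC format
#'
#' @param matrices Named list of 4 x L count matrices (rows A,C,G,T).
#' @param path Output path.
#' @export
write_transfac <- function(matrices, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(matrices)) {
    m <- matrices[[id]]
    writeLines(c(sprintf("ID %s", id), "XX", "P0      A      C      G      T"), con)
    for (j in seq_len(ncol(m))) {
      consensus <- DNA_BASES[which.max(m[, j])]
      writeLines(sprintf("%02d %6g %6g %6g %6g      %s",
                         j, m["A", j], m["C", j], m["G", j], m["T", j], consensus), con)
    }
    writeLines(c("XX", "//"), con)
  }
  invisible(path)
}

#' Extract a strand-aware upstream sequence window
#'
#' For a plus-strand anchor the window is `[anchor - width, anchor)` on the
#' forward strand; for a minus-strand anchor it is the reverse complement of
#' `[anchor, anchor + width)`. Windows are truncated (never padded) at
#' chromosome edges, so the returned sequence has length `min(width, available)`.
#'
#' @param genome Named [Biostrings::DNAStringSet] (or named character vector).
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param anchor 0-based anchor coordinate (e.g. a TSS).
#' @param width Window width in bp (> 0).
#' @return A character scalar (possibly empty at a chromosome edge).
#' @export
upstream_window <- function(genome, chrom, strand, anchor, width = 100) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (width <= 0) stop_meiutr("width must be > 0")
  if (!chrom %in% names(genome)) stop_meiutr("chromosome '%s' not in genome", chrom)
  len <- length(genome[[chrom]])
  if (anchor < 0 || anchor > len) {
    stop_meiutr("anchor %d outside chromosome %s [0,%d]", anchor, chrom, len)
  }
  if (strand == "+") {
    s <- max(0, anchor - width)
    if (anchor == s) return("")
    as.character(Biostrings::subseq(genome[[chrom]], start = s + 1, end = anchor))
  } else if (strand == "-") {
    e <- min(len, anchor + width)
    if (e == anchor) return("")
    seq <- Biostrings::subseq(genome[[chrom]], start = anchor + 1, end = e)
    as.character(Biostrings::reverseComplement(seq))
  } else {
    stop_meiutr("strand must be '+' or '-'")
  }
}

#' Extract upstream windows for a table of anchors
#'
#' @param anchors Tibble with columns `chrom`, `strand`, `anchor` (plus any id
#'   columns, preserved).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param width Window width in bp.
#' @return The input tibble with a `seq` column appended.
#' @export
upstream_windows <- function(anchors, genome, width = 100) {
  anchors <- as_tibble(anchors)
  anchors$seq <- purrr::pmap_chr(
    anchors[c("chrom", "strand", "anchor")],
    function(chrom, strand, anchor) upstream_window(genome, chrom, strand, anchor, width)
  )
  anchors
}

#' Write mUTR calls as BED6
#'
#' The name field is `gene_id|side|timing` and the score is
#' `round(1000 * (1 - p_adjusted))` clamped to `[0, 1000]`.
#'
#' @param calls mUTR call tibble (see [call_mutrs()]); a `timing` column is
#'   used when present, `"none"` otherwise.
#' @param path Output path.
#' @export
write_mutr_bed <- function(calls, path) {
  if (nrow(calls) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  timing <- if ("timing" %in% names(calls)) as.character(calls$timing) else rep(NA_character_, nrow(calls))
  timing[is.na(timing)] <- "none"
  score <- pmin(1000, pmax(0, round(1000 * (1 - calls$p_adjusted))))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   calls$chrom, calls$start, calls$end,
                   paste(calls$gene_id, calls$side, timing, sep = "|"),
                   as.integer(score), calls$strand)
  writeLines(lines, path)
  invisible(path)
}
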