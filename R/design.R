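## The fixed 45-sample study design shared by the generator and the caller.

#' The canonical sample design
#'
#' The sample layout the analysis assumes: a synchronized haploid MATa mitotic
#' time course (0-135 min every 5 min, 28 samples), fermenting (YPD) and
#' respiring (YPA) MATa/alpha diploids, hourly sporulation samples (SPII
#' 1-12 h) of the same diploid, and a meiosis-deficient MATalpha/alpha control
#' in YPA and SPII 8 and 10 h; 45 samples in total at one replicate.
#'
#' @param replicates Replicate count per condition (>= 1). Replicated samples
#'   carry a `_repN` id suffix; correlation analysis averages replicates per
#'   condition first.
#' @return A sample sheet tibble (`id`, `strain`, `medium`, `timepoint`;
#'   minutes for the synchronized course, hours otherwise).
#' @export
sample_design <- function(replicates = 1L) {
  stopifnot(replicates >= 1)
  base <- bind_rows(
    tibble(id = sprintf("mata_sync_%03dmin", seq(0, 135, by = 5)),
           strain = "MATa", medium = "sync",
           timepoint = as.numeric(seq(0, 135, by = 5))),
    tibble(id = "dip_ypd", strain = "MATa/alpha", medium = "YPD", timepoint = NA_real_),
    tibble(id = "dip_ypa", strain = "MATa/alpha", medium = "YPA", timepoint = NA_real_),
    tibble(id = sprintf("dip_spii_%02dh", 1:12),
           strain = "MATa/alpha", medium = "SPII", timepoint = as.numeric(1:12)),
    tibble(id = "alpha_ypa", strain = "MATalpha/alpha", medium = "YPA", timepoint = NA_real_),
    tibble(id = sprintf("alpha_spii_%02dh", c(8, 10)),
           strain = "MATalpha/alpha", medium = "SPII", timepoint = c(8, 10))
  )
  if (replicates == 1L) return(base)
  purrr::map_dfr(seq_len(replicates), function(r) {
    mutate(base, id = if (r == 1L) .data$id else paste0(.data$id, "_rep", r))
  })
}

sample_classes <- function(samples) {
  with(samples, dplyr::case_when(
    strain == "MATa" ~ "mitotic_sync",
    strain == "MATa/alpha" & medium == "YPD" ~ "dip_ypd",
    strain == "MATa/alpha" & medium == "YPA" ~ "dip_ypa",
    strain == "MATa/alpha" & medium == "SPII" ~ "dip_spii",
    strain == "MATalpha/alpha" ~ "alpha_control",
    TRUE ~ "other"
  ))
}

# Averaged per-condition values used by the correlation test: YPD, YPA and
# SPII 1-12 h of the MATa/alpha diploid (14 conditions; replicates averaged).
# Returns a numeric matrix rows = ids, cols = conditions.
condition_profile <- function(expr, ids = NULL) {
  samples <- expr$samples
  values <- expr$values
  if (!is.null(ids)) {
    missing <- setdiff(ids, values$id)
    if (length(missing)) stop_meiutr("expression rows missing: %s", paste(missing, collapse = ","))
    values <- values[match(ids, values$id), ]
  }
  cond <- dplyr::case_when(
    samples$strain == "MATa/alpha" & samples$medium == "YPD" ~ "YPD",
    samples$strain == "MATa/alpha" & samples$medium == "YPA" ~ "YPA",
    samples$strain == "MATa/alpha" & samples$medium == "SPII" ~
      sprintf("SPII_%02d", samples$timepoint),
    TRUE ~ NA_character_
  )
  keep <- !is.na(cond)
  expected <- c("YPD", "YPA", sprintf("SPII_%02d", 1:12))
  got <- unique(cond[keep])
  if (!setequal(got, expected)) {
    stop_meiutr("correlation design requires YPD, YPA and SPII 1-12 h diploid samples (missing: %s)",
                paste(setdiff(expected, got), collapse = ","))
  }
  m <- as.matrix(values[, samples$id[keep], drop = FALSE])
  grp <- factor(cond[keep], levels = expected)
  out <- t(apply(m, 1, function(v) tapply(v, grp, mean)))
  rownames(out) <- values$id
  out
}
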