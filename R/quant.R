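## Exactly-specified ChIP / Q-PCR quantification calculators.

#' Relative ChIP signal from cycle thresholds
#'
#' The delta-delta-Ct ratio of immunoprecipitate to input:
#' `2^-(ct_target_ip - ct_control_ip) / 2^-(ct_target_input - ct_control_input)`,
#' i.e. target enrichment in the IP normalised to an internal control locus
#' and to the input chromatin. Vectorised; invariant under adding a constant
#' to all four Ct values.
#'
#' @param ct_target_ip,ct_control_ip,ct_target_input,ct_control_input Finite
#'   positive PCR cycle-threshold values.
#' @return Fold enrichment (1 on fully symmetric inputs).
#' @export
chip_relative_signal <- function(ct_target_ip, ct_control_ip,
                                 ct_target_input, ct_control_input) {
  cts <- c(ct_target_ip, ct_control_ip, ct_target_input, ct_control_input)
  if (any(!is.finite(cts)) || any(cts <= 0)) {
    stop_meiutr("Ct values must be finite and > 0")
  }
  2^-(ct_target_ip - ct_control_ip) / 2^-(ct_target_input - ct_control_input)
}

#' qPCR fold enrichment from gene copy numbers
#'
#' Ratio of precipitated to input copy number for the target, normalised over
#' a negative-control locus: `(target_ip / target_input) / (neg_ip / neg_input)`.
#'
#' @param target_ip_copies,target_input_copies,neg_ip_copies,neg_input_copies
#'   Positive copy numbers.
#' @return Fold enrichment.
#' @export
qpcr_fold_enrichment <- function(target_ip_copies, target_input_copies,
                                 neg_ip_copies, neg_input_copies) {
  xs <- c(target_ip_copies, target_input_copies, neg_ip_copies, neg_input_copies)
  if (any(!is.finite(xs)) || any(xs <= 0)) {
    stop_meiutr("copy numbers must be finite and > 0")
  }
  (target_ip_copies / target_input_copies) / (neg_ip_copies / neg_input_copies)
}

#' Normalise condition values to the wild type
#'
#' Divides every value by the wild-type value so that WT maps to exactly 1
#' and other conditions read as fold changes relative to it.
#'
#' @param values Named numeric vector of per-condition signals.
#' @param wt_key Name of the wild-type entry (must exist, value > 0).
#' @return Named vector of fold changes with `values[wt_key] == 1`.
#' @export
normalize_to_wt <- function(values, wt_key = "WT") {
  if (!wt_key %in% names(values)) stop_meiutr("wild-type key '%s' missing", wt_key)
  wt <- values[[wt_key]]
  if (!is.finite(wt) || wt <= 0) stop_meiutr("wild-type value must be finite and > 0")
  values / wt
}
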