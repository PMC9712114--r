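#' Cell-level filtering mask
#'
#' Retains cells whose quality score is at least 0.75, that are not flagged
#' as S-phase, and whose contaminating-read fraction is at most 5%. S-phase
#' and contamination classification are inputs produced by upstream
#' classifiers, not computed here.
#'
#' @param qc QC table (see [read_qc()]).
#' @param min_quality Minimum quality score, inclusive (default 0.75).
#' @param max_contam Maximum contaminating fraction, inclusive (default 0.05).
#' @return Named logical vector over `qc$cell_id`; `TRUE` = keep. Cells with
#'   missing quality are dropped with a message.
#' @export
filter_cells <- function(qc, min_quality = 0.75, max_contam = 0.05) {
  miss <- is.na(qc$quality)
  if (any(miss))
    message(sum(miss), " cell(s) dropped: missing quality score")
  keep <- !miss &
    qc$quality >= min_quality &
    !qc$s_phase_flag &
    qc$contam_fraction <= max_contam
  stats::setNames(keep, qc$cell_id)
}
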