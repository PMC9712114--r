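#' Detect parallel haplotype-specific copy number events
#'
#' A segment shows parallel evolution when independent subsets of cells have
#' altered the two different homologues in the same direction: the fraction
#' of cells with a gain (or loss) relative to the modal state exceeds 1% on
#' both the A and the B allele, on a segment spanning more than 4 Mbp.
#'
#' @param seg_table Genotyped disjoint segments from
#'   [disjoin_and_genotype()].
#' @param min_span Segment span must be strictly greater than this (4 Mbp).
#' @param min_frac Per-allele altered-cell fraction must be strictly greater
#'   than this (0.01).
#' @return `data.frame` of events: `segment_id`, `chrom`, `start`, `end`,
#'   `span`, `direction`, `frac_a`, `frac_b`, `ccf`, `clonality`. CCF is the
#'   fraction of cells whose total state differs from the modal total in the
#'   event direction; clonality classes follow [classify_clonality()].
#' @export
detect_parallel_cna <- function(seg_table, min_span = 4e6,
                                min_frac = 0.01) {
  out <- list()
  for (sid in unique(seg_table$segment_id)) {
    seg <- seg_table[seg_table$segment_id == sid, , drop = FALSE]
    if (seg$span[1] <= min_span) next
    ab <- .mode_pair(seg$a, seg$b)
    tmode <- as.integer(.mode_val(seg$total))
    ok <- !is.na(seg$a) & !is.na(seg$b)
    if (!any(ok)) next
    for (direction in c("gain", "loss")) {
      cmp <- if (direction == "gain") `>` else `<`
      fa <- mean(cmp(seg$a[ok], ab[1]))
      fb <- mean(cmp(seg$b[ok], ab[2]))
      if (fa > min_frac && fb > min_frac) {
        okt <- !is.na(seg$total)
        ccf <- mean(cmp(seg$total[okt], tmode))
        out[[length(out) + 1L]] <- data.frame(
          segment_id = sid, chrom = seg$chrom[1], start = seg$start[1],
          end = seg$end[1], span = seg$span[1], direction = direction,
          frac_a = fa, frac_b = fb, ccf = ccf,
          clonality = classify_clonality(ccf))
      }
    }
  }
  if (!length(out))
    return(data.frame(segment_id = integer(), chrom = character(),
                      start = integer(), end = integer(), span = numeric(),
                      direction = character(), frac_a = numeric(),
                      frac_b = numeric(), ccf = numeric(),
                      clonality = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Clonality class from a cancer cell fraction
#'
#' Clonal when CCF > 0.8, subclonal when 0.2 < CCF <= 0.8, rare when
#' CCF <= 0.2 (boundaries follow the printed inequalities exactly).
#'
#' @param ccf Numeric vector of cancer cell fractions.
#' @return Character vector in \{"clonal", "subclonal", "rare"\}.
#' @examples
#' classify_clonality(c(0.85, 0.5, 0.2))
#' @export
classify_clonality <- function(ccf) {
  ifelse(ccf > 0.8, "clonal", ifelse(ccf > 0.2, "subclonal", "rare"))
}
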