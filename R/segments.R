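# Segment-level machinery: per-cell gain/loss calls relative to ploidy,
# piecewise-constant segmentation of profiles, and the disjoint genotyped
# segment table shared by the parallel-CNA, event-rate and clonality logic.

# Maximal runs of constant value along one chromosome's unmasked bins.
# Returns first/last bin index (into the supplied vectors) and the value.
.runs <- function(values, first_idx = seq_along(values)) {
  if (!length(values)) return(NULL)
  r <- rle(values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(from = first_idx[starts], to = first_idx[ends], value = r$values)
}

#' Per-cell gain and loss segments
#'
#' Labels every unmasked bin as gain (state above the cell's ploidy), loss
#' (below) or neutral, merges consecutive bins sharing a label into segments,
#' and discards gain/loss segments whose genomic span is at most `min_span`
#' (default 1.5e6 bp, i.e. three 500-kb bins) to suppress segments caused by
#' noise in the integer states. Span is the total width of the segment's
#' unmasked bins, so calls are invariant to masked bins inside a run.
#'
#' @param cn Long copy-number table.
#' @param grid Bin grid.
#' @param ploidy Optional named ploidies; computed by [cell_ploidy()] when
#'   missing.
#' @param bin_mask Optional logical bin mask.
#' @param min_span Segments with span less than or equal to this are dropped.
#' @return `data.frame`: `cell_id`, `chrom`, `start`, `end`, `label`
#'   (gain/loss), `state`, `n_bins`, `span`.
#' @export
call_gain_loss_segments <- function(cn, grid, ploidy = NULL, bin_mask = NULL,
                                    min_span = 1.5e6) {
  keep_bins <- if (is.null(bin_mask)) rep(TRUE, nrow(grid)) else bin_mask
  state_m <- .to_matrix(cn, grid, "state")[, keep_bins, drop = FALSE]
  g <- grid[keep_bins, , drop = FALSE]
  if (is.null(ploidy))
    ploidy <- apply(state_m, 1, function(x) as.integer(.mode_val(x)))
  out <- list()
  for (ci in seq_len(nrow(state_m))) {
    pl <- ploidy[[rownames(state_m)[ci]]]
    lab <- ifelse(state_m[ci, ] > pl, "gain",
                  ifelse(state_m[ci, ] < pl, "loss", "neutral"))
    for (ch in unique(g$chrom)) {
      idx <- which(g$chrom == ch & !is.na(lab))
      runs <- .runs(lab[idx], idx)
      if (is.null(runs)) next
      runs <- runs[runs$value != "neutral", , drop = FALSE]
      for (k in seq_len(nrow(runs))) {
        bins <- runs$from[k]:runs$to[k]
        span <- sum(g$width[bins])
        if (span <= min_span) next
        out[[length(out) + 1L]] <- data.frame(
          cell_id = rownames(state_m)[ci], chrom = ch,
          start = g$start[runs$from[k]], end = g$end[runs$to[k]],
          label = runs$value[k],
          state = as.integer(.mode_val(state_m[ci, bins])),
          n_bins = length(bins), span = span)
      }
    }
  }
  if (!length(out))
    return(data.frame(cell_id = character(), chrom = character(),
                      start = integer(), end = integer(), label = character(),
                      state = integer(), n_bins = integer(), span = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gain/loss segment ratio
#'
#' @param segments Output of [call_gain_loss_segments()] (optionally one
#'   cell's subset).
#' @return List with `n_gain`, `n_loss` and `ratio`; the ratio is `Inf` with
#'   gains but no losses and `NaN` when there are neither.
#' @export
gain_loss_ratio <- function(segments) {
  n_gain <- sum(segments$label == "gain")
  n_loss <- sum(segments$label == "loss")
  list(n_gain = n_gain, n_loss = n_loss, ratio = n_gain / n_loss)
}

# Piecewise-constant segmentation of a state vector over a grid (all state
# changes are breakpoints, no gain/loss labelling, no span filter).
.segment_states <- function(states, g) {
  out <- list()
  for (ch in unique(g$chrom)) {
    idx <- which(g$chrom == ch & !is.na(states))
    runs <- .runs(states[idx], idx)
    if (is.null(runs)) next
    out[[ch]] <- data.frame(chrom = ch, start = g$start[runs$from],
                            end = g$end[runs$to], state = runs$value,
                            from = runs$from, to = runs$to)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Disjoint segmentation with per-cell genotypes
#'
#' Takes one segmentation per group (clone), forms the disjoint union of all
#' their breakpoints, and genotypes every cell on every resulting segment by
#' the modal total state and modal (a, b) pair over the segment's bins.
#'
#' @param segmentations `data.frame` with `chrom`, `start`, `end` (one row
#'   per segment, all groups concatenated; overlaps across groups are what
#'   the disjoin resolves).
#' @param hscn Long HSCN table ([infer_population_hscn()]); `state`, `a`,
#'   `b` per cell per bin.
#' @param grid Bin grid.
#' @param bin_mask Optional logical bin mask.
#' @return Long `data.frame`: `segment_id`, `chrom`, `start`, `end`, `span`,
#'   `cell_id`, `total`, `a`, `b`. Segments partition the covered genome.
#' @export
disjoin_and_genotype <- function(segmentations, hscn, grid,
                                 bin_mask = NULL) {
  gr <- GenomicRanges::disjoin(.df_gr(segmentations))
  segs <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr))
  segs <- segs[order(segs$chrom, segs$start), , drop = FALSE]
  segs$segment_id <- seq_len(nrow(segs))
  keep_bins <- if (is.null(bin_mask)) rep(TRUE, nrow(grid)) else bin_mask
  t_m <- .to_matrix(hscn, grid, "state")
  a_m <- .to_matrix(hscn, grid, "a")
  b_m <- .to_matrix(hscn, grid, "b")
  cells <- rownames(t_m)
  hit <- GenomicRanges::findOverlaps(.df_gr(segs), .grid_gr(grid))
  out <- list()
  for (si in seq_len(nrow(segs))) {
    bins <- S4Vectors::subjectHits(hit)[S4Vectors::queryHits(hit) == si]
    bins <- bins[keep_bins[bins]]
    if (!length(bins)) next
    ab <- vapply(seq_along(cells), function(ci)
      .mode_pair(a_m[ci, bins], b_m[ci, bins]), integer(2))
    out[[si]] <- data.frame(
      segment_id = segs$segment_id[si], chrom = segs$chrom[si],
      start = segs$start[si], end = segs$end[si],
      span = segs$end[si] - segs$start[si] + 1,
      cell_id = cells,
      total = apply(t_m[, bins, drop = FALSE], 1, function(x)
        as.integer(.mode_val(x))),
      a = ab[1, ], b = ab[2, ])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
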