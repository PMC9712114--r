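# Serriform structural variation (SSV): cell-to-cell variability in the
# genomic position of a shared copy-number breakpoint. Cells of a clone share
# a consensus breakpoint; each cell's own breakpoint is located by matching
# its segments to the clone's, noisy cells are removed, and the serration
# score of the event is the fraction of cells whose breakpoint position is
# rare (carried by fewer than 5% of the event's cells).

#' Normalize cell states to the clone ploidy
#'
#' `state / cell_ploidy * clone_ploidy`, real-valued; used for comparisons
#' when matching cell segments to clone segments so genome-doubled cells
#' align with their clone.
#'
#' @param states Integer state vector.
#' @param cell_ploidy,clone_ploidy Scalar ploidies; `cell_ploidy` must be
#'   positive.
#' @export
normalize_to_clone_ploidy <- function(states, cell_ploidy, clone_ploidy) {
  if (cell_ploidy == 0) stop("cell ploidy is zero", call. = FALSE)
  states / cell_ploidy * clone_ploidy
}

# relation of x to a neighbour state: -1 below, 0 equal, 1 above
.rel <- function(x, nb) sign(x - nb)

#' Match cell segments to clone consensus segments
#'
#' A clone segment is a local minimum, local maximum or intermediate
#' relative to its two neighbours; a cell segment is compatible with it only
#' when the cell segment's (ploidy-normalized) state stands in the same
#' relation to the clone segment's neighbour states (less than both, greater
#' than both, or strictly between). Chromosome-terminal clone segments have
#' one neighbour and use the one-sided comparison. Each cell segment is
#' assigned to the compatible clone segment it overlaps the most (tie:
#' leftmost); assignment is deterministic.
#'
#' @param cell_segs `data.frame` with `chrom`, `from`, `to` (bin indices)
#'   and `state` (normalized, may be real-valued).
#' @param clone_segs Same columns for the clone consensus segmentation.
#' @return Integer vector over `cell_segs` rows: matched `clone_segs` row
#'   index, `NA` when unmatched.
#' @export
match_cell_segments <- function(cell_segs, clone_segs) {
  matched <- rep(NA_integer_, nrow(cell_segs))
  for (ch in unique(cell_segs$chrom)) {
    cj <- which(clone_segs$chrom == ch)
    if (!length(cj)) next
    cl <- clone_segs[cj, , drop = FALSE]
    n <- nrow(cl)
    left <- c(NA, cl$state[-n])
    right <- c(cl$state[-1], NA)
    is_compat <- function(x, j) {
      l <- left[j]; r <- right[j]
      if (is.na(l) && is.na(r)) return(TRUE)
      if (is.na(l)) return(.rel(x, r) == .rel(cl$state[j], r))
      if (is.na(r)) return(.rel(x, l) == .rel(cl$state[j], l))
      if (cl$state[j] < l && cl$state[j] < r) return(x < l && x < r)
      if (cl$state[j] > l && cl$state[j] > r) return(x > l && x > r)
      x > min(l, r) && x < max(l, r)
    }
    for (si in which(cell_segs$chrom == ch)) {
      ov <- pmax(0, pmin(cell_segs$to[si], cl$to) -
                   pmax(cell_segs$from[si], cl$from) + 1)
      compat <- vapply(seq_len(n), function(j)
        is_compat(cell_segs$state[si], j), logical(1))
      cand <- which(compat & ov > 0)
      if (length(cand)) matched[si] <- cj[cand[which.max(ov[cand])]]
    }
  }
  matched
}

#' Breakpoint noise filter
#'
#' Cells are retained when their breakpoint noise — the mean absolute
#' difference between raw copy and the integer state over up to five bins on
#' each side of their breakpoint — does not exceed the mean noise of the
#' stable cells (cells whose breakpoint sits at the clone-level position).
#'
#' @param noise Numeric noise value per cell.
#' @param stable Logical: is the cell's breakpoint at the clone position?
#' @return Logical retained mask; `NULL` (event skipped) when no cell is
#'   stable.
#' @export
breakpoint_noise_filter <- function(noise, stable) {
  if (!any(stable)) return(NULL)
  threshold <- mean(noise[stable])
  noise <= threshold
}

#' Serration score of one breakpoint event
#'
#' Position frequencies are computed over the retained cells; a position is
#' rare when it occurs in strictly less than `rare` (default 5%) of them.
#' The score is the fraction of retained cells at rare positions, in
#' \[0, 1\].
#'
#' @param positions Breakpoint position per retained cell (any comparable
#'   scalar type).
#' @param rare Rarity threshold (strict, default 0.05).
#' @return Score; `NA` with fewer than two retained cells.
#' @examples
#' serration_score(c(rep(10, 96), 11, 12, 13, 14))  # 0.04
#' @export
serration_score <- function(positions, rare = 0.05) {
  n <- length(positions)
  if (n < 2) return(NA_real_)
  freq <- table(positions) / n
  mean(freq[as.character(positions)] < rare)
}

#' Clone-consensus breakpoint events with serration scores
#'
#' Builds clone consensus profiles, segments them into maximal
#' constant-state runs, and for every boundary between adjacent clone
#' segments locates each clone cell's own breakpoint by segment matching
#' (cell states ploidy-normalized), applies the breakpoint noise filter, and
#' scores serration. Breakpoint position is the index of the first bin of
#' the right-hand segment. An event is eligible for dataset-level summaries
#' when at least `min_cells` cells carry it and its two adjacent consensus
#' segments span at least `min_span` bp in total.
#'
#' @param cn Long copy-number table (needs `state` and `raw_copy`).
#' @param clones Named clone labels.
#' @param grid Bin grid.
#' @param bin_mask Optional logical bin mask.
#' @param window Noise-filter window, bins per side (default 5).
#' @param rare Rare-position threshold (default 0.05, strict).
#' @param min_cells Eligibility: minimum cells carrying the event (100).
#' @param min_span Eligibility: minimum total span of the two adjacent
#'   consensus segments (20 Mbp = 40 bins at 500 kb).
#' @return `data.frame`: `event_id`, `clone`, `chrom`, `position` (bin row
#'   in the unmasked grid), `start` (genomic start of the right segment),
#'   `left_state`, `right_state`, `n_cells`, `n_retained`, `score`,
#'   `eligible`. Events in clones with no stable cells are skipped.
#' @export
serration_events <- function(cn, clones, grid, bin_mask = NULL, window = 5,
                             rare = 0.05, min_cells = 100, min_span = 2e7) {
  keep_bins <- if (is.null(bin_mask)) rep(TRUE, nrow(grid)) else bin_mask
  g <- grid[keep_bins, , drop = FALSE]
  state_m <- .to_matrix(cn, grid, "state")[, keep_bins, drop = FALSE]
  raw_m <- .to_matrix(cn, grid, "raw_copy")[, keep_bins, drop = FALSE]
  cells <- rownames(state_m)
  lab <- clones[cells]
  cp <- apply(state_m, 1, function(x) as.integer(.mode_val(x)))
  out <- list()
  eid <- 0L
  for (cl in sort(unique(lab))) {
    rows <- which(lab == cl)
    cons <- apply(state_m[rows, , drop = FALSE], 2, function(x)
      as.integer(.mode_val(x)))
    clp <- as.integer(.mode_val(cons))
    clone_segs <- .segment_states(cons, g)
    if (is.null(clone_segs) || nrow(clone_segs) < 2) next
    # per-cell segmentations with normalized states
    cell_seg_list <- lapply(rows, function(ci) {
      segs <- .segment_states(state_m[ci, ], g)
      if (is.null(segs)) return(NULL)
      segs$state <- normalize_to_clone_ploidy(segs$state, cp[ci], clp)
      segs$matched <- match_cell_segments(segs, clone_segs)
      segs
    })
    names(cell_seg_list) <- cells[rows]
    for (j in seq_len(nrow(clone_segs) - 1)) {
      if (clone_segs$chrom[j] != clone_segs$chrom[j + 1]) next
      clone_pos <- clone_segs$from[j + 1]
      span <- (clone_segs$end[j] - clone_segs$start[j] + 1) +
        (clone_segs$end[j + 1] - clone_segs$start[j + 1] + 1)
      pos <- noise <- numeric(0)
      who <- character(0)
      for (cell in names(cell_seg_list)) {
        segs <- cell_seg_list[[cell]]
        if (is.null(segs)) next
        hitL <- which(segs$matched == j)
        hitR <- which(segs$matched == j + 1)
        adj <- hitR[(hitR - 1) %in% hitL]
        if (!length(adj)) next
        p <- segs$from[adj[1]]
        side <- which(g$chrom == clone_segs$chrom[j] &
                        abs(seq_len(nrow(g)) - (p - 0.5)) <= window)
        nz <- mean(abs(raw_m[cell, side] - state_m[cell, side]),
                   na.rm = TRUE)
        pos <- c(pos, p); noise <- c(noise, nz); who <- c(who, cell)
      }
      n_cells <- length(pos)
      if (!n_cells) next
      retained <- breakpoint_noise_filter(noise, pos == clone_pos)
      if (is.null(retained)) {
        message("event at ", clone_segs$chrom[j], ":", clone_pos,
                " skipped: no stable cells")
        next
      }
      eid <- eid + 1L
      out[[eid]] <- data.frame(
        event_id = eid, clone = cl, chrom = clone_segs$chrom[j],
        position = clone_pos, start = g$start[clone_pos],
        left_state = clone_segs$state[j],
        right_state = clone_segs$state[j + 1],
        n_cells = n_cells, n_retained = sum(retained),
        score = serration_score(pos[retained], rare),
        eligible = n_cells >= min_cells && span >= min_span)
    }
  }
  if (!length(out))
    return(data.frame(event_id = integer(), clone = character(),
                      chrom = character(), position = integer(),
                      start = integer(), left_state = numeric(),
                      right_state = numeric(), n_cells = integer(),
                      n_retained = integer(), score = numeric(),
                      eligible = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Dataset-level serration summary
#'
#' Restricts to eligible events and reports the score distribution and the
#' fraction of events at or above the reporting threshold.
#'
#' @param events Output of [serration_events()].
#' @param threshold Score threshold for the reported fraction (default
#'   0.15).
#' @return List with `n_events`, `scores`, `fraction_high`; all empty/NA
#'   when no event is eligible.
#' @export
serration_summary <- function(events, threshold = 0.15) {
  ok <- events[events$eligible & !is.na(events$score), , drop = FALSE]
  if (!nrow(ok))
    return(list(n_events = 0L, scores = numeric(0), fraction_high = NA_real_))
  list(n_events = nrow(ok), scores = ok$score,
       fraction_high = mean(ok$score >= threshold))
}
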