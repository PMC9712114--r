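#' Detect chromosome missegregation events
#'
#' Compares every cell to its clone's consensus profile. Cells whose ploidy
#' differs from the clone consensus ploidy are first normalized
#' (`state * clone_ploidy / cell_ploidy`, rounded half away from zero) so a
#' clean genome doubling does not register as 23 events. Per bin the offset
#' is the normalized state minus the consensus state; a chromosome is flagged
#' as missegregated with offset `k != 0` when bins with exactly that offset
#' cover at least 75% of its unmasked bins.
#'
#' @param cn Long copy-number table.
#' @param clones Named clone labels per cell.
#' @param grid Bin grid.
#' @param consensus Optional precomputed [consensus_profile()]; computed from
#'   `cn` when missing.
#' @param bin_mask Optional logical bin mask.
#' @param min_fraction Coverage threshold for calling an event (default
#'   0.75).
#' @return `data.frame` with `cell_id`, `chrom`, `offset`, `fraction` (of the
#'   chromosome's unmasked bins at that offset); zero rows when no events.
#' @export
detect_missegregations <- function(cn, clones, grid, consensus = NULL,
                                   bin_mask = NULL, min_fraction = 0.75) {
  if (is.null(consensus)) consensus <- consensus_profile(cn, clones, grid,
                                                         bin_mask = bin_mask)
  keep_bins <- if (is.null(bin_mask)) rep(TRUE, nrow(grid)) else bin_mask
  state_m <- .to_matrix(cn, grid, "state")[, keep_bins, drop = FALSE]
  g <- grid[keep_bins, , drop = FALSE]
  cells <- rownames(state_m)
  cp <- apply(state_m, 1, function(x) as.integer(.mode_val(x)))
  cl_ploidy <- clone_ploidy(consensus)
  cons_m <- do.call(rbind, lapply(split(consensus, consensus$clone),
                                  function(d) d$state[order(match(
                                    paste(d$chrom, d$start),
                                    paste(g$chrom, g$start)))]))
  rownames(cons_m) <- names(split(consensus, consensus$clone))
  out <- list()
  for (ci in seq_along(cells)) {
    cl <- clones[[cells[ci]]]
    st <- state_m[ci, ]
    if (cp[ci] != cl_ploidy[[cl]])
      st <- .round_half_away(st * cl_ploidy[[cl]] / cp[ci])
    offset <- st - cons_m[cl, ]
    for (ch in unique(g$chrom)) {
      idx <- which(g$chrom == ch & !is.na(offset))
      if (!length(idx)) next
      tb <- table(offset[idx])
      frac <- tb / length(idx)
      hit <- names(frac)[frac >= min_fraction & names(frac) != "0"]
      for (k in hit)
        out[[length(out) + 1L]] <- data.frame(
          cell_id = cells[ci], chrom = ch, offset = as.integer(k),
          fraction = as.numeric(frac[[k]]))
    }
  }
  if (!length(out))
    return(data.frame(cell_id = character(), chrom = character(),
                      offset = integer(), fraction = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
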