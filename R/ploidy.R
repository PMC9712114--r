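#' Cell ploidy as the modal copy number state
#'
#' @param cn Long copy-number table, or an integer vector of states for a
#'   single cell.
#' @param grid Bin grid (required for the long-table form).
#' @param bin_mask Optional logical bin mask; masked bins are excluded.
#' @return Named integer vector of ploidies (ties resolve to the smaller
#'   state). Errors if a cell has no unmasked bins.
#' @examples
#' cell_ploidy(c(2L, 2L, 3L))  # 2
#' @export
cell_ploidy <- function(cn, grid = NULL, bin_mask = NULL) {
  if (is.atomic(cn)) {
    x <- cn[!is.na(cn)]
    if (!length(x)) stop("all bins masked or missing", call. = FALSE)
    return(as.integer(.mode_val(x)))
  }
  m <- .to_matrix(cn, grid, "state")
  if (!is.null(bin_mask)) m <- m[, bin_mask, drop = FALSE]
  out <- apply(m, 1, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) stop("cell with all bins masked", call. = FALSE)
    as.integer(.mode_val(x))
  })
  out
}

#' Consensus (pseudobulk) profiles per cell group
#'
#' Aggregates cells of a group (clone or any custom set) into one profile per
#' bin: the mode of the integer state, the median raw copy, the median BAF
#' and the mode of the haplotype-specific (a, b) pair. Tie rules are
#' deterministic: modal ties go to the smaller value (lexicographic for
#' pairs); medians of real-valued fields use the arithmetic mean of the two
#' middle values.
#'
#' @param cn Long copy-number table.
#' @param clones Named character vector mapping `cell_id` to group label.
#' @param grid Bin grid.
#' @param hscn Optional long HSCN table from [infer_population_hscn()]; when
#'   supplied, consensus `a`, `b` and `baf` are included.
#' @param bin_mask Optional logical bin mask.
#' @return Long `data.frame`: `clone`, `chrom`, `start`, `end`, `state`,
#'   `copy`, plus `a`, `b`, `baf` when `hscn` is given, with the group size
#'   in `n_cells`. Empty groups are dropped with a warning.
#' @export
consensus_profile <- function(cn, clones, grid, hscn = NULL,
                              bin_mask = NULL) {
  state_m <- .to_matrix(cn, grid, "state")
  raw_m <- .to_matrix(cn, grid, "raw_copy")
  cells <- rownames(state_m)
  lab <- clones[cells]
  if (anyNA(lab))
    stop("cells without a clone label: ",
         paste(head(cells[is.na(lab)], 3), collapse = ", "), call. = FALSE)
  keep_bins <- if (is.null(bin_mask)) rep(TRUE, nrow(grid)) else bin_mask
  a_m <- b_m <- baf_m <- NULL
  if (!is.null(hscn)) {
    a_m <- .to_matrix(hscn, grid, "a")[cells, , drop = FALSE]
    b_m <- .to_matrix(hscn, grid, "b")[cells, , drop = FALSE]
    baf_m <- .to_matrix(hscn, grid, "baf")[cells, , drop = FALSE]
  }
  out <- list()
  for (cl in sort(unique(lab))) {
    rows <- which(lab == cl)
    if (!length(rows)) next
    g <- grid[keep_bins, , drop = FALSE]
    bi <- which(keep_bins)
    df <- data.frame(
      clone = cl, chrom = g$chrom, start = g$start, end = g$end,
      state = apply(state_m[rows, bi, drop = FALSE], 2, function(x)
        as.integer(.mode_val(x))),
      copy = apply(raw_m[rows, bi, drop = FALSE], 2, median, na.rm = TRUE),
      n_cells = length(rows))
    if (!is.null(hscn)) {
      ab <- apply(rbind(a_m[rows, bi, drop = FALSE],
                        b_m[rows, bi, drop = FALSE]), 2, function(col) {
        k <- length(col) / 2
        .mode_pair(col[seq_len(k)], col[k + seq_len(k)])
      })
      df$a <- ab[1, ]
      df$b <- ab[2, ]
      df$baf <- apply(baf_m[rows, bi, drop = FALSE], 2, median, na.rm = TRUE)
    }
    out[[cl]] <- df
  }
  if (!length(out)) warning("no non-empty groups", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Clone-level ploidy from a consensus profile
#'
#' @param consensus Output of [consensus_profile()].
#' @return Named integer vector over clones (modal consensus state, ties to
#'   the smaller value).
#' @export
clone_ploidy <- function(consensus) {
  vapply(split(consensus$state, consensus$clone),
         function(x) as.integer(.mode_val(x)), integer(1))
}
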