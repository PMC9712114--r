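#' Build a fixed-width genomic bin grid
#'
#' Creates the ordered bin table that all per-cell matrices are indexed
#' against. Coordinates are 1-based inclusive. Every bin has constant width
#' except possibly the last bin of each chromosome, which is truncated to the
#' chromosome length.
#'
#' @param chrom_sizes Named integer vector of chromosome lengths in bp.
#' @param width Bin width in bp (default 500 kb).
#' @param mappability Either a single value recycled to all bins or a vector
#'   of per-bin mappability fractions in \[0, 1\].
#' @param gc Per-bin GC fraction, recycled like `mappability`.
#' @return A `data.frame` with columns `bin_id`, `chrom`, `start`, `end`,
#'   `width`, `mappability`, `gc`, sorted by (chrom, start).
#' @examples
#' grid <- bin_grid(c(chr1 = 5e6, chr2 = 2.5e6))
#' @export
bin_grid <- function(chrom_sizes, width = 5e5, mappability = 1, gc = 0.45) {
  stopifnot(length(chrom_sizes) >= 1, !is.null(names(chrom_sizes)), width >= 1)
  rows <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- seq(1, len, by = width)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + width - 1, len))
  })
  grid <- do.call(rbind, rows)
  grid$bin_id <- seq_len(nrow(grid))
  grid$width <- grid$end - grid$start + 1L
  grid$mappability <- rep_len(mappability, nrow(grid))
  grid$gc <- rep_len(gc, nrow(grid))
  validate_bin_grid(grid)
  grid[, c("bin_id", "chrom", "start", "end", "width", "mappability", "gc")]
}

#' Validate a bin grid
#'
#' Checks sortedness, non-overlap within chromosomes, coordinate sanity and
#' that mappability/GC lie in \[0, 1\]. Called by all readers.
#'
#' @param grid A bin grid `data.frame`.
#' @return The grid, invisibly; errors name the first offending row.
#' @export
validate_bin_grid <- function(grid) {
  need <- c("chrom", "start", "end", "mappability", "gc")
  if (!all(need %in% names(grid)))
    stop("bin grid is missing columns: ",
         paste(setdiff(need, names(grid)), collapse = ", "), call. = FALSE)
  bad <- which(grid$end < grid$start)
  if (length(bad)) .stop_row("bin end < start", bad)
  for (ch in unique(grid$chrom)) {
    g <- grid[grid$chrom == ch, ]
    if (is.unsorted(g$start, strictly = TRUE))
      stop("bins out of order on ", ch, call. = FALSE)
    if (nrow(g) > 1 && any(g$start[-1] <= g$end[-nrow(g)]))
      stop("overlapping bins on ", ch, call. = FALSE)
  }
  bad <- which(grid$mappability < 0 | grid$mappability > 1)
  if (length(bad)) .stop_row("mappability outside [0, 1]", bad)
  invisible(grid)
}

#' Bin-level filtering mask
#'
#' Removes bins with low mappability or overlapping a blacklist, mirroring
#' standard single-cell WGS bin hygiene: bins whose mappability score is 0.99
#' or below are dropped, as is anything intersecting the supplied blacklist
#' intervals.
#'
#' @param grid Bin grid.
#' @param blacklist Optional `data.frame` with columns `chrom`, `start`,
#'   `end` (1-based inclusive). Intervals on chromosomes absent from the grid
#'   produce a warning and are ignored.
#' @param min_mappability Bins with mappability less than or equal to this
#'   value are removed (default 0.99).
#' @return Logical vector, one entry per grid row; `TRUE` = keep.
#' @export
filter_bins <- function(grid, blacklist = NULL, min_mappability = 0.99) {
  validate_bin_grid(grid)
  keep <- grid$mappability > min_mappability
  if (!is.null(blacklist) && nrow(blacklist)) {
    unknown <- setdiff(unique(blacklist$chrom), unique(grid$chrom))
    if (length(unknown)) {
      warning("blacklist intervals on unknown chromosome(s) ignored: ",
              paste(unknown, collapse = ", "), call. = FALSE)
      blacklist <- blacklist[!blacklist$chrom %in% unknown, , drop = FALSE]
    }
    if (nrow(blacklist)) {
      hit <- GenomicRanges::findOverlaps(.grid_gr(grid), .df_gr(blacklist))
      keep[unique(S4Vectors::queryHits(hit))] <- FALSE
    }
  }
  keep
}

.grid_gr <- function(grid) {
  GenomicRanges::GRanges(grid$chrom,
                         IRanges::IRanges(grid$start, grid$end))
}

.df_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
}

#' Centromere coordinate table
#'
#' One record per chromosome; used to classify events as whole-chromosome,
#' arm-level or segmental.
#'
#' @param chrom,start,end Vectors of equal length; `start`/`end` delimit the
#'   centromere (1-based inclusive).
#' @return A validated `data.frame`.
#' @export
centromere_table <- function(chrom, start, end) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (anyDuplicated(chrom))
    stop("one centromere record per chromosome required", call. = FALSE)
  data.frame(chrom = as.character(chrom), start = start, end = end)
}

#' Midpoint centromeres for a grid
#'
#' Convenience constructor placing each centromere at the middle of the
#' chromosome; used by the simulator and tests.
#'
#' @param grid Bin grid.
#' @export
default_centromeres <- function(grid) {
  sp <- split(grid, grid$chrom)
  rows <- lapply(sp, function(g) {
    mid <- (min(g$start) + max(g$end)) / 2
    data.frame(chrom = g$chrom[1], start = floor(mid), end = floor(mid) + 1)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
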