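# Delimited-text readers and writers for every table the package consumes.
# All tables are plain TSV with a header so fixtures stay diffable; the only
# binary-adjacent format at the boundary is BED (0-based half-open), which is
# converted to 1-based inclusive coordinates on read.

#' Read / write a bin grid TSV
#'
#' Columns: `chrom`, `start`, `end`, `mappability`, `gc` (plus optional
#' `bin_id`, `width`, regenerated if absent).
#'
#' @param path File path.
#' @return `read_bin_grid`: a validated bin grid.
#' @export
read_bin_grid <- function(path) {
  grid <- read.delim(path, stringsAsFactors = FALSE)
  if (is.null(grid$bin_id)) grid$bin_id <- seq_len(nrow(grid))
  if (is.null(grid$width)) grid$width <- grid$end - grid$start + 1L
  validate_bin_grid(grid)
  grid[, c("bin_id", "chrom", "start", "end", "width", "mappability", "gc")]
}

#' @rdname read_bin_grid
#' @param grid Bin grid to serialize.
#' @export
write_bin_grid <- function(grid, path) {
  write.table(grid, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a per-cell copy-number table
#'
#' Long TSV with columns `cell_id`, `chrom`, `start`, `end`, `state`,
#' `raw_copy`. `state` is the integer total copy number; `raw_copy` the
#' GC-corrected read count scaled so the per-cell mean over unmasked bins
#' equals the cell ploidy.
#'
#' @param path File path.
#' @param grid Optional bin grid; when supplied, rows are checked to lie on
#'   the grid.
#' @export
read_cn <- function(path, grid = NULL) {
  cn <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "chrom", "start", "end", "state", "raw_copy")
  miss <- setdiff(need, names(cn))
  if (length(miss))
    stop("copy-number table missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(cn$state < 0)
  if (length(bad)) .stop_row("negative copy number state", bad)
  bad <- which(!is.na(cn$raw_copy) & cn$raw_copy < 0)
  if (length(bad)) .stop_row("negative raw copy", bad)
  if (!is.null(grid)) {
    idx <- .bin_index(cn, grid)
    if (anyNA(idx)) .stop_row("bin not on grid", which(is.na(idx)))
  }
  cn
}

#' @rdname read_cn
#' @param cn Copy-number table to serialize.
#' @export
write_cn <- function(cn, path) {
  write.table(cn, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write haplotype-block allele counts
#'
#' Long TSV with columns `cell_id`, `chrom`, `start`, `end`, `b_count`,
#' `t_count`; `b_count` is the number of reads supporting the B haplotype of
#' the block, `t_count` the total informative reads. The invariant
#' `0 <= b_count <= t_count` is enforced on read.
#'
#' @param path File path.
#' @export
read_alleles <- function(path) {
  al <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "chrom", "start", "end", "b_count", "t_count")
  miss <- setdiff(need, names(al))
  if (length(miss))
    stop("allele-count table missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(al$b_count < 0 | al$t_count < 0)
  if (length(bad)) .stop_row("negative allele count", bad)
  bad <- which(al$b_count > al$t_count)
  if (length(bad)) .stop_row("b_count > t_count", bad)
  al
}

#' @rdname read_alleles
#' @param alleles Allele-count table to serialize.
#' @export
write_alleles <- function(alleles, path) {
  write.table(alleles, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write per-cell quality-control records
#'
#' Columns: `cell_id`, `quality` in \[0,1\], `s_phase_flag` (logical),
#' `contam_fraction` in \[0,1\], `clone` (label; clone assignment is an
#' input, not computed here).
#'
#' @param path File path.
#' @export
read_qc <- function(path) {
  qc <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "quality", "s_phase_flag", "contam_fraction", "clone")
  miss <- setdiff(need, names(qc))
  if (length(miss))
    stop("QC table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  qc$s_phase_flag <- as.logical(qc$s_phase_flag)
  bad <- which(!is.na(qc$quality) & (qc$quality < 0 | qc$quality > 1))
  if (length(bad)) .stop_row("quality outside [0, 1]", bad)
  qc
}

#' @rdname read_qc
#' @param qc QC table to serialize.
#' @export
write_qc <- function(qc, path) {
  write.table(qc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED blacklist
#'
#' BED is 0-based half-open; coordinates are converted to the package's
#' 1-based inclusive convention at this boundary only.
#'
#' @param path BED file (3+ columns, no header).
#' @return `data.frame` with `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_blacklist_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = bed[[1]], start = bed[[2]] + 1L, end = bed[[3]])
}

#' @rdname read_blacklist_bed
#' @param blacklist 1-based inclusive intervals to write as BED.
#' @export
write_blacklist_bed <- function(blacklist, path) {
  bed <- data.frame(blacklist$chrom, blacklist$start - 1L, blacklist$end)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- internal long-table <-> matrix plumbing ---------------------------------

.bin_index <- function(df, grid) {
  match(paste(df$chrom, df$start), paste(grid$chrom, grid$start))
}

# cells x bins matrix of `value` from a long table; missing entries NA
.to_matrix <- function(df, grid, value) {
  cells <- sort(unique(df$cell_id))
  m <- matrix(NA_real_, length(cells), nrow(grid),
              dimnames = list(cells, grid$bin_id))
  m[cbind(match(df$cell_id, cells), .bin_index(df, grid))] <- df[[value]]
  m
}

.from_matrix <- function(m, grid, value) {
  df <- data.frame(cell_id = rep(rownames(m), times = ncol(m)),
                   chrom = rep(grid$chrom, each = nrow(m)),
                   start = rep(grid$start, each = nrow(m)),
                   end = rep(grid$end, each = nrow(m)))
  df[[value]] <- as.vector(m)
  df[order(df$cell_id, .bin_index(df, grid)), , drop = FALSE]
}
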