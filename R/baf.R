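#' B-allele frequency
#'
#' @param b_count,t_count Integer vectors; B-supporting and total informative
#'   read counts.
#' @return `b_count / t_count`, `NA` where `t_count` is 0.
#' @examples
#' compute_baf(3, 12)   # 0.25
#' @export
compute_baf <- function(b_count, t_count) {
  ifelse(t_count > 0, b_count / t_count, NA_real_)
}

#' Population-level phasing of haplotype blocks
#'
#' Haplotype blocks arrive with arbitrary orientation: the "B" allele of one
#' block need not lie on the same homologue as the "B" allele of the next.
#' Because copy number alterations make one homologue the chromosome-wide
#' minor allele in aggregate, flipping every block whose population-aggregate
#' BAF exceeds 0.5 aligns all blocks of a chromosome to a consistent
#' homologue (aggregate B becomes the chromosome-level minor allele).
#'
#' @param alleles Long allele-count table (see [read_alleles()]).
#' @return A list with `alleles` (counts after orientation, same shape as the
#'   input) and `orientation`, a per-block `data.frame` (chrom, start, end,
#'   orientation in \{+1, -1\}, aggregate_baf after orientation). Blocks with
#'   zero total count across all cells are dropped with a warning. The
#'   operation is deterministic: blocks at aggregate BAF exactly 0.5 keep
#'   their orientation.
#' @export
phase_blocks <- function(alleles) {
  key <- paste(alleles$chrom, alleles$start, alleles$end)
  bsum <- tapply(alleles$b_count, key, sum)
  tsum <- tapply(alleles$t_count, key, sum)
  dead <- names(tsum)[tsum == 0]
  if (length(dead)) {
    warning(length(dead), " block(s) with zero total counts dropped",
            call. = FALSE)
    keep <- !key %in% dead
    alleles <- alleles[keep, , drop = FALSE]
    key <- key[keep]
  }
  agg <- bsum[key] / tsum[key]
  flip <- agg > 0.5
  out <- alleles
  out$b_count <- ifelse(flip, alleles$t_count - alleles$b_count,
                        alleles$b_count)
  ori_key <- !duplicated(key)
  orientation <- data.frame(
    chrom = alleles$chrom[ori_key],
    start = alleles$start[ori_key],
    end = alleles$end[ori_key],
    orientation = ifelse(flip[ori_key], -1L, 1L),
    aggregate_baf = ifelse(flip[ori_key], 1 - agg[ori_key], agg[ori_key]))
  rownames(orientation) <- NULL
  list(alleles = out, orientation = orientation)
}

# Apply an orientation table (per-block +1/-1) to an allele-count table.
.apply_orientation <- function(alleles, orientation) {
  key <- paste(alleles$chrom, alleles$start, alleles$end)
  okey <- paste(orientation$chrom, orientation$start, orientation$end)
  o <- orientation$orientation[match(key, okey)]
  o[is.na(o)] <- 1L
  out <- alleles
  out$b_count <- ifelse(o < 0, alleles$t_count - alleles$b_count,
                        alleles$b_count)
  out
}

#' Aggregate block allele counts to grid bins
#'
#' Each block is assigned to the bin containing its midpoint; counts are
#' summed per cell per bin.
#'
#' @param alleles Long allele-count table (already oriented).
#' @param grid Bin grid.
#' @return `data.frame` with `cell_id`, `bin_id`, `b`, `t`.
#' @export
aggregate_blocks_to_bins <- function(alleles, grid) {
  mid <- floor((alleles$start + alleles$end) / 2)
  gr <- GenomicRanges::GRanges(alleles$chrom, IRanges::IRanges(mid, mid))
  hit <- GenomicRanges::findOverlaps(gr, .grid_gr(grid))
  bin <- rep(NA_integer_, nrow(alleles))
  bin[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
  keep <- !is.na(bin)
  key <- paste(alleles$cell_id[keep], bin[keep])
  b <- tapply(alleles$b_count[keep], key, sum)
  t <- tapply(alleles$t_count[keep], key, sum)
  parts <- do.call(rbind, strsplit(names(b), " ", fixed = TRUE))
  out <- data.frame(cell_id = parts[, 1], bin_id = as.integer(parts[, 2]),
                    b = as.vector(b), t = as.vector(t))
  out[order(out$cell_id, out$bin_id), , drop = FALSE]
}
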