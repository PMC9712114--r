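# Mapping DNA-derived haplotype phasing onto scRNA-seq SNP counts. SNP
# counts in scRNA-seq are two orders of magnitude sparser than in scDNA, so
# they are aggregated over large segments (>= 10 Mbp) and low-count cells
# are removed before computing per-cell allelic imbalance.

#' Aggregate phased scRNA SNP counts to segment-level BAF
#'
#' SNP phase orientations are taken from the DNA phasing upstream; this
#' function assigns each SNP to the segment containing it, drops segments
#' shorter than `min_segment` and cells with fewer than `min_counts` total
#' SNP counts, and computes per cell per segment BAF as the ratio of summed
#' counts.
#'
#' @param snps `data.frame`: `cell_id`, `chrom`, `pos`, `b_count`,
#'   `t_count`.
#' @param segments `data.frame`: `segment_id`, `chrom`, `start`, `end`.
#' @param min_segment Minimum segment span in bp, inclusive (default 10
#'   Mbp).
#' @param min_counts Minimum per-cell total SNP counts, cells strictly below
#'   are removed (default 200).
#' @return Long `data.frame` (`cell_id`, `segment_id`, `b`, `t`, `baf`);
#'   segment/cell combinations with zero counts are absent (missing).
#'   Attribute `dropped_cells` lists removed cells.
#' @export
aggregate_rna_baf <- function(snps, segments, min_segment = 1e7,
                              min_counts = 200) {
  seg <- segments[(segments$end - segments$start + 1) >= min_segment, ,
                  drop = FALSE]
  totals <- tapply(snps$t_count, snps$cell_id, sum)
  dropped <- names(totals)[totals < min_counts]
  snps <- snps[!snps$cell_id %in% dropped, , drop = FALSE]
  hit <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(snps$chrom, IRanges::IRanges(snps$pos, snps$pos)),
    .df_gr(seg))
  qi <- S4Vectors::queryHits(hit)
  si <- S4Vectors::subjectHits(hit)
  key <- paste(snps$cell_id[qi], seg$segment_id[si])
  b <- tapply(snps$b_count[qi], key, sum)
  t <- tapply(snps$t_count[qi], key, sum)
  parts <- do.call(rbind, strsplit(names(b), " ", fixed = TRUE))
  out <- data.frame(cell_id = parts[, 1], segment_id = parts[, 2],
                    b = as.vector(b), t = as.vector(t))
  out <- out[out$t > 0, , drop = FALSE]
  out$baf <- out$b / out$t
  out <- out[order(out$cell_id, out$segment_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_cells") <- dropped
  out
}

#' Compare segment-level BAF between DNA and RNA modalities
#'
#' Averages BAF per segment in each modality over cells and reports the
#' Pearson correlation across shared segments; symmetric in modality order.
#'
#' @param dna,rna Long tables with `segment_id` and `baf` (e.g. DNA segment
#'   BAFs and [aggregate_rna_baf()] output).
#' @return List with `per_segment` (`segment_id`, `dna`, `rna`) and
#'   `correlation` (`NA` with fewer than three shared segments).
#' @export
compare_dna_rna_baf <- function(dna, rna) {
  d <- tapply(dna$baf, as.character(dna$segment_id), mean, na.rm = TRUE)
  r <- tapply(rna$baf, as.character(rna$segment_id), mean, na.rm = TRUE)
  shared <- intersect(names(d), names(r))
  per_seg <- data.frame(segment_id = shared, dna = as.numeric(d[shared]),
                        rna = as.numeric(r[shared]))
  corr <- if (length(shared) >= 3) cor(per_seg$dna, per_seg$rna) else NA_real_
  list(per_segment = per_seg, correlation = corr)
}

#' Neighbourhood enrichment of allelic states
#'
#' For each cell, the observed fraction of its nearest neighbours sharing
#' its allelic state is divided by the expected fraction (the global
#' fraction of cells in that state) and log2-transformed, so 0 denotes a
#' perfectly mixed neighbourhood, positive values overrepresentation and
#' negative values underrepresentation. An observed fraction of 0 yields
#' `-Inf`, reported as a censored minimum.
#'
#' @param neighbors Named list: for each cell id, the character vector of
#'   its neighbour cell ids (graph construction is upstream; see
#'   [knn_graph()]).
#' @param states Named character vector of per-cell allelic states.
#' @return `data.frame`: `cell_id`, `state`, `observed`, `expected`,
#'   `score`.
#' @examples
#' nn <- list(c1 = c("c2", "c3"), c2 = c("c1", "c3"), c3 = c("c1", "c2"))
#' st <- c(c1 = "A", c2 = "A", c3 = "B")
#' nn_enrichment(nn, st)
#' @export
nn_enrichment <- function(neighbors, states) {
  global <- table(states) / length(states)
  rows <- lapply(names(neighbors), function(cell) {
    st <- states[[cell]]
    nb <- states[neighbors[[cell]]]
    observed <- mean(nb == st)
    expected <- as.numeric(global[[st]])
    data.frame(cell_id = cell, state = st, observed = observed,
               expected = expected, score = log2(observed / expected))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' k-nearest-neighbour lists from an embedding
#'
#' Utility for building the neighbour input of [nn_enrichment()] from any
#' per-cell embedding matrix (Euclidean distance).
#'
#' @param embedding Numeric matrix, rows = cells (rownames required).
#' @param k Number of neighbours.
#' @return Named list of neighbour id vectors.
#' @export
knn_graph <- function(embedding, k) {
  d <- as.matrix(dist(embedding))
  diag(d) <- Inf
  out <- lapply(seq_len(nrow(d)), function(i)
    rownames(d)[order(d[i, ])[seq_len(k)]])
  names(out) <- rownames(d)
  out
}
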