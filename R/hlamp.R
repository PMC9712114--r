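# High-level amplification (HLAMP) statistics. A HLAMP is a locus at 10 or
# more copies; the bin-level detection rule requires at least 10 cells at raw
# copy >= 10 so singleton outlier cells do not nominate loci.

#' Detect HLAMP bins
#'
#' @param cn Long copy-number table with `raw_copy`.
#' @param grid Bin grid.
#' @param min_copy Raw copy threshold, inclusive (default 10).
#' @param min_cells Minimum number of cells at or above `min_copy`,
#'   inclusive (default 10).
#' @param bin_mask Optional logical bin mask.
#' @return `data.frame` of flagged bins: `bin_id`, `chrom`, `start`, `end`,
#'   `n_cells_high`.
#' @export
detect_hlamp_bins <- function(cn, grid, min_copy = 10, min_cells = 10,
                              bin_mask = NULL) {
  raw_m <- .to_matrix(cn, grid, "raw_copy")
  n_high <- colSums(raw_m >= min_copy, na.rm = TRUE)
  keep <- n_high >= min_cells
  if (!is.null(bin_mask)) keep <- keep & bin_mask
  out <- grid[keep, c("bin_id", "chrom", "start", "end")]
  out$n_cells_high <- n_high[keep]
  rownames(out) <- NULL
  out
}

#' HLAMP copy number variance
#'
#' Cell-to-cell variance of the amplification amplitude, adjusted for ploidy
#' and clone: each cell's raw copy is divided by its ploidy, the clone mean
#' of that quantity (per bin) is subtracted, and the variance of the adjusted
#' values across cells is reported per HLAMP bin together with the dataset
#' mean over HLAMP bins.
#'
#' @param cn Long copy-number table.
#' @param clones Named clone labels per cell.
#' @param grid Bin grid.
#' @param hlamp_bins Output of [detect_hlamp_bins()] (or any bin subset).
#' @param ploidy Optional named ploidies; computed when missing.
#' @return List with `per_bin` (`bin_id`, `variance`) and `mean_variance`.
#'   Single-cell clones contribute adjusted values of exactly 0.
#' @export
hlamp_copy_variance <- function(cn, clones, grid, hlamp_bins,
                                ploidy = NULL) {
  raw_m <- .to_matrix(cn, grid, "raw_copy")
  cells <- rownames(raw_m)
  if (is.null(ploidy))
    ploidy <- cell_ploidy(cn, grid)
  rel <- raw_m / ploidy[cells]
  lab <- clones[cells]
  for (cl in unique(lab)) {
    rows <- which(lab == cl)
    mu <- colMeans(rel[rows, , drop = FALSE], na.rm = TRUE)
    rel[rows, ] <- sweep(rel[rows, , drop = FALSE], 2, mu)
  }
  bins <- hlamp_bins$bin_id
  v <- apply(rel[, bins, drop = FALSE], 2, var, na.rm = TRUE)
  list(per_bin = data.frame(bin_id = bins, variance = as.numeric(v)),
       mean_variance = mean(v, na.rm = TRUE))
}

#' Clone-level amplitude ratio over gene regions
#'
#' For each gene, the ratio of the maximum to the minimum clone consensus
#' copy over the gene's bins; genes with ratio at least 2 are flagged as
#' having variable amplitude between clones (minimum 0 gives an infinite,
#' variable ratio).
#'
#' @param consensus Output of [consensus_profile()] (needs `copy`).
#' @param genes `data.frame` with `gene`, `chrom`, `start`, `end`.
#' @param grid Bin grid.
#' @param min_ratio Variability threshold, inclusive (default 2).
#' @return `data.frame`: `gene`, `max_copy`, `min_copy`, `ratio`,
#'   `variable`. Errors when a gene lies outside the grid.
#' @export
clone_amplitude_ratio <- function(consensus, genes, grid, min_ratio = 2) {
  if (length(unique(consensus$clone)) < 2)
    stop("at least two clones required", call. = FALSE)
  hit <- suppressWarnings(
    GenomicRanges::findOverlaps(.df_gr(genes), .grid_gr(grid)))
  out <- list()
  for (gi in seq_len(nrow(genes))) {
    bins <- S4Vectors::subjectHits(hit)[S4Vectors::queryHits(hit) == gi]
    if (!length(bins))
      stop("gene outside bin grid: ", genes$gene[gi], call. = FALSE)
    g <- grid[bins, ]
    sel <- paste(consensus$chrom, consensus$start) %in% paste(g$chrom, g$start)
    cl_copy <- tapply(consensus$copy[sel], consensus$clone[sel], mean,
                      na.rm = TRUE)
    mx <- max(cl_copy); mn <- min(cl_copy)
    ratio <- if (mn == 0) Inf else mx / mn
    out[[gi]] <- data.frame(gene = genes$gene[gi], max_copy = mx,
                            min_copy = mn, ratio = ratio,
                            variable = ratio >= min_ratio)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genomic feature vector around a HLAMP locus
#'
#' Summarizes the 15-Mbp flanks of each locus of interest: Shannon entropy of
#' the haplotype-specific state frequencies in the window, structural variant
#' count and type proportions (fold-back inversion, duplication, deletion,
#' translocation), number of chromosomes involved in translocations, the
#' ratio of the locus bin's copy to the chromosome mean, mean copy state,
#' mean segment size and count, and mean minor-allele copy — all averaged
#' across cells. Windows are clipped at chromosome ends; windows with no SVs
#' report zero for the SV-derived features.
#'
#' @param loci `data.frame` with `locus`, `chrom`, `pos`.
#' @param hscn Long HSCN table.
#' @param cn Long copy-number table.
#' @param svs SV table: `chrom1`, `pos1`, `chrom2`, `pos2`, `type` with type
#'   in \{foldback, duplication, deletion, translocation, ...\}; an input —
#'   SV calling is upstream.
#' @param grid Bin grid.
#' @param window Flank size either side of the locus (default 15 Mbp).
#' @return One row per locus of standardized-ready numeric features.
#' @export
hlamp_feature_vector <- function(loci, hscn, cn, svs, grid, window = 15e6) {
  t_m <- .to_matrix(hscn, grid, "state")
  a_m <- .to_matrix(hscn, grid, "a")
  b_m <- .to_matrix(hscn, grid, "b")
  raw_m <- .to_matrix(cn, grid, "raw_copy")
  out <- list()
  for (li in seq_len(nrow(loci))) {
    ch <- loci$chrom[li]; pos <- loci$pos[li]
    lo <- pos - window; hi <- pos + window
    bins <- which(grid$chrom == ch & grid$end >= lo & grid$start <= hi)
    locus_bin <- which(grid$chrom == ch & grid$start <= pos &
                         grid$end >= pos)
    chrom_bins <- which(grid$chrom == ch)
    key <- paste(a_m[, bins, drop = FALSE], b_m[, bins, drop = FALSE])
    pfreq <- table(key) / length(key)
    entropy <- -sum(pfreq * log2(pfreq))
    in_win <- (svs$chrom1 == ch & svs$pos1 >= lo & svs$pos1 <= hi) |
      (svs$chrom2 == ch & svs$pos2 >= lo & svs$pos2 <= hi)
    sv <- svs[in_win, , drop = FALSE]
    n_sv <- nrow(sv)
    prop <- function(tp) if (n_sv) mean(sv$type == tp) else 0
    tr <- sv[sv$type == "translocation", , drop = FALSE]
    n_tr_chrom <- length(unique(c(tr$chrom1, tr$chrom2)))
    # per-cell segment structure within the window
    seg_stats <- t(vapply(seq_len(nrow(t_m)), function(ci) {
      r <- rle(t_m[ci, bins])
      c(mean(r$lengths) * mean(grid$width[bins]), length(r$lengths))
    }, numeric(2)))
    out[[li]] <- data.frame(
      locus = loci$locus[li],
      entropy = entropy,
      n_sv = n_sv,
      prop_foldback = prop("foldback"),
      prop_duplication = prop("duplication"),
      prop_deletion = prop("deletion"),
      prop_translocation = prop("translocation"),
      n_translocation_chroms = n_tr_chrom,
      copy_ratio = mean(raw_m[, locus_bin], na.rm = TRUE) /
        mean(raw_m[, chrom_bins], na.rm = TRUE),
      mean_copy = mean(t_m[, bins], na.rm = TRUE),
      mean_segment_size = mean(seg_stats[, 1]),
      mean_segment_count = mean(seg_stats[, 2]),
      mean_minor_copy = mean(pmin(a_m[, bins], b_m[, bins]), na.rm = TRUE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cluster HLAMP feature vectors
#'
#' Standardizes the feature matrix, clusters hierarchically (complete
#' linkage, Euclidean) and picks the number of clusters in `2:k_max` with the
#' best mean silhouette width.
#'
#' @param features Output of [hlamp_feature_vector()] for several loci.
#' @param k_max Largest number of clusters to consider.
#' @return List with `clusters` (named integer vector), `k`, `silhouette`
#'   (mean width at the chosen `k`).
#' @export
cluster_hlamp_features <- function(features, k_max = 6) {
  m <- scale(as.matrix(features[, setdiff(names(features), "locus")]))
  m[, apply(m, 2, function(x) all(!is.finite(x)))] <- 0
  m[!is.finite(m)] <- 0
  d <- dist(m)
  hc <- hclust(d, method = "complete")
  ks <- 2:min(k_max, nrow(m) - 1)
  sil <- vapply(ks, function(k) {
    cl <- cutree(hc, k)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, numeric(1))
  k <- ks[which.max(sil)]
  list(clusters = setNames(cutree(hc, k), features$locus), k = k,
       silhouette = max(sil))
}
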