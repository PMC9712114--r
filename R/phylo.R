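# Phylogeny-based statistics: parsimony event rates on single-cell trees
# and cophenetic diversity. Trees are `ape` phylo objects (Newick at the
# boundary); tree inference itself is upstream.

# Sankoff small-parsimony score for binary tip states on an arbitrary
# (possibly multifurcating) rooted tree with unit transition costs. Exact
# minimal-cost ancestral labelling by dynamic programming.
.sankoff_score <- function(tree, states) {
  tips <- tree$tip.label
  x <- states[tips]
  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  cost <- matrix(Inf, n_node, 2)
  cost[cbind(seq_len(n_tip), x + 1L)] <- 0
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (node in unique(edge[, 1])) {
    kids <- edge[edge[, 1] == node, 2]
    for (s in 1:2) {
      tot <- 0
      for (k in kids) tot <- tot + min(cost[k, s], cost[k, 3 - s] + 1)
      cost[node, s] <- tot
    }
  }
  root <- setdiff(edge[, 1], edge[, 2])[1]
  min(cost[root, ])
}

#' Parsimony event rates from a single-cell phylogeny
#'
#' For every genotyped disjoint segment, each cell is labelled gained (total
#' above the modal state across cells) or not, and lost or not; the minimal
#' number of state transitions explaining the labels on the tree (unit
#' costs, Sankoff ancestral state reconstruction) is the segment's parsimony
#' score. Scores are summed within segment-scale class (whole chromosome,
#' arm, segmental), direction and copy number background, and divided by the
#' number of cells, giving effective events per cell division.
#'
#' @param tree `phylo` object whose tip labels are cell ids (a superset of
#'   tips is an error; tips without genotypes are dropped with a warning).
#' @param seg_table Genotyped segments from [disjoin_and_genotype()].
#' @param grid Bin grid.
#' @param centromeres [centromere_table()] for arm classification.
#' @param bin_mask Optional logical bin mask.
#' @return List with `rates` (per class x direction x background: `score`,
#'   `n_cells`, `rate`) and `per_segment` detail.
#' @export
parsimony_event_rate <- function(tree, seg_table, grid, centromeres,
                                 bin_mask = NULL) {
  cells <- unique(seg_table$cell_id)
  missing_tips <- setdiff(tree$tip.label, cells)
  if (length(missing_tips)) {
    warning(length(missing_tips),
            " tip(s) without genotypes dropped", call. = FALSE)
    tree <- ape::drop.tip(tree, missing_tips)
  }
  n_cells <- length(tree$tip.label)
  segs <- unique(seg_table[, c("segment_id", "chrom", "start", "end")])
  scale <- classify_segment_scale(segs, grid, centromeres,
                                  bin_mask = bin_mask)
  per_seg <- list()
  for (k in seq_len(nrow(segs))) {
    sid <- segs$segment_id[k]
    seg <- seg_table[seg_table$segment_id == sid, , drop = FALSE]
    seg <- seg[match(tree$tip.label, seg$cell_id), , drop = FALSE]
    tmode <- as.integer(.mode_val(seg$total))
    ab <- .mode_pair(seg$a, seg$b)
    background <- paste0(ab[1], "|", ab[2])
    for (direction in c("gain", "loss")) {
      cmp <- if (direction == "gain") `>` else `<`
      st <- as.integer(cmp(seg$total, tmode))
      st[is.na(st)] <- 0L
      names(st) <- tree$tip.label
      score <- if (any(st == 1)) .sankoff_score(tree, st) else 0
      per_seg[[length(per_seg) + 1L]] <- data.frame(
        segment_id = sid, class = scale[k], direction = direction,
        background = background, score = score)
    }
  }
  per_seg <- do.call(rbind, per_seg)
  agg <- stats::aggregate(score ~ class + direction + background,
                          data = per_seg, FUN = sum)
  agg$n_cells <- n_cells
  agg$rate <- agg$score / n_cells
  list(rates = agg, per_segment = per_seg)
}

#' Classify segment scale: whole chromosome, arm or segmental
#'
#' Whole chromosome when the segment covers at least 95% of the
#' chromosome's unmasked bins; arm when it covers at least 95% of one arm
#' (but less than 95% of the chromosome); segmental otherwise. A chromosome
#' without a centromere record is classified segmental with a warning.
#'
#' @param segments `data.frame` with `chrom`, `start`, `end`.
#' @param grid Bin grid.
#' @param centromeres [centromere_table()].
#' @param tol Coverage tolerance (default 0.95).
#' @param bin_mask Optional logical bin mask.
#' @return Character vector over segment rows.
#' @export
classify_segment_scale <- function(segments, grid, centromeres, tol = 0.95,
                                   bin_mask = NULL) {
  keep_bins <- if (is.null(bin_mask)) rep(TRUE, nrow(grid)) else bin_mask
  g <- grid[keep_bins, , drop = FALSE]
  vapply(seq_len(nrow(segments)), function(k) {
    ch <- segments$chrom[k]
    bins <- g$chrom == ch
    if (!any(bins)) return("segmental")
    covered <- bins & g$start <= segments$end[k] & g$end >= segments$start[k]
    if (sum(covered) / sum(bins) >= tol) return("whole_chromosome")
    cen <- centromeres[centromeres$chrom == ch, , drop = FALSE]
    if (!nrow(cen)) {
      warning("no centromere record for ", ch, "; segmental assumed",
              call. = FALSE)
      return("segmental")
    }
    p_arm <- bins & g$end < cen$start[1]
    q_arm <- bins & g$start > cen$end[1]
    for (arm in list(p_arm, q_arm)) {
      if (any(arm) && sum(covered & arm) / sum(arm) >= tol) return("arm")
    }
    "segmental"
  }, character(1))
}

#' Mean pairwise phylogenetic distance between tips
#'
#' Cophenetic diversity: the mean path length over all unordered tip pairs.
#' With branch lengths in copy-number change points this measures the
#' genomic diversity of the sampled population.
#'
#' @param tree `phylo` with branch lengths; needs at least two tips.
#' @return Scalar mean distance.
#' @export
cophenetic_diversity <- function(tree) {
  if (length(tree$tip.label) < 2)
    stop("need at least two tips", call. = FALSE)
  d <- ape::cophenetic.phylo(tree)
  mean(d[upper.tri(d)])
}
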