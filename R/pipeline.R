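#' Run the full analysis pipeline on a set of input tables
#'
#' One-shot runner: read tables, apply bin and cell filters, infer
#' haplotype-specific copy number, compute per-cell and per-clone metrics
#' (ploidy, consensus profiles, missegregation, gain/loss segments, HLAMP
#' variance), serration events, the disjoint genotyped segment table,
#' parallel events, the pairwise distance summary and — when a tree is
#' supplied — parsimony event rates and cophenetic diversity. All outputs
#' are written as TSV under `out_dir` together with a `manifest.yaml`
#' capturing resolved parameters, seed and package version. A failing stage
#' aborts with the stage name.
#'
#' @param paths Named list of input paths: `grid`, `cn`, `alleles`, `qc`;
#'   optional `blacklist` (BED), `tree` (Newick).
#' @param out_dir Output directory (created).
#' @param params [hscn_params()] overrides.
#' @param seed Integer seed recorded in the manifest and used for the
#'   distance subsample.
#' @param max_distance_cells Subsample size for pairwise distances.
#' @return Invisibly, the list of computed objects.
#' @export
run_pipeline <- function(paths, out_dir, params = hscn_params(), seed = 1,
                         max_distance_cells = 250) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  grid <- stage("read", read_bin_grid(paths$grid))
  cn <- stage("read", read_cn(paths$cn, grid))
  alleles <- stage("read", read_alleles(paths$alleles))
  qc <- stage("read", read_qc(paths$qc))
  blacklist <- if (!is.null(paths$blacklist))
    read_blacklist_bed(paths$blacklist) else NULL
  tree <- if (!is.null(paths$tree)) ape::read.tree(paths$tree) else NULL

  bin_mask <- stage("filter", filter_bins(grid, blacklist))
  cell_mask <- stage("filter", filter_cells(qc))
  keep_cells <- names(cell_mask)[cell_mask]
  cn <- cn[cn$cell_id %in% keep_cells, , drop = FALSE]
  alleles <- alleles[alleles$cell_id %in% keep_cells, , drop = FALSE]
  clones <- setNames(qc$clone, qc$cell_id)[keep_cells]

  hscn <- stage("hscn",
                infer_population_hscn(cn, alleles, grid, params, bin_mask))
  write_cn(hscn, file.path(out_dir, "hscn.tsv"))

  ploidy <- stage("metrics", cell_ploidy(cn, grid, bin_mask))
  consensus <- stage("metrics",
                     consensus_profile(cn, clones, grid, hscn, bin_mask))
  write.table(consensus, file.path(out_dir, "consensus.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  misseg <- stage("metrics",
                  detect_missegregations(cn, clones, grid, consensus,
                                         bin_mask))
  write.table(misseg, file.path(out_dir, "missegregations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  segs <- stage("metrics",
                call_gain_loss_segments(cn, grid, ploidy, bin_mask))
  write.table(segs, file.path(out_dir, "gain_loss_segments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  hlamp <- stage("metrics", detect_hlamp_bins(cn, grid, bin_mask = bin_mask))
  write.table(hlamp, file.path(out_dir, "hlamp_bins.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  serr <- stage("serration", serration_events(cn, clones, grid, bin_mask))
  write.table(serr, file.path(out_dir, "serration.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  clone_segs <- stage("segments", {
    cons_sp <- split(consensus, consensus$clone)
    do.call(rbind, lapply(cons_sp, function(d)
      .segment_states(d$state, d[, c("chrom", "start", "end")])))
  })
  seg_table <- stage("segments",
                     disjoin_and_genotype(clone_segs, hscn, grid, bin_mask))
  write.table(seg_table, file.path(out_dir, "segments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  par_ev <- stage("parallel", detect_parallel_cna(seg_table))
  write.table(par_ev, file.path(out_dir, "parallel_events.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  dists <- stage("distance",
                 pairwise_distance_matrix(hscn, grid, max_distance_cells,
                                          seed, bin_mask))
  write.table(dists$dist, file.path(out_dir, "distance_matrix.tsv"),
              sep = "\t", quote = FALSE)

  rates <- NULL
  if (!is.null(tree)) {
    drop <- setdiff(tree$tip.label, keep_cells)
    if (length(drop)) tree <- ape::drop.tip(tree, drop)
    rates <- stage("rates",
                   parsimony_event_rate(tree, seg_table, grid,
                                        default_centromeres(grid), bin_mask))
    write.table(rates$rates, file.path(out_dir, "event_rates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else message("no tree supplied: event-rate stage skipped")

  manifest <- list(
    inputs = lapply(paths, normalizePath, mustWork = FALSE),
    seed = seed,
    params = unclass(params),
    n_cells = length(keep_cells),
    n_bins_retained = sum(bin_mask),
    version = as.character(utils::packageVersion("hapcells")))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(hscn = hscn, ploidy = ploidy, consensus = consensus,
                 missegregations = misseg, segments = segs,
                 hlamp_bins = hlamp, serration = serr,
                 seg_table = seg_table, parallel = par_ev,
                 distances = dists, rates = rates))
}

#' Write simulated population tables to a directory
#'
#' Serializes a [simulate_population()] result in the package's input
#' formats (plus the ground-truth states and the Newick tree), so the
#' simulator output can be fed straight back into [run_pipeline()].
#'
#' @param sim A `hapcells_sim` object.
#' @param out_dir Output directory.
#' @return Named list of file paths.
#' @export
write_sim <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(grid = file.path(out_dir, "bins.tsv"),
                cn = file.path(out_dir, "cn.tsv"),
                alleles = file.path(out_dir, "alleles.tsv"),
                qc = file.path(out_dir, "qc.tsv"),
                tree = file.path(out_dir, "tree.nwk"),
                truth = file.path(out_dir, "truth.tsv"))
  write_bin_grid(sim$grid, paths$grid)
  write_cn(sim$cn, paths$cn)
  write_alleles(sim$alleles, paths$alleles)
  write_qc(sim$qc, paths$qc)
  ape::write.tree(sim$tree, paths$tree)
  truth <- .from_matrix(sim$truth$a, sim$grid, "a")
  truth$b <- .from_matrix(sim$truth$b, sim$grid, "b")$b
  write.table(truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}
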