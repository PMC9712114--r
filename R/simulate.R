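# Seeded simulator of clone-structured single-cell populations with known
# haplotype-specific ground truth. Clone genotypes are generated by walking
# a random clone tree and applying haplotype-specific gains and losses at
# whole-chromosome, arm and segment scale; cells inherit their clone's
# genotype plus private events, planted parallel events, serrate breakpoints
# and high-level amplifications. Readouts mimic shallow single-cell WGS:
# negative-binomial bin read counts, binomially thinned allele-informative
# totals and Beta-Binomial B counts on randomly oriented haplotype blocks
# with phase-switch errors.

#' Simulation configuration
#'
#' Defaults describe a small two-clone diploid population; event rates are
#' expected counts per clone-tree edge, amplitudes are in copies.
#'
#' @param n_cells Number of cells.
#' @param n_chromosomes,bins_per_chrom,bin_width Genome shape (defaults: 2
#'   chromosomes x 50 bins of 500 kb).
#' @param n_clones,clone_fractions Clone structure; fractions must sum to 1
#'   (equal when `NULL`).
#' @param events_per_edge Named vector: expected haplotype-specific events
#'   per clone-tree edge for `whole_chromosome`, `arm` and `segment` scales.
#' @param prob_loss Probability an event is a loss (else a gain).
#' @param segment_bins Range (bins) of segment-scale event lengths.
#' @param wgd_prob Per-clone probability of whole-genome doubling.
#' @param cell_event_rate Expected private segment events per cell.
#' @param n_hlamp,hlamp_copies,hlamp_jitter_sd High-level amplification
#'   loci: count, added copies, and lognormal sdlog of the per-cell
#'   amplitude jitter.
#' @param n_parallel,parallel_span,parallel_frac,parallel_direction Planted
#'   parallel events: count, span (bp), the fractions of cells altered on
#'   haplotype A and B, and the direction.
#' @param n_serration,serration_p Serrate breakpoints: count and the
#'   geometric parameter of the per-cell offset from the modal position
#'   (smaller p = more serrate).
#' @param reads_per_bin Expected reads per bin at total copy 2.
#' @param nb_dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param allele_depth Expected allele-informative counts per bin at total
#'   copy 2.
#' @param bb_s Beta-Binomial concentration of simulated B counts.
#' @param blocks_per_bin Haplotype blocks per bin.
#' @param phase_switch_prob Per-block probability of a phase switch error
#'   (wrong orientation relative to the chromosome's reference haplotype,
#'   shared by all cells, as produced by upstream statistical phasing).
#' @param scramble_orientation Randomize every block's orientation
#'   independently instead (leaves only relabelling-invariant quantities
#'   identifiable; useful for invariance tests).
#' @param baf_error Base allelic error: expected BAF is clamped into
#'   \[baf_error, 1 - baf_error\].
#' @param seed Integer seed; recorded in the output.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_cells = 200, n_chromosomes = 2, bins_per_chrom = 50,
                       bin_width = 5e5, n_clones = 2, clone_fractions = NULL,
                       events_per_edge = c(whole_chromosome = 0.5, arm = 0.5,
                                           segment = 1),
                       prob_loss = 0.5, segment_bins = c(8, 20),
                       wgd_prob = 0, cell_event_rate = 0,
                       n_hlamp = 0, hlamp_copies = 15, hlamp_jitter_sd = 0.2,
                       n_parallel = 0, parallel_span = 5e6,
                       parallel_frac = c(0.02, 0.03),
                       parallel_direction = "loss",
                       n_serration = 0, serration_p = 0.5,
                       reads_per_bin = 100, nb_dispersion = 0.1,
                       allele_depth = 20, bb_s = 50, blocks_per_bin = 3,
                       phase_switch_prob = 0.02, baf_error = 0.01,
                       scramble_orientation = FALSE, seed = 1L) {
  if (is.null(clone_fractions))
    clone_fractions <- rep(1 / n_clones, n_clones)
  stopifnot(abs(sum(clone_fractions) - 1) < 1e-8,
            all(clone_fractions >= 0), n_cells >= 1)
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

.rbetabinom <- function(n, size, mu, s) {
  rbinom(n, size, rbeta(n, mu * s, (1 - mu) * s))
}

# pick a contiguous bin region of the requested scale on a random chromosome
.sample_region <- function(grid, scale, segment_bins) {
  ch <- sample(unique(grid$chrom), 1)
  bins <- which(grid$chrom == ch)
  n <- length(bins)
  if (scale == "whole_chromosome") return(bins)
  if (scale == "arm") {
    half <- floor(n / 2)
    if (runif(1) < 0.5) return(bins[seq_len(half)])
    return(bins[(half + 1):n])
  }
  len <- min(n, sample(segment_bins[1]:segment_bins[2], 1))
  s <- sample(seq_len(n - len + 1), 1)
  bins[s:(s + len - 1)]
}

#' Simulate a clone-structured cell population
#'
#' @param config A [sim_config()].
#' @return List of class `hapcells_sim`: `grid`, `cn` (long copy-number
#'   table with true integer states and noisy raw copies), `alleles` (long
#'   block allele counts in randomized orientation), `qc`, `tree` (`phylo`,
#'   tips = cells), `clones` (named labels) and `truth` (per-cell true
#'   (a, b) matrices, the event registry, clone genotypes, the seed).
#'   Fully reproducible: identical config (including seed) gives identical
#'   output.
#' @export
simulate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sizes <- setNames(rep(config$bins_per_chrom * config$bin_width,
                        config$n_chromosomes),
                    paste0("chr", seq_len(config$n_chromosomes)))
  grid <- bin_grid(sizes, width = config$bin_width)
  nb <- nrow(grid)
  clones <- paste0("clone_", seq_len(config$n_clones))
  counts <- diff(round(cumsum(c(0, config$clone_fractions)) * config$n_cells))
  counts[length(counts)] <- config$n_cells - sum(counts[-length(counts)])
  cell_clone <- rep(clones, counts)
  cell_ids <- sprintf("cell_%03d", seq_len(config$n_cells))
  names(cell_clone) <- cell_ids
  events <- list()
  reg <- function(type, chrom, bins, hap, direction, who) {
    events[[length(events) + 1L]] <<- data.frame(
      type = type, chrom = chrom, start = grid$start[bins[1]],
      end = grid$end[bins[length(bins)]], haplotype = hap,
      direction = direction, carrier = who)
  }

  # clone tree and clone genotypes
  if (config$n_clones > 1) {
    ctree <- ape::rtree(config$n_clones, tip.label = clones, br = NULL)
    ctree$edge.length <- rep(1, nrow(ctree$edge))
  } else ctree <- NULL
  geno <- list()
  root <- list(a = rep(1L, nb), b = rep(1L, nb))
  apply_event <- function(g, scale) {
    bins <- .sample_region(grid, scale, config$segment_bins)
    hap <- sample(c("a", "b"), 1)
    direction <- if (runif(1) < config$prob_loss) "loss" else "gain"
    if (direction == "loss" && all(g[[hap]][bins] == 0)) {
      message("infeasible loss skipped (", scale, ")")
      return(list(g = g, ev = NULL))
    }
    if (direction == "loss") g[[hap]][bins] <- pmax(g[[hap]][bins] - 1L, 0L)
    else g[[hap]][bins] <- g[[hap]][bins] + 1L
    list(g = g, ev = list(scale = scale, chrom = grid$chrom[bins[1]],
                          bins = bins, hap = hap, direction = direction))
  }
  if (is.null(ctree)) {
    geno[[clones[1]]] <- root
  } else {
    # reverse postorder = parents before children
    edge <- ape::reorder.phylo(ctree, "postorder")$edge
    node_geno <- list()
    root_node <- config$n_clones + 1L
    node_geno[[root_node]] <- root
    for (k in rev(seq_len(nrow(edge)))) {
      g <- node_geno[[edge[k, 1]]]
      for (scale in names(config$events_per_edge)) {
        for (i in seq_len(rpois(1, config$events_per_edge[[scale]]))) {
          r <- apply_event(g, scale)
          g <- r$g
          if (!is.null(r$ev)) {
            kid <- edge[k, 2]
            carrier <- if (kid <= config$n_clones) ctree$tip.label[kid]
              else paste0("node_", kid)
            reg(r$ev$scale, r$ev$chrom, r$ev$bins, r$ev$hap, r$ev$direction,
                carrier)
          }
        }
      }
      node_geno[[edge[k, 2]]] <- g
    }
    for (i in seq_len(config$n_clones))
      geno[[ctree$tip.label[i]]] <- node_geno[[i]]
  }
  # whole-genome doubling per clone
  for (cl in clones) {
    if (runif(1) < config$wgd_prob) {
      geno[[cl]]$a <- 2L * geno[[cl]]$a
      geno[[cl]]$b <- 2L * geno[[cl]]$b
      reg("wgd", grid$chrom[1], c(1L, nb), "both", "gain", cl)
    }
  }
  # high-level amplification loci (clone-specific, haplotype A)
  hlamp_loci <- integer(0)
  hlamp_clone <- character(0)
  if (config$n_hlamp > 0) {
    hlamp_loci <- sample(nb, config$n_hlamp)
    hlamp_clone <- sample(clones, config$n_hlamp, replace = TRUE)
    for (i in seq_along(hlamp_loci)) {
      geno[[hlamp_clone[i]]]$a[hlamp_loci[i]] <-
        geno[[hlamp_clone[i]]]$a[hlamp_loci[i]] + config$hlamp_copies
      reg("hlamp", grid$chrom[hlamp_loci[i]], rep(hlamp_loci[i], 2), "a",
          "gain", hlamp_clone[i])
    }
  }

  # per-cell truth
  A <- matrix(0L, config$n_cells, nb, dimnames = list(cell_ids, NULL))
  B <- A
  for (ci in seq_len(config$n_cells)) {
    g <- geno[[cell_clone[ci]]]
    A[ci, ] <- g$a
    B[ci, ] <- g$b
  }
  # planted parallel events: disjoint cell subsets altered on A and on B
  if (config$n_parallel > 0) {
    len <- max(1L, round(config$parallel_span / config$bin_width))
    used <- integer(0)
    for (i in seq_len(config$n_parallel)) {
      region <- NULL
      for (try in 1:50) {       # planted events must not overlap
        ch <- sample(unique(grid$chrom), 1)
        bins <- which(grid$chrom == ch)
        s <- sample(seq_len(length(bins) - len + 1), 1)
        cand <- bins[s:(s + len - 1)]
        if (!any(cand %in% used)) { region <- cand; break }
      }
      if (is.null(region)) {
        message("no room for parallel event ", i, "; skipped")
        next
      }
      used <- c(used, region)
      nA <- max(1L, round(config$parallel_frac[1] * config$n_cells))
      nB <- max(1L, round(config$parallel_frac[2] * config$n_cells))
      pick <- sample(config$n_cells, nA + nB)
      delta <- if (config$parallel_direction == "loss") -1L else 1L
      A[pick[seq_len(nA)], region] <-
        pmax(A[pick[seq_len(nA)], region] + delta, 0L)
      B[pick[nA + seq_len(nB)], region] <-
        pmax(B[pick[nA + seq_len(nB)], region] + delta, 0L)
      reg("parallel", ch, region, "both", config$parallel_direction,
          paste0(nA, "+", nB, "cells"))
    }
  }
  # serrate breakpoints: clone-level gain with jittered per-cell boundary
  if (config$n_serration > 0) {
    for (i in seq_len(config$n_serration)) {
      cl <- sample(clones, 1)
      members <- which(cell_clone == cl)
      ch <- sample(unique(grid$chrom), 1)
      bins <- which(grid$chrom == ch)
      m <- bins[floor(length(bins) / 2)]
      for (ci in members) {
        off <- rgeom(1, config$serration_p) * sample(c(-1L, 1L), 1)
        bp <- min(max(m + off, bins[2]), bins[length(bins)])
        A[ci, bp:bins[length(bins)]] <- A[ci, bp:bins[length(bins)]] + 1L
      }
      reg("serration", ch, c(m, bins[length(bins)]), "a", "gain", cl)
    }
  }
  # private cell events
  if (config$cell_event_rate > 0) {
    for (ci in seq_len(config$n_cells)) {
      for (i in seq_len(rpois(1, config$cell_event_rate))) {
        bins <- .sample_region(grid, "segment", config$segment_bins)
        hap <- sample(c("a", "b"), 1)
        direction <- if (runif(1) < config$prob_loss) "loss" else "gain"
        M <- if (hap == "a") A else B
        if (direction == "loss") M[ci, bins] <- pmax(M[ci, bins] - 1L, 0L)
        else M[ci, bins] <- M[ci, bins] + 1L
        if (hap == "a") A[ci, ] <- M[ci, ] else B[ci, ] <- M[ci, ]
      }
    }
  }

  total <- A + B
  ploidy_true <- apply(total, 1, function(x) as.integer(.mode_val(x)))
  # read counts: NB with mean proportional to total copy; HLAMP bins get
  # per-cell lognormal amplitude jitter on the continuous copy value
  eff <- total
  storage.mode(eff) <- "double"
  if (length(hlamp_loci)) {
    for (i in seq_along(hlamp_loci)) {
      rows <- which(cell_clone == hlamp_clone[i])
      eff[rows, hlamp_loci[i]] <- eff[rows, hlamp_loci[i]] *
        rlnorm(length(rows), 0, config$hlamp_jitter_sd)
    }
  }
  mu <- config$reads_per_bin * eff / 2
  reads <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                  nrow(mu), ncol(mu), dimnames = dimnames(eff))
  raw <- reads / pmax(rowMeans(reads), 1e-9) * ploidy_true

  # allele counts on haplotype blocks. Orientation mimics statistically
  # phased input: each chromosome's reference haplotype labelling is an
  # arbitrary coin flip and individual blocks suffer switch errors at the
  # configured rate (a property of the block, shared by all cells);
  # scramble_orientation = TRUE randomizes every block independently
  # instead, which leaves only relabelling-invariant quantities
  # identifiable.
  bpb <- config$blocks_per_bin
  t_bin <- matrix(rbinom(length(reads), reads,
                         min(1, config$allele_depth / config$reads_per_bin)),
                  nrow(reads), ncol(reads))
  chroms <- unique(grid$chrom)
  chrom_flip <- setNames(runif(length(chroms)) < 0.5, chroms)
  block_chrom <- grid$chrom[rep(seq_len(nb), each = bpb)]
  if (isTRUE(config$scramble_orientation)) {
    block_flip <- runif(nb * bpb) < 0.5
  } else {
    block_flip <- xor(chrom_flip[block_chrom],
                      runif(nb * bpb) < config$phase_switch_prob)
  }
  blocks <- data.frame(
    bin = rep(seq_len(nb), each = bpb),
    k = rep(seq_len(bpb), times = nb))
  bw <- grid$width[blocks$bin]
  blocks$chrom <- grid$chrom[blocks$bin]
  blocks$start <- grid$start[blocks$bin] +
    floor(bw * (blocks$k - 1) / bpb)
  blocks$end <- grid$start[blocks$bin] + floor(bw * blocks$k / bpb) - 1L
  allele_rows <- vector("list", config$n_cells)
  for (ci in seq_len(config$n_cells)) {
    tb <- t_bin[ci, ]
    t_blk <- unlist(lapply(seq_len(nb), function(i) {
      if (tb[i] == 0) return(rep(0L, bpb))
      as.integer(rmultinom(1, tb[i], rep(1, bpb)))
    }))
    tot <- total[ci, blocks$bin]
    mu_b <- ifelse(tot > 0, B[ci, blocks$bin] / tot, 0.5)
    mu_b <- pmin(pmax(mu_b, config$baf_error), 1 - config$baf_error)
    mu_eff <- ifelse(block_flip, 1 - mu_b, mu_b)
    b_blk <- ifelse(t_blk > 0,
                    .rbetabinom(length(t_blk), t_blk, mu_eff, config$bb_s),
                    0L)
    allele_rows[[ci]] <- data.frame(
      cell_id = cell_ids[ci], chrom = blocks$chrom, start = blocks$start,
      end = blocks$end, b_count = as.integer(b_blk),
      t_count = as.integer(t_blk))
  }
  alleles <- do.call(rbind, allele_rows)

  cn <- .from_matrix(total, grid, "state")
  cn$raw_copy <- .from_matrix(raw, grid, "raw_copy")$raw_copy
  qc <- data.frame(cell_id = cell_ids, quality = 0.95, s_phase_flag = FALSE,
                   contam_fraction = 0, clone = unname(cell_clone))

  # cell-level tree: cells as a polytomy under their clone tip
  clone_sub <- function(cl) {
    members <- cell_ids[cell_clone == cl]
    if (length(members) == 1) return(members)
    paste0("(", paste0(members, ":1", collapse = ","), ")", cl)
  }
  if (is.null(ctree)) {
    nwk <- paste0(clone_sub(clones[1]), ";")
  } else {
    nwk <- ape::write.tree(ctree)
    for (cl in clones)
      nwk <- sub(paste0("\\b", cl, "\\b"), clone_sub(cl), nwk)
  }
  tree <- ape::read.tree(text = nwk)

  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(type = character(), chrom = character(), start = integer(),
               end = integer(), haplotype = character(),
               direction = character(), carrier = character())
  structure(list(
    grid = grid, cn = cn, alleles = alleles, qc = qc, tree = tree,
    clones = cell_clone,
    truth = list(a = A, b = B, events = ev, clone_genotypes = geno,
                 ploidy = ploidy_true, reads = reads, seed = config$seed),
    config = config), class = "hapcells_sim")
}

#' Compare inferred haplotype-specific states to simulation truth
#'
#' A/B labels are arbitrary per chromosome (up to the aggregate-BAF
#' convention), so accuracy is evaluated under the better of the two
#' labellings per chromosome. LOH calls (minor allele 0 with total > 0) are
#' label-invariant and scored bin-wise.
#'
#' @param hscn Long HSCN table from [infer_population_hscn()].
#' @param sim A `hapcells_sim` object.
#' @return List: `accuracy` (bin-level state accuracy), `loh_precision`,
#'   `loh_recall`, `n` (cell-bin observations).
#' @export
truth_metrics <- function(hscn, sim) {
  grid <- sim$grid
  a_i <- .to_matrix(hscn, grid, "a")
  b_i <- .to_matrix(hscn, grid, "b")
  cells <- rownames(a_i)
  a_t <- sim$truth$a[cells, , drop = FALSE]
  b_t <- sim$truth$b[cells, , drop = FALSE]
  correct <- 0
  for (ch in unique(grid$chrom)) {
    bins <- which(grid$chrom == ch)
    same <- sum(a_i[, bins] == a_t[, bins] & b_i[, bins] == b_t[, bins],
                na.rm = TRUE)
    swap <- sum(a_i[, bins] == b_t[, bins] & b_i[, bins] == a_t[, bins],
                na.rm = TRUE)
    correct <- correct + max(same, swap)
  }
  n <- sum(!is.na(a_i))
  loh_i <- pmin(a_i, b_i) == 0 & (a_i + b_i) > 0
  loh_t <- pmin(a_t, b_t) == 0 & (a_t + b_t) > 0
  tp <- sum(loh_i & loh_t, na.rm = TRUE)
  list(accuracy = correct / n,
       loh_precision = if (sum(loh_i, na.rm = TRUE)) tp /
         sum(loh_i, na.rm = TRUE) else NA_real_,
       loh_recall = if (sum(loh_t, na.rm = TRUE)) tp /
         sum(loh_t, na.rm = TRUE) else NA_real_,
       n = n)
}
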