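# Haplotype-specific copy number inference. Conditioned on the per-bin total
# copy number state t, the hidden state of a bin is the pair (a, b) with
# a + b = t; the observation is the number of B-haplotype reads among the
# bin's allele-informative reads, modelled Beta-Binomial around the expected
# BAF b / (a + b). A first-order chain along each chromosome favours keeping
# the current phase: the self-transition mass goes to the state of the next
# bin whose BAF is nearest the current one.

#' HMM parameters for haplotype-specific inference
#'
#' @param e Self-transition probability in (0, 1). Default 0.95; 0.999 is the
#'   documented alternative for noisy samples.
#' @param s Beta-Binomial concentration (alpha + beta); larger is less
#'   overdispersed. Default 50, estimable by method of moments from balanced
#'   regions.
#' @param eps Shrinkage of the expected BAF away from \{0, 1\}; models
#'   sequencing error so pure-allele states never have zero likelihood.
#' @param t_max Cap on the total copy number used to build the state space;
#'   bins above the cap keep the BAF grid of `t_max` states.
#' @param max_phase_iters Maximum rounds of block re-orientation in
#'   [infer_population_hscn()].
#' @return A list of class `hscn_params`.
#' @export
hscn_params <- function(e = 0.95, s = 50, eps = 0.01, t_max = 12L,
                        max_phase_iters = 10L) {
  stopifnot(e > 0, e < 1, s > 0, eps > 0, eps < 0.5, t_max >= 1)
  structure(list(e = e, s = s, eps = eps, t_max = as.integer(t_max),
                 max_phase_iters = as.integer(max_phase_iters)),
            class = "hscn_params")
}

# Beta-Binomial pmf with mean mu and concentration s.
.dbetabinom <- function(x, size, mu, s, log = FALSE) {
  a <- mu * s
  b <- (1 - mu) * s
  ll <- lchoose(size, x) + lbeta(x + a, size - x + b) - lbeta(a, b)
  if (log) ll else exp(ll)
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Per-bin emission log-likelihoods for one chromosome. Bins with no counts
# (t_obs == 0) emit log-likelihood 0 for every state; bins with total state 0
# carry the single state (0, 0) and emit nothing (counts there are discordant
# and merely reported).
.hscn_emissions <- function(tt, b_obs, t_obs, p) {
  lapply(seq_along(tt), function(i) {
    bs <- 0:tt[i]
    if (t_obs[i] == 0 || tt[i] == 0) return(rep(0, length(bs)))
    mu <- pmin(pmax(bs / tt[i], p$eps), 1 - p$eps)
    .dbetabinom(b_obs[i], t_obs[i], mu, p$s, log = TRUE)
  })
}

# Transition log-probability matrix from the states of bin i (totals t1) to
# bin i + 1 (totals t2): probability e to the phase-preserving successor (the
# state with nearest BAF; ties to smaller b), remaining mass uniform over the
# other states.
.hscn_trans <- function(t1, t2, p) {
  baf1 <- if (t1 > 0) (0:t1) / t1 else 0.5
  baf2 <- if (t2 > 0) (0:t2) / t2 else 0.5
  n1 <- t1 + 1L
  n2 <- t2 + 1L
  M <- matrix(if (n2 > 1) log((1 - p$e) / (n2 - 1)) else 0, n1, n2)
  succ <- vapply(baf1, function(x) which.min(abs(baf2 - x)), integer(1))
  if (n2 > 1) M[cbind(seq_len(n1), succ)] <- log(p$e)
  M
}

# Viterbi + forward-backward over one chromosome. Returns the maximum a
# posteriori path of b-states on the clamped totals plus the posterior
# probability of each assigned state.
.viterbi_chrom <- function(totals, b_obs, t_obs, p) {
  n <- length(totals)
  tt <- pmin(totals, p$t_max)
  emis <- .hscn_emissions(tt, b_obs, t_obs, p)
  init <- lapply(tt, function(t1) rep(-log(t1 + 1), t1 + 1))
  # Viterbi
  delta <- vector("list", n)
  psi <- vector("list", n)
  delta[[1]] <- init[[1]] + emis[[1]]
  if (n > 1) {
    for (i in 2:n) {
      M <- .hscn_trans(tt[i - 1], tt[i], p)
      sc <- delta[[i - 1]] + M            # column-recycled: n1 x n2
      delta[[i]] <- apply(sc, 2, max) + emis[[i]]
      psi[[i]] <- apply(sc, 2, which.max)
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[[n]])
  if (n > 1) for (i in (n - 1):1) path[i] <- psi[[i + 1]][path[i + 1]]
  loglik_path <- max(delta[[n]])
  # forward-backward for the posterior of the assigned states
  alpha <- vector("list", n)
  beta <- vector("list", n)
  alpha[[1]] <- init[[1]] + emis[[1]]
  if (n > 1) for (i in 2:n) {
    M <- .hscn_trans(tt[i - 1], tt[i], p)
    alpha[[i]] <- apply(alpha[[i - 1]] + M, 2, .logsumexp) + emis[[i]]
  }
  beta[[n]] <- rep(0, tt[n] + 1)
  if (n > 1) for (i in (n - 1):1) {
    M <- .hscn_trans(tt[i], tt[i + 1], p)
    beta[[i]] <- apply(t(M) + (emis[[i + 1]] + beta[[i + 1]]), 2, .logsumexp)
  }
  llk <- .logsumexp(alpha[[n]])
  post <- vapply(seq_len(n), function(i)
    exp(alpha[[i]][path[i]] + beta[[i]][path[i]] - llk), numeric(1))
  list(b = path - 1L, total = tt, posterior = post, loglik = loglik_path,
       discordant = sum(t_obs > 0 & totals == 0))
}

#' Haplotype-specific states for a single cell
#'
#' Runs the Viterbi decoding independently per chromosome given the cell's
#' total copy number states and its phased, bin-aggregated allele counts.
#'
#' @param states Integer total copy number per bin (grid order).
#' @param b_counts,t_counts Phased B counts and total counts per bin; use 0
#'   where a bin has no informative reads.
#' @param chrom Chromosome of each bin (grid order).
#' @param params [hscn_params()].
#' @return `data.frame` with per-bin `a`, `b`, `total` (clamped), `baf`
#'   (observed), `posterior`. Attribute `discordant` counts bins with reads
#'   but total state 0.
#' @export
infer_cell_hscn <- function(states, b_counts, t_counts, chrom,
                            params = hscn_params()) {
  stopifnot(length(states) == length(b_counts),
            length(states) == length(t_counts),
            length(states) == length(chrom))
  out <- data.frame(a = integer(length(states)), b = integer(length(states)),
                    total = integer(length(states)),
                    baf = compute_baf(b_counts, t_counts),
                    posterior = numeric(length(states)))
  disc <- 0L
  for (idx in split(seq_along(states), factor(chrom, unique(chrom)))) {
    v <- .viterbi_chrom(states[idx], b_counts[idx], t_counts[idx], params)
    out$b[idx] <- v$b
    out$total[idx] <- v$total
    out$a[idx] <- v$total - v$b
    out$posterior[idx] <- v$posterior
    disc <- disc + v$discordant
  }
  attr(out, "discordant") <- disc
  out
}

#' Haplotype-specific copy number across a cell population
#'
#' Full inference over a cell population. Haplotype blocks from statistical
#' phasing are mostly oriented consistently along a chromosome, with
#' occasional switch errors; by default the input orientation is therefore
#' trusted and only repaired: each round, every block is compared against a
#' local reference — the count-weighted mean signed BAF deviation of each
#' cell over the block's neighbours within `phase_window` blocks — and
#' flipped when its own per-cell deviations anticorrelate with that
#' reference. Using which cells deviate (not just the population mean)
#' resolves regions whose aggregate BAF is balanced because different cell
#' subsets carry events on opposite homologues. With
#' `initial = "aggregate"`, orientations are first reset by [phase_blocks()]
#' (population-aggregate minor allele), appropriate when input orientations
#' are arbitrary. After convergence (or `max_phase_iters`) each cell is
#' decoded by Viterbi, and the A/B labels of each chromosome are made
#' canonical: the aggregate BAF of allele B is at most 0.5.
#'
#' @param cn Long per-cell copy-number table (see [read_cn()]).
#' @param alleles Long haplotype-block allele counts.
#' @param grid Bin grid.
#' @param params [hscn_params()].
#' @param bin_mask Optional logical bin mask from [filter_bins()]; masked
#'   bins are excluded from the output.
#' @param initial `"input"` (default) keeps the supplied block orientations;
#'   `"aggregate"` re-initializes them with [phase_blocks()].
#' @param phase_window Local window (blocks each side) for the switch-error
#'   repair.
#' @return Long `data.frame` (`cell_id`, `chrom`, `start`, `end`, `state`,
#'   `a`, `b`, `baf`, `posterior`) with attributes `orientation` (final block
#'   orientation table) and `phase_iterations`.
#' @export
infer_population_hscn <- function(cn, alleles, grid, params = hscn_params(),
                                  bin_mask = NULL,
                                  initial = c("input", "aggregate"),
                                  phase_window = 10L) {
  initial <- match.arg(initial)
  cells <- sort(unique(cn$cell_id))
  if (!length(cells)) stop("no cells to analyse", call. = FALSE)
  state_m <- .to_matrix(cn, grid, "state")
  alleles <- alleles[alleles$cell_id %in% cells, , drop = FALSE]
  if (initial == "aggregate") {
    ph <- phase_blocks(alleles)
    oriented <- ph$alleles
    orientation <- ph$orientation
  } else {
    oriented <- alleles
    key0 <- paste(alleles$chrom, alleles$start, alleles$end)
    first <- !duplicated(key0)
    orientation <- data.frame(chrom = alleles$chrom[first],
                              start = alleles$start[first],
                              end = alleles$end[first],
                              orientation = 1L)
  }
  orientation <- orientation[order(orientation$chrom, orientation$start), ,
                             drop = FALSE]
  rownames(orientation) <- NULL
  key <- paste(oriented$chrom, oriented$start, oriented$end)
  okey <- paste(orientation$chrom, orientation$start, orientation$end)
  bidx <- match(key, okey)
  cidx <- match(oriented$cell_id, cells)
  # cell x block count matrices on the current orientation (genomic order)
  n_blk <- nrow(orientation)
  Bm <- matrix(0, length(cells), n_blk)
  Tm <- Bm
  Bm[cbind(cidx, bidx)] <- oriented$b_count
  Tm[cbind(cidx, bidx)] <- oriented$t_count
  iters <- 0L
  repeat {
    iters <- iters + 1L
    X <- Bm / Tm - 0.5
    WX <- Tm * X
    WX[!is.finite(WX)] <- 0
    Wn <- Tm
    flips <- logical(n_blk)
    for (ch in unique(orientation$chrom)) {
      bs <- which(orientation$chrom == ch)
      k <- length(bs)
      csWX <- cbind(0, t(apply(WX[, bs, drop = FALSE], 1, cumsum)))
      csWn <- cbind(0, t(apply(Wn[, bs, drop = FALSE], 1, cumsum)))
      lo <- pmax(seq_len(k) - phase_window, 1L)
      hi <- pmin(seq_len(k) + phase_window, k)
      # neighbour sums exclude the block itself
      SWX <- csWX[, hi + 1, drop = FALSE] - csWX[, lo, drop = FALSE] -
        WX[, bs, drop = FALSE]
      SWn <- csWn[, hi + 1, drop = FALSE] - csWn[, lo, drop = FALSE] -
        Wn[, bs, drop = FALSE]
      Rloc <- SWX / SWn
      Rloc[!is.finite(Rloc)] <- 0
      flips[bs] <- colSums(WX[, bs, drop = FALSE] * Rloc, na.rm = TRUE) < 0
    }
    if (!any(flips) || iters >= params$max_phase_iters) break
    orientation$orientation[flips] <- -orientation$orientation[flips]
    Bm[, flips] <- Tm[, flips] - Bm[, flips]
  }

  # aggregate final block counts to bins (midpoint rule) and decode
  mid <- floor((orientation$start + orientation$end) / 2)
  hit <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(orientation$chrom, IRanges::IRanges(mid, mid)),
    .grid_gr(grid))
  blk_bin <- rep(NA_integer_, n_blk)
  blk_bin[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
  Z <- matrix(0, n_blk, nrow(grid))
  ok_blk <- !is.na(blk_bin)
  Z[cbind(which(ok_blk), blk_bin[ok_blk])] <- 1
  bmat <- Bm %*% Z
  tmat <- Tm %*% Z
  dimnames(bmat) <- dimnames(tmat) <- list(cells, NULL)
  res_b <- bmat * NA
  res_t <- bmat * NA
  res_post <- bmat * NA
  for (ci in seq_along(cells)) {
    st <- state_m[ci, ]
    st[is.na(st)] <- 0L
    r <- infer_cell_hscn(st, bmat[ci, ], tmat[ci, ], grid$chrom, params)
    res_b[ci, ] <- r$b
    res_t[ci, ] <- r$total
    res_post[ci, ] <- r$posterior
  }

  # canonical per-chromosome labels: aggregate BAF of B <= 0.5
  for (ch in unique(grid$chrom)) {
    bins <- which(grid$chrom == ch)
    btot <- sum(bmat[, bins], na.rm = TRUE)
    ttot <- sum(tmat[, bins], na.rm = TRUE)
    if (ttot > 0 && btot / ttot > 0.5) {
      res_b[, bins] <- res_t[, bins] - res_b[, bins]
      bmat[, bins] <- tmat[, bins] - bmat[, bins]
      on_ch <- orientation$chrom == ch
      orientation$orientation[on_ch] <- -orientation$orientation[on_ch]
    }
  }

  keep_bins <- if (is.null(bin_mask)) rep(TRUE, nrow(grid)) else bin_mask
  g <- grid[keep_bins, , drop = FALSE]
  nb <- sum(keep_bins)
  out <- data.frame(
    cell_id = rep(cells, times = nb),
    chrom = rep(g$chrom, each = length(cells)),
    start = rep(g$start, each = length(cells)),
    end = rep(g$end, each = length(cells)),
    state = as.vector(res_t[, keep_bins, drop = FALSE]),
    a = as.vector((res_t - res_b)[, keep_bins, drop = FALSE]),
    b = as.vector(res_b[, keep_bins, drop = FALSE]),
    baf = as.vector((bmat / ifelse(tmat > 0, tmat, NA))[, keep_bins,
                                                        drop = FALSE]),
    posterior = as.vector(res_post[, keep_bins, drop = FALSE]))
  out <- out[order(out$cell_id, match(paste(out$chrom, out$start),
                                      paste(g$chrom, g$start))), ]
  rownames(out) <- NULL
  attr(out, "orientation") <- orientation
  attr(out, "phase_iterations") <- iters
  out
}
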