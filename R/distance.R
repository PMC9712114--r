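# Copy number transformation distance: the minimum number of events needed
# to turn one integer copy number profile into another, where an event adds
# or subtracts one copy over a contiguous run of positions, copy numbers
# floor at zero, and a position at zero copies can never regain them. The
# whole-genome-doubling-aware variant additionally allows doubling either
# profile at the cost of one extra event.

#' Copy number transformation distance between two profiles
#'
#' Exact dynamic program. A solution is characterized by, per position, the
#' number of deletion events `d` and amplification events `a` covering it;
#' with deletions scheduled before amplifications, a surviving position
#' (`v > 0`) requires `d <= u - 1` and `a = v - u + d`, a deleted-away
#' position (`v = 0`, `u > 0`) requires `d >= u` with `a` free (once at
#' zero it is transparent to amplifications), and a position at zero in both
#' profiles is transparent to every event. The number of events equals the
#' "strokes" of the `d` and `a` sequences (the sum of their positive
#' increments), minimized over all admissible sequences by a min-plus
#' envelope sweep; consecutive positions with identical `(u, v)` are
#' run-length compressed first. A position at zero that must gain copies is
#' infeasible (zero positions can never regain copies).
#'
#' @param u,v Equal-length non-negative integer vectors (one chromosome, one
#'   haplotype).
#' @return Non-negative integer count of events; `Inf` when `v` requires
#'   copies at a position where `u` is 0.
#' @examples
#' cnt_distance(c(2, 2, 2), c(4, 4, 4))  # 2
#' cnt_distance(c(1, 2, 1), c(2, 2, 2))  # 2
#' @export
cnt_distance <- function(u, v) {
  if (length(u) != length(v))
    stop("profiles differ in length", call. = FALSE)
  if (any(u == 0 & v > 0)) return(Inf)
  keep <- u > 0                     # zero-zero positions are transparent
  u <- u[keep]; v <- v[keep]
  if (!length(u)) return(0)
  run <- c(TRUE, diff(u) != 0 | diff(v) != 0)
  u <- u[run]; v <- v[run]
  md <- max(u)                      # deletions never usefully exceed max(u)
  ma <- max(v)                      # amplifications never exceed max(v)
  nd <- md + 1L
  na <- ma + 1L
  # cost[d + 1, a + 1]: minimal strokes so far ending with d deletions and
  # a amplifications covering the previous position
  cost <- matrix(Inf, nd, na)
  cost[1, 1] <- 0
  envelope <- function(m) {
    # min over (d', a') of m[d', a'] + (d - d')+ + (a - a')+
    dd <- seq_len(nd) - 1
    aa <- seq_len(na) - 1
    for (j in seq_len(ncol(m))) {
      col <- rev(cummin(rev(m[, j])))        # d' >= d is free
      m[, j] <- cummin(col - dd) + dd        # d' <= d costs d - d'
    }
    for (i in seq_len(nrow(m))) {
      row <- rev(cummin(rev(m[i, ])))        # a' >= a is free
      m[i, ] <- cummin(row - aa) + aa        # a' <= a costs a - a'
    }
    m
  }
  for (i in seq_along(u)) {
    m <- envelope(cost)
    nxt <- matrix(Inf, nd, na)
    if (v[i] > 0) {
      ds <- 0:min(u[i] - 1, md)             # position must survive
      as_ <- v[i] - u[i] + ds
      ok <- as_ >= 0 & as_ <= ma
      nxt[cbind(ds[ok] + 1, as_[ok] + 1)] <- m[cbind(ds[ok] + 1,
                                                     as_[ok] + 1)]
    } else {
      nxt[(u[i] + 1):nd, ] <- m[(u[i] + 1):nd, , drop = FALSE]
    }
    cost <- nxt
  }
  min(cost)
}

# total transformation distance between two haplotype-specific genomes:
# cnt_distance per chromosome per haplotype, summed.
.profile_f <- function(a1, b1, a2, b2, chrom) {
  s <- 0
  for (idx in split(seq_along(chrom), factor(chrom, unique(chrom)))) {
    s <- s + cnt_distance(a1[idx], a2[idx]) + cnt_distance(b1[idx], b2[idx])
  }
  s
}

#' WGD-aware copy number distance between two cells
#'
#' Computes `d1 = f(A, B)`, `d2 = f(2A, B)` and `d3 = f(A, 2B)`, where `f`
#' is the transformation distance summed over chromosomes and both
#' haplotypes and `2x` doubles a genome; the distance is the minimum of the
#' three, plus one when the minimum is `d2` or `d3` (whole-genome doubling
#' counts as one extra event; ties favouring `d1` take `d1` with no
#' increment).
#'
#' @param a1,b1 Haplotype A/B integer copy vectors of the first cell.
#' @param a2,b2 Same for the second cell.
#' @param chrom Chromosome label per position (single chromosome when
#'   omitted).
#' @return Non-negative number, possibly `Inf` on infeasible pairs.
#' @export
wgd_distance <- function(a1, b1, a2, b2, chrom = rep("1", length(a1))) {
  d1 <- .profile_f(a1, b1, a2, b2, chrom)
  d2 <- .profile_f(2 * a1, 2 * b1, a2, b2, chrom)
  d3 <- .profile_f(a1, b1, 2 * a2, 2 * b2, chrom)
  d <- min(d1, d2, d3)
  if (d1 == d) d1 else d + 1
}

#' Pairwise WGD-aware distances across a cell population
#'
#' Subsamples at most `max_n` cells uniformly without replacement (seeded)
#' and computes every pairwise [wgd_distance()] on the haplotype-specific
#' genotypes.
#'
#' @param hscn Long HSCN table ([infer_population_hscn()]).
#' @param grid Bin grid.
#' @param max_n Subsample size (default 250 cells, i.e. 31,125 pairs).
#' @param seed Seed for the subsample.
#' @param bin_mask Optional logical bin mask.
#' @return List: `dist` (symmetric matrix with cell ids), `median`, `mean`,
#'   `n_pairs`.
#' @export
pairwise_distance_matrix <- function(hscn, grid, max_n = 250, seed = 1,
                                     bin_mask = NULL) {
  keep_bins <- if (is.null(bin_mask)) rep(TRUE, nrow(grid)) else bin_mask
  a_m <- .to_matrix(hscn, grid, "a")[, keep_bins, drop = FALSE]
  b_m <- .to_matrix(hscn, grid, "b")[, keep_bins, drop = FALSE]
  chrom <- grid$chrom[keep_bins]
  cells <- rownames(a_m)
  if (length(cells) < 2) stop("need at least two cells", call. = FALSE)
  if (length(cells) > max_n) {
    has_seed <- exists(".Random.seed", envir = globalenv())
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    set.seed(seed)
    cells <- sort(sample(cells, max_n))
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
  }
  n <- length(cells)
  D <- matrix(0, n, n, dimnames = list(cells, cells))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # undirected dissimilarity: the cheaper transformation direction
      # (a profile with lost positions can still be reached from its pair)
      D[i, j] <- D[j, i] <- min(
        wgd_distance(a_m[cells[i], ], b_m[cells[i], ],
                     a_m[cells[j], ], b_m[cells[j], ], chrom),
        wgd_distance(a_m[cells[j], ], b_m[cells[j], ],
                     a_m[cells[i], ], b_m[cells[i], ], chrom))
    }
  }
  ut <- D[upper.tri(D)]
  finite <- ut[is.finite(ut)]
  list(dist = D, median = median(finite), mean = mean(finite),
       n_pairs = length(ut), n_infeasible = sum(!is.finite(ut)))
}
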