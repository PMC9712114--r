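# Copy number transformation distance, WGD-aware distance, parallel event
# detection, parsimony event rates and cophenetic diversity.

test_that("transformation distance matches worked examples and handles zeros", {
  expect_equal(cnt_distance(c(2, 2, 2), c(2, 2, 2)), 0)
  expect_equal(cnt_distance(c(2, 2, 2), c(4, 4, 4)), 2)
  expect_equal(cnt_distance(c(1, 2, 1), c(2, 2, 2)), 2)
  expect_equal(cnt_distance(c(0, 2), c(0, 3)), 1)   # zero is transparent
  expect_equal(cnt_distance(c(2, 0, 2), c(3, 0, 3)), 1)
  expect_equal(cnt_distance(c(0, 2), c(1, 2)), Inf) # zeros never regain
  expect_error(cnt_distance(c(1, 2), c(1, 2, 3)), "length")
})

test_that("transformation distance equals the BFS oracle on small profiles", {
  # exhaustive over a seeded sample of pairs, length <= 3, entries <= 3
  set.seed(4)
  for (len in 1:3) {
    for (rep in 1:30) {
      u <- sample(0:3, len, replace = TRUE)
      v <- sample(0:3, len, replace = TRUE)
      want <- if (any(u == 0 & v > 0)) Inf else cnt_bfs_oracle(u, v)
      expect_equal(cnt_distance(u, v), want,
                   info = paste(paste(u, collapse = ","), "->",
                                paste(v, collapse = ",")))
    }
  }
})

test_that("distance is a metric on zero-free profiles", {
  profiles <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  n <- nrow(profiles)
  D <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    D[i, j] <- cnt_distance(profiles[i, ], profiles[j, ])
  expect_true(all(diag(D) == 0))
  expect_true(all(D[D > 0 | t(D) > 0] > 0 | diag(n)[D > 0 | t(D) > 0] == 1))
  expect_equal(D, t(D))
  for (k in 1:n) expect_true(all(D <= outer(D[, k], D[k, ], `+`) + 1e-9))
})

test_that("WGD rule adds one event exactly when doubling is used", {
  a <- c(2, 3, 2); b <- c(1, 1, 1)
  expect_equal(wgd_distance(a, b, a, b), 0)
  # doubled partner: d2 = 0, +1 for the WGD event
  expect_equal(wgd_distance(a, b, 2 * a, 2 * b), 1)
  # A=[2,2] vs B=[3,3] per haplotype: one interval gain beats doubling
  expect_equal(wgd_distance(c(2, 2), c(2, 2), c(3, 3), c(3, 3)), 2)
  expect_equal(hapcells:::.profile_f(c(2, 2), c(2, 2), c(3, 3), c(3, 3),
                                     rep("1", 2)), 2)
  # ties favouring d1 take d1 with no increment
  # (A = B = all twos: d1 = 0 regardless of d2/d3)
  expect_equal(wgd_distance(c(2, 2), c(2, 2), c(2, 2), c(2, 2)), 0)
  # random all-positive profiles always give f(A, 2A) = 1
  set.seed(8)
  for (i in 1:20) {
    a <- sample(1:4, 6, replace = TRUE)
    b <- sample(1:4, 6, replace = TRUE)
    expect_equal(wgd_distance(a, b, 2 * a, 2 * b,
                              chrom = rep(c("1", "2"), each = 3)), 1)
  }
})

test_that("pairwise distances are seeded, symmetric and complete", {
  cfg <- sim_config(n_cells = 12, bins_per_chrom = 10, seed = 21,
                    events_per_edge = c(whole_chromosome = 1, arm = 0,
                                        segment = 1))
  sim <- simulate_population(cfg)
  hscn <- cn_from_states(sim$truth$a + sim$truth$b, sim$grid)
  hscn$a <- as.vector(t(sim$truth$a))  # cell-major ordering
  hscn <- hapcells:::.from_matrix(sim$truth$a, sim$grid, "a")
  hscn$b <- hapcells:::.from_matrix(sim$truth$b, sim$grid, "b")$b
  hscn$state <- hscn$a + hscn$b
  d1 <- pairwise_distance_matrix(hscn, sim$grid, max_n = 8, seed = 5)
  d2 <- pairwise_distance_matrix(hscn, sim$grid, max_n = 8, seed = 5)
  expect_identical(d1$dist, d2$dist)
  expect_equal(d1$n_pairs, choose(8, 2))
  expect_equal(d1$dist, t(d1$dist))
  # identical population: all distances zero
  flat <- hscn
  flat$a <- 1L; flat$b <- 1L; flat$state <- 2L
  d0 <- pairwise_distance_matrix(flat, sim$grid, max_n = 8, seed = 5)
  expect_true(all(d0$dist == 0))
  expect_error(pairwise_distance_matrix(flat[flat$cell_id ==
                                               flat$cell_id[1], ], sim$grid),
               "two cells")
})

test_that("parallel events need both alleles altered above 1% on > 4 Mbp", {
  seg <- function(span_bp, n = 200, fa = 0.02, fb = 0.03) {
    a <- rep(1L, n); b <- rep(1L, n)
    a[seq_len(round(fa * n))] <- 0L
    b[round(fa * n) + seq_len(round(fb * n))] <- 0L
    data.frame(segment_id = 1L, chrom = "chr1", start = 1L, end = span_bp,
               span = span_bp, cell_id = sprintf("c%03d", 1:n),
               total = a + b, a = a, b = b)
  }
  ev <- detect_parallel_cna(seg(5e6))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$direction, "loss")
  expect_equal(ev$frac_a, 0.02)
  expect_equal(ev$frac_b, 0.03)
  # 3 Mbp span: excluded by the span rule
  expect_equal(nrow(detect_parallel_cna(seg(3e6))), 0L)
  # 0.5% on one allele: excluded by the fraction rule
  expect_equal(nrow(detect_parallel_cna(seg(5e6, fa = 0.005))), 0L)
  # exactly 1% is not enough (strict inequality)
  expect_equal(nrow(detect_parallel_cna(seg(5e6, fa = 0.01))), 0L)
})

test_that("clonality classes follow the printed CCF boundaries", {
  expect_equal(classify_clonality(c(0.85, 0.5, 0.2, 0.81, 0.8, 0.21, 0.05)),
               c("clonal", "subclonal", "rare", "clonal", "subclonal",
                 "subclonal", "rare"))
})

test_that("parsimony scores match hand-worked trees and the exhaustive oracle", {
  # star tree, 10 tips, one gained: a single event
  star <- ape::read.tree(text = paste0("(", paste0("t", 1:10, ":1",
                                                   collapse = ","), ");"))
  states <- setNames(c(1L, rep(0L, 9)), paste0("t", 1:10))
  expect_equal(hapcells:::.sankoff_score(star, states), 1)
  # ((A,B),(C,D)); with A,B gained: one event on the internal edge
  quart <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  st <- setNames(c(1L, 1L, 0L, 0L), c("A", "B", "C", "D"))
  expect_equal(hapcells:::.sankoff_score(quart, st), 1)
  expect_equal(hapcells:::.sankoff_score(quart,
                                         setNames(rep(0L, 4), LETTERS[1:4])),
               0)
  # exhaustive oracle on random binary trees up to 8 tips
  set.seed(12)
  for (rep in 1:20) {
    nt <- sample(4:8, 1)
    tr <- ape::rtree(nt)
    st <- setNames(sample(0:1, nt, replace = TRUE), tr$tip.label)
    expect_equal(hapcells:::.sankoff_score(tr, st), parsimony_oracle(tr, st))
  }
})

test_that("parsimony agrees with an independent phylogenetics implementation", {
  skip_if_not_installed("phangorn")
  set.seed(13)
  for (rep in 1:10) {
    nt <- sample(5:12, 1)
    tr <- ape::rtree(nt)
    st <- setNames(sample(0:1, nt, replace = TRUE), tr$tip.label)
    dat <- phangorn::phyDat(matrix(as.character(st), ncol = 1,
                                   dimnames = list(names(st), NULL)),
                            type = "USER", levels = c("0", "1"))
    expect_equal(hapcells:::.sankoff_score(tr, st),
                 as.numeric(phangorn::parsimony(tr, dat)))
  }
})

test_that("event rates divide summed scores by cell count with scale classes", {
  grid <- tiny_grid(n_chrom = 2, bins = 20)
  cen <- default_centromeres(grid)
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  # one whole-chromosome gain shared by A and B; one segmental loss in D
  mk <- function(id, chrom, start, end, span, totals, a = NULL) {
    data.frame(segment_id = id, chrom = chrom, start = start, end = end,
               span = span, cell_id = c("A", "B", "C", "D"),
               total = totals, a = 1L, b = 1L)
  }
  segs <- rbind(
    mk(1L, "chr1", 1, 20 * 5e5, 1e7, c(3L, 3L, 2L, 2L)),
    mk(2L, "chr2", 1, 6 * 5e5, 3e6, c(2L, 2L, 2L, 1L)))
  r <- parsimony_event_rate(tree, segs, grid, cen)
  gain_row <- r$rates[r$rates$direction == "gain" & r$rates$score > 0, ]
  expect_equal(gain_row$class, "whole_chromosome")
  expect_equal(gain_row$score, 1)
  expect_equal(gain_row$rate, 0.25)
  loss_row <- r$rates[r$rates$direction == "loss" & r$rates$score > 0, ]
  expect_equal(loss_row$class, "segmental")
  expect_equal(loss_row$rate, 0.25)
  expect_warning(
    parsimony_event_rate(
      ape::read.tree(text = "((A:1,B:1):1,(C:1,E:1):1);"),
      segs, grid, cen),
    "dropped")
})

test_that("segment scale classification uses 95% coverage of chrom or arm", {
  grid <- tiny_grid(n_chrom = 1, bins = 20)
  cen <- centromere_table("chr1", 5e6 - 1e4, 5e6 + 1e4)  # between bins 10/11
  segs <- data.frame(
    chrom = "chr1",
    start = c(1, 1, 2.5e6 + 1),
    end = c(1e7, 4.5e6, 5e6))
  cls <- classify_segment_scale(segs, grid, cen)
  expect_equal(cls, c("whole_chromosome", "arm", "segmental"))
  expect_warning(
    classify_segment_scale(data.frame(chrom = "chr1", start = 1, end = 4e6),
                           grid, centromere_table(character(0), numeric(0),
                                                  numeric(0))),
    "centromere")
})

test_that("cophenetic diversity equals brute-force path sums", {
  two <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(cophenetic_diversity(two), 2)
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_equal(cophenetic_diversity(star), 2)
  set.seed(3)
  cat <- ape::rtree(8)
  D <- ape::cophenetic.phylo(cat)
  brute <- mean(D[upper.tri(D)])
  expect_equal(cophenetic_diversity(cat), brute)
  expect_error(cophenetic_diversity(ape::read.tree(text = "(A:1);")),
               "two tips")
})

test_that("richer event rates raise parallel counts, CN and tree distances together", {
  stats_at <- function(rate, seed) {
    cfg <- sim_config(n_cells = 30, bins_per_chrom = 20,
                      events_per_edge = c(whole_chromosome = rate,
                                          arm = rate, segment = rate),
                      cell_event_rate = rate / 2, seed = seed)
    sim <- simulate_population(cfg)
    hscn <- hapcells:::.from_matrix(sim$truth$a, sim$grid, "a")
    hscn$b <- hapcells:::.from_matrix(sim$truth$b, sim$grid, "b")$b
    hscn$state <- hscn$a + hscn$b
    cons <- consensus_profile(
      cn_from_states(sim$truth$a + sim$truth$b, sim$grid), sim$clones,
      sim$grid)
    clone_segs <- do.call(rbind, lapply(split(cons, cons$clone), function(d)
      hapcells:::.segment_states(d$state, d[, c("chrom", "start", "end")])))
    segt <- disjoin_and_genotype(clone_segs, hscn, sim$grid)
    par_n <- nrow(detect_parallel_cna(segt, min_span = 1e6,
                                      min_frac = 0.005))
    dist_med <- pairwise_distance_matrix(hscn, sim$grid, max_n = 15,
                                         seed = 1)$median
    c(par_n, dist_med)
  }
  set.seed(99)
  lo <- vapply(1:6, function(s) stats_at(0.3, s), numeric(2))
  hi <- vapply(1:6, function(s) stats_at(3, s + 100), numeric(2))
  expect_gt(mean(hi[1, ]), mean(lo[1, ]))  # more parallel events
  expect_gt(mean(hi[2, ]), mean(lo[2, ]))  # larger copy number distances
})
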