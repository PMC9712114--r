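# Ploidy, consensus profiles, missegregation, gain/loss segments, HLAMP
# statistics and the disjoint genotyped segment table.

test_that("cell ploidy is the modal state with ties to the smaller value", {
  expect_equal(cell_ploidy(c(rep(2L, 6), rep(3L, 4))), 2L)
  expect_equal(cell_ploidy(c(rep(2L, 5), rep(4L, 5))), 2L)  # tie rule
  expect_equal(cell_ploidy(rep(4L, 8)), 4L)                 # polyploid cell
  expect_error(cell_ploidy(NA_integer_), "masked")
})

test_that("consensus profiles take modes and medians with stated tie rules", {
  grid <- tiny_grid(bins = 2)
  states <- rbind(c(2L, 2L), c(2L, 2L), c(3L, 2L))
  rownames(states) <- paste0("c", 1:3)
  cn <- cn_from_states(states, grid, raw = states + 0.1)
  clones <- setNames(rep("A", 3), paste0("c", 1:3))
  hscn <- cn_from_states(states, grid)
  # rows are cell-major: (c1,b1),(c1,b2),(c2,b1),(c2,b2),(c3,b1),(c3,b2)
  hscn$a <- c(2L, 1L, 2L, 1L, 1L, 1L)   # bin 1 states: (2,1),(2,1),(1,2)
  hscn$b <- c(1L, 1L, 1L, 1L, 2L, 1L)
  hscn$baf <- c(0.2, 0.5, 0.4, 0.5, 0.3, 0.5)
  cons <- consensus_profile(cn, clones, grid, hscn)
  expect_equal(cons$state, c(2L, 2L))          # mode of {2,2,3}
  expect_equal(cons$baf[1], 0.3)               # median of {0.2, 0.4, 0.3}
  expect_equal(c(cons$a[1], cons$b[1]), c(2L, 1L))  # mode of {(2,1),(2,1),(1,2)}
  expect_error(consensus_profile(cn, clones[1:2], grid), "clone label")
})

test_that("missegregation uses the 75% rule with ploidy normalization", {
  grid <- tiny_grid(n_chrom = 2, bins = 20)
  base <- matrix(2L, 10, 40)
  rownames(base) <- sprintf("c%02d", 1:10)
  clones <- setNames(rep("A", 10), rownames(base))
  # cell 1: +1 on 80% of chr1 bins -> event; cell 2: +1 on 74% -> none
  m <- base
  m[1, 1:16] <- 3L
  m[2, 1:14] <- 3L   # 14/20 = 70% < 75%
  ev <- detect_missegregations(cn_from_states(m, grid), clones, grid)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$cell_id, "c01")
  expect_equal(ev$chrom, "chr1")
  expect_equal(ev$offset, 1L)
  expect_equal(ev$fraction, 0.8)
  # a clean tetraploid cell in a diploid clone normalizes away
  m2 <- base
  m2[3, ] <- 4L
  ev2 <- detect_missegregations(cn_from_states(m2, grid), clones, grid)
  expect_equal(nrow(ev2), 0L)
  # tetraploid cell with one extra chromosome relative to doubled genome
  m3 <- base
  m3[4, ] <- 4L
  m3[4, 21:40] <- 6L   # chr2 at 6 -> normalized 3 vs consensus 2
  ev3 <- detect_missegregations(cn_from_states(m3, grid), clones, grid)
  expect_equal(ev3$chrom, "chr2")
  expect_equal(ev3$offset, 1L)
})

test_that("gain/loss segments respect the 1.5 Mb noise filter", {
  grid <- tiny_grid(bins = 20)  # 500 kb bins
  states <- matrix(2L, 1, 20, dimnames = list("c1"))
  states[1, 3:5] <- 3L    # 3 bins = 1.5 Mb exactly -> discarded
  states[1, 10:13] <- 3L  # 4 bins = 2.0 Mb -> kept
  segs <- call_gain_loss_segments(cn_from_states(states, grid), grid,
                                  ploidy = c(c1 = 2L))
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$label, "gain")
  expect_equal(segs$n_bins, 4L)
  # flat profile yields no segments
  flat <- call_gain_loss_segments(
    cn_from_states(matrix(2L, 1, 20, dimnames = list("c1")), grid), grid,
    ploidy = c(c1 = 2L))
  expect_equal(nrow(flat), 0L)
  # masked bins inside a run do not break or shorten it
  states2 <- matrix(2L, 1, 20, dimnames = list("c1"))
  states2[1, 8:13] <- 1L
  mask <- rep(TRUE, 20); mask[10] <- FALSE
  s_masked <- call_gain_loss_segments(cn_from_states(states2, grid), grid,
                                      ploidy = c(c1 = 2L), bin_mask = mask)
  s_full <- call_gain_loss_segments(cn_from_states(states2, grid), grid,
                                    ploidy = c(c1 = 2L))
  expect_equal(nrow(s_masked), 1L)
  expect_equal(s_masked$label, s_full$label)
  expect_equal(s_masked$start, s_full$start)
  expect_equal(s_masked$end, s_full$end)
})

test_that("gain/loss ratio flags degenerate denominators", {
  segs <- data.frame(label = c(rep("gain", 4), rep("loss", 2)))
  expect_equal(gain_loss_ratio(segs)$ratio, 2)
  expect_true(is.nan(gain_loss_ratio(segs[0, , drop = FALSE])$ratio))
  expect_equal(gain_loss_ratio(data.frame(label = rep("gain", 5)))$ratio, Inf)
})

test_that("HLAMP bins need >= 10 cells at raw copy >= 10", {
  grid <- tiny_grid(bins = 3)
  raw <- matrix(2, 12, 3)
  rownames(raw) <- sprintf("c%02d", 1:12)
  raw[1:10, 1] <- 10.2   # 10 cells at >= 10 -> HLAMP
  raw[1:9, 2] <- 50      # 9 cells -> not HLAMP
  states <- matrix(2L, 12, 3, dimnames = dimnames(raw))
  hl <- detect_hlamp_bins(cn_from_states(states, grid, raw = raw), grid)
  expect_equal(hl$bin_id, 1L)
  expect_equal(hl$n_cells_high, 10)
  # an all-diploid population nominates nothing
  none <- detect_hlamp_bins(cn_from_states(states, grid, raw = states * 1.0),
                            grid)
  expect_equal(nrow(none), 0L)
})

test_that("HLAMP variance centers by clone and recovers planted jitter", {
  grid <- tiny_grid(bins = 2)
  # two clones with different means but zero within-clone spread -> var 0
  raw <- rbind(matrix(12, 5, 2), matrix(20, 5, 2))
  rownames(raw) <- sprintf("c%02d", 1:10)
  states <- matrix(2L, 10, 2, dimnames = dimnames(raw))
  clones <- setNames(rep(c("A", "B"), each = 5), rownames(raw))
  cn <- cn_from_states(states, grid, raw = raw)
  hl <- data.frame(bin_id = 1:2)
  v <- hlamp_copy_variance(cn, clones, grid, hl)
  expect_equal(v$per_bin$variance, c(0, 0))
  expect_equal(v$mean_variance, 0)
  # invariance: multiplying a clone's raw copies by its ploidy changes nothing
  raw2 <- raw
  states2 <- states
  states2[clones == "B", ] <- 4L   # clone B tetraploid
  raw2[clones == "B", ] <- raw[clones == "B", ] * 2
  v2 <- hlamp_copy_variance(cn_from_states(states2, grid, raw = raw2),
                            clones, grid, hl)
  expect_equal(v2$mean_variance, 0)
  # planted amplitude jitter is recovered within 20% at 500 cells
  set.seed(5)
  sigma <- 0.8
  big <- matrix(10 + rnorm(500 * 2, 0, sigma), 500, 2)
  rownames(big) <- sprintf("c%03d", 1:500)
  st <- matrix(1L, 500, 2, dimnames = dimnames(big))
  cl <- setNames(rep("A", 500), rownames(big))
  v3 <- hlamp_copy_variance(cn_from_states(st, grid, raw = big), cl, grid, hl)
  expect_lt(abs(v3$mean_variance - sigma^2) / sigma^2, 0.2)
})

test_that("clone amplitude ratio uses the inclusive ratio-2 boundary", {
  grid <- tiny_grid(bins = 1)
  cons <- data.frame(clone = c("A", "B"), chrom = "chr1", start = 1,
                     end = 5e5, state = 2L, copy = c(16, 8), n_cells = 5)
  genes <- data.frame(gene = "G1", chrom = "chr1", start = 100, end = 200)
  r <- clone_amplitude_ratio(cons, genes, grid)
  expect_equal(r$ratio, 2)
  expect_true(r$variable)
  cons$copy <- c(3, 2)
  expect_false(clone_amplitude_ratio(cons, genes, grid)$variable)
  cons$copy <- c(6, 0)
  r3 <- clone_amplitude_ratio(cons, genes, grid)
  expect_equal(r3$ratio, Inf)
  expect_true(r3$variable)
  genes$chrom <- "chrX"
  expect_error(clone_amplitude_ratio(cons, genes, grid), "outside")
})

test_that("disjoint segments partition breakpoint unions and genotype by mode", {
  grid <- tiny_grid(bins = 20)
  # segmentations [1-10],[11-20] and [1-15],[16-20] in bins
  segm <- data.frame(
    chrom = "chr1",
    start = grid$start[c(1, 11, 1, 16)],
    end = grid$end[c(10, 20, 15, 20)])
  states <- matrix(2L, 2, 20)
  states[2, 11:15] <- 3L
  rownames(states) <- c("c1", "c2")
  hscn <- cn_from_states(states, grid)
  hscn$a <- pmax(hscn$state - 1L, 0L)
  hscn$b <- pmin(hscn$state, 1L)
  st <- disjoin_and_genotype(segm, hscn, grid)
  segs <- unique(st[, c("chrom", "start", "end")])
  expect_equal(nrow(segs), 3L)   # [1-10], [11-15], [16-20]
  expect_equal(segs$start, grid$start[c(1, 11, 16)])
  expect_equal(segs$end, grid$end[c(10, 15, 20)])
  # coverage without overlap
  expect_equal(sum(segs$end - segs$start + 1), 20 * 5e5)
  # genotype is modal per segment
  expect_equal(st$total[st$cell_id == "c2" & st$start == grid$start[11]], 3L)
  # mixed states within a segment genotype to the mode
  states3 <- matrix(c(2L, 2L, 3L), 1, 3)
  rownames(states3) <- "c1"
  g3 <- tiny_grid(bins = 3)
  h3 <- cn_from_states(states3, g3)
  h3$a <- states3[1, ] - 1L
  h3$b <- rep(1L, 3)
  one <- disjoin_and_genotype(
    data.frame(chrom = "chr1", start = 1, end = max(g3$end)), h3, g3)
  expect_equal(one$total, 2L)
})

test_that("HLAMP locus features follow their definitions on fixtures", {
  grid <- tiny_grid(bins = 10, width = 5e5)
  states <- matrix(4L, 2, 10)
  rownames(states) <- c("c1", "c2")
  raw <- states * 1.0
  raw[, 5] <- 16
  hscn <- cn_from_states(states, grid)
  hscn$a <- rep(2L, 20); hscn$b <- rep(2L, 20)
  cn <- cn_from_states(states, grid, raw = raw)
  svs <- data.frame(chrom1 = "chr1", pos1 = c(1e6, 1.2e6, 2e6, 2.2e6),
                    chrom2 = c("chr1", "chr1", "chr2", "chr3"),
                    pos2 = c(3e6, 3.1e6, 5e5, 5e5),
                    type = c("foldback", "foldback", "translocation",
                             "duplication"))
  loci <- data.frame(locus = "ONC1", chrom = "chr1", pos = 2.25e6)
  fv <- hlamp_feature_vector(loci, hscn, cn, svs, grid)
  expect_equal(fv$entropy, 0)             # single HSCN state in window
  expect_equal(fv$n_sv, 4)
  expect_equal(fv$prop_foldback, 0.5)     # 2 of 4
  expect_equal(fv$copy_ratio, 16 / mean(raw[, 1:10]))
  expect_equal(fv$mean_minor_copy, 2)
  # no SVs in window -> SV features are zero
  fv0 <- hlamp_feature_vector(loci, hscn, cn, svs[0, , drop = FALSE], grid)
  expect_equal(fv0$n_sv, 0)
  expect_equal(fv0$prop_foldback, 0)
})

test_that("feature clustering selects k by silhouette on separable loci", {
  set.seed(1)
  features <- data.frame(
    locus = sprintf("L%02d", 1:12),
    entropy = c(rnorm(6, 0, 0.05), rnorm(6, 3, 0.05)),
    n_sv = c(rnorm(6, 1, 0.1), rnorm(6, 20, 0.1)),
    copy_ratio = c(rnorm(6, 1, 0.02), rnorm(6, 8, 0.02)))
  cl <- cluster_hlamp_features(features, k_max = 5)
  expect_equal(cl$k, 2)
  expect_equal(length(unique(cl$clusters[1:6])), 1L)
  expect_equal(length(unique(cl$clusters[7:12])), 1L)
})
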