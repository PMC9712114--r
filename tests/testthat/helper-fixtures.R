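# Fixture builders and independent oracles shared across the test files.
# Oracles deliberately avoid the package's own code paths: brute-force
# enumeration, BFS over operation graphs, and numerically integrated
# Beta-Binomial likelihoods.

tiny_grid <- function(n_chrom = 1, bins = 10, width = 5e5, mappability = 1) {
  sizes <- setNames(rep(bins * width, n_chrom),
                    paste0("chr", seq_len(n_chrom)))
  bin_grid(sizes, width = width, mappability = mappability)
}

# long cn table from a cells x bins state matrix (rownames = cell ids)
cn_from_states <- function(states, grid, raw = NULL) {
  if (is.null(rownames(states)))
    rownames(states) <- sprintf("cell_%02d", seq_len(nrow(states)))
  df <- hapcells:::.from_matrix(states, grid, "state")
  if (is.null(raw)) raw <- states
  rownames(raw) <- rownames(states)
  df$raw_copy <- hapcells:::.from_matrix(raw, grid, "raw_copy")$raw_copy
  rownames(df) <- NULL
  df
}

# one haplotype block per bin, counts given per cell x bin
alleles_from_counts <- function(b, t, grid) {
  if (is.null(rownames(b)))
    rownames(b) <- rownames(t) <- sprintf("cell_%02d", seq_len(nrow(b)))
  df <- hapcells:::.from_matrix(b, grid, "b_count")
  df$t_count <- hapcells:::.from_matrix(t, grid, "t_count")$t_count
  rownames(df) <- NULL
  df
}

qc_for <- function(cell_ids, clone = "clone_1") {
  data.frame(cell_id = cell_ids, quality = 0.95, s_phase_flag = FALSE,
             contam_fraction = 0, clone = clone)
}

# ---- independent Beta-Binomial pmf (numeric integration over the Beta) ----
bb_pmf_oracle <- function(x, size, mu, s) {
  f <- function(p) choose(size, x) * p^x * (1 - p)^(size - x) *
    stats::dbeta(p, mu * s, (1 - mu) * s)
  stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
}

# ---- exhaustive max-likelihood path oracle for the per-chromosome HMM ----
# Mirrors the model definition (uniform initial distribution, e to the
# BAF-nearest successor, eps-clamped emission mean) but enumerates every
# path and evaluates emissions with the integrated pmf above.
hmm_path_oracle <- function(totals, b_obs, t_obs, p) {
  tt <- pmin(totals, p$t_max)
  spaces <- lapply(tt, function(t1) 0:t1)
  paths <- expand.grid(rev(spaces))[, length(spaces):1, drop = FALSE]
  baf_of <- function(b, t1) if (t1 > 0) b / t1 else 0.5
  score <- apply(paths, 1, function(path) {
    ll <- -log(tt[1] + 1)
    for (i in seq_along(tt)) {
      if (t_obs[i] > 0 && tt[i] > 0) {
        mu <- min(max(path[i] / tt[i], p$eps), 1 - p$eps)
        ll <- ll + log(bb_pmf_oracle(b_obs[i], t_obs[i], mu, p$s))
      }
      if (i > 1) {
        baf2 <- vapply(spaces[[i]], baf_of, numeric(1), t1 = tt[i])
        succ <- spaces[[i]][which.min(abs(baf2 - baf_of(path[i - 1],
                                                        tt[i - 1])))]
        n2 <- tt[i] + 1
        ll <- ll + if (n2 == 1) 0 else
          if (path[i] == succ) log(p$e) else log((1 - p$e) / (n2 - 1))
      }
    }
    ll
  })
  list(b = as.integer(paths[which.max(score), ]), loglik = max(score))
}

# ---- BFS oracle for the copy number transformation distance --------------
# States are integer profiles; one operation adds or subtracts 1 on a
# contiguous interval, values floor at 0, zero positions never regain
# copies. Intermediate values are capped at `cap` (overshooting past the
# target maximum is never useful).
cnt_bfs_oracle <- function(u, v, cap = max(u, v)) {
  if (identical(u, v)) return(0)
  n <- length(u)
  key <- function(x) paste(x, collapse = ",")
  seen <- new.env(hash = TRUE)
  assign(key(u), TRUE, envir = seen)
  frontier <- list(u)
  depth <- 0
  ops <- list()
  for (i in 1:n) for (j in i:n) for (d in c(1L, -1L))
    ops[[length(ops) + 1L]] <- list(i = i, j = j, d = d)
  while (length(frontier)) {
    depth <- depth + 1
    nxt <- list()
    for (x in frontier) {
      for (op in ops) {
        y <- x
        idx <- op$i:op$j
        if (op$d > 0) {
          y[idx] <- ifelse(y[idx] == 0, 0L, y[idx] + 1L)  # zeros never regain
          if (any(y > cap)) next
        } else {
          y[idx] <- pmax(y[idx] - 1L, 0L)
        }
        if (identical(as.integer(y), as.integer(v))) return(depth)
        k <- key(y)
        if (!exists(k, envir = seen)) {
          assign(k, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- y
        }
      }
    }
    frontier <- nxt
    if (depth > 30) return(Inf)
  }
  Inf
}

# ---- exhaustive parsimony oracle -----------------------------------------
# Minimal number of state changes over all labellings of internal nodes.
parsimony_oracle <- function(tree, states) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  x <- states[tree$tip.label]
  best <- Inf
  for (mask in 0:(2^n_int - 1)) {
    lab <- c(x, as.integer(intToBits(mask))[seq_len(n_int)])
    cost <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, cost)
  }
  best
}
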