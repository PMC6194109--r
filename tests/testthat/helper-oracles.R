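# Independent brute-force oracles, coded from the textbook definitions with
# explicit loops. They share no internals with the package.

# Pairwise-identity probability oracle: the chance that two distinct draws
# from the sample are identical, by explicit double loop.
oracle_match_probability <- function(items) {
  n <- length(items)
  same <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && identical(items[[i]], items[[j]])) same <- same + 1L
  }
  same / (n * (n - 1))
}

# AMOVA oracle: sums of squares from explicit pairwise-distance partitions,
# variance components from the standard nested ANOVA coefficient formulas.
oracle_amova <- function(X, pop, assign = NULL) {
  n <- nrow(X)
  d2 <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d2[i, j] <- sum((X[i, ] - X[j, ])^2)
  pop <- as.character(pop)
  pops <- sort(unique(pop))
  P <- length(pops)
  np <- vapply(pops, function(p) sum(pop == p), 0L)
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    ss_total <- ss_total + d2[i, j]
  ss_total <- ss_total / n
  ss_wp <- 0
  for (p in pops) {
    idx <- which(pop == p)
    s <- 0
    for (a in idx) for (b in idx) if (a < b) s <- s + d2[a, b]
    ss_wp <- ss_wp + s / length(idx)
  }
  if (is.null(assign)) {
    df_a <- P - 1; df_w <- n - P
    ss_ap <- ss_total - ss_wp
    n0 <- (n - sum(np^2) / n) / df_a
    sigma_w <- ss_wp / df_w
    sigma_a <- (ss_ap / df_a - sigma_w) / n0
    list(ss = c(among = ss_ap, within = ss_wp, total = ss_total),
         sigma2 = c(among = sigma_a, within = sigma_w),
         phi_st = sigma_a / (sigma_a + sigma_w))
  } else {
    grp_of_pop <- assign[pops]
    groups <- sort(unique(grp_of_pop))
    G <- length(groups)
    grp <- grp_of_pop[pop]
    Ng <- vapply(groups, function(g) sum(grp == g), 0)
    ss_wg <- 0
    for (g in groups) {
      idx <- which(grp == g)
      s <- 0
      for (a in idx) for (b in idx) if (a < b) s <- s + d2[a, b]
      ss_wg <- ss_wg + s / length(idx)
    }
    ss_ag <- ss_total - ss_wg
    ss_ap <- ss_wg - ss_wp
    df_ag <- G - 1; df_ap <- P - G; df_w <- n - P
    A <- vapply(groups, function(g) {
      sel <- pops[grp_of_pop == g]
      sum(np[sel]^2) / sum(np[sel])
    }, 0)
    n1 <- (n - sum(A)) / df_ap
    n2 <- (sum(A) - sum(np^2) / n) / df_ag
    n3 <- (n - sum(Ng^2) / n) / df_ag
    sigma_c <- ss_wp / df_w
    sigma_b <- (ss_ap / df_ap - sigma_c) / n1
    sigma_a <- (ss_ag / df_ag - sigma_c - n2 * sigma_b) / n3
    tot <- sigma_a + sigma_b + sigma_c
    list(ss = c(among_groups = ss_ag, among = ss_ap, within = ss_wp,
                total = ss_total),
         sigma2 = c(among_groups = sigma_a, among = sigma_b,
                    within = sigma_c),
         phi_st = (sigma_a + sigma_b) / tot,
         phi_ct = sigma_a / tot,
         phi_sc = sigma_b / (sigma_b + sigma_c))
  }
}

# All permutations of 1..n (recursive, independent of the package helper).
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1)) for (pos in 0:(n - 1))
    out[[length(out) + 1L]] <- append(p, n, after = pos)
  out
}

# Exhaustive one-sided Mantel p-value.
oracle_mantel_p <- function(dm1, dm2) {
  n <- nrow(dm1)
  ut <- upper.tri(dm1)
  r_obs <- cor(dm1[ut], dm2[ut])
  rs <- vapply(oracle_perms(n), function(p) cor(dm1[ut], dm2[p, p][ut]), 0)
  mean(rs >= r_obs - 1e-12)
}

# All spanning trees of a complete graph on n nodes with weight matrix D,
# by enumerating edge subsets of size n-1 and keeping the connected ones.
oracle_spanning_trees <- function(D) {
  n <- nrow(D)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  subsets <- utils::combn(nrow(pairs), n - 1)
  trees <- list()
  for (s in seq_len(ncol(subsets))) {
    es <- pairs[subsets[, s], , drop = FALSE]
    # connectivity check by label propagation
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (e in seq_len(nrow(es))) {
        a <- es[e, 1]; b <- es[e, 2]
        m <- min(comp[a], comp[b])
        if (comp[a] != m || comp[b] != m) {
          comp[comp == comp[a] | comp == comp[b]] <- m
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    if (length(unique(comp)) == 1L)
      trees[[length(trees) + 1L]] <-
        list(edges = es, weight = sum(D[es]))
  }
  trees
}

# Minimal Steiner-tree length for terminals given as integer rows of X
# (small L), allowing at most one extra point chosen from the bounding box.
oracle_steiner_length <- function(X) {
  mst_len <- function(M) {
    n <- nrow(M)
    if (n < 2) return(0)
    D <- as.matrix(dist(M, method = "manhattan"))
    in_tree <- c(TRUE, rep(FALSE, n - 1)); dmin <- D[1, ]; tot <- 0
    for (k in 2:n) {
      cand <- which(!in_tree)
      i <- cand[which.min(dmin[cand])]
      tot <- tot + dmin[i]; in_tree[i] <- TRUE
      dmin <- pmin(dmin, D[i, ])
    }
    tot
  }
  best <- mst_len(X)
  grid <- expand.grid(lapply(seq_len(ncol(X)), function(j)
    seq(min(X[, j]), max(X[, j]))))
  for (g in seq_len(nrow(grid)))
    best <- min(best, mst_len(rbind(X, as.numeric(grid[g, ]))))
  best
}
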