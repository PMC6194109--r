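#' Squared repeat-count distance between two haplotypes
#'
#' The molecular distance underlying R_ST-style AMOVA: the sum over loci of
#' squared repeat-count differences (Slatkin-type, the convention used for
#' Y-STR database comparisons). Requires the reduced panel: no DYS385a/b,
#' no microvariants.
#'
#' @param h1,h2 named numeric vectors of repeat counts (same locus set).
#' @return Non-negative scalar; zero iff the haplotypes are identical.
#' @export
rst_distance_pair <- function(h1, h2) {
  if (!setequal(names(h1), names(h2)))
    stop("haplotypes cover different loci", call. = FALSE)
  sum((h1 - h2[names(h1)])^2)
}

# Exact pairwise squared Euclidean distances between rows of X.
pairwise_sq_dist <- function(X) {
  rs <- rowSums(X^2)
  D2 <- outer(rs, rs, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  diag(D2) <- 0
  D2
}

# Population block sums of a squared-distance matrix: B[p,p] = sum over
# unordered within-population pairs; B[p,q] = sum over all cross pairs.
pop_block_sums <- function(d2, pop) {
  pop <- factor(pop)
  P <- nlevels(pop)
  B <- matrix(0, P, P, dimnames = list(levels(pop), levels(pop)))
  idx <- split(seq_along(pop), pop)
  for (p in 1:P) for (q in p:P) {
    block <- d2[idx[[p]], idx[[q]], drop = FALSE]
    B[p, q] <- B[q, p] <- if (p == q) sum(block) / 2 else sum(block)
  }
  B
}

# Variance components from block sums. assign: integer group id per
# population (NULL for the one-level design among populations).
amova_from_blocks <- function(B, np, assign = NULL) {
  N <- sum(np); P <- length(np)
  ssd_total <- ((sum(B) - sum(diag(B))) / 2 + sum(diag(B))) / N
  ssd_wp <- sum(diag(B) / np)
  if (is.null(assign)) {
    df_a <- P - 1; df_w <- N - P
    ssd_ap <- ssd_total - ssd_wp
    n0 <- (N - sum(np^2) / N) / df_a
    sigma_w <- ssd_wp / df_w
    sigma_a <- (ssd_ap / df_a - sigma_w) / n0
    tot <- sigma_a + sigma_w
    phi_st <- if (tot == 0) 0 else sigma_a / tot
    list(ss = c(among_populations = ssd_ap, within = ssd_wp,
                total = ssd_total),
         df = c(among_populations = df_a, within = df_w, total = N - 1),
         sigma2 = c(among_groups = NA_real_, among_populations = sigma_a,
                    within = sigma_w),
         phi = c(phi_st = phi_st, phi_ct = NA_real_, phi_sc = NA_real_))
  } else {
    G <- length(unique(assign))
    Ng <- tapply(np, assign, sum)
    # within-group sums of squared deviations
    ssd_wg <- 0
    for (g in unique(assign)) {
      sel <- which(assign == g)
      tot_g <- sum(B[sel, sel, drop = FALSE]) / 2 + sum(diag(B)[sel]) / 2
      ssd_wg <- ssd_wg + tot_g / sum(np[sel])
    }
    ssd_ag <- ssd_total - ssd_wg
    ssd_ap <- ssd_wg - ssd_wp
    df_ag <- G - 1; df_ap <- P - G; df_w <- N - P
    A <- tapply(seq_along(np), assign, function(i) sum(np[i]^2)) /
      as.vector(Ng)
    n1 <- (N - sum(A)) / df_ap
    n2 <- (sum(A) - sum(np^2) / N) / df_ag
    n3 <- (N - sum(Ng^2) / N) / df_ag
    sigma_c <- ssd_wp / df_w
    sigma_b <- (ssd_ap / df_ap - sigma_c) / n1
    sigma_a <- (ssd_ag / df_ag - sigma_c - n2 * sigma_b) / n3
    tot <- sigma_a + sigma_b + sigma_c
    list(ss = c(among_groups = ssd_ag, among_populations = ssd_ap,
                within = ssd_wp, total = ssd_total),
         df = c(among_groups = df_ag, among_populations = df_ap,
                within = df_w, total = N - 1),
         sigma2 = c(among_groups = sigma_a, among_populations = sigma_b,
                    within = sigma_c),
         phi = c(phi_st = if (tot == 0) 0 else (sigma_a + sigma_b) / tot,
                 phi_ct = if (tot == 0) 0 else sigma_a / tot,
                 phi_sc = if (sigma_b + sigma_c == 0) 0 else
                   sigma_b / (sigma_b + sigma_c)))
  }
}

amova_stats <- function(d2, pop, assign = NULL) {
  pop <- factor(pop)
  np <- as.vector(table(pop))
  amova_from_blocks(pop_block_sums(d2, pop), np, assign)
}

#' Analysis of molecular variance on squared repeat differences
#'
#' One- or two-level AMOVA of a reduced cohort using the R_ST molecular
#' distance ([rst_distance_pair()]). With no `grouping`, variance is
#' partitioned among and within populations (Phi_ST). With a `grouping`
#' (named vector mapping population to group), a hierarchical design
#' among groups / among populations within groups / within populations is
#' fitted (Phi_CT, Phi_SC, Phi_ST). Permutation p-values permute sample
#' population labels (Phi_ST), whole populations among groups (Phi_CT) and
#' samples among populations within groups (Phi_SC). Negative variance
#' component estimates are reported raw; displays clamp them at zero.
#'
#' @param cohort a reduced `ystr_cohort` (see [reduce_for_rst()]) with at
#'   least two populations, each of size >= 2.
#' @param grouping optional named vector/list mapping each population to a
#'   group label.
#' @param permutations number of permutations for p-values (0 to skip).
#' @param seed RNG seed, required when `permutations > 0`.
#' @return An object of class `amova_result`.
#' @export
amova <- function(cohort, grouping = NULL, permutations = 0, seed = NULL) {
  pop <- factor(cohort$data$population)
  if (nlevels(pop) < 2L) stop("need >= 2 populations", call. = FALSE)
  np <- table(pop)
  if (any(np < 2L))
    stop("population(s) with a single sample: ",
         paste(names(np)[np < 2L], collapse = ", "), call. = FALSE)
  X <- repeat_matrix(cohort)
  d2 <- pairwise_sq_dist(X)
  assign <- NULL
  if (!is.null(grouping)) {
    grouping <- unlist(grouping)
    missing_g <- setdiff(levels(pop), names(grouping))
    if (length(missing_g))
      stop("grouping lacks population(s): ",
           paste(missing_g, collapse = ", "), call. = FALSE)
    assign <- as.integer(factor(unname(grouping[levels(pop)])))
  }
  res <- amova_stats(d2, pop, assign)
  p_values <- NULL
  if (permutations > 0) {
    if (is.null(seed)) stop("seed is required when permutations > 0",
                            call. = FALSE)
    set.seed(seed)
    obs <- res$phi
    hits_st <- 0L
    hits_ct <- 0L
    B <- pop_block_sums(d2, pop)
    for (b in seq_len(permutations)) {
      perm_pop <- sample(pop)
      phi_p <- amova_stats(d2, perm_pop, assign)$phi
      if (phi_p[["phi_st"]] >= obs[["phi_st"]] - 1e-12) hits_st <- hits_st + 1L
      if (!is.null(assign)) {
        perm_assign <- sample(assign)
        phi_c <- amova_from_blocks(B, as.vector(table(pop)), perm_assign)$phi
        if (phi_c[["phi_ct"]] >= obs[["phi_ct"]] - 1e-12) hits_ct <- hits_ct + 1L
      }
    }
    p_values <- c(phi_st = (1 + hits_st) / (permutations + 1))
    if (!is.null(assign))
      p_values <- c(p_values, phi_ct = (1 + hits_ct) / (permutations + 1))
  }
  sig <- res$sigma2[!is.na(res$sigma2)]
  structure(c(res, list(
    variance_pct = 100 * pmax(sig, 0) / sum(pmax(sig, 0)),
    p_values = p_values, n_permutations = permutations, seed = seed,
    n = nrow(X), populations = levels(pop), grouping = grouping)),
    class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA on squared repeat-count differences (n = ", x$n, ", ",
      length(x$populations), " populations)\n", sep = "")
  comp <- data.frame(df = x$df[names(x$df) != "total"],
                     SS = x$ss[names(x$ss) != "total"])
  print(comp)
  sig <- x$sigma2[!is.na(x$sigma2)]
  cat("Variance components (raw): ",
      paste(names(sig), signif(sig, 4), sep = " = ", collapse = ", "), "\n")
  cat("Percent of variance (clamped at 0): ",
      paste(names(x$variance_pct), sprintf("%.1f%%", x$variance_pct),
            sep = " = ", collapse = ", "), "\n")
  phi <- x$phi[!is.na(x$phi)]
  cat("Phi: ", paste(names(phi), signif(phi, 4), sep = " = ",
                     collapse = ", "), "\n")
  if (!is.null(x$p_values))
    cat("Permutation p (", x$n_permutations, " perms): ",
        paste(names(x$p_values), signif(x$p_values, 3), sep = " = ",
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Pairwise Phi_ST (R_ST) between populations
#'
#' Runs [amova()] restricted to every pair of populations. Negative
#' estimates are reported raw; `clamp = TRUE` floors them at zero for
#' display or downstream ordination.
#'
#' @param cohort a reduced `ystr_cohort`.
#' @param permutations permutations per pair for p-values (0 to skip).
#' @param seed RNG seed (one stream per pair, derived deterministically).
#' @param clamp floor negative estimates at zero.
#' @return A list with `rst` (symmetric matrix, zero diagonal) and `p`
#'   (p-value matrix, `NA` if `permutations == 0`), class `pairwise_rst`.
#' @export
pairwise_rst <- function(cohort, permutations = 0, seed = NULL,
                         clamp = FALSE) {
  pops <- sort(unique(cohort$data$population))
  P <- length(pops)
  if (P < 2L) stop("need >= 2 populations", call. = FALSE)
  rst <- matrix(0, P, P, dimnames = list(pops, pops))
  pm <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  pair_id <- 0L
  for (i in seq_len(P - 1L)) for (j in (i + 1L):P) {
    pair_id <- pair_id + 1L
    sub <- cohort
    keep <- sub$data$population %in% pops[c(i, j)]
    sub$data <- sub$data[keep, , drop = FALSE]
    fit <- amova(sub, permutations = permutations,
                 seed = if (permutations > 0) seed + pair_id else NULL)
    rst[i, j] <- rst[j, i] <- fit$phi[["phi_st"]]
    if (permutations > 0) pm[i, j] <- pm[j, i] <- fit$p_values[["phi_st"]]
  }
  if (clamp) rst[rst < 0] <- 0
  structure(list(rst = rst, p = pm, clamped = clamp,
                 n_permutations = permutations, seed = seed),
            class = "pairwise_rst")
}

#' @export
print.pairwise_rst <- function(x, ...) {
  cat("Pairwise Phi_ST (", if (x$clamped) "clamped" else "raw", "):\n",
      sep = "")
  print(round(x$rst, 4))
  invisible(x)
}

#' Nei's standard genetic distance between populations
#'
#' Nei (1972) standard distance D = -ln I, with the normalized identity
#' I = J_XY / sqrt(J_X J_Y), where the J terms are Sigma p^2 /
#' Sigma p_X p_Y quantities arithmetically averaged over loci. Computed on
#' the full panel (DYS385a/b alleles both counted; microvariants are
#' ordinary allele categories). If two populations share no alleles at any
#' locus (I = 0), D is capped at `cap` with a warning rather than reported
#' as infinite.
#'
#' @param cohort a `ystr_cohort` with >= 2 populations.
#' @param cap distance assigned when I = 0 (default `log(1000)`).
#' @return Symmetric labeled distance matrix.
#' @export
nei_distance <- function(cohort, cap = log(1000)) {
  pops <- sort(unique(cohort$data$population))
  if (length(pops) < 2L) stop("need >= 2 populations", call. = FALSE)
  loci <- cohort_loci(cohort)
  # per-population allele frequency vectors on the union of alleles
  freqs <- lapply(pops, function(p) {
    sub <- cohort
    sub$data <- cohort$data[cohort$data$population == p, , drop = FALSE]
    if (nrow(sub$data) == 0L) stop("population with no data: ", p,
                                   call. = FALSE)
    lapply(loci, function(loc) {
      sp <- allele_spectrum(sub, loc)
      stats::setNames(spectrum_freqs(sp), sp$labels)
    })
  })
  names(freqs) <- pops
  D <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-length(pops)]) for (j in (i + 1):length(pops)) {
    jx <- jy <- jxy <- numeric(length(loci))
    for (l in seq_along(loci)) {
      fx <- freqs[[i]][[l]]; fy <- freqs[[j]][[l]]
      alleles <- union(names(fx), names(fy))
      px <- stats::setNames(rep(0, length(alleles)), alleles); px[names(fx)] <- fx
      py <- stats::setNames(rep(0, length(alleles)), alleles); py[names(fy)] <- fy
      jx[l] <- sum(px^2); jy[l] <- sum(py^2); jxy[l] <- sum(px * py)
    }
    I <- mean(jxy) / sqrt(mean(jx) * mean(jy))
    if (I <= 0) {
      warning("no shared alleles between ", pops[i], " and ", pops[j],
              "; Nei distance capped at ", signif(cap, 4))
      D[i, j] <- D[j, i] <- cap
    } else {
      D[i, j] <- D[j, i] <- min(-log(I), cap)
    }
  }
  D
}

# ---- SAMOVA-style search for the grouping maximizing Phi_CT --------------

stirling2 <- function(n, k) {
  if (k == 0) return(as.numeric(n == 0))
  S <- matrix(0, n + 1, k + 1)
  S[1, 1] <- 1
  for (i in 1:n) for (j in 1:min(i, k))
    S[i + 1, j + 1] <- j * S[i, j + 1] + S[i, j]
  S[n + 1, k + 1]
}

# Enumerate all partitions of 1..P into exactly k unlabeled non-empty
# groups, as a list of integer assignment vectors in restricted growth form.
enumerate_partitions <- function(P, k) {
  out <- list()
  recurse <- function(assign, used) {
    i <- length(assign) + 1L
    if (i > P) {
      if (used == k) out[[length(out) + 1L]] <<- assign
      return(invisible(NULL))
    }
    remaining <- P - i + 1L
    for (g in seq_len(min(used + 1L, k))) {
      if (used + (g > used) + 0L > k) next
      new_used <- max(used, g)
      if (new_used + remaining - 1L >= k)  # can still fill k groups
        recurse(c(assign, g), new_used)
    }
  }
  recurse(integer(0), 0L)
  out
}

#' Search for the population grouping maximizing among-group variance
#'
#' A SAMOVA-style search: find the partition of populations into `k` groups
#' that maximizes Phi_CT under the two-level AMOVA of [amova()]. When the
#' number of possible partitions (Stirling number of the second kind) is at
#' most `exhaustive_limit` the search is exhaustive and therefore exact;
#' otherwise simulated annealing is used (geometric cooling, rate 0.95,
#' 100 single-population reassignment moves per temperature, `restarts`
#' independent restarts). Deterministic given `seed`.
#'
#' @param cohort a reduced `ystr_cohort`.
#' @param k number of groups, `2 <= k <` number of populations.
#' @param restarts annealing restarts (ignored for exhaustive search).
#' @param seed RNG seed (annealing only).
#' @param exhaustive_limit max partition count for exhaustive search.
#' @return A list with `grouping` (named vector population -> group index),
#'   `phi_ct`, `method`, and `amova` (the fitted `amova_result`).
#' @export
samova_search <- function(cohort, k, restarts = 3, seed = NULL,
                          exhaustive_limit = 1e4) {
  pops <- sort(unique(cohort$data$population))
  P <- length(pops)
  if (k < 2 || k >= P)
    stop("infeasible k: need 2 <= k < ", P, call. = FALSE)
  X <- repeat_matrix(cohort)
  d2 <- pairwise_sq_dist(X)
  pop <- factor(cohort$data$population, levels = pops)
  np <- as.vector(table(pop))
  B <- pop_block_sums(d2, pop)
  objective <- function(assign) {
    amova_from_blocks(B, np, assign)$phi[["phi_ct"]]
  }
  n_part <- stirling2(P, k)
  if (n_part <= exhaustive_limit) {
    parts <- enumerate_partitions(P, k)
    vals <- vapply(parts, objective, 0)
    best <- parts[[which.max(vals)]]
    method <- "exhaustive"
  } else {
    if (is.null(seed)) stop("seed required for annealing search", call. = FALSE)
    set.seed(seed)
    best <- NULL; best_val <- -Inf
    for (r in seq_len(restarts)) {
      assign <- c(seq_len(k), sample(k, P - k, replace = TRUE))[sample(P)]
      while (length(unique(assign)) < k)  # ensure all groups occupied
        assign <- c(seq_len(k), sample(k, P - k, replace = TRUE))[sample(P)]
      cur_val <- objective(assign)
      temp <- 0.1
      while (temp > 1e-4) {
        for (m in 1:100) {
          i <- sample(P, 1)
          if (sum(assign == assign[i]) == 1L) next  # would empty a group
          g_new <- sample(setdiff(seq_len(k), assign[i]), 1)
          cand <- assign; cand[i] <- g_new
          cand_val <- objective(cand)
          if (cand_val >= cur_val ||
              stats::runif(1) < exp((cand_val - cur_val) / temp)) {
            assign <- cand; cur_val <- cand_val
          }
        }
        temp <- temp * 0.95
      }
      if (cur_val > best_val) { best_val <- cur_val; best <- assign }
    }
    method <- "annealing"
  }
  grouping <- stats::setNames(best, pops)
  fit <- amova(cohort, grouping = grouping)
  list(grouping = grouping, phi_ct = fit$phi[["phi_ct"]],
       method = method, amova = fit)
}
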