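test_that("squared repeat distance behaves as a locus-wise metric", {
  h1 <- c(L1 = 14, L2 = 10)
  expect_equal(rst_distance_pair(h1, h1), 0)
  expect_equal(rst_distance_pair(c(L1 = 14), c(L1 = 16)), 4)
  expect_equal(rst_distance_pair(h1, c(L1 = 15, L2 = 11)), 2)
  expect_error(rst_distance_pair(h1, c(L1 = 14, L3 = 10)),
               "different loci")
})

test_that("AMOVA on internally monomorphic populations gives Phi_ST = 1", {
  X <- rbind(matrix(10L, 4, 3), matrix(13L, 4, 3))
  co <- toy_cohort(X, pop = rep(c("A", "B"), each = 4))
  fit <- amova(co)
  expect_equal(fit$phi[["phi_st"]], 1)
  expect_equal(unname(fit$sigma2["within"]), 0)
})

test_that("identical population multisets yield no positive structure", {
  # the unbiased estimator is negative here (no among-population SS at
  # all), not zero; the oracle pins the exact value
  X <- rbind(c(10L, 10L), c(12L, 11L), c(10L, 10L), c(12L, 11L))
  co <- toy_cohort(X, pop = c("A", "A", "B", "B"))
  fit <- amova(co)
  orc <- oracle_amova(X, c("A", "A", "B", "B"))
  expect_equal(fit$phi[["phi_st"]], orc$phi_st, tolerance = 1e-12)
  expect_lte(fit$phi[["phi_st"]], 0)
})

test_that("a single-sample population is rejected by name", {
  X <- matrix(10L, 5, 2)
  co <- toy_cohort(X, pop = c("A", "A", "B", "B", "LONER"))
  expect_error(amova(co), "LONER")
})

test_that("one- and two-level AMOVA match the brute-force oracle", {
  set.seed(99)
  for (rep in 1:30) {
    sizes <- sample(2:4, 3, replace = TRUE)
    n <- sum(sizes)
    X <- matrix(sample(9:14, n * 2, replace = TRUE), n, 2)
    pop <- rep(c("A", "B", "C"), sizes)
    co <- toy_cohort(X, pop = pop)
    fit <- amova(co)
    orc <- oracle_amova(X, pop)
    expect_equal(unname(fit$sigma2[["among_populations"]]),
                 unname(orc$sigma2[["among"]]), tolerance = 1e-9)
    expect_equal(unname(fit$sigma2[["within"]]),
                 unname(orc$sigma2[["within"]]), tolerance = 1e-9)
    expect_equal(fit$phi[["phi_st"]], orc$phi_st, tolerance = 1e-9)
    # hierarchical design: A+B vs C
    grouping <- c(A = "g1", B = "g1", C = "g2")
    fit2 <- amova(co, grouping = grouping)
    orc2 <- oracle_amova(X, pop, assign = grouping)
    expect_equal(unname(fit2$sigma2[["among_groups"]]),
                 unname(orc2$sigma2[["among_groups"]]), tolerance = 1e-9)
    expect_equal(fit2$phi[["phi_ct"]], orc2$phi_ct, tolerance = 1e-9)
    expect_equal(fit2$phi[["phi_sc"]], orc2$phi_sc, tolerance = 1e-9)
    expect_equal(fit2$phi[["phi_st"]], orc2$phi_st, tolerance = 1e-9)
  }
})

test_that("pairwise Phi_ST equals AMOVA restricted to the pair", {
  sim <- simulate_cohort(sim_config(seed = 5, n_samples = 60,
                                    microvariant_rate = 0))
  red <- reduce_for_rst(sim$cohort)
  pw <- pairwise_rst(red)
  expect_true(isSymmetric(pw$rst))
  expect_true(all(diag(pw$rst) == 0))
  pops <- rownames(pw$rst)
  sub <- red
  keep <- sub$data$population %in% pops[1:2]
  sub$data <- sub$data[keep, , drop = FALSE]
  expect_identical(pw$rst[pops[1], pops[2]],
                   amova(sub)$phi[["phi_st"]])
})

test_that("permutation p-values are uniform under the null", {
  set.seed(2024)
  # rich allele space over several loci keeps Phi_ST effectively
  # continuous, so permutation ties do not bias the p-value distribution
  pvals <- replicate(200, {
    X <- matrix(sample(5:30, 12 * 8, replace = TRUE), 12, 8)
    co <- toy_cohort(X, pop = rep(c("A", "B", "C"), each = 4))
    amova(co, permutations = 99,
          seed = sample.int(1e6, 1))$p_values[["phi_st"]]
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("Nei distance matches hand arithmetic and degenerate contracts", {
  # two populations, one locus, two alleles: hand-computed -ln I
  X <- matrix(c(10L, 10L, 10L, 11L), 4, 1)
  co <- toy_cohort(X, pop = c("A", "A", "B", "B"))
  p1 <- c(1, 0); p2 <- c(0.5, 0.5)
  I <- sum(p1 * p2) / sqrt(sum(p1^2) * sum(p2^2))
  D <- nei_distance(co)
  expect_equal(D["A", "B"], -log(I), tolerance = 1e-12)
  # identical allele-frequency profiles -> zero distance
  co0 <- toy_cohort(rbind(X, X[3:4, , drop = FALSE]),
                    pop = c("A", "A", "A", "A", "B", "B"))
  co0$data[paste0("L", 1)] <- c("10", "11", "10", "11", "10", "11")
  expect_equal(nei_distance(co0)["A", "B"], 0, tolerance = 1e-12)
  # disjoint allele sets -> capped with a warning
  Xd <- matrix(c(10L, 10L, 20L, 20L), 4, 1)
  cod <- toy_cohort(Xd, pop = c("A", "A", "B", "B"))
  expect_warning(Dd <- nei_distance(cod), "capped")
  expect_equal(Dd["A", "B"], log(1000))
})

test_that("SAMOVA search is exact on small instances", {
  # 3 populations, k = 2: verify against the 3 possible splits
  set.seed(7)
  X <- matrix(sample(10:14, 9 * 2, replace = TRUE), 9, 2)
  pop <- rep(c("A", "B", "C"), each = 3)
  co <- toy_cohort(X, pop = pop)
  out <- samova_search(co, k = 2)
  expect_identical(out$method, "exhaustive")
  splits <- list(c(A = 1, B = 1, C = 2), c(A = 1, B = 2, C = 1),
                 c(A = 1, B = 2, C = 2))
  best <- max(vapply(splits, function(g)
    oracle_amova(X, pop, assign = g)$phi_ct, 0))
  expect_equal(out$phi_ct, best, tolerance = 1e-9)
  expect_error(samova_search(co, k = 3), "infeasible")
})

test_that("SAMOVA recovers a planted two-cluster structure", {
  cfg <- sim_config(seed = 21, n_samples = 80,
                    divergence_generations = 800,
                    genealogy_depth_mean = 30, microvariant_rate = 0)
  co <- reduce_for_rst(simulate_two_pop_divergence(cfg))
  # split each diverged population into two labelled subpopulations
  co$data$population <- paste0(co$data$population,
                               rep_len(c("1", "2"), n_samples(co)))
  out <- samova_search(co, k = 2)
  g <- out$grouping
  expect_equal(g[["PopA1"]], g[["PopA2"]])
  expect_equal(g[["PopB1"]], g[["PopB2"]])
  expect_false(g[["PopA1"]] == g[["PopB1"]])
  # identical populations: every partition is equally structureless
  Xn <- rbind(c(10L, 11L), c(11L, 10L))[rep(1:2, 6), ]
  con <- toy_cohort(Xn, pop = rep(c("A", "B", "C"), each = 4))
  outn <- samova_search(con, k = 2)
  expect_lt(abs(outn$phi_ct), 0.35)
})
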