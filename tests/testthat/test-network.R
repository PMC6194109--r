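test_that("variance bins reproduce the published weight table", {
  expect_identical(unname(variance_bin_weight(c(0.1, 0.5, 0.9))),
                   c(10L, 6L, 2L))
  expect_identical(unname(variance_bin_weight(0)), 10L)  # monomorphic
  # half-open boundaries: each boundary value falls in the next bin down
  expect_identical(unname(variance_bin_weight(c(0.2, 0.4, 0.6, 0.8))),
                   c(8L, 6L, 4L, 2L))
  expect_identical(unname(variance_bin_weight(c(0.3, 0.7, 5))),
                   c(8L, 4L, 2L))
  expect_error(variance_bin_weight(-0.1), "non-negative")
})

test_that("locus weights derive from repeat variances, optionally on a subset", {
  X <- rbind(c(10L, 10L), c(10L, 12L), c(10L, 14L), c(10L, 16L))
  co <- toy_cohort(X)
  w <- locus_weights_from_variance(co)
  expect_equal(unname(w$variances), c(0, var(c(10, 12, 14, 16))))
  expect_identical(unname(w$weights), c(10L, 2L))
  w2 <- locus_weights_from_variance(co, subset = c("s001", "s002"))
  expect_equal(unname(w2$variances[2]), 2)
  expect_error(locus_weights_from_variance(co, subset = "nope"),
               "no samples")
})

test_that("identical haplotypes collapse into multiplicity-weighted nodes", {
  haps <- list(base_hap(), base_hap(), base_hap(DYS19 = "17"),
               base_hap(DYS390 = "22"), base_hap(DYS391 = "12"))
  net <- collapse_and_msn(ppy23_cohort(haps))
  expect_equal(nrow(net$nodes), 4)
  expect_equal(sort(net$nodes$multiplicity), c(1L, 1L, 1L, 2L))
  expect_equal(sum(net$nodes$multiplicity), 5)
  expect_false(any(net$nodes$is_median))
  # a duplicate-only cohort is one node, no edges
  net1 <- collapse_and_msn(ppy23_cohort(list(base_hap(), base_hap())))
  expect_equal(nrow(net1$nodes), 1)
  expect_equal(nrow(net1$edges), 0)
})

test_that("the MSN keeps all tied minimum-spanning connections", {
  # three mutually equidistant haplotypes: full triangle, not 2 edges
  X <- rbind(c(0L, 0L), c(2L, 0L), c(1L, 1L))  # pairwise L1 distance 2
  co <- toy_cohort(X)
  net <- mj_network(co, max_medians = 0)
  expect_equal(nrow(net$edges), 3)
})

test_that("MSN edges are exactly the union of all minimum spanning trees", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(5:7, 1)
    X <- matrix(sample(0:3, n * 3, replace = TRUE), n, 3)
    X <- X[!duplicated(X), , drop = FALSE]
    co <- toy_cohort(X)
    net <- mj_network(co, max_medians = 0)
    D <- as.matrix(dist(X, method = "manhattan"))
    trees <- oracle_spanning_trees(D)
    wmin <- min(vapply(trees, `[[`, 0, "weight"))
    msts <- trees[vapply(trees, `[[`, 0, "weight") < wmin + 1e-9]
    in_some_mst <- unique(do.call(rbind, lapply(msts, `[[`, "edges")))
    keys <- apply(X, 1, paste, collapse = "|")
    got <- net$edges
    # same edge set
    expect_equal(nrow(got), nrow(in_some_mst))
    for (e in seq_len(nrow(in_some_mst))) {
      a <- keys[in_some_mst[e, 1]]; b <- keys[in_some_mst[e, 2]]
      expect_true(any((got$from == a & got$to == b) |
                        (got$from == b & got$to == a)))
    }
    # MSN total spanning weight equals the MST weight
    expect_equal(min(vapply(msts, `[[`, 0, "weight")),
                 ystrpop:::mst_total_length(D))
  }
})

test_that("median joining resolves the three-haplotype star", {
  # pairwise L1 distance 2; the consensus point joins all three at cost 3
  X <- rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  co <- toy_cohort(X)
  net <- mj_network(co)
  expect_equal(sum(net$nodes$is_median), 1)
  expect_equal(nrow(net$edges), 3)
  med <- net$nodes$key[net$nodes$is_median]
  expect_identical(med, "0|0|0")
  expect_true(all(net$edges$from == med | net$edges$to == med))
  expect_equal(sum(net$edges$weight), oracle_steiner_length(X))
})

test_that("two haplotypes one step apart join by a single edge", {
  X <- rbind(c(10L, 10L), c(11L, 10L))
  net <- mj_network(toy_cohort(X))
  expect_equal(nrow(net$nodes), 2)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 1)
  expect_false(any(net$nodes$is_median))
})

test_that("median addition preserves observed nodes and shortens the network", {
  set.seed(9)
  for (rep in 1:5) {
    X <- matrix(sample(8:12, 6 * 4, replace = TRUE), 6, 4)
    X <- X[!duplicated(X), , drop = FALSE]
    co <- toy_cohort(X)
    msn <- mj_network(co, max_medians = 0)
    mj <- mj_network(co)
    obs_keys <- msn$nodes$key
    expect_true(all(obs_keys %in% mj$nodes$key))
    len_of <- function(net) {
      keys <- net$nodes$key
      V <- do.call(rbind, lapply(strsplit(keys, "|", fixed = TRUE),
                                 as.numeric))
      ystrpop:::mst_total_length(
        as.matrix(dist(V, method = "manhattan")))
    }
    expect_lte(len_of(mj), len_of(msn) + 1e-9)
  }
})

test_that("weighted distances drive the network geometry", {
  X <- rbind(c(10L, 10L), c(11L, 10L), c(10L, 11L))
  co <- toy_cohort(X)
  w <- setNames(c(10L, 2L), c("L1", "L2"))
  net <- mj_network(co, weights = w, max_medians = 0)
  e <- net$edges
  w12 <- e$weight[(e$from == "10|10" & e$to == "11|10") |
                    (e$from == "11|10" & e$to == "10|10")]
  w13 <- e$weight[(e$from == "10|10" & e$to == "10|11") |
                    (e$from == "10|11" & e$to == "10|10")]
  expect_equal(w12, 10)
  expect_equal(w13, 2)
})

test_that("the haplotype guard and exports work", {
  sim <- simulate_cohort(sim_config(seed = 23, n_samples = 30,
                                    microvariant_rate = 0))
  red <- reduce_for_rst(qc_filter_biallelic(sim$cohort)$cohort)
  expect_error(mj_network(red, max_haplotypes = 5), "guard")
  net <- collapse_and_msn(sim$cohort)
  gml <- withr::local_tempfile(fileext = ".graphml")
  dot <- withr::local_tempfile(fileext = ".dot")
  write_network(net, gml)
  write_network(net, dot, format = "dot")
  expect_true(file.size(gml) > 0)
  expect_true(file.size(dot) > 0)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
})
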