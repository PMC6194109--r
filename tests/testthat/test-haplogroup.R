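# A tiny two-haplogroup model over three loci: haplogroup A modal alleles
# are absent from B and vice versa.
tiny_model <- function(pseudocount = 1e-3) {
  haplogroup_model(list(
    A = list(L1 = c("10" = 0.9, "11" = 0.1),
             L2 = c("20" = 0.8, "21" = 0.2),
             L3 = c("30" = 1.0)),
    B = list(L1 = c("14" = 0.9, "15" = 0.1),
             L2 = c("24" = 0.8, "25" = 0.2),
             L3 = c("34" = 1.0))),
    pseudocount = pseudocount)
}

test_that("an everywhere-modal haplotype is assigned with score 100", {
  call <- predict_haplogroup(c(L1 = "10", L2 = "20", L3 = "30"),
                             tiny_model(), min_loci = 3)
  expect_identical(call$best, "A")
  expect_equal(call$score, 100)
  expect_gt(call$posterior, 0.999)
})

test_that("an uninformative model leaves every haplotype unassigned", {
  flat <- list(L1 = c("10" = 0.5, "11" = 0.5), L2 = c("20" = 1.0))
  model <- haplogroup_model(list(A = flat, B = flat, C = flat))
  call <- predict_haplogroup(c(L1 = "10", L2 = "20"), model, min_loci = 2)
  expect_identical(call$best, "UNASSIGNED")
  expect_equal(call$posterior, 1 / 3, tolerance = 1e-12)
})

test_that("posteriors sum to one and respect prior monotonicity", {
  set.seed(13)
  for (rep in 1:20) {
    freqs <- lapply(1:3, function(g) {
      lapply(setNames(1:4, paste0("L", 1:4)), function(l) {
        p <- runif(3); setNames(p / sum(p), as.character(10:12))
      })
    })
    names(freqs) <- c("A", "B", "C")
    h <- setNames(as.character(sample(10:12, 4, TRUE)), paste0("L", 1:4))
    model <- haplogroup_model(freqs)
    call <- predict_haplogroup(h, model, min_loci = 4)
    expect_equal(sum(call$per_haplogroup$posterior), 1, tolerance = 1e-12)
    # raising B's prior never lowers B's posterior
    up <- haplogroup_model(freqs, priors = c(A = 1, B = 3, C = 1))
    call_up <- predict_haplogroup(h, up, min_loci = 4)
    pb <- call$per_haplogroup$posterior[call$per_haplogroup$haplogroup == "B"]
    pb_up <- call_up$per_haplogroup$posterior[
      call_up$per_haplogroup$haplogroup == "B"]
    expect_gte(pb_up, pb - 1e-12)
  }
})

test_that("classification is invariant to locus ordering", {
  h <- c(L1 = "10", L2 = "21", L3 = "30")
  a <- predict_haplogroup(h, tiny_model(), min_loci = 3)
  b <- predict_haplogroup(h[c(3, 1, 2)], tiny_model(), min_loci = 3)
  expect_identical(a$best, b$best)
  expect_equal(a$score, b$score)
  expect_equal(a$posterior, b$posterior)
})

test_that("insufficient locus overlap is an error", {
  expect_error(predict_haplogroup(c(L1 = "10"), tiny_model(), min_loci = 3),
               "shares only 1")
})

test_that("fitted models smooth unseen alleles and round-trip as JSON", {
  sim <- simulate_cohort(sim_config(seed = 17, n_samples = 200))
  labels <- setNames(sim$truth$haplogroup, sim$truth$sample_id)
  model <- fit_haplogroup_model(sim$cohort, labels)
  for (hg in model$haplogroups) {
    f <- model$freqs[[hg]][["DYS19"]]
    expect_equal(sum(f), 1, tolerance = 1e-12)
    expect_true(all(f > 0))
  }
  path <- withr::local_tempfile(fileext = ".json")
  write_haplogroup_model(model, path)
  back <- read_haplogroup_model(path)
  expect_equal(back$freqs, model$freqs, tolerance = 1e-12)
  expect_equal(back$priors, model$priors)
  h <- sim$cohort$data[1, cohort_loci(sim$cohort)]
  a <- predict_haplogroup(unlist(h), model)
  b <- predict_haplogroup(unlist(h), back)
  expect_equal(a$score, b$score, tolerance = 1e-9)
  expect_identical(a$best, b$best)
})

test_that("batch prediction tallies regions and handles empty cohorts", {
  sim <- simulate_cohort(sim_config(seed = 19, n_samples = 150))
  labels <- setNames(sim$truth$haplogroup, sim$truth$sample_id)
  model <- fit_haplogroup_model(sim$cohort, labels)
  bp <- batch_predict(sim$cohort, model)
  expect_equal(nrow(bp$calls), 150)
  expect_equal(bp$n_assigned + sum(bp$calls$best == "UNASSIGNED"), 150)
  if (length(bp$proportions))
    expect_equal(sum(bp$proportions), 100, tolerance = 1e-9)
  # batch agrees with the single-haplotype path
  h <- unlist(sim$cohort$data[3, cohort_loci(sim$cohort)])
  single <- predict_haplogroup(h, model)
  expect_identical(bp$calls$best[3], single$best)
  expect_equal(bp$calls$score[3], single$score, tolerance = 1e-12)
  empty <- sim$cohort
  empty$data <- empty$data[0, ]
  bp0 <- batch_predict(empty, model)
  expect_equal(bp0$n_total, 0L)
  expect_equal(nrow(bp0$calls), 0)
})
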