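test_that("allele strings round-trip through parse and format", {
  x <- c("14", "13.2", "9", "22.3")
  p <- parse_allele(x)
  expect_identical(p$repeats, c(14L, 13L, 9L, 22L))
  expect_identical(p$partial, c(0L, 2L, 0L, 3L))
  expect_identical(format_allele(p), x)
})

test_that("malformed allele strings are rejected with their text", {
  expect_error(parse_allele("13.20"), "13\\.20")
  expect_error(parse_allele("a"), "unparseable")
  expect_error(parse_allele(""), "unparseable")
  expect_error(parse_allele("13.7"), "unparseable")  # partial must be < 5
})

test_that("DYS385 pairs are canonicalized to ascending order", {
  co <- ppy23_cohort(list(base_hap(DYS385 = "14,11")))
  expect_identical(co$data$DYS385, "11,14")
})

test_that("cohort CSV write/read round-trips exactly", {
  sim <- simulate_cohort(sim_config(seed = 7, n_samples = 40,
                                    microvariant_rate = 0.2,
                                    biallelic_artifact_count = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(sim$cohort, path)
  back <- read_cohort(path)
  expect_equal(back$data, sim$cohort$data)
  expect_equal(back$panel, sim$cohort$panel)
})

test_that("reader rejects degenerate or malformed files", {
  hdr_only <- withr::local_tempfile(fileext = ".csv")
  sim <- simulate_cohort(sim_config(seed = 1, n_samples = 3))
  write_cohort(sim$cohort, hdr_only)
  lines <- readLines(hdr_only)
  writeLines(lines[1], hdr_only)
  expect_error(read_cohort(hdr_only), "empty cohort")
  # a populated file missing a locus column is a format error
  trunc <- withr::local_tempfile(fileext = ".csv")
  tab0 <- read.csv(hdr_only, check.names = FALSE)[, -6]
  full <- read.csv(text = lines, check.names = FALSE,
                   colClasses = "character")
  write.csv(full[, -6], trunc, row.names = FALSE)
  expect_error(read_cohort(trunc), "lacks column")
  # unparseable allele names the sample and locus
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, bad)
  tab <- read.csv(bad, check.names = FALSE, colClasses = "character")
  tab$DYS19[2] <- "xx"
  write.csv(tab, bad, row.names = FALSE)
  err <- tryCatch(read_cohort(bad), error = conditionMessage)
  expect_match(err, "DYS19")
  expect_match(err, tab$SampleID[2], fixed = TRUE)
  expect_error(read_cohort(withr::local_tempfile(fileext = ".csv")),
               "no such file")
})

test_that("biallelic QC removes exactly the artifact samples", {
  sim <- simulate_cohort(sim_config(seed = 11, n_samples = 407,
                                    biallelic_artifact_count = 4))
  qc <- qc_filter_biallelic(sim$cohort)
  expect_equal(n_samples(qc$cohort), 403)
  expect_setequal(qc$discarded,
                  sim$truth$sample_id[sim$truth$biallelic])
  expect_equal(n_samples(qc$cohort) + length(qc$discarded),
               n_samples(sim$cohort))
  # idempotent
  again <- qc_filter_biallelic(qc$cohort)
  expect_equal(again$cohort$data, qc$cohort$data)
  expect_length(again$discarded, 0)
})

test_that("the DYS385 pair never triggers biallelic removal", {
  co <- ppy23_cohort(list(base_hap(DYS385 = "11,14"), base_hap()))
  qc <- qc_filter_biallelic(co)
  expect_equal(n_samples(qc$cohort), 2)
  co2 <- ppy23_cohort(list(base_hap(DYS19 = "14,15"), base_hap()))
  qc2 <- qc_filter_biallelic(co2)
  expect_equal(n_samples(qc2$cohort), 1)
  expect_equal(qc2$discarded, "s001")
})

test_that("reduction drops DYS385 and microvariant carriers", {
  haps <- list(base_hap(), base_hap(DYS458 = "16.2"), base_hap(),
               base_hap(DYS448 = "19.2"), base_hap())
  co <- ppy23_cohort(haps)
  red <- reduce_for_rst(co)
  expect_false("DYS385" %in% cohort_loci(red))
  expect_equal(ncol(repeat_matrix(red)), 21)
  expect_equal(n_samples(red), 3)
  expect_setequal(attr(red, "discarded"), c("s002", "s004"))
  expect_equal(n_samples(red) + length(attr(red, "discarded")),
               n_samples(co))
  # a microvariant only at the dropped DYS385 does not cost the sample
  co385 <- ppy23_cohort(list(base_hap(DYS385 = "11.2,14"), base_hap()))
  expect_equal(n_samples(reduce_for_rst(co385)), 2)
  # degenerate: everyone carries a microvariant
  all_mv <- ppy23_cohort(list(base_hap(DYS458 = "16.2"),
                              base_hap(DYS570 = "17.2")))
  expect_warning(red2 <- reduce_for_rst(all_mv), "empty")
  expect_equal(n_samples(red2), 0)
})
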