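#' Default sampling locations: 12 populations in 4 regions of India
#'
#' State-level sampling design emulating a pan-Indian survey: 12
#' populations (state codes) spread over the North, South, East and West
#' geographic regions, with approximate state-centroid coordinates.
#'
#' @return data frame with columns `population`, `region`, `lat`, `lon`,
#'   `weight` (equal sampling weights).
#' @export
default_populations <- function() {
  data.frame(
    population = c("UP", "RJ", "PB", "KA", "TN", "TS",
                   "MH", "GJ", "WB", "JH", "OD", "BR"),
    region = c("North", "North", "North", "South", "South", "South",
               "West", "West", "East", "East", "East", "East"),
    lat = c(26.85, 26.91, 31.15, 15.32, 11.13, 17.92,
            19.75, 22.31, 22.99, 23.61, 20.94, 25.60),
    lon = c(80.95, 75.79, 75.34, 75.71, 78.66, 79.59,
            75.71, 71.69, 87.85, 85.28, 85.10, 85.32),
    weight = rep(1, 12))
}

#' Default founder haplotypes per haplogroup
#'
#' Modal 22-locus haplotypes for the six simulated haplogroups. They are
#' synthetic: a realistic PPY23 base profile offset by distinct small
#' repeat shifts at several loci per haplogroup, so that haplogroups are
#' separable by allele frequencies, as real Y lineages are.
#'
#' @return named list of founder haplotypes; each is a list mapping locus
#'   to an integer repeat count (length-2 vector for DYS385).
#' @export
default_founders <- function() {
  base <- list(DYS19 = 15L, DYS389I = 13L, DYS389II = 29L, DYS390 = 24L,
               DYS391 = 10L, DYS392 = 11L, DYS393 = 12L, DYS437 = 14L,
               DYS438 = 10L, DYS439 = 11L, DYS448 = 19L, DYS456 = 15L,
               DYS458 = 16L, DYS481 = 22L, DYS533 = 11L, DYS549 = 12L,
               DYS570 = 17L, DYS576 = 18L, DYS635 = 23L, DYS643 = 10L,
               YGATAH4 = 12L, DYS385 = c(11L, 14L))
  shift <- function(...) {
    h <- base
    for (s in list(...)) h[[s[[1]]]] <- h[[s[[1]]]] + as.integer(s[[2]])
    h
  }
  list(
    R1a = shift(list("DYS19", 1), list("DYS390", 1), list("DYS391", 1),
                list("DYS392", -1), list("DYS448", 1), list("DYS458", -1),
                list("DYS481", 3), list("DYS635", 0), list("DYS385", c(0, 0))),
    H   = shift(list("DYS19", 0), list("DYS389I", 1), list("DYS390", -1),
                list("DYS437", 1), list("DYS438", -1), list("DYS456", 1),
                list("DYS570", 1), list("DYS643", 1)),
    L   = shift(list("DYS19", -1), list("DYS389II", 1), list("DYS392", 3),
                list("DYS393", 1), list("DYS439", 1), list("DYS533", 1),
                list("DYS576", -1), list("DYS635", -2)),
    J2  = shift(list("DYS19", -1), list("DYS390", -1), list("DYS391", -1),
                list("DYS437", 1), list("DYS448", 1), list("DYS458", 2),
                list("DYS481", -2), list("DYS549", 1)),
    Q   = shift(list("DYS19", -2), list("DYS389I", -1), list("DYS392", 3),
                list("DYS438", 1), list("DYS439", -1), list("DYS456", -1),
                list("DYS570", -2), list("DYS635", 2)),
    G   = shift(list("DYS19", 0), list("DYS389II", -1), list("DYS390", -2),
                list("DYS391", 1), list("DYS393", 2), list("DYS533", -1),
                list("DYS549", -1), list("DYS643", -2)))
}

#' Simulation configuration
#'
#' Bundles and validates every parameter of the forward stepwise-mutation
#' simulator. Defaults emulate a 407-sample pan-Indian PPY23 survey:
#' haplogroup mix dominated by R1a (51.5%), H (16.2%) and L (15.8%)
#' (remainder J2/Q/G), 12 populations in 4 regions, exponential genealogy
#' depth of mean 150 generations (a late-Holocene expansion scale at
#' which nearly all 23-locus haplotypes are unique), per-locus mutation
#' rates from the panel (2e-3, rapidly mutating loci 1e-2), a 2% chance
#' per sample of carrying one microvariant allele, and no biallelic
#' artifacts unless requested.
#'
#' @param seed integer RNG seed (mandatory).
#' @param n_samples cohort size.
#' @param haplogroup_mix named proportions summing to 1 (names must match
#'   `founders`).
#' @param founders named list of founder haplotypes (see
#'   [default_founders()]).
#' @param panel a [ystr_panel()]; locus set must match the founders.
#' @param genealogy_depth_mean mean coalescent depth, generations.
#' @param populations data frame as [default_populations()].
#' @param divergence_generations two-population mode divergence time.
#' @param microvariant_rate per-sample probability of one microvariant.
#' @param biallelic_artifact_count exact number of samples given a second
#'   allele at one single-copy locus.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_samples = 407,
                       haplogroup_mix = c(R1a = 0.515, H = 0.162, L = 0.158,
                                          J2 = 0.085, Q = 0.05, G = 0.03),
                       founders = default_founders(),
                       panel = ppy23_panel(),
                       genealogy_depth_mean = 150,
                       populations = default_populations(),
                       divergence_generations = 0,
                       microvariant_rate = 0.02,
                       biallelic_artifact_count = 0) {
  if (missing(seed) || !is.numeric(seed))
    stop("seed is mandatory", call. = FALSE)
  if (n_samples < 1) stop("n_samples must be positive", call. = FALSE)
  if (abs(sum(haplogroup_mix) - 1) > 1e-8)
    stop("haplogroup_mix proportions must sum to 1", call. = FALSE)
  if (!all(names(haplogroup_mix) %in% names(founders)))
    stop("haplogroup_mix names missing from founders: ",
         paste(setdiff(names(haplogroup_mix), names(founders)),
               collapse = ", "), call. = FALSE)
  for (hg in names(founders)) {
    missing_loci <- setdiff(panel$name, names(founders[[hg]]))
    if (length(missing_loci))
      stop("founder ", hg, " lacks loci: ",
           paste(missing_loci, collapse = ", "), call. = FALSE)
  }
  if (genealogy_depth_mean <= 0)
    stop("genealogy_depth_mean must be positive", call. = FALSE)
  if (microvariant_rate < 0 || microvariant_rate > 1)
    stop("microvariant_rate must lie in [0, 1]", call. = FALSE)
  if (biallelic_artifact_count < 0 ||
      biallelic_artifact_count > n_samples)
    stop("biallelic_artifact_count must lie in [0, n_samples]",
         call. = FALSE)
  if (divergence_generations < 0)
    stop("divergence_generations must be >= 0", call. = FALSE)
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 haplogroup_mix = haplogroup_mix, founders = founders,
                 panel = panel,
                 genealogy_depth_mean = genealogy_depth_mean,
                 populations = populations,
                 divergence_generations = divergence_generations,
                 microvariant_rate = microvariant_rate,
                 biallelic_artifact_count =
                   as.integer(biallelic_artifact_count)),
            class = "sim_config")
}

# Net repeat displacement after Poisson(lambda) symmetric +/-1 steps.
smm_steps <- function(lambda) {
  k <- stats::rpois(length(lambda), lambda)
  2L * stats::rbinom(length(k), k, 0.5) - k
}

#' Simulate a Y-STR cohort under the stepwise mutation model
#'
#' Forward star-like genealogy: each sample draws a haplogroup from the
#' configured mix, a genealogy depth from an exponential distribution,
#' and mutates each locus of its founder haplotype by a Poisson
#' (depth x rate) number of symmetric single-repeat steps. Samples are
#' assigned to populations by weight (independently of haplotype, so the
#' default cohort carries no population structure); microvariants and
#' exactly `biallelic_artifact_count` two-allele artifacts are injected
#' afterwards. Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `cohort` (a `ystr_cohort`) and `truth` (data frame:
#'   `sample_id`, `haplogroup`, `depth`, `microvariant`, `biallelic`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  panel <- config$panel
  mix <- config$haplogroup_mix
  hg <- sample(names(mix), n, replace = TRUE, prob = mix)
  depth <- stats::rexp(n, rate = 1 / config$genealogy_depth_mean)
  pops <- config$populations
  pop_idx <- sample(nrow(pops), n, replace = TRUE, prob = pops$weight)
  cols <- list(sample_id = sprintf("S%04d", seq_len(n)),
               population = pops$population[pop_idx],
               region = pops$region[pop_idx],
               lat = pops$lat[pop_idx], lon = pops$lon[pop_idx])
  sc <- single_copy_loci(panel)
  rate <- stats::setNames(panel$mutation_rate, panel$name)
  for (loc in panel$name) {
    founder_alleles <- vapply(config$founders[hg],
                              function(f) f[[loc]][1], 0L)
    if (panel$copy_number[panel$name == loc] == 2L) {
      f2 <- vapply(config$founders[hg], function(f) f[[loc]][2], 0L)
      a <- pmax(founder_alleles + smm_steps(depth * rate[loc]), 1L)
      b <- pmax(f2 + smm_steps(depth * rate[loc]), 1L)
      lo <- pmin(a, b); hi <- pmax(a, b)
      cols[[loc]] <- paste(lo, hi, sep = ",")
    } else {
      cols[[loc]] <- as.character(
        pmax(founder_alleles + smm_steps(depth * rate[loc]), 1L))
    }
  }
  # microvariants: with prob microvariant_rate a sample gains a ".2"
  # partial repeat at one random single-copy locus
  mv <- stats::runif(n) < config$microvariant_rate
  mv_locus <- sample(sc, n, replace = TRUE)
  for (i in which(mv)) {
    loc <- mv_locus[i]
    cols[[loc]][i] <- paste0(cols[[loc]][i], ".2")
  }
  # biallelic artifacts: exactly the requested number of samples get a
  # second allele (one repeat longer) at one random single-copy locus
  ba <- rep(FALSE, n)
  if (config$biallelic_artifact_count > 0) {
    pick <- sample(n, config$biallelic_artifact_count)
    ba[pick] <- TRUE
    ba_locus <- sample(sc, length(pick), replace = TRUE)
    for (j in seq_along(pick)) {
      i <- pick[j]; loc <- ba_locus[j]
      first <- strsplit(cols[[loc]][i], ".", fixed = TRUE)[[1]][1]
      cols[[loc]][i] <- paste0(cols[[loc]][i], ",",
                               as.integer(first) + 1L)
    }
  }
  cohort <- ystr_cohort(as.data.frame(cols, check.names = FALSE), panel)
  truth <- data.frame(sample_id = cols$sample_id, haplogroup = hg,
                      depth = depth, microvariant = mv, biallelic = ba)
  list(cohort = cohort, truth = truth)
}

#' Simulate two populations diverging from one founder
#'
#' Supports structure-recovery tests: a single founder haplotype evolves
#' independently along two population stems for
#' `divergence_generations`, then each population's samples radiate from
#' their stem haplotype with the configured within-population depth.
#' Expected Phi_ST grows with divergence time and is ~0 at divergence 0.
#' No microvariants or artifacts are injected, so the cohort is already
#' reduced apart from the DYS385a/b drop.
#'
#' @param config a [sim_config()]; `n_samples` is split equally between
#'   the populations `PopA` (region A) and `PopB` (region B).
#' @return A `ystr_cohort`.
#' @export
simulate_two_pop_divergence <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  panel <- config$panel
  founder <- config$founders[[1]]
  rate <- stats::setNames(panel$mutation_rate, panel$name)
  gens <- config$divergence_generations
  stems <- lapply(1:2, function(p) {
    h <- founder
    for (loc in panel$name)
      h[[loc]] <- pmax(h[[loc]] + smm_steps(rep(gens * rate[loc],
                                                length(h[[loc]]))), 1L)
    h
  })
  n <- config$n_samples
  n1 <- n %/% 2L; n2 <- n - n1
  pop <- rep(c("PopA", "PopB"), c(n1, n2))
  depth <- stats::rexp(n, rate = 1 / config$genealogy_depth_mean)
  cols <- list(sample_id = sprintf("S%04d", seq_len(n)),
               population = pop,
               region = rep(c("A", "B"), c(n1, n2)),
               lat = rep(c(20, 25), c(n1, n2)),
               lon = rep(c(75, 85), c(n1, n2)))
  stem_idx <- rep(1:2, c(n1, n2))
  for (loc in panel$name) {
    base <- vapply(stems, function(s) s[[loc]][1], 0L)[stem_idx]
    if (panel$copy_number[panel$name == loc] == 2L) {
      base2 <- vapply(stems, function(s) s[[loc]][2], 0L)[stem_idx]
      a <- pmax(base + smm_steps(depth * rate[loc]), 1L)
      b <- pmax(base2 + smm_steps(depth * rate[loc]), 1L)
      cols[[loc]] <- paste(pmin(a, b), pmax(a, b), sep = ",")
    } else {
      cols[[loc]] <- as.character(pmax(base + smm_steps(depth * rate[loc]),
                                       1L))
    }
  }
  ystr_cohort(as.data.frame(cols, check.names = FALSE), panel)
}
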