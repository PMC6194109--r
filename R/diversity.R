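#' Frequency spectra and forensic summary statistics
#'
#' @description
#' The diversity statistics of a Y-STR survey are all functions of a
#' frequency spectrum: a set of category labels (alleles at one locus, or
#' whole haplotypes) with their observed counts. [freq_spectrum()] builds
#' one from a named count vector; [allele_spectrum()] and
#' [haplotype_spectrum()] derive them from a cohort.
#'
#' @param counts named integer vector of positive counts.
#' @return An object of class `freq_spectrum` with fields `labels`,
#'   `counts` and `n`.
#' @export
freq_spectrum <- function(counts) {
  counts <- counts[order(names(counts))]
  if (any(counts <= 0)) stop("counts must be positive", call. = FALSE)
  structure(list(labels = names(counts),
                 counts = as.integer(counts),
                 n = sum(as.integer(counts))),
            class = "freq_spectrum")
}

#' @export
print.freq_spectrum <- function(x, ...) {
  cat("Frequency spectrum: ", length(x$counts), " categories, n = ", x$n,
      "\n", sep = "")
  invisible(x)
}

spectrum_freqs <- function(spectrum) spectrum$counts / spectrum$n

#' Allele frequency spectrum at one locus
#'
#' Counts every allele observation at the locus by the counting method. For
#' the duplicated DYS385a/b locus both alleles of each pair are counted, so
#' `n` is twice the number of samples there.
#'
#' @param cohort a `ystr_cohort`.
#' @param locus locus name present in the cohort's panel.
#' @return A `freq_spectrum` of allele strings.
#' @export
allele_spectrum <- function(cohort, locus) {
  if (!locus %in% cohort_loci(cohort))
    stop("unknown locus: ", locus, call. = FALSE)
  if (n_samples(cohort) == 0L) stop("empty cohort", call. = FALSE)
  alleles <- unlist(strsplit(cohort$data[[locus]], ",", fixed = TRUE))
  freq_spectrum(table(alleles))
}

#' Haplotype frequency spectrum
#'
#' The haplotype key is the full canonical profile across all panel loci
#' (DYS385a/b as its sorted pair, microvariants included): forensic
#' statistics always use the complete marker set.
#'
#' @param cohort a QC-filtered `ystr_cohort`.
#' @return A `freq_spectrum` keyed by haplotype strings.
#' @export
haplotype_spectrum <- function(cohort) {
  keys <- haplotype_keys(cohort)
  freq_spectrum(table(keys))
}

haplotype_keys <- function(cohort) {
  do.call(paste, c(unname(cohort$data[cohort_loci(cohort)]), sep = "|"))
}

#' Genetic diversity of a locus
#'
#' The unbiased gene-diversity analogue
#' \deqn{GD = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)}
#' where \eqn{p_i} is the frequency of the i-th allele and n the number of
#' allele observations. Zero for a monomorphic locus, exactly 1 when every
#' observation is distinct.
#'
#' @param spectrum a `freq_spectrum` (see [allele_spectrum()]); `n >= 2`.
#' @return GD in `[0, 1]`.
#' @export
locus_gd <- function(spectrum) {
  n <- as.numeric(spectrum$n)
  if (n < 2) stop("GD requires n >= 2", call. = FALSE)
  # n/(n-1) * (1 - Sum p^2) evaluated on integer count sums, so the
  # monomorphic (0) and all-distinct (1) endpoints are exact
  S <- sum(as.numeric(spectrum$counts)^2)
  (n * n - S) / (n * n - n)
}

#' Haplotype diversity
#'
#' The same estimator as [locus_gd()] applied to whole-haplotype
#' frequencies: \eqn{HD = n/(n-1)\,(1 - \sum_i h_i^2)}.
#'
#' @param spectrum a haplotype `freq_spectrum`; `n >= 2`.
#' @return HD in `[0, 1]`; exactly 1 when all haplotypes are unique.
#' @export
haplotype_diversity <- function(spectrum) locus_gd(spectrum)

#' Discrimination capacity
#'
#' The ratio of the number of distinct haplotypes to the total number of
#' haplotypes sampled.
#'
#' @param spectrum a haplotype `freq_spectrum`.
#' @return DC in `(0, 1]`.
#' @export
discrimination_capacity <- function(spectrum) {
  length(spectrum$counts) / spectrum$n
}

#' Combined match probability
#'
#' The sum of squared haplotype frequencies \eqn{\sum_i h_i^2}: the
#' probability that two males drawn at random from the sample share a full
#' haplotype. Bounded below by 1/n.
#'
#' @param spectrum a haplotype `freq_spectrum`.
#' @return CMP in `(0, 1]`.
#' @export
combined_match_probability <- function(spectrum) {
  n <- as.numeric(spectrum$n)
  sum(as.numeric(spectrum$counts)^2) / (n * n)
}

#' Forensic summary of a cohort
#'
#' Computes HD, DC and CMP on the full-panel haplotype spectrum. The
#' algebraic identity `hd == n/(n-1) * (1 - cmp)` holds to machine
#' precision because all three are computed from the same spectrum.
#'
#' @param cohort a QC-filtered `ystr_cohort`.
#' @return An object of class `forensic_summary` with fields `hd`, `dc`,
#'   `cmp`, `n`, `n_distinct`.
#' @export
forensic_summary <- function(cohort) {
  sp <- haplotype_spectrum(cohort)
  structure(list(hd = haplotype_diversity(sp),
                 dc = discrimination_capacity(sp),
                 cmp = combined_match_probability(sp),
                 n = sp$n,
                 n_distinct = length(sp$counts)),
            class = "forensic_summary")
}

#' @export
print.forensic_summary <- function(x, digits = 10, ...) {
  cat("Forensic summary (n = ", x$n, ", distinct haplotypes = ",
      x$n_distinct, ")\n", sep = "")
  cat("  haplotype diversity (HD):      ", format(x$hd, digits = digits), "\n")
  cat("  discrimination capacity (DC):  ", format(x$dc, digits = digits), "\n")
  cat("  combined match prob. (CMP):    ", format(x$cmp, digits = digits), "\n")
  invisible(x)
}

#' Per-population, per-locus genetic diversity table
#'
#' Applies [locus_gd()] within each population. A population with fewer
#' than two allele observations at a locus cannot support the unbiased
#' estimator; it is kept in the table as `NA` and listed in the
#' `"flagged"` attribute rather than silently dropped.
#'
#' @param cohort a `ystr_cohort`.
#' @return A populations x loci numeric matrix of GD values with attribute
#'   `"flagged"`.
#' @export
per_population_gd_table <- function(cohort) {
  pops <- sort(unique(cohort$data$population))
  loci <- cohort_loci(cohort)
  out <- matrix(NA_real_, length(pops), length(loci),
                dimnames = list(pops, loci))
  flagged <- character(0)
  for (p in pops) {
    sub <- cohort
    sub$data <- cohort$data[cohort$data$population == p, , drop = FALSE]
    for (loc in loci) {
      sp <- allele_spectrum(sub, loc)
      if (sp$n < 2L) {
        flagged <- c(flagged, paste0(p, ":", loc))
      } else {
        out[p, loc] <- locus_gd(sp)
      }
    }
  }
  attr(out, "flagged") <- flagged
  out
}
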