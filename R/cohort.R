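#' Construct a Y-STR cohort
#'
#' A cohort bundles a marker panel with a sample table: one row per genotyped
#' male carrying a sample identifier, population and geographic-region
#' labels, sampling coordinates, and one character column per locus holding
#' canonical allele strings. Multi-allele cells are comma-separated; the
#' duplicated DYS385a/b locus always holds an unordered pair, stored sorted
#' ascending. A single-copy locus with more than one allele marks a biallelic
#' (multi-peak) artifact, retained until [qc_filter_biallelic()].
#'
#' @param data data frame with columns `sample_id`, `population`, `region`,
#'   `lat`, `lon`, then one column per panel locus.
#' @param panel a [ystr_panel()].
#' @return An object of class `ystr_cohort`.
#' @export
ystr_cohort <- function(data, panel = ppy23_panel()) {
  meta <- c("sample_id", "population", "region", "lat", "lon")
  missing_meta <- setdiff(meta, names(data))
  if (length(missing_meta))
    stop("missing column(s): ", paste(missing_meta, collapse = ", "), call. = FALSE)
  missing_loci <- setdiff(panel$name, names(data))
  if (length(missing_loci))
    stop("missing locus column(s): ", paste(missing_loci, collapse = ", "),
         call. = FALSE)
  data <- data[, c(meta, panel$name)]
  data$sample_id <- as.character(data$sample_id)
  data$population <- as.character(data$population)
  data$region <- as.character(data$region)
  data$lat <- as.numeric(data$lat)
  data$lon <- as.numeric(data$lon)
  if (anyDuplicated(data$sample_id))
    stop("sample_id values must be unique", call. = FALSE)
  for (loc in panel$name) {
    cells <- as.character(data[[loc]])
    canon <- tryCatch(canonicalize_cells(cells), error = function(e) e)
    if (inherits(canon, "error")) {
      bad <- which(vapply(cells, function(cell) {
        inherits(tryCatch(split_calls(cell), error = function(e) e), "error")
      }, TRUE))[1]
      stop("sample ", sQuote(data$sample_id[bad]), ", locus ", loc, ": ",
           conditionMessage(canon), call. = FALSE)
    }
    if (loc %in% multi_copy_loci(panel) && any(n_calls(canon) != 2L)) {
      bad <- which(n_calls(canon) != 2L)[1]
      stop("sample ", sQuote(data$sample_id[bad]), ": locus ", loc,
           " must hold an allele pair \"a,b\"", call. = FALSE)
    }
    data[[loc]] <- canon
  }
  rownames(data) <- NULL
  structure(list(panel = panel, data = data), class = "ystr_cohort")
}

#' @export
print.ystr_cohort <- function(x, ...) {
  cat("Y-STR cohort: ", nrow(x$data), " samples, ",
      nrow(x$panel), " loci (", sum(x$panel$copy_number), " markers), ",
      length(unique(x$data$population)), " populations in ",
      length(unique(x$data$region)), " regions\n", sep = "")
  invisible(x)
}

n_samples <- function(cohort) nrow(cohort$data)

cohort_loci <- function(cohort) cohort$panel$name

#' Read a cohort from a CSV haplotype table
#'
#' Expects a comma-separated, UTF-8 file with a header row naming the
#' columns `SampleID, Population, Region, Lat, Lon` followed by one column
#' per panel locus. DYS385a/b is encoded as a quoted pair `"11,14"`;
#' microvariants as dotted alleles (`13.2`). A blank or unparseable call is
#' an error naming the sample, locus and line; missing data are not modeled.
#'
#' @param path file path.
#' @param panel a [ystr_panel()]; defaults to [ppy23_panel()].
#' @return A `ystr_cohort`.
#' @export
read_cohort <- function(path, panel = ppy23_panel()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  if (nrow(raw) == 0L) stop("empty cohort file: ", path, call. = FALSE)
  hdr <- c(SampleID = "sample_id", Population = "population",
           Region = "region", Lat = "lat", Lon = "lon")
  missing_cols <- setdiff(c(names(hdr), panel$name), names(raw))
  if (length(missing_cols))
    stop("file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  names(raw)[match(names(hdr), names(raw))] <- hdr
  out <- tryCatch(ystr_cohort(raw, panel), error = function(e) e)
  if (inherits(out, "error"))
    stop("while reading ", path, ": ", conditionMessage(out), call. = FALSE)
  out
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: the written file round-trips to an identical
#' cohort. Allele pairs are quoted (`"11,14"`) and microvariants keep their
#' dotted form.
#'
#' @param cohort a `ystr_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  d <- cohort$data
  names(d)[1:5] <- c("SampleID", "Population", "Region", "Lat", "Lon")
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Remove samples with biallelic artifacts at single-copy loci
#'
#' A single-copy Y-STR showing two peaks in one male is a genotyping
#' artifact (or a duplication); such samples are discarded before any
#' statistics are computed. The duplicated DYS385a/b locus legitimately
#' carries two alleles and never triggers removal.
#'
#' @param cohort a `ystr_cohort`.
#' @return A list with elements `cohort` (retained samples) and `discarded`
#'   (character vector of removed sample ids).
#' @export
qc_filter_biallelic <- function(cohort) {
  sc <- single_copy_loci(cohort$panel)
  flag <- rep(FALSE, n_samples(cohort))
  for (loc in sc) flag <- flag | n_calls(cohort$data[[loc]]) > 1L
  discarded <- cohort$data$sample_id[flag]
  cohort$data <- cohort$data[!flag, , drop = FALSE]
  rownames(cohort$data) <- NULL
  list(cohort = cohort, discarded = discarded)
}

#' Reduce a cohort for repeat-difference distance analyses
#'
#' R_ST-style distances compare integer repeat counts locus by locus, so the
#' unordered DYS385a/b pair is dropped from the panel and every sample still
#' carrying a microvariant (partial-repeat) allele at a retained locus is
#' removed. The ids of removed samples are attached as attribute
#' `"discarded"`.
#'
#' @param cohort a QC-filtered `ystr_cohort`.
#' @return A `ystr_cohort` on the reduced panel.
#' @export
reduce_for_rst <- function(cohort) {
  keep_loci <- single_copy_loci(cohort$panel)
  drop_loci <- multi_copy_loci(cohort$panel)
  panel <- cohort$panel[cohort$panel$name %in% keep_loci, , drop = FALSE]
  rownames(panel) <- NULL
  data <- cohort$data[, c("sample_id", "population", "region", "lat", "lon",
                          keep_loci)]
  mv <- rep(FALSE, nrow(data))
  for (loc in keep_loci) mv <- mv | has_microvariant(data[[loc]])
  discarded <- data$sample_id[mv]
  data <- data[!mv, , drop = FALSE]
  rownames(data) <- NULL
  if (nrow(data) == 0L)
    warning("all samples carried microvariants; reduced cohort is empty")
  out <- structure(list(panel = panel, data = data), class = "ystr_cohort")
  attr(out, "discarded") <- discarded
  attr(out, "dropped_loci") <- drop_loci
  out
}

# Integer repeat-count matrix (samples x loci) for a reduced cohort.
# Errors if the cohort still contains pairs or microvariants.
repeat_matrix <- function(cohort) {
  loci <- cohort_loci(cohort)
  if (length(multi_copy_loci(cohort$panel)))
    stop("cohort must be reduced (reduce_for_rst) before distance analyses",
         call. = FALSE)
  n <- n_samples(cohort)
  X <- matrix(0L, n, length(loci), dimnames = list(cohort$data$sample_id, loci))
  for (j in seq_along(loci)) {
    cells <- cohort$data[[loci[j]]]
    if (any(n_calls(cells) > 1L))
      stop("biallelic call at single-copy locus ", loci[j],
           "; run qc_filter_biallelic first", call. = FALSE)
    p <- parse_allele(cells)
    if (any(p$partial > 0))
      stop("microvariant alleles present at ", loci[j],
           "; run reduce_for_rst first", call. = FALSE)
    X[, j] <- p$repeats
  }
  X
}
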