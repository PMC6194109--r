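#' Parse Y-STR allele strings
#'
#' Y-STR alleles are named by repeat count, with microvariants (partial
#' repeats) written as a dotted suffix, e.g. `"13.2"` for 13 full repeats plus
#' 2 bases of a partial repeat. Alleles are held as an integer pair
#' (`repeats`, `partial`) rather than as floating point, so that haplotype
#' identity is exact.
#'
#' @param x character vector of allele strings (e.g. `"14"`, `"13.2"`).
#' @return A data frame with integer columns `repeats` and `partial`
#'   (`partial == 0` for full repeats), one row per element of `x`.
#' @examples
#' parse_allele(c("14", "13.2"))
#' @export
parse_allele <- function(x) {
  x <- trimws(as.character(x))
  m <- regmatches(x, regexec("^([0-9]+)(\\.([1-4]))?$", x))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("unparseable allele string(s): ",
         paste(sQuote(unique(x[bad])), collapse = ", "),
         " (expected e.g. \"14\" or \"13.2\" with partial digit 1-4)",
         call. = FALSE)
  }
  repeats <- as.integer(vapply(m, `[`, "", 2L))
  partial <- vapply(m, `[`, "", 4L)
  partial <- ifelse(partial == "", 0L, as.integer(partial))
  data.frame(repeats = repeats, partial = as.integer(partial))
}

#' Format alleles back to their canonical string form
#'
#' Inverse of [parse_allele()]: `format_allele(parse_allele(x))` reproduces
#' `x` exactly for canonical input.
#'
#' @param repeats integer vector of repeat counts, or a data frame as
#'   returned by [parse_allele()].
#' @param partial integer vector of partial-repeat bases (0 for full repeats).
#' @return character vector of canonical allele strings.
#' @export
format_allele <- function(repeats, partial = 0L) {
  if (is.data.frame(repeats)) {
    partial <- repeats$partial
    repeats <- repeats$repeats
  }
  ifelse(partial > 0, paste0(repeats, ".", partial), as.character(repeats))
}

# Numeric ordering value for an allele string; partial repeats sort between
# integer alleles (13 < 13.2 < 14). Used for canonical sorting and for
# full-panel network distances, never for haplotype identity.
allele_value <- function(x) {
  p <- parse_allele(x)
  p$repeats + p$partial / 10
}

# Split a multi-allele cell ("11,14") into canonical ascending order and
# reformat each allele. Returns a character vector of alleles.
split_calls <- function(cell) {
  a <- trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
  a <- a[nzchar(a)]
  if (length(a) == 0L) stop("blank allele call", call. = FALSE)
  a <- format_allele(parse_allele(a))
  a[order(allele_value(a))]
}

# Canonicalize a whole column of cells; returns character vector.
# Single-allele cells take a vectorized fast path.
canonicalize_cells <- function(cells) {
  out <- as.character(cells)
  multi <- grepl(",", out, fixed = TRUE)
  if (any(!multi))
    out[!multi] <- format_allele(parse_allele(out[!multi]))
  if (any(multi))
    out[multi] <- vapply(out[multi], function(cell)
      paste(split_calls(cell), collapse = ","), "", USE.NAMES = FALSE)
  out
}

# Number of alleles in each cell of a column.
n_calls <- function(cells) {
  lengths(regmatches(cells, gregexpr(",", cells, fixed = TRUE))) + 1L
}

# TRUE for cells containing any microvariant allele.
has_microvariant <- function(cells) {
  grepl(".", cells, fixed = TRUE)
}
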