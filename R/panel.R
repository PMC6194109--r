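#' Define a Y-STR marker panel
#'
#' A panel is a table of loci with their copy number (1 for ordinary Y-STRs,
#' 2 for the duplicated DYS385a/b locus, which is reported as an unordered
#' allele pair) and a per-generation mutation rate used only by the
#' simulator.
#'
#' @param name character vector of locus names (unique).
#' @param copy_number integer vector, 1 or 2 per locus.
#' @param mutation_rate numeric vector of per-generation single-step mutation
#'   rates (simulator only).
#' @return A data frame of class `ystr_panel`.
#' @seealso [ppy23_panel()]
#' @export
ystr_panel <- function(name, copy_number = 1L, mutation_rate = 2e-3) {
  name <- as.character(name)
  if (anyDuplicated(name)) stop("panel locus names must be unique", call. = FALSE)
  copy_number <- as.integer(rep_len(copy_number, length(name)))
  if (!all(copy_number %in% c(1L, 2L)))
    stop("copy_number must be 1 or 2", call. = FALSE)
  mutation_rate <- rep_len(as.numeric(mutation_rate), length(name))
  if (any(mutation_rate < 0 | mutation_rate >= 0.05))
    stop("mutation_rate must lie in [0, 0.05)", call. = FALSE)
  structure(
    data.frame(name = name, copy_number = copy_number,
               mutation_rate = mutation_rate),
    class = c("ystr_panel", "data.frame"))
}

#' The 23-marker PowerPlex Y23 panel
#'
#' The standard PPY23 multiplex: 21 single-copy Y-STRs plus the duplicated
#' DYS385a/b locus (22 named loci, 23 markers). DYS570 and DYS576 are the
#' rapidly mutating loci of the system and carry a higher default simulator
#' mutation rate (1e-2 vs 2e-3 per generation).
#'
#' @return A `ystr_panel` data frame with 22 rows.
#' @export
ppy23_panel <- function() {
  loci <- c("DYS19", "DYS389I", "DYS389II", "DYS390", "DYS391", "DYS392",
            "DYS393", "DYS437", "DYS438", "DYS439", "DYS448", "DYS456",
            "DYS458", "DYS481", "DYS533", "DYS549", "DYS570", "DYS576",
            "DYS635", "DYS643", "YGATAH4", "DYS385")
  cn <- ifelse(loci == "DYS385", 2L, 1L)
  mu <- ifelse(loci %in% c("DYS570", "DYS576"), 1e-2, 2e-3)
  ystr_panel(loci, cn, mu)
}

single_copy_loci <- function(panel) panel$name[panel$copy_number == 1L]
multi_copy_loci  <- function(panel) panel$name[panel$copy_number == 2L]
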