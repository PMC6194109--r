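# Small-cohort builders used across the suite.

toy_panel <- function(n_loci, copy_number = 1L) {
  ystr_panel(paste0("L", seq_len(n_loci)), copy_number)
}

# Build a reduced-style cohort (single-copy loci, integer alleles) from an
# integer matrix X (samples x loci) and a population vector.
toy_cohort <- function(X, pop = rep("P1", nrow(X)),
                       region = rep("R1", nrow(X)),
                       lat = 0, lon = 0) {
  panel <- toy_panel(ncol(X))
  d <- data.frame(sample_id = sprintf("s%03d", seq_len(nrow(X))),
                  population = pop, region = region, lat = lat, lon = lon)
  for (j in seq_len(ncol(X))) d[[paste0("L", j)]] <- as.character(X[, j])
  ystr_cohort(d, panel)
}

# A cohort on the full PPY23 panel built from a list of named haplotypes
# (character cells, DYS385 as "a,b").
ppy23_cohort <- function(haps, pop = rep("P1", length(haps)),
                         region = rep("R1", length(haps))) {
  panel <- ppy23_panel()
  d <- data.frame(sample_id = sprintf("s%03d", seq_along(haps)),
                  population = pop, region = region, lat = 0, lon = 0)
  for (loc in panel$name)
    d[[loc]] <- vapply(haps, function(h) h[[loc]], "")
  ystr_cohort(d, panel)
}

# One fully specified base haplotype for PPY23 fixtures.
base_hap <- function(...) {
  h <- lapply(default_founders()$R1a, function(a) paste(a, collapse = ","))
  mods <- list(...)
  for (loc in names(mods)) h[[loc]] <- mods[[loc]]
  h
}
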