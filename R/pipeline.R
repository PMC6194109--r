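#' Run the full Y-STR analysis pipeline
#'
#' Orchestrates the standard analysis sequence on a cohort (read from CSV
#' or simulated): QC filtering, diversity tables and forensic summary,
#' panel reduction, AMOVA and pairwise R_ST, SAMOVA grouping search,
#' Nei distance with PCoA, Sammon MDS, the Mantel test of geography
#' against genetics, haplogroup prediction, and the MSN / median-joining
#' networks. Each stage writes its artifact into `out_dir` and logs one
#' line; a stage failure aborts with the stage name while earlier outputs
#' are preserved. Every stochastic stage takes its seed from
#' `config$seed`, so a rerun with the same config reproduces all outputs
#' exactly.
#'
#' @param config a list with elements: one of `input` (cohort CSV path) or
#'   `sim` (a [sim_config()]); `out_dir`; optional `stages` (subset of
#'   `c("diversity", "structure", "ordination", "haplogroup", "network")`,
#'   default all); `permutations` (default 199); `seed` (default the sim
#'   seed, mandatory otherwise); `min_score` (40), `min_prob` (0.95);
#'   `samova_k` (default the number of regions); `model` (a
#'   `haplogroup_model`; default fitted from simulation truth labels when
#'   available, else the stage is skipped).
#' @param quiet suppress per-stage log lines.
#' @return A summary list (also written as `summary.json`), invisibly.
#' @export
run_ystr_pipeline <- function(config, quiet = FALSE) {
  stages_all <- c("diversity", "structure", "ordination", "haplogroup",
                  "network")
  stages <- if (is.null(config$stages)) stages_all else
    match.arg(config$stages, stages_all, several.ok = TRUE)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  permutations <- if (is.null(config$permutations)) 199 else
    config$permutations
  log_line <- function(...) if (!quiet) message("[ystrpop] ", ...)
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("stage ", sQuote(name), " failed: ", conditionMessage(e),
           call. = FALSE))
    log_line("stage ", name, " done")
    res
  }
  summary <- list()

  # ---- input ----
  truth <- NULL
  if (!is.null(config$sim)) {
    sim <- run_stage("simulate", simulate_cohort(config$sim))
    cohort <- sim$cohort
    truth <- sim$truth
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
    seed <- if (is.null(config$seed)) config$sim$seed else config$seed
  } else if (!is.null(config$input)) {
    cohort <- run_stage("read", read_cohort(config$input))
    seed <- config$seed
    if (is.null(seed) && permutations > 0)
      stop("config$seed is required when permutations > 0", call. = FALSE)
  } else stop("config must provide either $input or $sim", call. = FALSE)
  summary$n_input <- n_samples(cohort)

  # ---- QC ----
  qc <- run_stage("qc_filter", qc_filter_biallelic(cohort))
  cohort <- qc$cohort
  writeLines(qc$discarded, file.path(out_dir, "qc_discarded.txt"))
  summary$n_retained <- n_samples(cohort)
  summary$n_discarded_biallelic <- length(qc$discarded)
  log_line(summary$n_retained, " of ", summary$n_input,
           " samples retained after biallelic QC")

  # ---- diversity ----
  if ("diversity" %in% stages) {
    run_stage("diversity", {
      gd <- vapply(cohort_loci(cohort), function(loc)
        locus_gd(allele_spectrum(cohort, loc)), 0)
      utils::write.csv(data.frame(locus = names(gd), gd = gd),
                       file.path(out_dir, "gd_by_locus.csv"),
                       row.names = FALSE)
      tab <- per_population_gd_table(cohort)
      utils::write.csv(as.data.frame(tab),
                       file.path(out_dir, "gd_by_population.csv"))
      fs <- forensic_summary(cohort)
      jsonlite::write_json(unclass(fs),
                           file.path(out_dir, "forensic_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      summary$forensic <- unclass(fs)
    })
  }

  # ---- reduction ----
  reduced <- run_stage("reduce_for_rst", reduce_for_rst(cohort))
  summary$n_reduced <- n_samples(reduced)
  summary$n_discarded_microvariant <- length(attr(reduced, "discarded"))

  # ---- structure ----
  if ("structure" %in% stages) {
    run_stage("structure", {
      fit <- amova(reduced, permutations = permutations, seed = seed)
      jsonlite::write_json(
        list(ss = as.list(fit$ss), df = as.list(fit$df),
             sigma2 = as.list(fit$sigma2), phi = as.list(fit$phi),
             variance_pct = as.list(fit$variance_pct),
             p_values = as.list(fit$p_values),
             n_permutations = fit$n_permutations),
        file.path(out_dir, "amova.json"), auto_unbox = TRUE, digits = NA)
      summary$phi_st_global <- fit$phi[["phi_st"]]
      summary$pct_within_populations <-
        unname(fit$variance_pct[["within"]])
      pw <- pairwise_rst(reduced, permutations = permutations,
                         seed = seed + 1000L)
      utils::write.csv(as.data.frame(pw$rst),
                       file.path(out_dir, "pairwise_rst.csv"))
      utils::write.csv(as.data.frame(pw$p),
                       file.path(out_dir, "pairwise_rst_p.csv"))
      summary$mean_pairwise_rst <-
        mean(pw$rst[upper.tri(pw$rst)])
      regions <- unique(reduced$data[, c("population", "region")])
      k <- if (is.null(config$samova_k))
        length(unique(regions$region)) else config$samova_k
      if (k >= 2 && k < length(unique(regions$population))) {
        sam <- samova_search(reduced, k = k, seed = seed + 2000L)
        jsonlite::write_json(
          list(grouping = as.list(sam$grouping), phi_ct = sam$phi_ct,
               method = sam$method),
          file.path(out_dir, "samova.json"), auto_unbox = TRUE,
          digits = NA)
        summary$samova_phi_ct <- sam$phi_ct
      }
    })
  }

  # ---- ordination + geography ----
  if ("ordination" %in% stages) {
    run_stage("ordination", {
      nei <- nei_distance(cohort)
      utils::write.csv(as.data.frame(nei), file.path(out_dir, "nei.csv"))
      ord <- pcoa(nei, k = 2)
      utils::write.csv(as.data.frame(ord$points),
                       file.path(out_dir, "pcoa.csv"))
      jsonlite::write_json(list(explained_pct = ord$explained),
                           file.path(out_dir, "pcoa_explained.json"),
                           digits = NA)
      summary$pcoa_explained_pct <- ord$explained
      pw <- pairwise_rst(reduced, clamp = TRUE)
      if (any(pw$rst[upper.tri(pw$rst)] <= 0)) {
        # Sammon needs strictly positive dissimilarities
        eps <- 1e-6
        pw$rst[pw$rst <= 0] <- eps
        diag(pw$rst) <- 0
      }
      mds <- sammon_mds(pw$rst, k = 2)
      utils::write.csv(as.data.frame(mds$points),
                       file.path(out_dir, "mds.csv"))
      geo <- geo_distance_matrix(cohort)
      gen <- pairwise_rst(reduced)$rst
      gen <- gen[rownames(geo), rownames(geo)]
      mt <- mantel_test(geo, gen, permutations = permutations,
                        seed = seed + 3000L)
      jsonlite::write_json(
        list(correlation = mt$correlation, r_squared = mt$r_squared,
             p_value = mt$p_value, permutations = mt$permutations,
             method = mt$method),
        file.path(out_dir, "mantel.json"), auto_unbox = TRUE, digits = NA)
      summary$mantel <- list(correlation = mt$correlation,
                              r_squared = mt$r_squared,
                              p_value = mt$p_value)
    })
  }

  # ---- haplogroup ----
  if ("haplogroup" %in% stages) {
    model <- config$model
    if (is.null(model) && !is.null(truth)) {
      labels <- stats::setNames(truth$haplogroup, truth$sample_id)
      model <- fit_haplogroup_model(cohort, labels)
    }
    if (is.null(model)) {
      log_line("stage haplogroup skipped: no model and no truth labels")
    } else {
      run_stage("haplogroup", {
        min_score <- if (is.null(config$min_score)) 40 else config$min_score
        min_prob <- if (is.null(config$min_prob)) 0.95 else config$min_prob
        bp <- batch_predict(cohort, model, min_score = min_score,
                            min_prob = min_prob)
        utils::write.csv(bp$calls,
                         file.path(out_dir, "haplogroup_calls.csv"),
                         row.names = FALSE)
        utils::write.csv(as.data.frame(bp$by_region),
                         file.path(out_dir, "haplogroup_by_region.csv"),
                         row.names = FALSE)
        summary$haplogroup <- list(
          n_assigned = bp$n_assigned, n_total = bp$n_total,
          proportions_pct = as.list(bp$proportions))
      })
    }
  }

  # ---- networks ----
  if ("network" %in% stages) {
    run_stage("network", {
      msn <- collapse_and_msn(cohort)
      write_network(msn, file.path(out_dir, "msn.graphml"))
      summary$msn <- list(n_nodes = nrow(msn$nodes),
                           n_edges = nrow(msn$edges))
      # MJ per major haplogroup when truth labels exist and the subset is
      # small enough; otherwise on the reduced cohort if it fits the guard
      w <- locus_weights_from_variance(reduced)
      utils::write.csv(data.frame(locus = names(w$weights),
                                  variance = w$variances,
                                  weight = w$weights),
                       file.path(out_dir, "locus_weights.csv"),
                       row.names = FALSE)
      mj_subset <- NULL
      if (!is.null(truth)) {
        major <- names(which.max(table(truth$haplogroup)))
        ids <- truth$sample_id[truth$haplogroup == major]
        sub <- reduced
        sub$data <- sub$data[sub$data$sample_id %in% ids, , drop = FALSE]
        if (n_samples(sub) > 0) mj_subset <- list(name = major, cohort = sub)
      }
      if (!is.null(mj_subset) &&
          length(unique(haplotype_keys(mj_subset$cohort))) <= 200) {
        mj <- mj_network(mj_subset$cohort, weights = w)
        write_network(mj, file.path(out_dir, paste0(
          "mj_", mj_subset$name, ".graphml")))
        summary$mj <- list(haplogroup = mj_subset$name,
                            n_nodes = nrow(mj$nodes),
                            n_median = sum(mj$nodes$is_median),
                            n_edges = nrow(mj$edges))
      }
    })
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line("pipeline complete; outputs in ", out_dir)
  invisible(summary)
}
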