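#' Construct an allele-frequency haplogroup model
#'
#' A naive-Bayes model over per-locus allele frequencies: for each
#' haplogroup and locus, the frequency of each allele string, plus a prior
#' over haplogroups and a pseudocount for alleles never observed in a
#' haplogroup. Frequencies at each locus are smoothed at fit time over the
#' union of alleles seen in any haplogroup, so each per-locus vector sums
#' to 1. For the duplicated DYS385a/b locus single-allele frequencies are
#' stored and a pair's likelihood is the product of its two allele
#' frequencies.
#'
#' @param freqs nested list: `freqs[[haplogroup]][[locus]]` = named numeric
#'   vector of allele frequencies.
#' @param priors named numeric vector over haplogroups (normalized
#'   internally); default uniform.
#' @param pseudocount floor frequency for alleles absent from a
#'   haplogroup's table (default `1e-3`).
#' @return An object of class `haplogroup_model`.
#' @export
haplogroup_model <- function(freqs, priors = NULL, pseudocount = 1e-3) {
  hgs <- names(freqs)
  if (is.null(hgs) || length(hgs) < 2)
    stop("need named frequency tables for >= 2 haplogroups", call. = FALSE)
  if (is.null(priors)) priors <- stats::setNames(rep(1, length(hgs)), hgs)
  priors <- priors[hgs] / sum(priors[hgs])
  loci <- Reduce(union, lapply(freqs, names))
  structure(list(haplogroups = hgs, loci = loci, freqs = freqs,
                 priors = priors, pseudocount = pseudocount),
            class = "haplogroup_model")
}

#' @export
print.haplogroup_model <- function(x, ...) {
  cat("Haplogroup frequency model: ", length(x$haplogroups),
      " haplogroups (", paste(x$haplogroups, collapse = ", "), "), ",
      length(x$loci), " loci, pseudocount ", x$pseudocount, "\n", sep = "")
  invisible(x)
}

#' Fit a haplogroup model from labeled training haplotypes
#'
#' Counts allele frequencies per haplogroup and locus from a cohort with
#' known (e.g. simulated) haplogroup labels, smoothing with `pseudocount`
#' over the union of alleles observed at each locus across all
#' haplogroups.
#'
#' @param cohort a `ystr_cohort`.
#' @param labels character vector of haplogroup labels, either named by
#'   sample id or aligned with the cohort rows.
#' @param pseudocount smoothing mass per unseen allele.
#' @param priors optional haplogroup priors (default uniform).
#' @return A `haplogroup_model`.
#' @export
fit_haplogroup_model <- function(cohort, labels, pseudocount = 1e-3,
                                 priors = NULL) {
  if (!is.null(names(labels)))
    labels <- labels[cohort$data$sample_id]
  if (length(labels) != n_samples(cohort))
    stop("labels must cover every sample", call. = FALSE)
  loci <- cohort_loci(cohort)
  hgs <- sort(unique(labels))
  # union of alleles per locus across the whole cohort
  union_alleles <- lapply(loci, function(loc)
    sort(unique(unlist(strsplit(cohort$data[[loc]], ",", fixed = TRUE)))))
  names(union_alleles) <- loci
  freqs <- lapply(hgs, function(hg) {
    rows <- which(labels == hg)
    out <- lapply(loci, function(loc) {
      obs <- unlist(strsplit(cohort$data[[loc]][rows], ",", fixed = TRUE))
      alleles <- union_alleles[[loc]]
      cnt <- stats::setNames(rep(0, length(alleles)), alleles)
      tb <- table(obs)
      cnt[names(tb)] <- tb
      (cnt + pseudocount) / (sum(cnt) + pseudocount * length(cnt))
    })
    names(out) <- loci
    out
  })
  names(freqs) <- hgs
  haplogroup_model(freqs, priors = priors, pseudocount = pseudocount)
}

# Per-sample per-haplogroup log-likelihood and per-locus modal log-freq,
# vectorized over samples. cells: list locus -> character vector of cells.
hg_loglik_matrix <- function(cells, model) {
  loci <- names(cells)
  n <- length(cells[[1]])
  G <- length(model$haplogroups)
  loglik <- matrix(0, n, G, dimnames = list(NULL, model$haplogroups))
  logmax <- matrix(0, n, G, dimnames = list(NULL, model$haplogroups))
  for (g in model$haplogroups) {
    for (loc in loci) {
      f <- model$freqs[[g]][[loc]]
      fmax <- max(f)
      cell <- cells[[loc]]
      multi <- grepl(",", cell, fixed = TRUE)
      if (any(multi)) {
        ll <- numeric(length(cell))
        lm <- numeric(length(cell))
        for (i in seq_along(cell)) {
          a <- strsplit(cell[i], ",", fixed = TRUE)[[1]]
          fa <- f[a]; fa[is.na(fa)] <- model$pseudocount
          ll[i] <- sum(log(fa))
          lm[i] <- length(a) * log(fmax)
        }
      } else {
        fa <- f[cell]
        fa[is.na(fa)] <- model$pseudocount
        ll <- log(fa)
        lm <- rep(log(fmax), length(cell))
      }
      loglik[, g] <- loglik[, g] + ll
      logmax[, g] <- logmax[, g] + lm
    }
  }
  list(loglik = loglik, logmax = logmax, n_loci = length(loci))
}

#' Predict the haplogroup of a single haplotype
#'
#' Naive-Bayes posterior over haplogroups with the assignment contract of
#' STR-based haplogroup predictors: the call is the maximum-posterior
#' haplogroup, reported as `UNASSIGNED` unless both the fitness score and
#' the posterior reach their thresholds. The score is the per-locus-
#' normalized geometric-mean fitness of the best haplogroup,
#' \deqn{score = 100\left(\prod_l \frac{f_{g,l}(a_l)}
#'   {\max_a f_{g,l}(a)}\right)^{1/L}}
#' so a haplotype modal at every locus scores 100.
#'
#' @param h named character vector (or one-row cohort) of allele strings
#'   per locus; DYS385a/b as `"a,b"`.
#' @param model a `haplogroup_model`.
#' @param min_score minimum score for assignment (default 40).
#' @param min_prob minimum posterior for assignment (default 0.95).
#' @param min_loci minimum locus overlap with the model (default 15).
#' @return An object of class `haplogroup_call`: fields `best`, `score`,
#'   `posterior`, `per_haplogroup` (data frame of log-likelihoods and
#'   posteriors).
#' @export
predict_haplogroup <- function(h, model, min_score = 40, min_prob = 0.95,
                               min_loci = 15) {
  loci <- intersect(names(h), model$loci)
  if (length(loci) < min_loci)
    stop("haplotype shares only ", length(loci), " loci with the model ",
         "(minimum ", min_loci, ")", call. = FALSE)
  cells <- lapply(loci, function(loc) as.character(h[[loc]]))
  names(cells) <- loci
  mats <- hg_loglik_matrix(cells, model)
  call_from_loglik(mats$loglik[1, ], mats$logmax[1, ], mats$n_loci, model,
                   min_score, min_prob)
}

call_from_loglik <- function(loglik, logmax, n_loci, model,
                             min_score, min_prob) {
  logpost <- loglik + log(model$priors[names(loglik)])
  logpost <- logpost - max(logpost)
  post <- exp(logpost) / sum(exp(logpost))
  best <- names(which.max(post))
  score <- 100 * exp((loglik[[best]] - logmax[[best]]) / n_loci)
  assigned <- score >= min_score && post[[best]] >= min_prob
  structure(list(best = if (assigned) best else "UNASSIGNED",
                 top = best,
                 score = unname(score), posterior = unname(post[[best]]),
                 per_haplogroup = data.frame(haplogroup = names(post),
                                             loglik = unname(loglik),
                                             posterior = unname(post))),
            class = "haplogroup_call")
}

#' @export
print.haplogroup_call <- function(x, ...) {
  cat("Haplogroup call: ", x$best,
      if (x$best == "UNASSIGNED") paste0(" (top: ", x$top, ")") else "",
      "  score = ", round(x$score, 1),
      "  posterior = ", format(x$posterior, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Predict haplogroups for a whole cohort
#'
#' Applies [predict_haplogroup()] to every sample and tabulates counts and
#' percentages of assigned haplogroups per geographic region and overall,
#' with the assigned/unassigned tally.
#'
#' @param cohort a `ystr_cohort`.
#' @param model a `haplogroup_model`.
#' @inheritParams predict_haplogroup
#' @return An object of class `haplogroup_batch`: `calls` (data frame of
#'   per-sample calls), `by_region` (counts), `proportions` (percent of
#'   assigned samples per haplogroup, overall), `n_assigned`, `n_total`.
#' @export
batch_predict <- function(cohort, model, min_score = 40, min_prob = 0.95,
                          min_loci = 15) {
  if (n_samples(cohort) == 0L) {
    return(structure(list(
      calls = data.frame(sample_id = character(), region = character(),
                         best = character(), score = numeric(),
                         posterior = numeric()),
      by_region = table(character(), character()),
      proportions = numeric(0), n_assigned = 0L, n_total = 0L),
      class = "haplogroup_batch"))
  }
  loci <- intersect(cohort_loci(cohort), model$loci)
  if (length(loci) < min_loci)
    stop("cohort shares only ", length(loci), " loci with the model ",
         "(minimum ", min_loci, ")", call. = FALSE)
  cells <- lapply(loci, function(loc) cohort$data[[loc]])
  names(cells) <- loci
  mats <- hg_loglik_matrix(cells, model)
  n <- n_samples(cohort)
  best <- character(n); score <- numeric(n); post_best <- numeric(n)
  logprior <- log(model$priors[colnames(mats$loglik)])
  for (i in seq_len(n)) {
    lp <- mats$loglik[i, ] + logprior
    lp <- lp - max(lp)
    post <- exp(lp) / sum(exp(lp))
    b <- names(which.max(post))
    s <- 100 * exp((mats$loglik[i, b] - mats$logmax[i, b]) / mats$n_loci)
    assigned <- s >= min_score && post[[b]] >= min_prob
    best[i] <- if (assigned) b else "UNASSIGNED"
    score[i] <- s; post_best[i] <- post[[b]]
  }
  calls <- data.frame(sample_id = cohort$data$sample_id,
                      population = cohort$data$population,
                      region = cohort$data$region,
                      best = best, score = score, posterior = post_best)
  assigned <- calls[calls$best != "UNASSIGNED", ]
  by_region <- table(assigned$region, assigned$best)
  proportions <- if (nrow(assigned)) {
    100 * table(assigned$best) / nrow(assigned)
  } else numeric(0)
  structure(list(calls = calls, by_region = by_region,
                 proportions = c(proportions),
                 n_assigned = nrow(assigned), n_total = n),
            class = "haplogroup_batch")
}

#' @export
print.haplogroup_batch <- function(x, ...) {
  cat("Haplogroup predictions: ", x$n_assigned, " of ", x$n_total,
      " samples assigned\n", sep = "")
  if (length(x$proportions)) {
    cat("Overall proportions among assigned (%):\n")
    print(round(sort(x$proportions, decreasing = TRUE), 1))
  }
  invisible(x)
}

#' Serialize a haplogroup model to JSON
#' @param model a `haplogroup_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_haplogroup_model <- function(model, path) {
  freqs <- lapply(model$freqs, function(hg) lapply(hg, as.list))
  jsonlite::write_json(list(haplogroups = model$haplogroups,
                            priors = as.list(model$priors),
                            pseudocount = model$pseudocount,
                            freqs = freqs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a haplogroup model from JSON
#' @param path JSON file written by [write_haplogroup_model()].
#' @return A `haplogroup_model`.
#' @export
read_haplogroup_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  freqs <- lapply(raw$freqs, function(hg) lapply(hg, unlist))
  haplogroup_model(freqs, priors = unlist(raw$priors),
                   pseudocount = raw$pseudocount)
}
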