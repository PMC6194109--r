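#' Variance-binned locus weights for network construction
#'
#' Median-joining networks down-weight fast-evolving loci: each locus gets
#' an integer weight inversely related to its observed repeat-count
#' variance, binned as variance `[0, 0.2) -> 10`, `[0.2, 0.4) -> 8`,
#' `[0.4, 0.6) -> 6`, `[0.6, 0.8) -> 4`, `>= 0.8 -> 2`. Bins are half-open
#' on the left, so a variance of exactly 0.2 falls in the weight-8 bin.
#' By default the variance is computed over the whole cohort; pass
#' `subset` (sample ids) to compute it within one haplogroup instead.
#'
#' @param cohort a reduced `ystr_cohort`.
#' @param subset optional character vector of sample ids.
#' @return An object of class `locus_weights`: named integer `weights` and
#'   numeric `variances`.
#' @export
locus_weights_from_variance <- function(cohort, subset = NULL) {
  if (!is.null(subset)) {
    keep <- cohort$data$sample_id %in% subset
    if (!any(keep)) stop("subset matches no samples", call. = FALSE)
    cohort$data <- cohort$data[keep, , drop = FALSE]
  }
  X <- repeat_matrix(cohort)
  variances <- apply(X, 2, stats::var)
  structure(list(weights = variance_bin_weight(variances),
                 variances = variances),
            class = "locus_weights")
}

#' Map repeat-count variances to network weights
#'
#' The pure binning function behind [locus_weights_from_variance()].
#'
#' @param v numeric vector of variances (>= 0).
#' @return Integer weights in `{2, 4, 6, 8, 10}` (named as `v`).
#' @export
variance_bin_weight <- function(v) {
  if (any(v < 0)) stop("variance must be non-negative", call. = FALSE)
  w <- ifelse(v < 0.2, 10L,
       ifelse(v < 0.4, 8L,
       ifelse(v < 0.6, 6L,
       ifelse(v < 0.8, 4L, 2L))))
  stats::setNames(as.integer(w), names(v))
}

#' @export
print.locus_weights <- function(x, ...) {
  print(data.frame(variance = round(x$variances, 3), weight = x$weights))
  invisible(x)
}

haplotype_network <- function(keys, multiplicity, is_median, pop_counts,
                              edges, epsilon) {
  nodes <- data.frame(key = keys, multiplicity = as.integer(multiplicity),
                      is_median = is_median)
  structure(list(nodes = nodes, pop_counts = pop_counts, edges = edges,
                 epsilon = epsilon),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("Haplotype network: ", nrow(x$nodes), " nodes (",
      sum(x$nodes$is_median), " median), ", nrow(x$edges), " edges, ",
      "total weighted length ", signif(sum(x$edges$weight), 6), "\n",
      sep = "")
  invisible(x)
}

# Edges of the epsilon-relaxed minimum spanning network: an edge (i, j) of
# weight w is included iff i and j are disconnected in the graph of all
# edges with weight < w - epsilon. For epsilon = 0 this is exactly the
# union of all minimum spanning trees.
msn_edge_table <- function(D, epsilon = 0) {
  n <- nrow(D)
  if (n < 2) return(data.frame(from = integer(), to = integer(),
                               weight = numeric()))
  Dr <- round(D, 9)
  ij <- which(upper.tri(Dr), arr.ind = TRUE)
  w <- Dr[ij]
  out_from <- integer(); out_to <- integer(); out_w <- numeric()
  for (wk in sort(unique(w))) {
    adj <- Dr < wk - epsilon - 1e-9
    diag(adj) <- FALSE
    comp <- connected_components(adj)
    sel <- which(abs(w - wk) < 1e-12)
    for (s in sel) {
      i <- ij[s, 1]; j <- ij[s, 2]
      if (comp[i] != comp[j]) {
        out_from <- c(out_from, i); out_to <- c(out_to, j)
        out_w <- c(out_w, wk)
      }
    }
  }
  data.frame(from = out_from, to = out_to, weight = out_w)
}

# Connected components of a logical adjacency matrix (BFS).
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Prim minimum-spanning-tree total length of a full distance matrix.
mst_total_length <- function(D) {
  n <- nrow(D)
  if (n < 2) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  dmin <- D[1, ]
  total <- 0
  for (k in 2:n) {
    cand <- which(!in_tree)
    i <- cand[which.min(dmin[cand])]
    total <- total + dmin[i]
    in_tree[i] <- TRUE
    dmin <- pmin(dmin, D[i, ])
  }
  unname(total)
}

# Population counts per distinct haplotype key.
node_pop_counts <- function(keys_per_sample, populations, keys) {
  tb <- table(factor(keys_per_sample, levels = keys), populations)
  m <- matrix(tb, nrow = length(keys),
              dimnames = list(keys, colnames(tb)))
  m
}

#' Collapse identical haplotypes and build the minimum spanning network
#'
#' Identical full-panel haplotypes are collapsed to one node sized by
#' multiplicity (with a per-population breakdown); the network is the
#' union of all minimum spanning trees over the collapsed haplotypes, so
#' tied alternative connections are all retained. Distances sum absolute
#' repeat differences per locus; the unordered DYS385a/b pair contributes
#' the minimum over pairings (attained by aligning the sorted pairs), and
#' microvariant partial repeats count as fractional (0.1 per base) steps.
#'
#' @param cohort a QC-filtered `ystr_cohort` (full panel).
#' @return A `haplotype_network` (no median nodes).
#' @export
collapse_and_msn <- function(cohort) {
  if (n_samples(cohort) == 0L) stop("empty cohort", call. = FALSE)
  keys <- haplotype_keys(cohort)
  ukeys <- sort(unique(keys))
  V <- expanded_value_matrix(cohort)[match(ukeys, keys), , drop = FALSE]
  D <- as.matrix(stats::dist(V, method = "manhattan"))
  edges <- msn_edge_table(D, epsilon = 0)
  haplotype_network(
    keys = ukeys,
    multiplicity = as.integer(table(factor(keys, levels = ukeys))),
    is_median = rep(FALSE, length(ukeys)),
    pop_counts = node_pop_counts(keys, cohort$data$population, ukeys),
    edges = data.frame(from = ukeys[edges$from], to = ukeys[edges$to],
                       weight = edges$weight),
    epsilon = 0)
}

# Numeric value matrix with one column per single-copy locus and two
# columns for each duplicated locus (sorted pair), for Manhattan distances.
expanded_value_matrix <- function(cohort) {
  cols <- list()
  for (loc in cohort_loci(cohort)) {
    cells <- cohort$data[[loc]]
    nc <- n_calls(cells)
    if (loc %in% multi_copy_loci(cohort$panel)) {
      parts <- strsplit(cells, ",", fixed = TRUE)
      cols[[paste0(loc, "_a")]] <- allele_value(vapply(parts, `[`, "", 1L))
      cols[[paste0(loc, "_b")]] <- allele_value(vapply(parts, `[`, "", 2L))
    } else {
      if (any(nc > 1L))
        stop("biallelic call at ", loc, "; run qc_filter_biallelic first",
             call. = FALSE)
      cols[[loc]] <- allele_value(cells)
    }
  }
  do.call(cbind, cols)
}

#' Median-joining haplotype network
#'
#' Builds a median-joining network on a reduced cohort (integer repeat
#' counts only): starting from the distinct observed haplotypes, candidate
#' median (consensus) haplotypes — the per-locus medians of triplets
#' linked in the epsilon-relaxed minimum spanning network — are added
#' greedily whenever they strictly shorten the network's minimum spanning
#' length (lexicographic tie-break, deterministic), then median nodes
#' whose removal leaves the spanning length unchanged are pruned, and the
#' final network is the epsilon-relaxed MSN over the surviving nodes.
#' Distances are weight-multiplied absolute repeat differences summed
#' over loci. All observed haplotypes remain nodes; median nodes carry
#' multiplicity 0.
#'
#' @param cohort a reduced `ystr_cohort` (see [reduce_for_rst()]).
#' @param weights a `locus_weights` object or named weight vector
#'   (default: weight 1 everywhere).
#' @param epsilon relaxation of the candidate-link criterion (default 0).
#' @param max_haplotypes guard on the number of distinct input haplotypes.
#' @param max_medians cap on generated median nodes.
#' @return A `haplotype_network`.
#' @export
mj_network <- function(cohort, weights = NULL, epsilon = 0,
                       max_haplotypes = 200, max_medians = 500) {
  if (n_samples(cohort) == 0L) stop("empty cohort", call. = FALSE)
  X <- repeat_matrix(cohort)
  keys <- apply(X, 1, paste, collapse = "|")
  ukeys <- sort(unique(keys))
  if (length(ukeys) > max_haplotypes)
    stop(length(ukeys), " distinct haplotypes exceed the guard of ",
         max_haplotypes, "; subset the cohort (e.g. one haplogroup) or ",
         "raise max_haplotypes", call. = FALSE)
  V <- X[match(ukeys, keys), , drop = FALSE]
  if (is.null(weights)) {
    w <- stats::setNames(rep(1, ncol(V)), colnames(V))
  } else {
    w <- if (inherits(weights, "locus_weights")) weights$weights else weights
    if (!all(colnames(V) %in% names(w)))
      stop("weights missing for some loci", call. = FALSE)
    w <- w[colnames(V)]
  }
  Vs <- sweep(V, 2, w, "*")  # weighted L1 == Manhattan on scaled columns
  is_median <- rep(FALSE, nrow(V))
  row_key <- function(m) paste(m, collapse = "|")
  n_added <- 0L
  repeat {
    D <- as.matrix(stats::dist(Vs, method = "manhattan"))
    base_len <- mst_total_length(D)
    edges <- msn_edge_table(D, epsilon = epsilon)
    cand <- median_candidates(V, edges)
    cand <- cand[!(names(cand) %in% apply(V, 1, row_key))]
    if (length(cand) == 0L || n_added >= max_medians) break
    cand <- cand[order(names(cand))]  # deterministic lexicographic order
    lens <- vapply(cand, function(m) {
      ms <- m * w
      dnew <- colSums(abs(t(Vs) - ms))
      Dn <- rbind(cbind(D, dnew), c(dnew, 0))
      mst_total_length(Dn)
    }, 0)
    if (min(lens) >= base_len - 1e-9) break
    pick <- which.min(lens)  # which.min takes the first (lex) minimum
    V <- rbind(V, cand[[pick]])
    Vs <- rbind(Vs, cand[[pick]] * w)
    is_median <- c(is_median, TRUE)
    n_added <- n_added + 1L
  }
  # prune median nodes that no longer shorten the spanning length
  repeat {
    D <- as.matrix(stats::dist(Vs, method = "manhattan"))
    base_len <- mst_total_length(D)
    med_idx <- which(is_median)
    removed <- FALSE
    for (i in med_idx) {
      if (mst_total_length(D[-i, -i, drop = FALSE]) <= base_len + 1e-9) {
        V <- V[-i, , drop = FALSE]; Vs <- Vs[-i, , drop = FALSE]
        is_median <- is_median[-i]
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  D <- as.matrix(stats::dist(Vs, method = "manhattan"))
  edges <- msn_edge_table(D, epsilon = epsilon)
  final_keys <- apply(V, 1, row_key)
  mult <- integer(length(final_keys))
  obs <- table(factor(keys, levels = final_keys))
  mult[!is_median] <- as.integer(obs[!is_median])
  haplotype_network(
    keys = final_keys, multiplicity = mult, is_median = is_median,
    pop_counts = node_pop_counts(keys, cohort$data$population, final_keys),
    edges = data.frame(from = final_keys[edges$from],
                       to = final_keys[edges$to], weight = edges$weight),
    epsilon = epsilon)
}

# Per-locus medians of all triplets (u, v, w) with u-v and u-w candidate
# links. Returns a named list of integer vectors keyed by haplotype key.
median_candidates <- function(V, edges) {
  out <- list()
  if (nrow(edges) < 2) return(out)
  nbrs <- split(c(edges$to, edges$from), c(edges$from, edges$to))
  for (u in as.integer(names(nbrs))) {
    nb <- unique(nbrs[[as.character(u)]])
    if (length(nb) < 2) next
    pairs <- utils::combn(nb, 2)
    for (p in seq_len(ncol(pairs))) {
      trip <- V[c(u, pairs[1, p], pairs[2, p]), , drop = FALSE]
      med <- as.integer(apply(trip, 2, stats::median))
      names(med) <- colnames(V)
      out[[paste(med, collapse = "|")]] <- med
    }
  }
  out
}

as_igraph_network <- function(network) {
  g <- igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = data.frame(name = network$nodes$key,
                          multiplicity = network$nodes$multiplicity,
                          is_median = as.integer(network$nodes$is_median)))
  pc <- network$pop_counts
  for (p in colnames(pc))
    g <- igraph::set_vertex_attr(g, paste0("n_", p),
                                 value = pc[network$nodes$key, p])
  g
}

#' Export a haplotype network to GraphML or DOT
#'
#' Node attributes: `multiplicity`, `is_median` and one `n_<population>`
#' count per population; edge attribute: `weight` (weighted distance).
#'
#' @param network a `haplotype_network`.
#' @param path output file.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(as_igraph_network(network), path, format = format)
  invisible(path)
}
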