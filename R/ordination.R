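as_distance_matrix <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm) || any(abs(dm - t(dm)) > 1e-10) ||
      any(diag(dm) != 0))
    stop("not a symmetric zero-diagonal distance matrix", call. = FALSE)
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <- seq_len(nrow(dm))
  dm
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Embeds a distance matrix by eigendecomposition of the double-centered
#' Gram matrix. Explained percentages are shares of the positive
#' eigenvalues only; negative eigenvalues (non-Euclidean input) are
#' excluded from the denominator, with a warning when the most negative
#' exceeds 5% of the largest in magnitude.
#'
#' @param dm symmetric distance matrix (labeled).
#' @param k number of output dimensions (must not exceed the number of
#'   positive eigenvalues).
#' @return An object of class `ordination` with fields `points`
#'   (labels x k), `explained` (percentages, non-increasing), `eig`,
#'   `method = "pcoa"`.
#' @export
pcoa <- function(dm, k = 2) {
  dm <- as_distance_matrix(dm)
  fit <- stats::cmdscale(stats::as.dist(dm), k = min(k, nrow(dm) - 1),
                         eig = TRUE)
  eig <- fit$eig
  tol <- max(abs(eig)) * 1e-9
  pos <- eig[eig > tol]
  if (k > length(pos))
    stop("k = ", k, " exceeds the number of positive eigenvalues (",
         length(pos), ")", call. = FALSE)
  if (any(eig < -tol) && abs(min(eig)) > 0.05 * max(eig))
    warning("distance matrix is markedly non-Euclidean (most negative ",
            "eigenvalue exceeds 5% of the largest); negative eigenvalues ",
            "excluded from explained-variance shares")
  pts <- fit$points[, seq_len(k), drop = FALSE]
  colnames(pts) <- paste0("Coord", seq_len(k))
  structure(list(points = pts,
                 explained = 100 * pos[seq_len(k)] / sum(pos),
                 eig = eig, method = "pcoa"),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat("Ordination (", x$method, "): ", nrow(x$points), " points in ",
      ncol(x$points), " dimensions\n", sep = "")
  if (!is.null(x$explained))
    cat("  explained: ", paste(sprintf("%.2f%%", x$explained),
                               collapse = ", "), "\n", sep = "")
  if (!is.null(x$stress))
    cat("  Sammon stress: ", format(x$stress, digits = 6), " after ",
        x$iterations, " iterations\n", sep = "")
  invisible(x)
}

#' @export
plot.ordination <- function(x, ...) {
  pts <- x$points
  graphics::plot(pts[, 1], pts[, 2],
                 xlab = colnames(pts)[1], ylab = colnames(pts)[2],
                 main = toupper(x$method), type = "n", ...)
  graphics::text(pts[, 1], pts[, 2], labels = rownames(pts))
  invisible(x)
}

sammon_stress <- function(delta, d) {
  sum((delta - d)^2 / delta) / sum(delta)
}

#' Sammon multidimensional scaling
#'
#' Nonlinear MDS minimizing Sammon stress
#' \deqn{E = \frac{1}{\sum_{i<j}\delta_{ij}} \sum_{i<j}
#'   \frac{(\delta_{ij}-d_{ij})^2}{\delta_{ij}}}
#' (input distances \eqn{\delta}, output distances d) by gradient descent
#' with step-halving line search from a PCoA initialization, so the stress
#' sequence is monotone non-increasing and the run is deterministic.
#' Requires all off-diagonal input distances strictly positive (collapse
#' duplicate objects first).
#'
#' @param dm symmetric distance matrix with positive off-diagonal entries.
#' @param k embedding dimension.
#' @param max_iter maximum gradient iterations.
#' @param tol stop when the relative stress decrease falls below this.
#' @param step0 initial step size (Sammon's "magic factor").
#' @return An `ordination` with fields `points`, `stress`, `stress_trace`,
#'   `iterations`.
#' @export
sammon_mds <- function(dm, k = 2, max_iter = 500, tol = 1e-12, step0 = 0.3) {
  delta <- as_distance_matrix(dm)
  n <- nrow(delta)
  off <- delta[upper.tri(delta)]
  if (any(off <= 0))
    stop("zero off-diagonal distance: collapse duplicate objects before ",
         "Sammon mapping", call. = FALSE)
  # init from classical scaling; pad with zeros if fewer positive axes
  init <- stats::cmdscale(stats::as.dist(delta), k = min(k, n - 1))
  Y <- matrix(0, n, k)
  Y[, seq_len(ncol(init))] <- init
  dist_out <- function(Y) as.matrix(stats::dist(Y))
  c_norm <- sum(off)
  D <- dist_out(Y)
  stress <- sammon_stress(off, D[upper.tri(D)])
  trace <- stress
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # gradient of E wrt Y
    W <- (delta - D) / (delta * pmax(D, 1e-12))
    diag(W) <- 0
    G <- -2 / c_norm * (rowSums(W) * Y - W %*% Y)
    gnorm <- sqrt(sum(G^2))
    if (gnorm < 1e-15) break
    step <- step0
    improved <- FALSE
    for (h in 1:40) {
      Y_new <- Y - step * G
      D_new <- dist_out(Y_new)
      s_new <- sammon_stress(off, D_new[upper.tri(D_new)])
      if (s_new <= stress) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) break
    rel <- (stress - s_new) / max(stress, 1e-300)
    Y <- Y_new; D <- D_new; stress <- s_new
    trace <- c(trace, stress)
    if (rel < tol) break
  }
  rownames(Y) <- rownames(delta)
  colnames(Y) <- paste0("Dim", seq_len(k))
  structure(list(points = Y, stress = stress, stress_trace = trace,
                 iterations = it, method = "sammon"),
            class = "ordination")
}

#' Great-circle distance in kilometers
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param a,b numeric `c(lat, lon)` in degrees, or two-column matrices
#'   (lat, lon) of equal row count.
#' @return distance(s) in km.
#' @export
haversine_km <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  if (any(abs(a[, 1]) > 90) || any(abs(b[, 1]) > 90) ||
      any(abs(a[, 2]) > 180) || any(abs(b[, 2]) > 180))
    stop("coordinates out of range: lat in [-90,90], lon in [-180,180]",
         call. = FALSE)
  # geosphere expects (lon, lat)
  as.vector(geosphere::distHaversine(a[, 2:1, drop = FALSE],
                                     b[, 2:1, drop = FALSE],
                                     r = 6371000)) / 1000
}

#' Pairwise great-circle distances between population locations
#'
#' @param cohort a `ystr_cohort`; each population's coordinates are taken
#'   from its first sample (coordinates are constant within population).
#' @return Symmetric labeled matrix of distances in km.
#' @export
geo_distance_matrix <- function(cohort) {
  d <- cohort$data
  first <- d[!duplicated(d$population), c("population", "lat", "lon")]
  first <- first[order(first$population), ]
  P <- nrow(first)
  out <- matrix(0, P, P, dimnames = list(first$population, first$population))
  for (i in seq_len(P - 1)) for (j in (i + 1):P)
    out[i, j] <- out[j, i] <- haversine_km(
      c(first$lat[i], first$lon[i]), c(first$lat[j], first$lon[j]))
  out
}

#' Mantel test of association between two distance matrices
#'
#' Pearson correlation over the off-diagonal upper-triangle entries, with
#' significance from permuting the labels of one matrix (one-sided,
#' positive association). When the full permutation group is no larger
#' than `permutations` the enumeration is exhaustive and the p-value
#' exact; otherwise random permutations are drawn under `seed`.
#' `r_squared = correlation^2` is reported for the regression framing
#' (share of variation in one distance explained by the other).
#'
#' @param dm1,dm2 distance matrices with identical labels in identical
#'   order (size >= 3).
#' @param permutations number of random permutations.
#' @param seed RNG seed for random permutations.
#' @return An object of class `mantel_test` with `correlation`,
#'   `r_squared`, `p_value`, `permutations`, `method`.
#' @export
mantel_test <- function(dm1, dm2, permutations = 999, seed = NULL) {
  dm1 <- as_distance_matrix(dm1); dm2 <- as_distance_matrix(dm2)
  n <- nrow(dm1)
  if (n < 3) stop("need at least 3 labels", call. = FALSE)
  if (!identical(rownames(dm1), rownames(dm2)))
    stop("matrices must share labels in the same order", call. = FALSE)
  ut <- upper.tri(dm1)
  r_obs <- stats::cor(dm1[ut], dm2[ut])
  if (factorial(n) <= permutations + 1) {
    perms <- all_permutations(n)
    r_perm <- vapply(perms, function(p) {
      stats::cor(dm1[ut], dm2[p, p][ut])
    }, 0)
    p_value <- mean(r_perm >= r_obs - 1e-12)
    method <- "exhaustive"
    n_used <- length(perms)
  } else {
    if (permutations > 0) {
      if (is.null(seed)) stop("seed required for random permutations",
                              call. = FALSE)
      set.seed(seed)
      hits <- 0L
      for (b in seq_len(permutations)) {
        p <- sample(n)
        if (stats::cor(dm1[ut], dm2[p, p][ut]) >= r_obs - 1e-12)
          hits <- hits + 1L
      }
      p_value <- (1 + hits) / (permutations + 1)
    } else {
      p_value <- NA_real_
    }
    method <- "sampled"
    n_used <- permutations
  }
  structure(list(correlation = r_obs, r_squared = r_obs^2,
                 p_value = p_value, permutations = n_used,
                 method = method, seed = seed),
            class = "mantel_test")
}

#' @export
print.mantel_test <- function(x, ...) {
  cat("Mantel test (", x$method, ", ", x$permutations, " permutations)\n",
      "  r = ", format(x$correlation, digits = 4),
      "  r^2 = ", format(x$r_squared, digits = 4),
      "  p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

# All permutations of 1..n as a list (n small).
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (i in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = i - 1L)
  }
  out
}
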