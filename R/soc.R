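# Squared Euclidean distances from every row of m to every row of centers.
dist_to_centers <- function(m, centers) {
  d2 <- outer(rowSums(m^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(m)), rowSums(centers^2)) - 2 * m %*% t(centers)
  d2[d2 < 0] <- 0
  d2
}

# Lloyd-style refinement: nearest assignment + centroid update until the
# largest center movement falls below `tol`. Empty clusters are re-seeded at
# the data point globally farthest from the cluster's current center.
refine_centers <- function(m, centers, tol = 1e-9, max_iter = 200L) {
  for (it in seq_len(max_iter)) {
    d2 <- dist_to_centers(m, centers)
    assign <- max.col(-d2, ties.method = "first")
    new_centers <- centers
    for (j in seq_len(nrow(centers))) {
      members <- which(assign == j)
      if (length(members) == 0L) {
        far <- which.max(d2[, j])
        new_centers[j, ] <- m[far, ]
      } else {
        new_centers[j, ] <- colMeans(m[members, , drop = FALSE])
      }
    }
    move <- max(abs(new_centers - centers))
    centers <- new_centers
    if (move < tol) break
  }
  d2 <- dist_to_centers(m, centers)
  assign <- max.col(-d2, ties.method = "first")
  within <- sum(sqrt(d2[cbind(seq_len(nrow(m)), assign)]))
  list(centers = centers, assignment = assign, within = within)
}

# Per-cluster radius / nearest-neighbour-center distance diagnostics.
soc_diagnostics <- function(m, centers, assignment, ratio) {
  N <- nrow(centers)
  cd <- as.matrix(stats::dist(centers))
  diag(cd) <- Inf
  purrr::map_dfr(seq_len(N), function(j) {
    members <- which(assignment == j)
    radius <- if (length(members) <= 1L) 0 else
      mean(sqrt(rowSums((m[members, , drop = FALSE] -
                           matrix(centers[j, ], length(members),
                                  ncol(m), byrow = TRUE))^2)))
    delta <- if (N > 1L) min(cd[j, ]) else Inf
    tibble::tibble(cluster = j, size = length(members), radius = radius,
                   delta = delta,
                   ok = length(members) <= 1L || radius < ratio * delta)
  })
}

#' Growing central-vector clustering of haplogroup distributions
#'
#' Finds the local condensation centres (central vectors, CVs) of the
#' population frequency vectors. The number of centres is grown from
#' `n_start` until every multi-member cluster satisfies the significance
#' criterion: the cluster *radius* (mean Euclidean distance of members to
#' their centre) must be smaller than `ratio` (default 1/3) times the
#' distance from the centre to its nearest neighbouring centre. Singleton
#' clusters pass trivially.
#'
#' At each size N the centres are refined by restart-stabilized
#' nearest-assignment/centroid updates (best of `n_restarts` random starts
#' plus a growth start that splits the worst-violating cluster at its
#' farthest member), and the best solution by total within-cluster distance
#' is checked against the criterion. If `max_n` is reached without
#' satisfying it, the best solution is returned with `converged = FALSE`.
#'
#' @param freq An `hg_freq` tibble (see [build_frequency_matrix()]) or a
#'   numeric matrix with one row per population.
#' @param ratio Radius-to-neighbour-distance criterion, default `1/3`.
#' @param n_start Initial number of centres, default 2.
#' @param max_n Maximal number of centres; default = number of populations.
#' @param n_restarts Random restarts per size, default 10.
#' @param seed Integer seed; the fit is deterministic given `seed`.
#' @param tol Center-movement convergence tolerance, default 1e-9.
#' @return An object of class `hg_soc`: list with `centers` (N x D matrix,
#'   rows `CV1...CVN`), `assignment` (named integer vector population ->
#'   cluster), `n_clusters`, `converged`, `criteria` (per-cluster
#'   diagnostics tibble), `within`, `ratio`, `seed`, and `data` (the fitted
#'   matrix, kept for diagnostics and plotting).
#' @seealso [cluster_radius()], [significance_check()], [inherence_matrix()]
#' @export
fit_soc <- function(freq, ratio = 1/3, n_start = 2L, max_n = NULL,
                    n_restarts = 10L, seed = 1L, tol = 1e-9) {
  m <- hg_matrix(freq)
  P <- nrow(m)
  if (is.null(max_n)) max_n <- P
  if (n_start < 2L) stop("`n_start` must be >= 2", call. = FALSE)
  if (max_n < n_start) stop("`max_n` must be >= `n_start`", call. = FALSE)
  if (max_n > P) stop("`max_n` cannot exceed the number of populations", call. = FALSE)
  if (P < n_start) stop("need at least `n_start` populations", call. = FALSE)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  prev_best <- NULL
  best_overall <- NULL
  for (N in seq.int(n_start, max_n)) {
    inits <- list()
    if (!is.null(prev_best)) {
      # grow by splitting the worst-violating cluster at its farthest member
      crit <- prev_best$criteria
      worst <- crit$cluster[which.max(crit$radius / pmax(crit$delta, 1e-300))]
      members <- which(prev_best$assignment == worst)
      if (length(members) > 0L) {
        c0 <- prev_best$centers[worst, ]
        dists <- sqrt(rowSums((m[members, , drop = FALSE] -
                                 matrix(c0, length(members), ncol(m),
                                        byrow = TRUE))^2))
        inits[[1]] <- rbind(prev_best$centers, m[members[which.max(dists)], ])
      }
    }
    for (r in seq_len(n_restarts))
      inits[[length(inits) + 1L]] <- m[sample.int(P, N), , drop = FALSE]

    fits <- lapply(inits, function(cen) refine_centers(m, cen, tol = tol))
    best <- fits[[which.min(vapply(fits, `[[`, 0.0, "within"))]]
    best$criteria <- soc_diagnostics(m, best$centers, best$assignment, ratio)
    best_overall <- best
    if (all(best$criteria$ok)) {
      return(new_hg_soc(m, best, N, TRUE, ratio, seed))
    }
    prev_best <- best
  }
  new_hg_soc(m, best_overall, max_n, FALSE, ratio, seed)
}

new_hg_soc <- function(m, fit, N, converged, ratio, seed) {
  rownames(fit$centers) <- paste0("CV", seq_len(N))
  colnames(fit$centers) <- colnames(m)
  assignment <- fit$assignment
  names(assignment) <- rownames(m)
  structure(list(centers = fit$centers, assignment = assignment,
                 n_clusters = N, converged = converged,
                 criteria = fit$criteria, within = fit$within,
                 ratio = ratio, seed = seed, data = m),
            class = "hg_soc")
}

#' @export
print.hg_soc <- function(x, ...) {
  cat("<hg_soc> ", x$n_clusters, " central vectors over ",
      nrow(x$data), " populations (", ncol(x$data), "-dimensional)",
      if (x$converged) "" else " [criterion NOT satisfied at max_n]",
      "\n", sep = "")
  print(x$criteria, ...)
  invisible(x)
}

#' @rdname fit_soc
#' @param x,object An `hg_soc` fit.
#' @param ... Unused.
#' @method tidy hg_soc
#' @export
tidy.hg_soc <- function(x, ...) {
  tibble::tibble(population = names(x$assignment),
                 cluster = unname(x$assignment))
}

#' @rdname fit_soc
#' @method glance hg_soc
#' @export
glance.hg_soc <- function(x, ...) {
  tibble::tibble(n_clusters = x$n_clusters, converged = x$converged,
                 total_within = x$within,
                 max_radius_ratio = max(x$criteria$radius /
                                          pmax(x$criteria$delta, 1e-300)))
}

#' Mean member-to-centre distance of one cluster
#'
#' @param freq Frequency data the fit was trained on (or any matching
#'   `hg_freq`/matrix).
#' @param fit An `hg_soc` object.
#' @param i Cluster index.
#' @return Mean Euclidean distance of the cluster's members to its centre;
#'   0 for a singleton.
#' @export
cluster_radius <- function(freq, fit, i) {
  stopifnot(inherits(fit, "hg_soc"))
  m <- hg_matrix(freq)
  members <- which(fit$assignment == i)
  if (length(members) == 0L) stop("cluster ", i, " is empty", call. = FALSE)
  mean(sqrt(rowSums((m[members, , drop = FALSE] -
                       matrix(fit$centers[i, ], length(members), ncol(m),
                              byrow = TRUE))^2)))
}

#' Per-cluster separation significance
#'
#' For every cluster with at least 3 members, a one-sided paired t-test of
#' whether member distances to the own centre are smaller than distances to
#' the nearest neighbouring centre. Returns `1 - p`: values above 0.99 mean
#' the nearest foreign centre is confidently farther than the own centre.
#'
#' @inheritParams cluster_radius
#' @return Tibble with columns `cluster`, `size`, `confidence` (`1 - p`, or
#'   `NA` when fewer than 3 members or zero variance makes the test
#'   non-computable).
#' @export
significance_check <- function(freq, fit) {
  stopifnot(inherits(fit, "hg_soc"))
  m <- hg_matrix(freq)
  cd <- as.matrix(stats::dist(fit$centers))
  diag(cd) <- Inf
  purrr::map_dfr(seq_len(fit$n_clusters), function(j) {
    members <- which(fit$assignment == j)
    conf <- NA_real_
    if (length(members) >= 3L && fit$n_clusters > 1L) {
      nn <- which.min(cd[j, ])
      mm <- m[members, , drop = FALSE]
      d_own <- sqrt(rowSums((mm - matrix(fit$centers[j, ], nrow(mm), ncol(m),
                                         byrow = TRUE))^2))
      d_other <- sqrt(rowSums((mm - matrix(fit$centers[nn, ], nrow(mm), ncol(m),
                                           byrow = TRUE))^2))
      conf <- tryCatch(
        1 - stats::t.test(d_other, d_own, paired = TRUE,
                          alternative = "greater")$p.value,
        error = function(e) NA_real_)
    }
    tibble::tibble(cluster = j, size = length(members), confidence = conf)
  })
}

#' Binary same-cluster (inherence) matrix
#'
#' Element (i, j) is 1 when populations i and j are assigned to the same
#' cluster, 0 otherwise; symmetric with a unit diagonal.
#'
#' @param fit An `hg_soc` object.
#' @return Integer matrix with population dimnames.
#' @export
inherence_matrix <- function(fit) {
  stopifnot(inherits(fit, "hg_soc"))
  a <- fit$assignment
  m <- outer(a, a, `==`) * 1L
  dimnames(m) <- list(names(a), names(a))
  m
}

#' Correlation between the inherence matrix and a distance matrix
#'
#' Pearson correlation over the off-diagonal upper-triangle entries of the
#' same-cluster indicator matrix and a population distance matrix. When the
#' clustering tracks the distances, within-cluster pairs (inherence 1) have
#' smaller distances, so a good correspondence shows up as a *negative*
#' value.
#'
#' @param fit An `hg_soc` object.
#' @param dist An `hg_dist` matrix (see [euclidean_matrix()]) or labeled
#'   square matrix over the same populations.
#' @return Signed Pearson correlation.
#' @export
inherence_distance_correlation <- function(fit, dist) {
  inh <- inherence_matrix(fit)
  d <- as_hg_dist(dist)
  common <- intersect(rownames(inh), rownames(d))
  if (length(common) < 3L)
    stop("fewer than 3 shared populations between fit and distance matrix",
         call. = FALSE)
  inh <- inh[common, common]
  d <- d[common, common]
  ut <- upper.tri(inh)
  if (stats::sd(inh[ut]) == 0)
    stop("inherence matrix is constant over population pairs; ",
         "correlation undefined", call. = FALSE)
  stats::cor(inh[ut], d[ut])
}
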