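# Coerce to a labeled square symmetric matrix of class hg_dist.
as_hg_dist <- function(x) {
  if (inherits(x, "dist")) x <- as.matrix(x)
  stopifnot(is.matrix(x), nrow(x) == ncol(x))
  if (is.null(rownames(x))) {
    rownames(x) <- colnames(x) <- paste0("P", seq_len(nrow(x)))
  }
  if (is.null(colnames(x))) colnames(x) <- rownames(x)
  if (max(abs(x - t(x))) > 1e-12)
    stop("distance matrix is not symmetric", call. = FALSE)
  storage.mode(x) <- "double"
  structure(x, class = c("hg_dist", "matrix", "array"))
}

#' Euclidean distance matrix of haplogroup distributions
#'
#' Pairwise unweighted Euclidean distances
#' `d_{m,n} = sqrt(sum_k (h_{m,k} - h_{n,k})^2)` between the population
#' frequency vectors. Unusable (unclassifiable) populations are excluded
#' with a warning.
#'
#' @param freq An `hg_freq` tibble or numeric population matrix.
#' @return A symmetric matrix of class `hg_dist` with population labels.
#' @export
euclidean_matrix <- function(freq) {
  m <- hg_matrix(freq)
  if (nrow(m) < 2L) stop("need at least 2 usable populations", call. = FALSE)
  as_hg_dist(as.matrix(stats::dist(m, method = "euclidean")))
}

# Align two labeled distance matrices on their shared populations.
align_dists <- function(d1, d2) {
  d1 <- as_hg_dist(d1)
  d2 <- as_hg_dist(d2)
  common <- intersect(rownames(d1), rownames(d2))
  if (length(common) < 3L)
    stop("fewer than 3 shared population labels between the two matrices",
         call. = FALSE)
  list(d1 = d1[common, common], d2 = d2[common, common], labels = common)
}

#' Correlation of two distance matrices
#'
#' Pearson correlation over the off-diagonal upper-triangle entries of two
#' labeled distance matrices, after reordering to their shared labels.
#'
#' @param d1,d2 `hg_dist` matrices (or labeled square matrices).
#' @return Single correlation value.
#' @export
matrix_correlation <- function(d1, d2) {
  al <- align_dists(d1, d2)
  ut <- upper.tri(al$d1)
  stats::cor(al$d1[ut], al$d2[ut])
}

#' Mantel permutation test between two distance matrices
#'
#' Tests the association of two distance matrices by randomly permuting the
#' populations of the second matrix (rows and columns jointly, preserving
#' symmetry) and recomputing the matrix correlation. The one-sided p-value
#' uses the +1-corrected estimator
#' `p = (1 + #\{r_perm >= r_obs\}) / (1 + n_permutations)`, so the smallest
#' achievable p is `1 / (n_permutations + 1)`.
#'
#' @inheritParams matrix_correlation
#' @param n_permutations Number of random permutations, >= 99; default 9999.
#' @param seed Integer seed; the test is deterministic given `seed`.
#' @return A list of class `hg_mantel`: `r_observed`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
mantel_test <- function(d1, d2, n_permutations = 9999L, seed = 1L) {
  if (n_permutations < 99L) stop("`n_permutations` must be >= 99", call. = FALSE)
  al <- align_dists(d1, d2)
  n <- length(al$labels)
  ut <- upper.tri(al$d1)
  v1 <- al$d1[ut]
  r_obs <- stats::cor(v1, al$d2[ut])

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  r_perm <- vapply(seq_len(n_permutations), function(i) {
    p <- sample.int(n)
    stats::cor(v1, al$d2[p, p][ut])
  }, 0.0)
  structure(list(r_observed = r_obs,
                 p_value = (1 + sum(r_perm >= r_obs)) / (1 + n_permutations),
                 n_permutations = as.integer(n_permutations),
                 seed = seed),
            class = "hg_mantel")
}

#' @export
print.hg_mantel <- function(x, ...) {
  cat("<hg_mantel> r = ", format(x$r_observed, digits = 4), ", p = ",
      format(x$p_value, digits = 4), " (", x$n_permutations,
      " permutations, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' @rdname mantel_test
#' @param x,object An `hg_mantel` result.
#' @param ... Unused.
#' @method glance hg_mantel
#' @export
glance.hg_mantel <- function(x, ...) {
  tibble::tibble(r_observed = x$r_observed, p_value = x$p_value,
                 n_permutations = x$n_permutations, seed = x$seed)
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Metric (Torgerson) scaling via [stats::cmdscale()]. Negative eigenvalues
#' of the doubly-centred matrix (non-Euclidean input) are truncated with a
#' warning.
#'
#' @param d An `hg_dist` matrix.
#' @param dims Embedding dimension, default 2; must be below the number of
#'   labels.
#' @return Tibble with columns `label`, `dim1`, ..., `dim<dims>`.
#' @export
mds_embedding <- function(d, dims = 2L) {
  d <- as_hg_dist(d)
  if (dims >= nrow(d)) stop("`dims` must be below the number of labels", call. = FALSE)
  fit <- stats::cmdscale(d, k = dims, eig = TRUE)
  if (any(fit$eig < -1e-8 * max(abs(fit$eig))))
    warning("non-Euclidean distances: negative eigenvalues truncated",
            call. = FALSE)
  pts <- fit$points
  if (ncol(pts) < dims)  # cmdscale drops axes with ~zero eigenvalue
    pts <- cbind(pts, matrix(0, nrow(pts), dims - ncol(pts)))
  colnames(pts) <- paste0("dim", seq_len(dims))
  dplyr::bind_cols(tibble::tibble(label = rownames(d)), tibble::as_tibble(pts))
}

#' Edges below a fractional distance threshold
#'
#' All pairs (i < j) whose distance is strictly below `fraction` times the
#' maximal distance in the matrix.
#'
#' @param d An `hg_dist` matrix.
#' @param fraction Fraction of the maximal distance, in (0, 1\]; default 0.35.
#' @return Tibble with columns `from`, `to`, `distance`.
#' @export
threshold_edges <- function(d, fraction = 0.35) {
  d <- as_hg_dist(d)
  if (fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  cutoff <- fraction * max(d)
  idx <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
  tibble::tibble(from = rownames(d)[idx[, 1]], to = colnames(d)[idx[, 2]],
                 distance = d[idx])
}

#' Minimum spanning tree of a distance matrix
#'
#' The n - 1 edges connecting all populations with minimal total distance
#' (via [igraph::mst()]).
#'
#' @param d An `hg_dist` matrix with at least 2 labels.
#' @return Tibble with columns `from`, `to`, `distance`; attribute
#'   `total_weight`.
#' @export
minimum_spanning_tree <- function(d) {
  d <- as_hg_dist(d)
  if (nrow(d) < 2L) stop("need at least 2 labels", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  t <- igraph::mst(g, weights = igraph::E(g)$weight)
  el <- igraph::as_edgelist(t)
  out <- tibble::tibble(from = el[, 1], to = el[, 2],
                        distance = igraph::E(t)$weight)
  out <- dplyr::arrange(out, .data$distance)
  attr(out, "total_weight") <- sum(out$distance)
  out
}
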