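# Decode a Pruefer sequence into the edge list of a labeled tree.
prufer_decode <- function(seq, n) {
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  k <- 0L
  for (s in seq) {
    leaf <- which(degree == 1L)[1L]
    k <- k + 1L
    edges[k, ] <- c(leaf, s)
    degree[leaf] <- degree[leaf] - 1L
    degree[s] <- degree[s] - 1L
  }
  last <- which(degree == 1L)
  edges[n - 1L, ] <- last
  edges
}

# Minimal spanning-tree weight by exhaustive enumeration of all labeled trees.
exhaustive_mst_weight <- function(d) {
  n <- nrow(d)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- Inf
  for (i in seq_len(nrow(seqs))) {
    e <- prufer_decode(seqs[i, ], n)
    best <- min(best, sum(d[e]))
  }
  best
}

test_that("Euclidean distances follow the direct summation formula", {
  m <- rbind(a = c(1, 0, 0), b = c(1, 0, 0), c = c(0, 1, 0))
  d <- euclidean_matrix(m)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], sqrt(2))  # one-hot rows on different axes
  withr::with_seed(71, {
    mm <- matrix(stats::runif(5 * 8), 5, 8,
                 dimnames = list(paste0("p", 1:5), NULL))
    dd <- euclidean_matrix(mm)
    for (i in 1:4) for (j in (i + 1):5)
      expect_equal(dd[i, j], sqrt(sum((mm[i, ] - mm[j, ])^2)),
                   tolerance = 1e-12)
    expect_true(isSymmetric(unclass(dd)))
    expect_equal(unname(diag(dd)), rep(0, 5))
  })
})

test_that("distances on simplex-valued data satisfy the triangle inequality", {
  freq <- generate_populations(generate_profiles(4, 12, seed = 72), 20,
                               mixture_mode = "admixed", noise_sd = 0.02,
                               seed = 73)
  d <- euclidean_matrix(freq)
  n <- nrow(d)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
})

test_that("matrix correlation is scale-invariant, label-aware and oracle-consistent", {
  withr::with_seed(74, {
    m1 <- matrix(stats::runif(6 * 5), 6, 5, dimnames = list(paste0("p", 1:6), NULL))
    m2 <- matrix(stats::runif(6 * 5), 6, 5, dimnames = list(paste0("p", 1:6), NULL))
    d1 <- euclidean_matrix(m1); d2 <- euclidean_matrix(m2)
    expect_equal(matrix_correlation(d1, d1), 1.0)
    expect_equal(matrix_correlation(d1, 2 * d1), 1.0)
    # flatten-and-correlate oracle
    ut <- upper.tri(d1)
    expect_equal(matrix_correlation(d1, d2), stats::cor(d1[ut], d2[ut]),
                 tolerance = 1e-12)
    # invariant to a common relabeling of both matrices
    p <- sample(6)
    relabel <- function(d) { x <- unclass(d)[p, p]; x }
    expect_equal(matrix_correlation(relabel(d1), relabel(d2)),
                 matrix_correlation(d1, d2), tolerance = 1e-12)
    # automatic reordering on shared labels
    q <- sample(6)
    expect_equal(matrix_correlation(d1, unclass(d2)[q, q]),
                 matrix_correlation(d1, d2), tolerance = 1e-12)
    expect_error(matrix_correlation(d1, euclidean_matrix(
      matrix(stats::runif(10), 5, 2, dimnames = list(paste0("z", 1:5), NULL)))),
      "shared")
  })
})

test_that("Mantel test attains its minimal p on identical matrices and detects planted association", {
  withr::with_seed(75, {
    m <- matrix(stats::runif(12 * 6), 12, 6,
                dimnames = list(paste0("p", 1:12), NULL))
    d <- euclidean_matrix(m)
    res <- mantel_test(d, d, n_permutations = 199, seed = 3)
    expect_equal(res$r_observed, 1.0)
    expect_equal(res$p_value, 1 / 200)
    # deterministic given seed
    res2 <- mantel_test(d, d, n_permutations = 199, seed = 3)
    expect_identical(res$p_value, res2$p_value)

    # planted correlation: reference = noisy copy of d
    ref <- unclass(d) + matrix(stats::runif(144, 0, 0.05), 12, 12)
    ref <- (ref + t(ref)) / 2; diag(ref) <- 0
    res3 <- mantel_test(d, ref, n_permutations = 999, seed = 4)
    expect_lt(res3$p_value, 0.01)
    expect_error(mantel_test(d, ref, n_permutations = 50), "99")
  })
})

test_that("the observed Mantel statistic agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  withr::with_seed(76, {
    m1 <- matrix(stats::runif(10 * 4), 10, 4, dimnames = list(paste0("p", 1:10), NULL))
    m2 <- m1 + matrix(stats::rnorm(40, sd = 0.2), 10, 4)
    rownames(m2) <- rownames(m1)
    d1 <- euclidean_matrix(m1); d2 <- euclidean_matrix(m2)
    ours <- mantel_test(d1, d2, n_permutations = 999, seed = 5)
    ref <- vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                         permutations = 999)
    expect_equal(ours$r_observed, unname(ref$statistic), tolerance = 1e-12)
    expect_lt(abs(ours$p_value - ref$signif), 0.05)
  })
})

test_that("classical MDS preserves configurations up to rigid motion", {
  # three collinear points
  x <- cbind(c(0, 1, 3), 0)
  rownames(x) <- c("a", "b", "c")
  d <- euclidean_matrix(x)
  emb <- mds_embedding(d, dims = 1)
  got <- abs(outer(emb$dim1, emb$dim1, "-"))
  expect_equal(got, unclass(d)[emb$label, emb$label], tolerance = 1e-9,
               ignore_attr = TRUE)

  # known 2-D configuration recovered up to rotation/reflection (Procrustes)
  withr::with_seed(77, {
    x2 <- matrix(stats::rnorm(2 * 8), 8, 2,
                 dimnames = list(paste0("p", 1:8), NULL))
    d2 <- euclidean_matrix(x2)
    emb2 <- mds_embedding(d2, dims = 2)
    A <- scale(x2[emb2$label, ], center = TRUE, scale = FALSE)
    B <- scale(as.matrix(emb2[, c("dim1", "dim2")]), center = TRUE, scale = FALSE)
    s <- svd(crossprod(B, A))
    expect_lt(max(abs(B %*% s$u %*% t(s$v) - A)), 1e-9)

    # random (still metric) input: embedding distances correlate positively
    m3 <- matrix(stats::runif(9 * 12), 9, 12, dimnames = list(paste0("q", 1:9), NULL))
    d3 <- euclidean_matrix(m3)
    e3 <- mds_embedding(d3, dims = 2)
    de <- as.matrix(stats::dist(e3[, c("dim1", "dim2")]))
    ut <- upper.tri(de)
    expect_gt(stats::cor(de[ut], unclass(d3)[e3$label, e3$label][ut]), 0)
  })
  expect_error(mds_embedding(d, dims = 3), "below")
})

test_that("threshold edges and the minimum spanning tree match hand and exhaustive oracles", {
  # crafted 4-point matrix: chain a-b-c-d with increasing gaps
  x <- cbind(c(0, 1, 2.5, 5), 0)
  rownames(x) <- letters[1:4]
  d <- euclidean_matrix(x)
  # max distance 5; threshold 0.35 -> cutoff 1.75: edges ab (1) and bc (1.5)
  te <- threshold_edges(d, 0.35)
  expect_equal(paste(te$from, te$to), c("a b", "b c"))
  expect_equal(nrow(threshold_edges(d, 1e-9)), 0L)
  full <- threshold_edges(d, 1)
  expect_equal(nrow(full), 5L)  # complete graph minus the maximal pair

  mst <- minimum_spanning_tree(d)
  expect_equal(nrow(mst), 3L)
  expect_equal(attr(mst, "total_weight"), 1 + 1.5 + 2.5)  # the chain

  withr::with_seed(78, {
    m <- matrix(stats::runif(6 * 5), 6, 5, dimnames = list(paste0("p", 1:6), NULL))
    dd <- euclidean_matrix(m)
    got <- minimum_spanning_tree(dd)
    expect_equal(attr(got, "total_weight"), exhaustive_mst_weight(unclass(dd)),
                 tolerance = 1e-12)
    # spanning: n - 1 edges touching every node, connected
    expect_equal(nrow(got), 5L)
    g <- igraph::graph_from_data_frame(got[, 1:2], directed = FALSE)
    expect_true(igraph::is_connected(g))
    expect_equal(igraph::vcount(g), 6L)
  })
})
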