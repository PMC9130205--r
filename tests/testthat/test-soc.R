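test_that("two well-separated clouds yield exactly two centres near the sample means", {
  tc <- two_clouds(n = 25, D = 6, sep = 12)
  fit <- fit_soc(tc$m, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$n_clusters, 2L)
  expect_true(same_partition(fit$assignment, tc$partition))
  # centres agree with the per-cloud sample means (the oracle) to ~3 SE
  se <- tc$sd / sqrt(tc$n)
  for (j in 1:2) {
    members <- which(fit$assignment == j)
    mu_hat <- colMeans(tc$m[members, ])
    expect_lt(max(abs(fit$centers[j, ] - mu_hat)), 1e-8)    # centroid property
    truth <- tc$mu[tc$partition[members[1]], ]
    expect_lt(max(abs(fit$centers[j, ] - truth)), 3 * se * 3)
  }
})

test_that("planted Dirichlet profile clusters are recovered exactly at low noise", {
  profiles <- generate_profiles(K = 5, D = 16, concentration = 0.4, seed = 2)
  freq <- generate_populations(profiles, P = 50, mixture_mode = "pure",
                               noise_sd = 0.004, seed = 3)
  truth <- attr(freq, "truth")
  fit <- fit_soc(freq, seed = 4)
  expect_true(fit$converged)
  expect_equal(fit$n_clusters, 5L)
  expect_true(same_partition(fit$assignment, truth$planted_partition))
  # recovered centres approach the planted profiles as noise is small
  perm <- apply(fit$centers, 1, function(cv)
    which.min(colSums((t(profiles) - cv)^2)))
  expect_equal(sort(unname(perm)), 1:5)
  expect_lt(max(abs(fit$centers - profiles[perm, ])), 0.02)
})

test_that("converged fits always satisfy the one-third radius criterion and nearest assignment", {
  withr::with_seed(41, {
    for (rep in 1:5) {
      K <- sample(2:4, 1)
      profiles <- generate_profiles(K, D = 10, concentration = 0.5, seed = rep)
      freq <- generate_populations(profiles, P = 8 * K, mixture_mode = "pure",
                                   noise_sd = 0.01, seed = rep + 100)
      fit <- fit_soc(freq, seed = rep)
      m <- fit$data
      # nearest-centre assignment, checked exhaustively
      d <- as.matrix(stats::dist(rbind(fit$centers, m)))
      d <- d[-(1:fit$n_clusters), 1:fit$n_clusters, drop = FALSE]
      expect_equal(unname(apply(d, 1, which.min)), unname(fit$assignment))
      if (fit$converged) {
        cd <- as.matrix(stats::dist(fit$centers)); diag(cd) <- Inf
        for (j in seq_len(fit$n_clusters)) {
          if (sum(fit$assignment == j) >= 2)
            expect_lt(cluster_radius(m, fit, j), min(cd[j, ]) / 3)
        }
      }
    }
  })
})

test_that("cluster radius matches direct averaging", {
  tc <- two_clouds(n = 10, D = 4)
  fit <- fit_soc(tc$m, seed = 5)
  for (j in seq_len(fit$n_clusters)) {
    members <- which(fit$assignment == j)
    if (length(members) == 1L) {
      expect_equal(cluster_radius(tc$m, fit, j), 0)
    } else {
      direct <- mean(apply(tc$m[members, , drop = FALSE], 1,
                           function(p) sqrt(sum((p - fit$centers[j, ])^2))))
      expect_equal(cluster_radius(tc$m, fit, j), direct, tolerance = 1e-12)
    }
  }
  expect_error(cluster_radius(tc$m, fit, fit$n_clusters + 1L), "empty")
})

test_that("separation significance exceeds 0.99 for well-separated clusters and degrades gracefully", {
  tc <- two_clouds(n = 20, D = 5, sep = 15)
  fit <- fit_soc(tc$m, seed = 6)
  sig <- significance_check(tc$m, fit)
  expect_true(all(sig$confidence > 0.99))

  # identical points: zero variance, not computable, no exception
  m0 <- rbind(matrix(0, 5, 3), matrix(1, 5, 3))
  rownames(m0) <- paste0("p", 1:10)
  fit0 <- fit_soc(m0, seed = 7)
  sig0 <- significance_check(m0, fit0)
  expect_true(all(is.na(sig0$confidence)))

  # heavily overlapping clouds: values below 0.99 are reported, no exception
  tc2 <- two_clouds(n = 20, D = 5, sep = 0.5, seed = 43)
  fit2 <- fit_soc(tc2$m, n_start = 2, max_n = 2, seed = 8)
  sig2 <- significance_check(tc2$m, fit2)
  expect_true(all(is.finite(sig2$confidence[sig2$size >= 3])))
})

test_that("inherence matrix encodes same-cluster membership", {
  tc <- two_clouds(n = 4, D = 3)
  fit <- fit_soc(tc$m, seed = 9)
  inh <- inherence_matrix(fit)
  expect_true(isSymmetric(inh))
  expect_true(all(diag(inh) == 1))
  expect_equal(unname(inh), unname(outer(fit$assignment, fit$assignment, "==") * 1L))

  # block structure for the planted partition
  ord <- order(fit$assignment)
  blocks <- inh[ord, ord]
  sizes <- table(fit$assignment)
  expect_equal(unname(blocks[1:sizes[1], 1:sizes[1]]),
               matrix(1L, sizes[1], sizes[1]))
  expect_true(all(blocks[seq_len(sizes[1]), -seq_len(sizes[1])] == 0L))
})

test_that("inherence-distance correlation is negative for real clusters and errors when constant", {
  tc <- two_clouds(n = 15, D = 5, sep = 10)
  fit <- fit_soc(tc$m, seed = 10)
  d <- euclidean_matrix(tc$m)
  expect_lt(inherence_distance_correlation(fit, d), -0.5)

  # single-cluster assignment: constant inherence, correlation undefined
  one <- fit
  one$assignment[] <- 1L
  expect_error(inherence_distance_correlation(one, d), "constant")
})

test_that("fits are reproducible given the seed", {
  profiles <- generate_profiles(3, 8, seed = 11)
  freq <- generate_populations(profiles, 15, noise_sd = 0.02, seed = 12)
  f1 <- fit_soc(freq, seed = 99)
  f2 <- fit_soc(freq, seed = 99)
  expect_identical(f1$centers, f2$centers)
  expect_identical(f1$assignment, f2$assignment)
  expect_error(fit_soc(freq, n_start = 5, max_n = 3), "max_n")
})
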