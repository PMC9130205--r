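test_that("the modeled distribution is the weighted sum of central vectors", {
  v <- orthonormal_cvs(4, 8, seed = 51)
  expect_equal(model_distribution(v, rep(0, 4)), rep(0, 8))
  expect_equal(model_distribution(v, c(0, 0, 1, 0)), v[3, ])
  withr::with_seed(52, {
    for (i in 1:10) {
      a <- stats::rnorm(4)
      direct <- a[1] * v[1, ] + a[2] * v[2, ] + a[3] * v[3, ] + a[4] * v[4, ]
      expect_equal(model_distribution(v, a), direct, tolerance = 1e-12)
    }
  })
  expect_error(model_distribution(v, rep(0, 3)), "weights")
})

test_that("error terms satisfy the defining identities", {
  v <- orthonormal_cvs(3, 6, seed = 53)
  h <- v[1, ]
  et <- error_terms(h, v, c(1, 0, 0))
  expect_equal(et$H, 0)
  expect_equal(et$J, 0)
  # all-zero weights: the unsuccessful model, J = 1
  et0 <- error_terms(h, v, rep(0, 3))
  expect_equal(et0$J, 1)
  expect_equal(et0$epsilon, h)
  withr::with_seed(54, {
    h2 <- stats::runif(6)
    a <- stats::rnorm(3)
    et2 <- error_terms(h2, v, a)
    eps <- h2 - drop(crossprod(v, a))
    expect_equal(et2$epsilon, eps)
    expect_equal(et2$H, sum(eps^2), tolerance = 1e-12)
    expect_equal(et2$J, sum(eps^2) / sum(h2^2), tolerance = 1e-12)
  })
  expect_error(error_terms(rep(0, 6), v, rep(0, 3)), "zero")
})

test_that("the analytic gradient matches hand computation and finite differences", {
  v <- orthonormal_cvs(3, 6, seed = 55)
  # at the exact solution the gradient vanishes
  expect_equal(unname(admix_gradient(v[2, ], v, c(0, 1, 0))), rep(0, 3),
               tolerance = 1e-12)
  # at zero weights with h = v_1 and orthonormal CVs, component 1 is -2
  g0 <- admix_gradient(v[1, ], v, rep(0, 3))
  expect_equal(unname(g0), c(-2, 0, 0), tolerance = 1e-12)

  withr::with_seed(56, {
    for (i in 1:10) {
      N <- sample(2:6, 1); D <- N + sample(2:6, 1)
      vv <- matrix(stats::rnorm(N * D), N, D)
      h <- stats::runif(D); a <- stats::rnorm(N)
      g <- unname(admix_gradient(h, vv, a))
      fd <- vapply(seq_len(N), function(m) {
        e <- rep(0, N); e[m] <- 1e-6
        (error_terms(h, vv, a + e)$H - error_terms(h, vv, a - e)$H) / 2e-6
      }, 0.0)
      expect_equal(g, fd, tolerance = 1e-5)
    }
  })
})

test_that("gradient search recovers exact representations and matches the least-squares oracle", {
  v <- orthonormal_cvs(4, 9, seed = 57)
  fit <- solve_weights(v[2, ], v)
  expect_equal(unname(fit$weights), c(0, 1, 0, 0), tolerance = 1e-6)
  expect_lt(fit$J, 1e-10)
  expect_true(fit$converged)

  withr::with_seed(58, {
    # full-rank random instances: H within 1e-8 (relative) of the
    # normal-equations residual computed first by the closed-form oracle
    for (i in 1:10) {
      vv <- matrix(stats::rnorm(5 * 10), 5, 10)
      h <- stats::runif(10)
      H_star <- oracle_H(h, vv)
      fit <- solve_weights(h, vv)
      expect_lt(abs(fit$H - H_star) / H_star, 1e-8)
    }
    # rank-deficient: duplicated central vector; H still matches the
    # pseudoinverse oracle (weights compared only through H)
    vv <- matrix(stats::rnorm(4 * 8), 4, 8)
    vv[4, ] <- vv[1, ]
    h <- stats::runif(8)
    H_star <- oracle_H(h, vv)
    fit <- solve_weights(h, vv)
    expect_lt(abs(fit$H - H_star) / max(H_star, 1e-12), 1e-6)
  })
})

test_that("accepted descent steps never increase H", {
  withr::with_seed(59, {
    for (i in 1:5) {
      vv <- matrix(stats::rnorm(6 * 12), 6, 12)
      h <- stats::runif(12)
      fit <- solve_weights(h, vv, keep_path = TRUE)
      expect_true(all(diff(fit$H_path) <= 0))
      expect_equal(fit$H_path[1], sum(h^2))  # descent starts at zero weights
      expect_true(fit$J >= 0 && fit$J <= 1)
    }
  })
})

test_that("J is invariant under permutation of the central vectors", {
  withr::with_seed(60, {
    vv <- matrix(stats::rgamma(5 * 12, 1), 5, 12)
    vv <- vv / rowSums(vv)      # correlated, non-orthogonal CVs
    h <- stats::runif(12)
    fit <- solve_weights(h, vv)
    p <- sample(5)
    fit_p <- solve_weights(h, vv[p, ], tol = 1e-14)
    expect_equal(fit_p$J, fit$J, tolerance = 1e-6)
    expect_equal(unname(fit_p$weights), unname(fit$weights[p]),
                 tolerance = 1e-3)
  })
})

test_that("non-negativity constraint and exact solver behave", {
  withr::with_seed(61, {
    vv <- matrix(stats::rgamma(4 * 10, 1), 4, 10)
    vv <- vv / rowSums(vv)
    h <- drop(crossprod(vv, c(0.7, 0.3, 0, 0)))
    fit <- solve_weights(h, vv, nonneg = TRUE)
    expect_true(all(fit$weights >= 0))
    expect_equal(unname(fit$weights), c(0.7, 0.3, 0, 0), tolerance = 1e-5)
    ex <- solve_weights(h, vv, solver = "exact")
    expect_equal(unname(ex$weights), c(0.7, 0.3, 0, 0), tolerance = 1e-8)
    ex_nn <- solve_weights(h, vv, solver = "exact", nonneg = TRUE)
    expect_true(all(ex_nn$weights >= 0))
  })
  expect_error(solve_weights(c(1, NA), matrix(1, 1, 2)), "non-finite")
})

test_that("batch fitting reports per-population errors and recovers planted mixtures", {
  profiles <- generate_profiles(4, 12, concentration = 0.8, seed = 62)
  # populations identical to the CVs model themselves perfectly
  adm_self <- fit_admixture(profiles, profiles)
  expect_true(all(adm_self$J <= 1e-10))

  # planted convex mixtures at zero noise: weights recovered to 1e-6
  freq <- generate_populations(profiles, 12, mixture_mode = "admixed",
                               noise_sd = 0, seed = 63)
  truth <- attr(freq, "truth")
  adm <- fit_admixture(freq, profiles)
  w <- as.matrix(tibble::as_tibble(adm)[, rownames(profiles)])
  expect_lt(max(abs(w - truth$mixture_weights)), 1e-6)
  expect_lt(attr(adm, "mean_J"), 1e-12)
  expect_equal(glance(adm)$n_failed, 0L)

  # weight error grows with noise (small-scale check)
  rmse_at <- function(sd, seed) {
    fr <- generate_populations(profiles, 12, mixture_mode = "admixed",
                               noise_sd = sd, seed = seed)
    tr <- attr(fr, "truth")
    a <- fit_admixture(fr, profiles)
    sqrt(mean((as.matrix(tibble::as_tibble(a)[, rownames(profiles)]) -
                 tr$mixture_weights)^2))
  }
  r <- vapply(1:10, function(s) c(rmse_at(0.002, s), rmse_at(0.05, s)),
              c(0, 0))
  expect_lt(mean(r[1, ]), mean(r[2, ]))
})
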