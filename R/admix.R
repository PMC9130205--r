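# Extract the N x D central-vector matrix from an hg_soc fit or a matrix.
cv_matrix <- function(cvset) {
  if (inherits(cvset, "hg_soc")) return(cvset$centers)
  if (is.data.frame(cvset)) return(hg_matrix(cvset))
  stopifnot(is.matrix(cvset))
  v <- cvset
  if (is.null(rownames(v))) rownames(v) <- paste0("CV", seq_len(nrow(v)))
  storage.mode(v) <- "double"
  v
}

#' Modeled distribution from central-vector weights
#'
#' The admixture model writes a population's haplogroup distribution `h` as
#' a weighted sum of the N central vectors plus an error term:
#' `h = a_1 v_1 + ... + a_N v_N + eps`. This returns the modeled part
#' `sum_i a_i v_i`.
#'
#' @param cvset An `hg_soc` fit or an N x D matrix of central vectors.
#' @param weights Numeric vector of length N.
#' @return Numeric D-vector (named by the haplogroup axes when available).
#' @export
model_distribution <- function(cvset, weights) {
  v <- cv_matrix(cvset)
  if (length(weights) != nrow(v))
    stop("`weights` must have one entry per central vector (", nrow(v), ")",
         call. = FALSE)
  drop(crossprod(v, weights))
}

#' Error terms of an admixture model
#'
#' Computes the error vector `eps = h - sum_i a_i v_i`, the error power
#' `H = sum_k eps_k^2`, and the normalized error `J = H / sum_k h_k^2`.
#' `J` is 0 for a perfect model and 1 for the null model with all weights 0.
#'
#' @param h Numeric D-vector, the haplogroup distribution to model.
#' @inheritParams model_distribution
#' @return List with elements `epsilon`, `H`, `J`.
#' @export
error_terms <- function(h, cvset, weights) {
  v <- cv_matrix(cvset)
  stopifnot(is.numeric(h), length(h) == ncol(v))
  power_h <- sum(h^2)
  if (power_h == 0)
    stop("`h` is the zero vector; normalized error J is undefined",
         call. = FALSE)
  eps <- h - model_distribution(v, weights)
  H <- sum(eps^2)
  list(epsilon = eps, H = H, J = H / power_h)
}

#' Gradient of the error power with respect to the weights
#'
#' The partial derivative of `H` with respect to weight `a_m` is
#' `-2 * sum_k eps_k * v_{m,k}`.
#'
#' @inheritParams error_terms
#' @return Numeric N-vector of partial derivatives.
#' @export
admix_gradient <- function(h, cvset, weights) {
  v <- cv_matrix(cvset)
  eps <- h - drop(crossprod(v, weights))
  drop(-2 * (v %*% eps))
}

#' Fit admixture weights by gradient search
#'
#' Minimizes the error power `H` of the linear-combination model by steepest
#' descent from the all-zero weight vector, with backtracking step control:
#' a step is accepted only if it lowers `H`; on failure the step size is
#' halved, on success grown by a factor 1.2. Because the search starts at
#' zero weights (where `J = 1`), the normalized error of any accepted
#' solution satisfies `0 <= J <= 1`. The weights are *not* constrained to
#' sum to 1 and may exceed 1; with `nonneg = TRUE` they are clipped at zero
#' after each step (projected gradient) to support a strict admixture
#' interpretation.
#'
#' Stopping: relative improvement of `H` below `tol`, step-size underflow
#' (no descent direction at machine precision), an essentially perfect fit
#' (`H` below `1e-24 * sum(h^2)`), or `max_iter`.
#'
#' With `solver = "exact"` the weights are instead obtained from the normal
#' equations (minimum-norm least squares via the pseudoinverse); this is the
#' closed-form fast path and the cross-check oracle for the gradient search.
#'
#' @inheritParams error_terms
#' @param learning_rate Initial step size relative to the Gram-matrix scale,
#'   default 0.1.
#' @param tol Relative-improvement stopping tolerance, default 1e-12.
#' @param max_iter Iteration cap, default 1e5.
#' @param nonneg Constrain weights to be non-negative? Default `FALSE`.
#' @param solver `"gradient"` (default, the reference implementation) or
#'   `"exact"`.
#' @param keep_path Record the sequence of accepted `H` values in the
#'   `H_path` element? Default `FALSE`.
#' @return An object of class `hg_admix_fit`: list with `weights`,
#'   `epsilon`, `H`, `J`, `iterations`, `converged`, `solver` (and
#'   `H_path` when `keep_path = TRUE`).
#' @export
solve_weights <- function(h, cvset, learning_rate = 0.1, tol = 1e-12,
                          max_iter = 1e5, nonneg = FALSE,
                          solver = c("gradient", "exact"), keep_path = FALSE) {
  solver <- match.arg(solver)
  v <- cv_matrix(cvset)
  if (!all(is.finite(h)) || !all(is.finite(v)))
    stop("non-finite values in `h` or the central vectors", call. = FALSE)
  stopifnot(length(h) == ncol(v))
  N <- nrow(v)
  power_h <- sum(h^2)

  if (solver == "exact") {
    a <- lstsq_weights(v, h)
    if (nonneg) a <- nnls_weights(v, h)
    et <- error_terms(h, v, a)
    return(new_admix_fit(a, et, 0L, TRUE, "exact", rownames(v)))
  }

  G <- v %*% t(v)            # Gram matrix of the central vectors
  b <- drop(v %*% h)
  scale <- max(rowSums(abs(G)))           # Gershgorin bound on the spectrum
  if (scale == 0) scale <- 1
  step <- learning_rate / (2 * scale)

  a <- rep(0, N)
  H <- power_h               # H at the all-zero start
  H_path <- if (keep_path) H else NULL
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    g <- 2 * (drop(G %*% a) - b)          # = -2 * V %*% eps
    accepted <- FALSE
    for (k in seq_len(60L)) {
      a_new <- a - step * g
      if (nonneg) a_new <- pmax(a_new, 0)
      H_new <- power_h - 2 * sum(a_new * b) + drop(crossprod(a_new, G %*% a_new))
      if (H_new < H) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; break }  # stationary at machine precision
    improvement <- H - H_new
    a <- a_new
    H <- H_new
    if (keep_path) H_path <- c(H_path, H)
    step <- step * 1.2
    if (improvement <= tol * max(H, .Machine$double.xmin) ||
        H <= 1e-24 * power_h) {
      converged <- TRUE
      break
    }
  }
  et <- error_terms(h, v, a)
  fit <- new_admix_fit(a, et, it, converged, "gradient", rownames(v))
  if (keep_path) fit$H_path <- H_path
  fit
}

# Minimum-norm least-squares weights via the pseudoinverse (SVD).
lstsq_weights <- function(v, h) {
  sv <- svd(t(v))
  pos <- sv$d > max(dim(v)) * .Machine$double.eps * max(sv$d, 0)
  drop(sv$v[, pos, drop = FALSE] %*%
         ((crossprod(sv$u[, pos, drop = FALSE], h)) / sv$d[pos]))
}

# Non-negative least squares by Lawson-Hanson active set (small N only).
nnls_weights <- function(v, h, max_iter = 10L * nrow(v)) {
  N <- nrow(v)
  passive <- logical(N)
  a <- rep(0, N)
  for (it in seq_len(max_iter)) {
    w <- drop(v %*% (h - drop(crossprod(v, a))))   # = -grad/2
    w[passive] <- -Inf
    if (all(w <= 1e-12)) break
    passive[which.max(w)] <- TRUE
    repeat {
      z <- rep(0, N)
      z[passive] <- lstsq_weights(v[passive, , drop = FALSE], h)
      if (all(z[passive] > 0)) { a <- z; break }
      neg <- passive & z <= 0
      alpha <- min(a[neg] / (a[neg] - z[neg]))
      a <- a + alpha * (z - a)
      passive <- passive & a > 1e-12
      a[!passive] <- 0
    }
  }
  a
}

new_admix_fit <- function(weights, et, iterations, converged, solver, cv_names) {
  names(weights) <- cv_names
  structure(list(weights = weights, epsilon = et$epsilon, H = et$H, J = et$J,
                 iterations = as.integer(iterations), converged = converged,
                 solver = solver),
            class = "hg_admix_fit")
}

#' @export
print.hg_admix_fit <- function(x, ...) {
  cat("<hg_admix_fit> ", length(x$weights), " weights; H = ",
      format(x$H, digits = 4), ", J = ", format(x$J, digits = 4),
      " (", x$solver, ", ", x$iterations, " iterations)\n", sep = "")
  invisible(x)
}

#' @rdname solve_weights
#' @param x,object An `hg_admix_fit`.
#' @param ... Unused.
#' @method tidy hg_admix_fit
#' @method tidy hg_admix
#' @export
tidy.hg_admix_fit <- function(x, ...) {
  tibble::tibble(cv = names(x$weights), weight = unname(x$weights))
}

#' @rdname solve_weights
#' @method glance hg_admix_fit
#' @method glance hg_admix
#' @export
glance.hg_admix_fit <- function(x, ...) {
  tibble::tibble(H = x$H, J = x$J, iterations = x$iterations,
                 converged = x$converged, solver = x$solver)
}

#' Fit the admixture model to every population
#'
#' Runs [solve_weights()] for each usable population row of a frequency
#' matrix against a common set of central vectors, and reports the weight
#' table (one column per CV) together with the error power `H` and
#' normalized error `J` per population, plus the mean `J` across
#' populations. A failing per-population fit is flagged rather than
#' aborting the batch.
#'
#' @param freq An `hg_freq` tibble or numeric population matrix.
#' @inheritParams solve_weights
#' @return A tibble of class `hg_admix` with columns `population`, one
#'   weight column per central vector, `H`, `J`, `iterations`, `converged`,
#'   `failed`; attribute `mean_J`.
#' @export
fit_admixture <- function(freq, cvset, learning_rate = 0.1, tol = 1e-12,
                          max_iter = 1e5, nonneg = FALSE,
                          solver = c("gradient", "exact")) {
  solver <- match.arg(solver)
  m <- hg_matrix(freq)
  v <- cv_matrix(cvset)
  if (ncol(m) != ncol(v))
    stop("frequency matrix and central vectors have different dimension (",
         ncol(m), " vs ", ncol(v), ")", call. = FALSE)
  rows <- purrr::map(seq_len(nrow(m)), function(i) {
    fit <- tryCatch(
      solve_weights(m[i, ], v, learning_rate = learning_rate, tol = tol,
                    max_iter = max_iter, nonneg = nonneg, solver = solver),
      error = function(e) NULL)
    if (is.null(fit)) {
      w <- rep(NA_real_, nrow(v))
      names(w) <- rownames(v)
      tibble::tibble(population = rownames(m)[i], !!!w, H = NA_real_,
                     J = NA_real_, iterations = NA_integer_,
                     converged = NA, failed = TRUE)
    } else {
      tibble::tibble(population = rownames(m)[i], !!!fit$weights, H = fit$H,
                     J = fit$J, iterations = fit$iterations,
                     converged = fit$converged, failed = FALSE)
    }
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("hg_admix", class(out)),
            mean_J = mean(out$J, na.rm = TRUE), cv_names = rownames(v))
}

#' @export
print.hg_admix <- function(x, ...) {
  cat("<hg_admix> ", nrow(x), " populations x ",
      length(attr(x, "cv_names")), " central vectors; mean J = ",
      format(attr(x, "mean_J"), digits = 4), "\n", sep = "")
  NextMethod()
}

#' @rdname fit_admixture
#' @param x,object An `hg_admix` table.
#' @param ... Unused.
#' @export
glance.hg_admix <- function(x, ...) {
  tibble::tibble(n_populations = nrow(x),
                 n_cvs = length(attr(x, "cv_names")),
                 mean_J = attr(x, "mean_J"),
                 n_failed = sum(x$failed))
}

#' @rdname fit_admixture
#' @export
tidy.hg_admix <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x)[, c("population", attr(x, "cv_names"))],
                      -"population", names_to = "cv", values_to = "weight")
}
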