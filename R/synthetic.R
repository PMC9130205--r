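# Run `expr` under a local RNG state seeded with `seed`.
with_local_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Token-prefix-free synthetic haplogroup basis labels
#'
#' Generates `D` depth-2 labels (letter run + digit) such that no label is a
#' token-prefix of another, so cumulating assignment of any extended
#' subclade label recovers its basis label exactly.
#'
#' @param D Number of labels.
#' @return Character vector of labels (`A1`, `B1`, ..., `A2`, ...).
#' @export
synthetic_basis_labels <- function(D) {
  stopifnot(D >= 1, D <= 26 * 99)
  paste0(LETTERS[(seq_len(D) - 1L) %% 26L + 1L],
         (seq_len(D) - 1L) %/% 26L + 1L)
}

#' Planted ancestral haplogroup frequency profiles
#'
#' Draws `K` Dirichlet-distributed frequency profiles over a `D`-dimensional
#' synthetic haplogroup basis. These play the role of the hypothetical
#' ancestral populations (the planted central vectors).
#'
#' @param K Number of profiles (>= 1).
#' @param D Basis dimension (>= 2).
#' @param concentration Symmetric Dirichlet concentration parameter; small
#'   values give sparse, well-separated profiles, large values approach the
#'   uniform distribution 1/D. Default 0.5.
#' @param seed Integer seed.
#' @return K x D matrix; rows sum to 1, columns named by
#'   [synthetic_basis_labels()], rows `profile1...profileK`.
#' @export
generate_profiles <- function(K, D, concentration = 0.5, seed = 1L) {
  stopifnot(K >= 1, D >= 2)
  if (concentration <= 0) stop("`concentration` must be > 0", call. = FALSE)
  with_local_seed(seed, {
    g <- matrix(stats::rgamma(K * D, shape = concentration), K, D)
    zero <- rowSums(g) == 0  # possible underflow at tiny concentration
    g[zero, ] <- 1
    p <- g / rowSums(g)
    dimnames(p) <- list(paste0("profile", seq_len(K)), synthetic_basis_labels(D))
    p
  })
}

#' Synthetic populations from planted ancestral profiles
#'
#' Builds `P` population frequency vectors from the planted profiles. In
#' `"pure"` mode each population copies one source profile (cycled over the
#' K profiles) plus truncated Gaussian noise (negative entries clipped to
#' zero) and renormalization; in `"admixed"` mode each population is a
#' convex combination of all profiles with Dirichlet-drawn weights, noised
#' the same way. The planted truth (profiles, mixture weights, partition)
#' is stored in the `truth` attribute.
#'
#' @param profiles K x D profile matrix from [generate_profiles()].
#' @param P Number of populations, >= K.
#' @param mixture_mode `"pure"` (default) or `"admixed"`.
#' @param noise_sd Standard deviation of the per-coordinate Gaussian noise
#'   before clipping, default 0.01.
#' @param weight_concentration Dirichlet concentration of the admixture
#'   weights (admixed mode), default 1 (uniform over the simplex).
#' @param seed Integer seed.
#' @return An `hg_freq` tibble (population rows, basis columns), with
#'   attribute `truth`: list with `ancestral_profiles`, `mixture_weights`
#'   (P x K), `planted_partition` (named integer vector), `noise_sd`,
#'   `mixture_mode`, `seed`.
#' @export
generate_populations <- function(profiles, P, mixture_mode = c("pure", "admixed"),
                                 noise_sd = 0.01, weight_concentration = 1,
                                 seed = 1L) {
  mixture_mode <- match.arg(mixture_mode)
  stopifnot(is.matrix(profiles))
  K <- nrow(profiles)
  D <- ncol(profiles)
  if (P < K) stop("`P` must be >= the number of profiles", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)

  with_local_seed(seed, {
    pops <- sprintf("pop%03d", seq_len(P))
    if (mixture_mode == "pure") {
      source <- rep_len(seq_len(K), P)
      w <- matrix(0, P, K)
      w[cbind(seq_len(P), source)] <- 1
    } else {
      g <- matrix(stats::rgamma(P * K, shape = weight_concentration), P, K)
      g[rowSums(g) == 0, ] <- 1
      w <- g / rowSums(g)
      source <- max.col(w, ties.method = "first")
    }
    values <- w %*% profiles
    if (noise_sd > 0) {
      values <- values + matrix(stats::rnorm(P * D, sd = noise_sd), P, D)
      values[values < 0] <- 0
      values[rowSums(values) == 0, ] <- 1 / D
      values <- values / rowSums(values)
    }
    dimnames(values) <- list(pops, colnames(profiles))
    dimnames(w) <- list(pops, rownames(profiles))
    names(source) <- pops

    out <- tibble::tibble(population = pops,
                          n_total = NA_integer_, n_classified = NA_integer_)
    out <- dplyr::bind_cols(out, tibble::as_tibble(values))
    structure(out,
              class = c("hg_freq", class(out)),
              basis = hg_basis(colnames(profiles)),
              mode = "synthetic", normalization = "classified",
              unusable = character(0),
              truth = list(ancestral_profiles = profiles, mixture_weights = w,
                           planted_partition = source, noise_sd = noise_sd,
                           mixture_mode = mixture_mode, seed = seed))
  })
}

# One random subclade token continuing a label whose last token is
# alphabetic (`last_alpha = TRUE`) or numeric.
random_subclade_token <- function(last_alpha) {
  if (last_alpha) {
    as.character(sample.int(99L, 1L))
  } else {
    paste0(sample(letters, sample.int(2L, 1L), replace = TRUE), collapse = "")
  }
}

#' Sample per-individual haplogroup records from a frequency matrix
#'
#' Draws `n_per_pop` individuals per population from its frequency vector
#' (multinomial sampling over the basis) and deepens each drawn basis label
#' into a random legal subclade: with probability `subclade_prob` per level
#' a new token (alternating digit/letter runs, 1-2 characters) is appended,
#' up to a total depth of `subclade_depth_max`. Extensions never collide
#' with an existing basis label, so cumulating re-assignment recovers the
#' drawn basis label exactly.
#'
#' @param freq An `hg_freq` tibble (rows must be usable).
#' @param n_per_pop Individuals per population, >= 1.
#' @param subclade_depth_max Maximal label depth after extension, default 7.
#' @param subclade_prob Per-level extension probability, default 0.5.
#' @param seed Integer seed.
#' @return Individual tibble (`sample_id`, `population_id`, `haplogroup`)
#'   with attribute `drawn_basis`: the basis label drawn for every
#'   individual (the recovery truth).
#' @export
sample_individuals <- function(freq, n_per_pop, subclade_depth_max = 7L,
                               subclade_prob = 0.5, seed = 1L) {
  stopifnot(n_per_pop >= 1)
  if (subclade_prob < 0 || subclade_prob > 1)
    stop("`subclade_prob` must be in [0, 1]", call. = FALSE)
  m <- hg_matrix(freq)
  basis <- colnames(m)
  basis_set <- as.environment(stats::setNames(as.list(rep(TRUE, length(basis))),
                                              basis))
  with_local_seed(seed, {
    per_pop <- purrr::map(seq_len(nrow(m)), function(i) {
      draws <- sample(basis, n_per_pop, replace = TRUE, prob = m[i, ])
      tibble::tibble(population_id = rownames(m)[i], drawn = draws)
    })
    tab <- dplyr::bind_rows(per_pop)
    tab$sample_id <- sprintf("ind%06d", seq_len(nrow(tab)))

    extend_one <- function(label) {
      toks <- hg_tokenize(label)[[1]]
      while (length(toks) < subclade_depth_max &&
             stats::runif(1) < subclade_prob) {
        last_alpha <- grepl("^[A-Za-z]", toks[length(toks)])
        ok <- FALSE
        for (try in 1:5) {
          cand <- c(toks, random_subclade_token(last_alpha))
          if (!exists(paste0(cand, collapse = ""), envir = basis_set,
                      inherits = FALSE)) {
            toks <- cand; ok <- TRUE; break
          }
        }
        if (!ok) break
      }
      paste0(toks, collapse = "")
    }
    tab$haplogroup <- if (subclade_prob == 0) tab$drawn else
      vapply(tab$drawn, extend_one, "", USE.NAMES = FALSE)

    out <- tibble::tibble(sample_id = tab$sample_id,
                          population_id = tab$population_id,
                          haplogroup = tab$haplogroup)
    attr(out, "drawn_basis") <- tab$drawn
    out
  })
}

#' One-call synthetic dataset with recorded truth
#'
#' Convenience wrapper chaining [generate_profiles()],
#' [generate_populations()] and [sample_individuals()].
#'
#' @inheritParams generate_profiles
#' @inheritParams generate_populations
#' @inheritParams sample_individuals
#' @param n_per_pop Individuals sampled per population.
#' @return List with `individuals`, `freq` (the planted frequency matrix),
#'   `profiles`, `basis`, `truth`.
#' @export
simulate_hg_dataset <- function(K = 5L, P = 60L, D = 20L, n_per_pop = 200L,
                                concentration = 0.5,
                                mixture_mode = "admixed", noise_sd = 0.01,
                                subclade_depth_max = 7L, subclade_prob = 0.5,
                                seed = 1L) {
  profiles <- generate_profiles(K, D, concentration, seed = seed)
  freq <- generate_populations(profiles, P, mixture_mode = mixture_mode,
                               noise_sd = noise_sd, seed = seed + 1L)
  individuals <- sample_individuals(freq, n_per_pop,
                                    subclade_depth_max = subclade_depth_max,
                                    subclade_prob = subclade_prob,
                                    seed = seed + 2L)
  list(individuals = individuals, freq = freq, profiles = profiles,
       basis = attr(freq, "basis"), truth = attr(freq, "truth"))
}
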