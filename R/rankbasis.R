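#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, as used to detect jointly
#' propagating haplogroup pairs. Thin wrapper over
#' `stats::cor(method = "spearman")` that errors on constant input instead
#' of returning `NA`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A single value in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rank correlation undefined for a constant vector", call. = FALSE)
  stats::cor(x, y, method = "spearman")
}

# Spearman rho returning -Inf instead of erroring on degenerate input,
# for use inside the greedy subset search.
spearman_or_neg_inf <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(-Inf)
  stats::cor(x, y, method = "spearman")
}

#' Greedy population-subset search for a correlating haplogroup pair
#'
#' High rank correlations between haplogroup frequencies cannot be expected
#' over a full heterogeneous population set; they emerge in subsets of
#' populations that shared the relevant migrations. `best_subset()`
#' reconstructs the iterative search: starting from all populations it
#' repeatedly removes the single population whose removal maximizes the
#' Spearman correlation (ties broken by lowest population index), until the
#' correlation reaches `rho_min` or only `min_pops` populations remain.
#'
#' @param x,y Numeric frequency vectors over the same populations.
#' @param rho_min Acceptance threshold on the rank correlation, default 0.8.
#' @param min_pops Minimal number of retained populations, default 10.
#' @param pop_ids Optional population identifiers (default integer indices).
#' @return A list of class `hg_pair` with elements `rho`, `support`
#'   (retained ids), `accepted` (`rho >= rho_min` with
#'   `length(support) >= min_pops`), `removed` (ids in removal order).
#' @export
best_subset <- function(x, y, rho_min = 0.8, min_pops = 10L, pop_ids = NULL) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (min_pops < 3L) stop("`min_pops` must be >= 3", call. = FALSE)
  if (length(x) < min_pops)
    stop("fewer populations than `min_pops`", call. = FALSE)
  if (is.null(pop_ids)) pop_ids <- seq_along(x)

  keep <- seq_along(x)
  rho <- spearman_or_neg_inf(x, y)
  removed <- integer(0)
  while (rho < rho_min && length(keep) > min_pops) {
    cand <- vapply(seq_along(keep), function(i) {
      k <- keep[-i]
      spearman_or_neg_inf(x[k], y[k])
    }, 0.0)
    best <- which.max(cand)  # which.max takes the first (lowest-index) tie
    if (!is.finite(cand[best]) && !is.finite(rho)) break
    removed <- c(removed, keep[best])
    keep <- keep[-best]
    rho <- cand[best]
  }
  structure(list(rho = rho,
                 support = pop_ids[keep],
                 accepted = is.finite(rho) && rho >= rho_min &&
                   length(keep) >= min_pops,
                 removed = pop_ids[removed]),
            class = "hg_pair")
}

#' @export
print.hg_pair <- function(x, ...) {
  cat("<hg_pair> rho = ", format(x$rho, digits = 4), ", support = ",
      length(x$support), if (x$accepted) " [accepted]" else " [rejected]",
      "\n", sep = "")
  invisible(x)
}

#' Select the jointly propagating haplogroup basis
#'
#' For every pair of basis haplogroups, runs the greedy population-subset
#' search ([best_subset()]) and accepts the pair when a rank correlation of
#' at least `rho_min` is found over at least `min_pops` populations. The
#' returned basis keeps exactly the haplogroups with at least one accepted
#' partner -- the "jointly propagating" set.
#'
#' Zero-frequency populations are retained in the rank vectors (tied at the
#' bottom rank): absence of a haplogroup is informative for propagation.
#'
#' Selection runs in two exact stages. First, all-pairs Spearman
#' correlations over the full population set are computed in one vectorized
#' pass; any pair at or above `rho_min` is accepted outright (support = all
#' populations). Second, only haplogroups still without a partner enter the
#' greedy subset search, trying partners in decreasing full-set correlation
#' and stopping at their first accepted pair. The selected haplogroup set is
#' identical to running the subset search on every pair; the reported pair
#' list is a *witness* list (at least one accepted partner per selected
#' haplogroup), not an exhaustive enumeration.
#'
#' @param freq An `hg_freq` tibble (or numeric matrix) of population
#'   frequencies; unusable populations are dropped.
#' @param rho_min Acceptance threshold on Spearman's rho, default 0.8.
#' @param min_pops Minimal supporting populations, default 10.
#' @return The selected [hg_basis()], with attribute `pairs`: a tibble of
#'   witness pairs (`hg_a`, `hg_b`, `rho`, `n_support`).
#' @export
select_correlating_hgs <- function(freq, rho_min = 0.8, min_pops = 10L) {
  m <- hg_matrix(freq)
  if (nrow(m) < min_pops)
    stop("need at least `min_pops` = ", min_pops, " usable populations, got ",
         nrow(m), call. = FALSE)
  labs <- colnames(m)
  D <- ncol(m)
  P <- nrow(m)
  acc <- vector("list", 0L)
  has_partner <- logical(D)
  if (D >= 2L) {
    # stage 1: vectorized all-pairs Spearman over the full population set
    ranks <- apply(m, 2L, rank)
    sds <- apply(ranks, 2L, stats::sd)
    full_rho <- suppressWarnings(stats::cor(ranks))
    full_rho[sds == 0, ] <- -Inf
    full_rho[, sds == 0] <- -Inf
    diag(full_rho) <- -Inf
    hits <- which(upper.tri(full_rho) & full_rho >= rho_min, arr.ind = TRUE)
    if (nrow(hits) > 0L) {
      has_partner[unique(c(hits))] <- TRUE
      acc[[1L]] <- tibble::tibble(hg_a = labs[hits[, 1L]],
                                  hg_b = labs[hits[, 2L]],
                                  rho = full_rho[hits],
                                  n_support = P)
    }
    # stage 2: greedy subset search only for still-unmatched haplogroups,
    # most promising partners first, stopping at the first acceptance
    for (a in which(!has_partner)) {
      if (has_partner[a]) next   # matched as a partner earlier in this loop
      for (b in order(full_rho[a, ], decreasing = TRUE)) {
        if (b == a || !is.finite(full_rho[a, b])) next
        res <- best_subset(m[, a], m[, b], rho_min = rho_min,
                           min_pops = min_pops, pop_ids = rownames(m))
        if (res$accepted) {
          has_partner[c(a, b)] <- TRUE
          acc[[length(acc) + 1L]] <- tibble::tibble(
            hg_a = labs[min(a, b)], hg_b = labs[max(a, b)], rho = res$rho,
            n_support = length(res$support))
          break
        }
      }
    }
  }
  pairs <- if (length(acc) > 0L) dplyr::bind_rows(acc) else
    tibble::tibble(hg_a = character(), hg_b = character(),
                   rho = double(), n_support = integer())
  out <- hg_basis(labs[has_partner])
  attr(out, "pairs") <- pairs
  attr(out, "params") <- list(rho_min = rho_min, min_pops = min_pops)
  out
}
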