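# Shared fixtures built in code.

# The worked assignment example: basis {A, B, A1, B2a}, one population of four
# individuals carrying A2a1, A1b, B2a3 and B.
example_basis <- function() hg_basis(c("A", "B", "A1", "B2a"))

example_individuals <- function(pop = "P1") {
  tibble::tibble(sample_id = paste0("s", 1:4),
                 population_id = pop,
                 haplogroup = c("A2a1", "A1b", "B2a3", "B"))
}

# Character-walk tokenizer: counts alternating letter/digit runs without
# regular expressions. Independent oracle for hg_tokenize()/hg_depth().
walk_tokens <- function(label) {
  chars <- strsplit(label, "")[[1]]
  is_digit <- chars %in% as.character(0:9)
  tokens <- character(0)
  cur <- chars[1]
  for (i in seq_along(chars)[-1]) {
    if (is_digit[i] == is_digit[i - 1]) {
      cur <- paste0(cur, chars[i])
    } else {
      tokens <- c(tokens, cur)
      cur <- chars[i]
    }
  }
  c(tokens, cur)
}

# Brute-force cumulating assignment: enumerate every token-prefix of the
# query and intersect with the basis, keeping the deepest hit.
brute_assign <- function(label, basis) {
  toks <- walk_tokens(label)
  prefixes <- vapply(seq_along(toks),
                     function(k) paste0(toks[1:k], collapse = ""), "")
  hit <- prefixes[prefixes %in% as.character(basis)]
  if (length(hit) == 0L) NA_character_ else hit[length(hit)]
}

# Two well-separated Gaussian point clouds in D dimensions.
two_clouds <- function(n = 25, D = 6, sep = 10, sd = 0.05, seed = 42) {
  withr::with_seed(seed, {
    mu1 <- rep(0, D)
    mu2 <- c(sep * sd, rep(0, D - 1))
    m <- rbind(matrix(stats::rnorm(n * D, sd = sd), n, D) +
                 matrix(mu1, n, D, byrow = TRUE),
               matrix(stats::rnorm(n * D, sd = sd), n, D) +
                 matrix(mu2, n, D, byrow = TRUE))
    rownames(m) <- paste0("p", seq_len(2 * n))
    list(m = m, mu = rbind(mu1, mu2),
         partition = rep(1:2, each = n), n = n, sd = sd)
  })
}

# Do two cluster assignments define the same partition?
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# Random orthonormal rows (N x D, N <= D).
orthonormal_cvs <- function(N, D, seed = 1) {
  withr::with_seed(seed, {
    q <- qr.Q(qr(matrix(stats::rnorm(D * D), D, D)))
    v <- t(q[, seq_len(N), drop = FALSE])
    rownames(v) <- paste0("CV", seq_len(N))
    v
  })
}

# Least-squares residual power via the normal equations (independent oracle
# for the gradient search); pseudoinverse handles rank deficiency.
oracle_H <- function(h, v) {
  a <- qr.coef(qr(t(v), LAPACK = TRUE), h)
  a[is.na(a)] <- 0
  # refine through the pseudoinverse for rank-deficient systems
  sv <- svd(t(v))
  pos <- sv$d > max(dim(v)) * .Machine$double.eps * max(sv$d)
  a <- drop(sv$v[, pos, drop = FALSE] %*%
              (crossprod(sv$u[, pos, drop = FALSE], h) / sv$d[pos]))
  sum((h - drop(crossprod(v, a)))^2)
}
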