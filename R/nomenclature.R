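#' Tokenize a hierarchical haplogroup label
#'
#' Mitochondrial haplogroup names encode the phylogeny as alternating runs of
#' letters and digits: `H`, `H1`, `H1a`, `H13a`, `K1a1b1a`. `hg_tokenize()`
#' splits a label into these runs; the number of runs is the label's
#' *phylogenetic depth* (`H1a` has depth 3, `K1a1b1a` depth 7).
#'
#' The first token is the maximal leading alphabetic run, so two-letter clades
#' such as `HV` or `JT` are a single token of depth 1. Case is normalized to
#' the published convention: the leading run is uppercased, later alphabetic
#' runs are lowercased (`hv0A` becomes `HV0a`).
#'
#' @param raw Character vector of haplogroup labels. Each must be non-empty,
#'   start with a letter and contain only letters and digits.
#' @return A list (one element per input label) of character vectors of
#'   tokens, named by the canonical-case label.
#' @examples
#' hg_tokenize("H13a")     # "H" "13" "a"
#' hg_tokenize("K1a1b1a")  # depth 7
#' @seealso [hg_depth()], [hg_truncate()], [hg_assign()]
#' @export
hg_tokenize <- function(raw) {
  stopifnot(is.character(raw))
  bad <- is.na(raw) | !nzchar(raw) | !grepl("^[A-Za-z][A-Za-z0-9]*$", raw)
  if (any(bad)) {
    stop("malformed haplogroup label(s): ",
         paste(utils::head(ifelse(is.na(raw[bad]), "<NA>",
                                  paste0("'", raw[bad], "'")), 5L),
               collapse = ", "),
         " (labels must be non-empty, start with a letter and contain only ",
         "letters and digits)", call. = FALSE)
  }
  toks <- regmatches(raw, gregexpr("[A-Za-z]+|[0-9]+", raw))
  toks <- lapply(toks, function(tk) {
    tk[1L] <- toupper(tk[1L])
    if (length(tk) > 1L) {
      alpha <- grepl("^[A-Za-z]", tk)
      alpha[1L] <- FALSE
      tk[alpha] <- tolower(tk[alpha])
    }
    tk
  })
  names(toks) <- vapply(toks, paste0, "", collapse = "")
  toks
}

#' Phylogenetic depth of haplogroup labels
#'
#' @inheritParams hg_tokenize
#' @return Integer vector of token counts (`"H"` is 1, `"HV0a"` is 3).
#' @examples
#' hg_depth(c("H", "HV", "U5a", "K1a1b1a"))  # 1 1 3 7
#' @export
hg_depth <- function(raw) {
  lengths(hg_tokenize(raw), use.names = FALSE)
}

#' Canonical form of haplogroup labels
#'
#' Re-assembles labels from their tokens with canonical casing (leading run
#' uppercase, later alphabetic runs lowercase). Used internally before any
#' label comparison.
#'
#' @inheritParams hg_tokenize
#' @return Character vector of canonical labels.
#' @export
hg_canonical <- function(raw) {
  names(hg_tokenize(raw))
}

#' Truncate haplogroup labels to a maximal phylogenetic depth
#'
#' Keeps the first `max_depth` tokens of each label; labels already at or
#' below the depth are returned unchanged (the operation is idempotent).
#'
#' @inheritParams hg_tokenize
#' @param max_depth Maximal number of tokens to keep (>= 1).
#' @return Character vector of truncated canonical labels.
#' @examples
#' hg_truncate("A2a1", 3)     # "A2a"
#' hg_truncate("K1a1b1a", 3)  # "K1a"
#' @export
hg_truncate <- function(raw, max_depth = 3L) {
  if (!is.numeric(max_depth) || length(max_depth) != 1L || max_depth < 1)
    stop("`max_depth` must be a single integer >= 1", call. = FALSE)
  max_depth <- as.integer(max_depth)
  toks <- hg_tokenize(raw)
  vapply(toks, function(tk) paste0(tk[seq_len(min(length(tk), max_depth))],
                                   collapse = ""), "", USE.NAMES = FALSE)
}

#' Construct a haplogroup basis
#'
#' A basis is a duplicate-free, canonically ordered set of haplogroup labels
#' that defines the coordinate axes of all population frequency vectors.
#' Labels are canonicalized, deduplicated and sorted (C-locale alphabetical
#' order, which groups clades by their leading letters).
#'
#' @param labels Character vector of haplogroup labels.
#' @return Character vector of class `hg_basis`.
#' @export
hg_basis <- function(labels) {
  labels <- hg_canonical(labels)
  labels <- sort(unique(labels), method = "radix")
  structure(labels, class = c("hg_basis", "character"))
}

#' @export
print.hg_basis <- function(x, ...) {
  cat("<hg_basis> ", length(x), " haplogroups\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

# All token-prefixes of one tokenized label, shallowest first.
token_prefixes <- function(tokens) {
  vapply(seq_along(tokens),
         function(k) paste0(tokens[seq_len(k)], collapse = ""), "")
}

#' Assign haplogroup labels to a common basis
#'
#' Maps each observed (possibly deeply classified) haplogroup label onto a
#' common basis by one of two rules:
#'
#' * **cumulating** -- the label is assigned to the *deepest* basis member
#'   that is a token-level prefix of it, i.e. to its nearest ancestor present
#'   in the basis. With basis `{A, B, A1, B2a}`, `A2a1` goes to `A`, `A1b`
#'   to `A1`, `B2a3` to `B2a` and `B` to `B`. Prefixes are token-level, not
#'   string-level: `H1` is *not* an ancestor of `H13a`.
#' * **cutting** -- only labels literally present in the basis survive;
#'   anything deeper is unassigned.
#'
#' Labels with no match are returned as `NA` (an explicit unassigned
#' sentinel); callers decide whether to drop them.
#'
#' @inheritParams hg_tokenize
#' @param basis An [hg_basis()] or character vector of basis labels.
#' @param mode `"cumulating"` (default) or `"cutting"`.
#' @return Character vector, same length as `raw`: the assigned basis label
#'   or `NA_character_` when unassigned.
#' @examples
#' b <- hg_basis(c("A", "B", "A1", "B2a"))
#' hg_assign(c("A2a1", "A1b", "B2a3", "B"), b)  # "A" "A1" "B2a" "B"
#' hg_assign("A2a1", b, mode = "cutting")       # NA
#' @export
hg_assign <- function(raw, basis, mode = c("cumulating", "cutting")) {
  mode <- match.arg(mode)
  basis <- hg_canonical(as.character(basis))
  if (length(basis) == 0L) stop("`basis` is empty", call. = FALSE)
  toks <- hg_tokenize(raw)
  if (mode == "cutting") {
    canon <- names(toks)
    out <- ifelse(canon %in% basis, canon, NA_character_)
    names(out) <- NULL
    return(out)
  }
  vapply(toks, function(tk) {
    hits <- match(token_prefixes(tk), basis)
    hits <- hits[!is.na(hits)]
    if (length(hits) == 0L) NA_character_ else basis[hits[length(hits)]]
  }, "", USE.NAMES = FALSE)
}
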