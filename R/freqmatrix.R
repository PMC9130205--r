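#' Read a per-individual haplogroup table
#'
#' Reads a delimited text file (TSV by default) with one row per individual
#' and at least the columns `sample_id`, `population_id` and `haplogroup`.
#' Rows whose haplogroup label cannot be tokenized (empty, leading digit,
#' illegal characters) are dropped with a warning; the number of rejected
#' rows is stored in the `rejected` attribute.
#'
#' @param file Path to the delimited file (or a connection).
#' @param delim Field delimiter, default tab.
#' @return A tibble with columns `sample_id`, `population_id`, `haplogroup`
#'   (canonical-case labels), attribute `rejected` = number of dropped rows.
#' @export
read_individuals <- function(file, delim = "\t") {
  tab <- readr::read_delim(file, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  names(tab) <- tolower(names(tab))
  if (!"haplogroup" %in% names(tab) && "haplogroup_label" %in% names(tab))
    tab <- dplyr::rename(tab, haplogroup = "haplogroup_label")
  need <- c("sample_id", "population_id", "haplogroup")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L)
    stop("individual table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  tab <- dplyr::select(tab, dplyr::all_of(need))
  ok <- !is.na(tab$haplogroup) & grepl("^[A-Za-z][A-Za-z0-9]*$", tab$haplogroup)
  n_bad <- sum(!ok)
  if (n_bad > 0L) {
    warning(n_bad, " row(s) with malformed haplogroup labels skipped (e.g. ",
            paste0("'", utils::head(tab$haplogroup[!ok], 3L), "'", collapse = ", "),
            ")", call. = FALSE)
    tab <- tab[ok, , drop = FALSE]
  }
  tab$haplogroup <- hg_canonical(tab$haplogroup)
  if (anyDuplicated(tab$sample_id))
    warning("duplicated sample_id values present", call. = FALSE)
  attr(tab, "rejected") <- n_bad
  tab
}

#' Candidate haplogroup basis at a maximal depth
#'
#' Truncates every observed label to `max_depth` tokens and returns the
#' deduplicated canonical set. This is the raw candidate basis before the
#' prevalence and correlation filters.
#'
#' @param individuals Tibble with a `haplogroup` column (see
#'   [read_individuals()]).
#' @param max_depth Maximal phylogenetic depth (tokens) retained, default 3.
#' @return An [hg_basis()].
#' @export
candidate_basis <- function(individuals, max_depth = 3L) {
  stopifnot(is.data.frame(individuals))
  if (nrow(individuals) == 0L) stop("individual table is empty", call. = FALSE)
  hg_basis(hg_truncate(individuals$haplogroup, max_depth))
}

#' Filter a basis by database-wide prevalence
#'
#' Assigns every individual in the whole table to the basis (under `mode`)
#' and keeps only basis labels whose pooled assignment count, divided by the
#' total number of individuals, strictly exceeds `threshold`. A label at
#' exactly the threshold frequency is removed.
#'
#' @inheritParams candidate_basis
#' @param basis An [hg_basis()].
#' @param threshold Minimal database-wide frequency, default 0.0005.
#' @param mode Assignment rule, `"cumulating"` (default) or `"cutting"`;
#'   counts are computed under the same rule used downstream.
#' @return The filtered [hg_basis()].
#' @export
prevalence_filter <- function(individuals, basis, threshold = 5e-4,
                              mode = c("cumulating", "cutting")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(individuals))
  if (nrow(individuals) == 0L) stop("individual table is empty", call. = FALSE)
  if (threshold < 0 || threshold > 1)
    stop("`threshold` must be in [0, 1]", call. = FALSE)
  assigned <- hg_assign(individuals$haplogroup, basis, mode)
  counts <- table(factor(assigned, levels = as.character(basis)))
  keep <- as.vector(counts) / nrow(individuals) > threshold
  hg_basis(as.character(basis)[keep])
}

#' Build a population-by-haplogroup frequency matrix
#'
#' Assigns each individual to the basis under the chosen rule and tabulates
#' per-population frequencies. With `normalization = "classified"` (default)
#' each usable population row sums to 1 over the basis axes; with `"total"`
#' the denominator is the full population size including unassigned
#' individuals. Populations with no classifiable individual are flagged
#' unusable: their rows carry `NA` frequencies and their ids are stored in
#' the `unusable` attribute.
#'
#' @inheritParams prevalence_filter
#' @param normalization `"classified"` (default) or `"total"`.
#' @return A tibble of class `hg_freq` with columns `population`, `n_total`,
#'   `n_classified`, then one frequency column per basis label (in basis
#'   order). Attributes: `basis` ([hg_basis()]), `mode`, `normalization`,
#'   `unusable` (character vector of unusable population ids).
#' @examples
#' ind <- tibble::tibble(sample_id = as.character(1:4), population_id = "P",
#'                       haplogroup = c("A2a1", "A1b", "B2a3", "B"))
#' build_frequency_matrix(ind, hg_basis(c("A", "B", "A1", "B2a")))
#' @export
build_frequency_matrix <- function(individuals, basis,
                                   mode = c("cumulating", "cutting"),
                                   normalization = c("classified", "total")) {
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  stopifnot(is.data.frame(individuals))
  if (length(basis) == 0L) stop("`basis` is empty", call. = FALSE)
  basis <- hg_basis(as.character(basis))

  tab <- tibble::tibble(
    population = as.character(individuals$population_id),
    assigned   = hg_assign(individuals$haplogroup, basis, mode)
  )
  pops <- sort(unique(tab$population), method = "radix")
  counts <- table(factor(tab$population, levels = pops),
                  factor(tab$assigned, levels = as.character(basis)))
  counts <- matrix(as.integer(counts), nrow = length(pops),
                   dimnames = list(pops, as.character(basis)))
  n_total <- as.integer(table(factor(tab$population, levels = pops)))
  n_classified <- as.integer(rowSums(counts))
  denom <- if (normalization == "classified") n_classified else n_total
  values <- counts / ifelse(denom == 0L, NA_integer_, denom)
  unusable <- pops[n_classified == 0L]
  if (length(unusable) > 0L)
    values[n_classified == 0L, ] <- NA_real_

  out <- tibble::tibble(population = pops, n_total = n_total,
                        n_classified = n_classified)
  out <- dplyr::bind_cols(out, tibble::as_tibble(values))
  structure(out,
            class = c("hg_freq", class(out)),
            basis = basis, mode = mode, normalization = normalization,
            unusable = unusable)
}

#' @export
print.hg_freq <- function(x, ...) {
  cat("<hg_freq> ", nrow(x), " populations x ", length(attr(x, "basis")),
      " haplogroups (", attr(x, "mode"), ", ", attr(x, "normalization"),
      "-normalized)\n", sep = "")
  if (length(attr(x, "unusable")) > 0L)
    cat("unusable populations: ", paste(attr(x, "unusable"), collapse = ", "),
        "\n", sep = "")
  NextMethod()
}

#' Extract the numeric frequency matrix from an `hg_freq` tibble
#'
#' @param freq An `hg_freq` tibble (see [build_frequency_matrix()]) or any
#'   data frame whose first character column labels rows and whose numeric
#'   columns are the axes; a plain numeric matrix passes through.
#' @param drop_unusable Drop rows containing `NA` frequencies (with a
#'   warning naming them)? Default `TRUE`.
#' @return Numeric matrix, rows = populations (rownames set), columns = axes.
#' @export
hg_matrix <- function(freq, drop_unusable = TRUE) {
  if (is.matrix(freq)) {
    m <- freq
    if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  } else {
    stopifnot(is.data.frame(freq))
    basis <- attr(freq, "basis")
    if (!is.null(basis)) {
      m <- as.matrix(freq[, as.character(basis), drop = FALSE])
      rownames(m) <- freq$population
    } else {
      num <- vapply(freq, is.numeric, TRUE)
      lab <- which(!num)[1]
      m <- as.matrix(freq[, num, drop = FALSE])
      rownames(m) <- if (is.na(lab)) paste0("row", seq_len(nrow(m))) else
        as.character(freq[[lab]])
    }
  }
  storage.mode(m) <- "double"
  bad <- rowSums(is.na(m)) > 0L
  if (any(bad) && drop_unusable) {
    warning("dropping ", sum(bad), " unusable population(s): ",
            paste(rownames(m)[bad], collapse = ", "), call. = FALSE)
    m <- m[!bad, , drop = FALSE]
  }
  m
}
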