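#' Read and write labeled distance matrices
#'
#' Distance matrices travel as labeled square CSV (first column = labels,
#' header row = the same labels) or as PHYLIP-style square matrix text
#' (first line = n, then one row per population: label followed by n
#' distances).
#'
#' @param file Path to the file.
#' @param format `"csv"` or `"phylip"`; `read_distance_matrix()` guesses
#'   from the first line when not given.
#' @return `read_distance_matrix()` returns an `hg_dist` matrix;
#'   `write_distance_matrix()` returns `file` invisibly.
#' @export
read_distance_matrix <- function(file, format = NULL) {
  first <- readLines(file, n = 1L)
  if (is.null(format))
    format <- if (grepl("^\\s*[0-9]+\\s*$", first)) "phylip" else "csv"
  if (format == "phylip") {
    n <- as.integer(trimws(first))
    lines <- readLines(file)[-1L]
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) != n)
      stop("PHYLIP matrix announces ", n, " rows but has ", length(lines),
           call. = FALSE)
    parts <- strsplit(trimws(lines), "\\s+")
    labs <- vapply(parts, `[[`, "", 1L)
    vals <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(n)))
    dimnames(vals) <- list(labs, labs)
    return(as_hg_dist(vals))
  }
  tab <- utils::read.csv(file, check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- as.character(tab[[1L]])
  as_hg_dist(m)
}

#' @rdname read_distance_matrix
#' @param d An `hg_dist` matrix (or labeled square matrix).
#' @export
write_distance_matrix <- function(d, file, format = c("csv", "phylip")) {
  format <- match.arg(format)
  d <- as_hg_dist(d)
  if (format == "csv") {
    tab <- data.frame(population = rownames(d), d, check.names = FALSE)
    utils::write.csv(tab, file, row.names = FALSE)
  } else {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(as.character(nrow(d)), con)
    for (i in seq_len(nrow(d)))
      writeLines(paste(c(rownames(d)[i], format(d[i, ], digits = 10,
                                                trim = TRUE)),
                       collapse = " "), con)
  }
  invisible(file)
}

#' Write an `hg_freq` frequency matrix as CSV
#'
#' Populations in rows, basis haplogroups in columns (header row = basis
#' order), preceded by the `population`, `n_total` and `n_classified`
#' columns.
#'
#' @param freq An `hg_freq` tibble.
#' @param file Path to write.
#' @export
write_frequency_matrix <- function(freq, file) {
  utils::write.csv(as.data.frame(freq), file, row.names = FALSE)
  invisible(file)
}

#' Read an `hg_freq` frequency matrix written by [write_frequency_matrix()]
#'
#' Also accepts a bare populations-by-haplogroups CSV whose first column is
#' the population label.
#'
#' @param file Path to a CSV file.
#' @return An `hg_freq` tibble.
#' @export
read_frequency_matrix <- function(file) {
  tab <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
  first <- names(tab)[1L]
  if (first != "population") tab <- dplyr::rename(tab, population = 1L)
  if (!"n_total" %in% names(tab)) tab$n_total <- NA_integer_
  if (!"n_classified" %in% names(tab)) tab$n_classified <- NA_integer_
  hgcols <- setdiff(names(tab), c("population", "n_total", "n_classified"))
  tab <- tab[, c("population", "n_total", "n_classified", hgcols)]
  nc <- rowSums(!is.na(tab[, hgcols, drop = FALSE]))
  structure(tab, class = c("hg_freq", class(tab)),
            basis = hg_basis(hgcols), mode = "file",
            normalization = "classified",
            unusable = tab$population[nc == 0L])
}

#' Import the published supplementary tables
#'
#' Optional reproduction harness for the original study's supplementary
#' workbooks (XLSX): the per-individual database, the published
#' 172-population frequency table, and the paired Euclidean/Fst distance
#' matrices for the 74 test populations. The files are *not* shipped with
#' the package and are never required by its tests; obtain them from the
#' publisher and point `path` at the directory holding them.
#'
#' The importer fails loudly (naming the file and sheet) on any layout it
#' does not recognize, rather than silently guessing.
#'
#' @param path Directory containing the supplementary XLSX files.
#' @param what One of `"individuals"`, `"frequencies"`, `"distances"`.
#' @param file File name within `path`; by default the conventional
#'   `supplementary_table_1.xlsx` / `_3` / `_5` names are tried.
#' @return For `"individuals"` an individual tibble; for `"frequencies"` an
#'   `hg_freq`; for `"distances"` a list of two `hg_dist` matrices
#'   (`euclidean`, `fst`).
#' @export
import_supplementary <- function(path, what = c("individuals", "frequencies",
                                                "distances"),
                                 file = NULL) {
  what <- match.arg(what)
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("the 'readxl' package is required to import XLSX tables", call. = FALSE)
  default <- c(individuals = "supplementary_table_1.xlsx",
               frequencies = "supplementary_table_3.xlsx",
               distances = "supplementary_table_5.xlsx")
  if (is.null(file)) file <- default[[what]]
  fp <- file.path(path, file)
  if (!file.exists(fp))
    stop("supplementary file not found: ", fp,
         " (this optional feature needs the published workbook)", call. = FALSE)
  sheets <- readxl::excel_sheets(fp)
  if (what == "individuals") {
    tab <- readxl::read_excel(fp, sheet = sheets[1L])
    names(tab) <- tolower(names(tab))
    keep <- intersect(c("sample_id", "population_id", "haplogroup"), names(tab))
    if (length(keep) < 3L)
      stop("unexpected sheet layout in ", fp, ": need columns sample_id, ",
           "population_id, haplogroup; found ",
           paste(names(tab), collapse = ", "), call. = FALSE)
    out <- tibble::as_tibble(tab[, keep])
    out$haplogroup <- hg_canonical(as.character(out$haplogroup))
    return(out)
  }
  if (what == "frequencies") {
    tab <- readxl::read_excel(fp, sheet = sheets[1L])
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(tmp))
    utils::write.csv(tab, tmp, row.names = FALSE)
    return(read_frequency_matrix(tmp))
  }
  if (length(sheets) < 2L)
    stop("unexpected workbook layout in ", fp,
         ": expected two sheets (Euclidean and Fst matrices), found ",
         length(sheets), call. = FALSE)
  read_one <- function(s) {
    tab <- as.data.frame(readxl::read_excel(fp, sheet = s))
    m <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(m) <- as.character(tab[[1L]])
    as_hg_dist(m)
  }
  list(euclidean = read_one(sheets[1L]), fst = read_one(sheets[2L]))
}
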