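#' Default pipeline configuration
#'
#' All defaults equal the study's stated analysis settings: maximal label
#' depth 3, cumulating assignment, database-wide prevalence threshold
#' 0.0005, rank-correlation acceptance at rho >= 0.8 over at least 10
#' populations, and the 1/3 radius criterion for the central-vector
#' clustering.
#'
#' @param ... Named overrides of any default.
#' @return Named list of class `hg_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(max_depth = 3L, assignment_mode = "cumulating",
              prevalence_threshold = 5e-4,
              rho_min = 0.8, min_pops = 10L,
              soc_ratio = 1/3, soc_restarts = 10L, soc_max_n = NULL,
              solver_tol = 1e-12, solver_max_iter = 1e5,
              n_permutations = 9999L, seed = 1L,
              skip_rank_selection = FALSE)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = "hg_config")
}

#' Run the full haplogroup-distribution pipeline
#'
#' Chains every stage: read individuals, build the depth-truncated candidate
#' basis, apply the prevalence filter, select the jointly propagating
#' (rank-correlating) basis, build the frequency matrix, fit the growing
#' central-vector clustering, fit the admixture model for every population,
#' compute the Euclidean distance matrix, and -- when a reference (e.g. Fst)
#' matrix is supplied -- the matrix correlation and Mantel test against it.
#' All results are written as plain-text files into `out_dir` together with
#' a run log (configuration echo, seed, per-stage counts).
#'
#' @param individuals_file Path to the per-individual TSV
#'   (`sample_id`, `population_id`, `haplogroup`), or an individual tibble.
#' @param out_dir Output directory (created if missing).
#' @param config An [pipeline_config()] list.
#' @param reference_matrix Optional path to a labeled square CSV/PHYLIP
#'   reference distance matrix, or an `hg_dist` matrix.
#' @return Invisibly, a list with all stage results (`basis`, `freq`, `soc`,
#'   `admixture`, `dist`, `mantel`, `log`).
#' @export
run_pipeline <- function(individuals_file, out_dir,
                         config = pipeline_config(),
                         reference_matrix = NULL) {
  st <- new.env()
  st$stage <- "read"
  tryCatch(
    run_pipeline_impl(individuals_file, out_dir, config, reference_matrix, st),
    error = function(e) {
      stop("pipeline failed at stage [", st$stage, "]: ",
           conditionMessage(e), call. = FALSE)
    }
  )
}

run_pipeline_impl <- function(individuals_file, out_dir, config,
                              reference_matrix, st = new.env()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(paste0("hgadmix pipeline, ", format(Sys.time(), "%Y-%m-%d")),
                 paste0("R ", getRversion(), ", hgadmix ",
                        as.character(utils::packageVersion("hgadmix"))),
                 "config:",
                 paste0("  ", names(config), " = ",
                        vapply(config, function(x)
                          if (is.null(x)) "NULL" else format(x), "")))

  st$stage <- "read"
  individuals <- if (is.data.frame(individuals_file)) individuals_file else {
    if (!file.exists(individuals_file))
      stop("input file not found: ", individuals_file, call. = FALSE)
    read_individuals(individuals_file)
  }
  log_lines <- c(log_lines,
                 paste0("individuals read: ", nrow(individuals),
                        " (rejected: ", attr(individuals, "rejected") %||% 0L, ")"))

  st$stage <- "basis"
  cand <- candidate_basis(individuals, config$max_depth)
  log_lines <- c(log_lines, paste0("candidate basis (depth <= ",
                                   config$max_depth, "): ", length(cand)))
  filt <- prevalence_filter(individuals, cand, config$prevalence_threshold,
                            mode = config$assignment_mode)
  log_lines <- c(log_lines, paste0("after prevalence filter (> ",
                                   config$prevalence_threshold, "): ",
                                   length(filt)))

  st$stage <- "rank-selection"
  if (isTRUE(config$skip_rank_selection)) {
    basis <- filt
    log_lines <- c(log_lines, "rank-correlation selection skipped by config")
  } else {
    pre_freq <- build_frequency_matrix(individuals, filt,
                                       mode = config$assignment_mode)
    basis <- select_correlating_hgs(pre_freq, rho_min = config$rho_min,
                                    min_pops = config$min_pops)
    log_lines <- c(log_lines,
                   paste0("correlating basis (rho >= ", config$rho_min,
                          " in >= ", config$min_pops, " populations): ",
                          length(basis)))
  }
  writeLines(as.character(basis), file.path(out_dir, "basis.txt"))

  st$stage <- "frequencies"
  freq <- build_frequency_matrix(individuals, basis,
                                 mode = config$assignment_mode)
  write_frequency_matrix(freq, file.path(out_dir, "frequencies.csv"))
  log_lines <- c(log_lines,
                 paste0("populations: ", nrow(freq), " (unusable: ",
                        length(attr(freq, "unusable")), ")"))

  st$stage <- "soc"
  soc <- fit_soc(freq, ratio = config$soc_ratio,
                 max_n = config$soc_max_n,
                 n_restarts = config$soc_restarts, seed = config$seed)
  utils::write.csv(data.frame(cv = rownames(soc$centers), soc$centers,
                              check.names = FALSE),
                   file.path(out_dir, "central_vectors.csv"),
                   row.names = FALSE)
  readr::write_tsv(tidy(soc), file.path(out_dir, "clusters.tsv"))
  log_lines <- c(log_lines, paste0("central vectors: ", soc$n_clusters,
                                   " (converged: ", soc$converged, ")"))

  st$stage <- "admixture"
  adm <- fit_admixture(freq, soc, tol = config$solver_tol,
                       max_iter = config$solver_max_iter)
  readr::write_tsv(tibble::as_tibble(adm), file.path(out_dir, "weights.tsv"))
  log_lines <- c(log_lines, paste0("mean normalized admixture error J = ",
                                   format(attr(adm, "mean_J"), digits = 6)))

  st$stage <- "distances"
  d <- euclidean_matrix(freq)
  write_distance_matrix(d, file.path(out_dir, "distances.csv"))

  mantel <- NULL
  if (!is.null(reference_matrix)) {
    st$stage <- "mantel"
    ref <- if (is.matrix(reference_matrix)) as_hg_dist(reference_matrix) else
      read_distance_matrix(reference_matrix)
    r <- matrix_correlation(d, ref)
    mantel <- mantel_test(d, ref, n_permutations = config$n_permutations,
                          seed = config$seed)
    writeLines(c(paste0("matrix correlation: ", format(r, digits = 6)),
                 paste0("mantel r: ", format(mantel$r_observed, digits = 6)),
                 paste0("mantel p: ", format(mantel$p_value, digits = 6)),
                 paste0("permutations: ", mantel$n_permutations),
                 paste0("seed: ", mantel$seed)),
               file.path(out_dir, "mantel.txt"))
    log_lines <- c(log_lines,
                   paste0("reference correlation = ", format(r, digits = 6),
                          ", Mantel p = ", format(mantel$p_value, digits = 6)))
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(basis = basis, freq = freq, soc = soc, admixture = adm,
                 dist = d, mantel = mantel, log = log_lines))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
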