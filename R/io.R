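# readers, writers, packaged fixtures and the pipeline driver

#' Path to a packaged example data file
#'
#' The package ships three transcriptions of the published survey of
#' *Quasipaa boulengeri*: `karyomorph_counts.csv` (individuals per
#' population, sex and karyomorph; 471 frogs from 33 populations),
#' `heteromorph_lengths.csv` (lengths in micrometres of the four focal
#' chromosomes in ten type IV cells), `idiogram_moments.csv` (per-chromosome
#' relative length and arm ratio, mean and SD, for karyomorphs I and IV)
#' and `idiogram_measurements.csv` (the moment table expanded to one
#' measurement row per homolog at the idiogram means).
#'
#' @param file file name within the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a vector of available file names).
#' @examples
#' example_path()
#' example_path("karyomorph_counts.csv")
#' @export
example_path <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "quadrivalent")))
  }
  path <- system.file("extdata", file, package = "quadrivalent")
  if (path == "") abort_schema(sprintf("no packaged example file '%s'", file))
  path
}

#' @rdname readers
#' @export
example_karyomorph_counts <- function() {
  read_karyomorph_counts(example_path("karyomorph_counts.csv"))
}

#' @rdname readers
#' @export
example_length_table <- function() {
  read_length_table(example_path("heteromorph_lengths.csv"))
}

.read_csv_checked <- function(path, what) {
  if (!file.exists(path)) {
    abort_schema(sprintf("%s file not found: %s", what, path))
  }
  out <- tryCatch(
    suppressWarnings(readr::read_csv(path, show_col_types = FALSE,
                                     progress = FALSE)),
    error = function(e) abort_schema(sprintf("cannot parse %s file %s: %s",
                                             what, path, conditionMessage(e)))
  )
  if (nrow(out) == 0 || ncol(out) == 0) {
    abort_schema(sprintf("%s file %s is empty", what, path))
  }
  out
}

#' Read and validate pipeline input tables
#'
#' Typed, validated readers for the three CSV inputs. Schema violations
#' (missing columns, negative counts, arm ratios below 1, unknown labels)
#' raise a schema error naming the offending row and column.
#'
#' `read_karyomorph_counts`: columns `population_id`, `sex` (male/female),
#' `karyomorph`, `count`.
#' `read_measurements`: columns `cell_id`, `chrom_index` (1-13),
#' `homolog_id` (1-2), `relative_length` (percent), `arm_ratio` (>= 1),
#' optional `has_5S_signal` (logical, empty allowed).
#' `read_length_table`: columns `cell_id`, `chrom` (`1-1`, `1-2`, `6-1`,
#' `6-2`), `length_um`.
#'
#' @param path path to a CSV file with a header row.
#' @return A validated tibble.
#' @name readers
#' @examples
#' counts <- read_karyomorph_counts(example_path("karyomorph_counts.csv"))
#' sum(counts$count) # 471 frogs
NULL

#' @rdname readers
#' @export
read_karyomorph_counts <- function(path) {
  validate_counts(.read_csv_checked(path, "karyomorph count"))
}

#' @rdname readers
#' @export
read_measurements <- function(path) {
  validate_measurements(.read_csv_checked(path, "measurement"))
}

#' @rdname readers
#' @export
read_length_table <- function(path) {
  out <- .read_csv_checked(path, "length table")
  if ("chrom" %in% names(out)) out$chrom <- as.character(out$chrom)
  validate_lengths(out)
}

#' Read model parameters from JSON
#'
#' Parameter files hold the segregation-mode probabilities and, optionally,
#' a viability map keyed by karyomorph label, e.g.
#' `{"p_alt": 0.95, "p_adj1": 0.05, "p_adj2": 0, "viability": {"IX": 1}}`.
#'
#' @param path path to a JSON file.
#' @return A list with elements `params` ([segregation_params()]) and
#'   `viability` (named vector).
#' @export
read_model_params <- function(path) {
  if (!file.exists(path)) abort_schema(sprintf("parameter file not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- segregation_params(
    p_alt = raw$p_alt %||% 1, p_adj1 = raw$p_adj1 %||% 0,
    p_adj2 = raw$p_adj2 %||% 0
  )
  viability <- if (!is.null(raw$viability)) {
    do.call(viability_map, as.list(unlist(raw$viability)))
  } else {
    default_viability()
  }
  list(params = params, viability = viability)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages — karyotype classification, frequency
#' tables, gamete-pool fitting, arm-length conservation, forward simulation
#' — over the input files and writes TSV/JSON reports plus a run log
#' (package and R versions, seed, configuration hash). Outputs are
#' byte-identical across runs with the same configuration and seed.
#'
#' @param config a named list or path to a JSON file. Recognised fields:
#'   `counts`, `measurements`, `lengths` (input CSV paths), `params`
#'   (segregation/viability, as in [read_model_params()]), `size_cutoff`,
#'   `simulate` (list with `generations`, optional `mode`, `N`, `init`),
#'   `seed`, `out_dir` (required).
#' @return Invisibly, a list with the computed results and the paths
#'   written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort_schema(sprintf("config file not found: %s", config))
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$out_dir)) abort_schema("config must set out_dir")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  params <- segregation_params(
    p_alt = config$params$p_alt %||% 1,
    p_adj1 = config$params$p_adj1 %||% 0,
    p_adj2 = config$params$p_adj2 %||% 0
  )
  viability <- if (!is.null(config$params$viability)) {
    do.call(viability_map, as.list(unlist(config$params$viability)))
  } else {
    default_viability()
  }

  results <- list()
  paths <- character(0)
  out <- function(name) file.path(config$out_dir, name)
  emit <- function(tbl, name) {
    readr::write_tsv(tbl, out(name))
    paths <<- c(paths, out(name))
  }

  if (!is.null(config$measurements)) {
    cells <- read_measurements(config$measurements)
    karyo <- classify_karyotype(
      cells, size_cutoff = config$size_cutoff %||% 7
    )
    results$karyotypes <- select(karyo, -"chromosomes")
    emit(results$karyotypes, "karyotypes.tsv")
    emit(bind_rows(karyo$chromosomes), "chromosomes.tsv")
  }

  if (!is.null(config$counts)) {
    counts <- read_karyomorph_counts(config$counts)
    results$frequencies <- frequency_table(counts)
    emit(results$frequencies, "frequencies.tsv")

    fit <- fit_gamete_pool(counts, viability = viability)
    results$fit <- fit
    jsonlite::write_json(
      list(
        estimates = as.list(fit$estimates),
        log_likelihood = fit$log_likelihood,
        n = fit$n, converged = fit$converged, boundary = fit$boundary
      ),
      out("gamete_pool_fit.json"), auto_unbox = TRUE, digits = NA
    )
    paths <- c(paths, out("gamete_pool_fit.json"))
  }

  if (!is.null(config$lengths)) {
    lengths <- read_length_table(config$lengths)
    results$conservation <- arm_conservation_test(lengths)
    emit(results$conservation, "arm_conservation.tsv")
  }

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    init <- if (!is.null(sim$init)) {
      unlist(sim$init)
    } else if (!is.null(results$frequencies)) {
      pooled <- filter(results$frequencies, .data$population_id == "pooled",
                       .data$n > 0)
      setNames(pooled$freq, pooled$karyomorph)
    } else {
      abort_schema("simulate stage needs an init or a counts input")
    }
    results$trajectory <- simulate_generations(
      init, generations = sim$generations %||% 10, params = params,
      viability = viability, mode = sim$mode %||% "deterministic",
      N = sim$N, seed = config$seed
    )
    emit(summarize_trajectory(results$trajectory), "trajectory.tsv")
  }

  log <- list(
    package = "quadrivalent",
    package_version = as.character(utils::packageVersion("quadrivalent")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = rlang::hash(config)
  )
  jsonlite::write_json(log, out("run_log.json"), auto_unbox = TRUE)
  paths <- c(paths, out("run_log.json"))

  invisible(c(results, list(paths = paths)))
}
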