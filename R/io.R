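#' Load a run configuration
#'
#' Reads a flat `key: value` text file (DCF, one field per line).  Every
#' generating-model parameter defaults to the base configuration of the
#' signal-strength scenario (`N_s = 100`, `N_g = 1000`, `n_inf = 300`,
#' `N_c = 8`, `n_min = 10`, `m = 5`, `sigma_y = 0.1`, `beta_mean = 0.25`);
#' run-level settings default to `scenario = 1`, `n_reps = 1000`,
#' `root_seed = 1`, `n_workers = 1`, `out_dir = "."`, `plots = FALSE`.
#' Unknown keys are rejected by name.
#'
#' @param path configuration file; `NULL` returns pure defaults.
#' @return List of class `run_config` with elements `params`
#'   (a [hornung_params()]) and the run-level settings.
#' @export
load_config <- function(path = NULL) {
  param_keys <- c("beta_mean", "n_inf", "N_s", "N_c", "n_min", "N_g", "m",
                  "sigma_y")
  run_defaults <- list(scenario = 1L, n_reps = 1000L, root_seed = 1L,
                       n_workers = 1L, out_dir = ".", plots = FALSE)
  overrides <- list()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop_invalid(sprintf("config file not found: %s", path),
                   "centersim_config_error")
    raw <- read.dcf(path)
    if (nrow(raw) > 0) {
      overrides <- as.list(raw[1, ])
      unknown <- setdiff(names(overrides), c(param_keys, names(run_defaults)))
      if (length(unknown))
        stop_invalid(paste0("unknown config key(s): ",
                            paste(unknown, collapse = ", ")),
                     "centersim_config_error")
    }
  }
  coerce <- function(key, val) {
    if (key %in% c("out_dir")) return(val)
    if (key == "plots") return(toupper(val) %in% c("TRUE", "1", "YES"))
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num))
      stop_invalid(sprintf("config key '%s' must be numeric, got '%s'",
                           key, val), "centersim_config_error")
    num
  }
  pargs <- list()
  run <- run_defaults
  for (key in names(overrides)) {
    val <- coerce(key, overrides[[key]])
    if (key %in% param_keys) pargs[[key]] <- val else run[[key]] <- val
  }
  params <- tryCatch(do.call(hornung_params, pargs), error = function(e)
    stop_invalid(paste0("invalid model parameters in config: ",
                        conditionMessage(e)), "centersim_config_error"))
  structure(c(list(params = params), run), class = "run_config")
}

#' Write / read result tables
#'
#' CSV writers and readers for the iteration-level and aggregated result
#' tables.  Numbers are written with full double precision so a round trip
#' reproduces the table to better than 1e-12.  On read, the column set is
#' checked against the file header and mismatches are reported by name.
#'
#' @param tab a `data.frame`.
#' @param path output/input CSV file.
#' @param required_cols optional character vector; reading fails (naming the
#'   missing columns) unless all are present.
#' @return `write_results` returns `path` invisibly; `read_results` the
#'   `data.frame`.
#' @export
write_results <- function(tab, path) {
  stopifnot(is.data.frame(tab))
  out <- tab
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path, required_cols = NULL) {
  if (!file.exists(path))
    stop_invalid(sprintf("results file not found: %s", path))
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(required_cols)) {
    missing <- setdiff(required_cols, names(tab))
    if (length(missing))
      stop_invalid(paste0("missing column(s) in ", path, ": ",
                          paste(missing, collapse = ", ")),
                   "centersim_schema_error")
  }
  tab
}

#' Write a generated cohort to plain text
#'
#' Expression matrix as CSV plus a sample-annotation CSV
#' (`sample_id, center, y, a`).  The orientation of the matrix file is
#' explicit: `samples_as = "rows"` (default) writes samples x genes,
#' `"cols"` genes x samples.
#'
#' @param dataset a `hornung_dataset`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param samples_as `"rows"` or `"cols"`.
#' @return Invisibly, the two file paths.
#' @export
write_dataset <- function(dataset, dir, prefix = "cohort",
                          samples_as = c("rows", "cols")) {
  stopifnot(inherits(dataset, "hornung_dataset"))
  samples_as <- match.arg(samples_as)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  X <- dataset$X
  n <- nrow(X)
  dimnames(X) <- list(sprintf("S%03d", seq_len(n)),
                      sprintf("g%04d", seq_len(ncol(X))))
  if (samples_as == "cols") X <- t(X)
  xpath <- file.path(dir, paste0(prefix, "_expression_samples_",
                                 samples_as, ".csv"))
  write.csv(X, xpath, quote = FALSE)
  ann <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                    center = dataset$centers, y = dataset$y, a = dataset$a,
                    design = dataset$design)
  apath <- file.path(dir, paste0(prefix, "_samples.csv"))
  write.csv(ann, apath, row.names = FALSE, quote = FALSE)
  invisible(c(expression = xpath, annotation = apath))
}

#' Write run metadata for reproducibility
#'
#' Echoes into the output directory everything needed to replay a run or any
#' single iteration of it: the configuration, the root seed, the package
#' version, and the per-iteration child seeds.
#'
#' @param dir output directory.
#' @param config a `run_config` (or list of settings).
#' @param iteration_seeds integer vector of per-iteration seeds.
#' @return Invisibly, the metadata file path.
#' @export
write_run_metadata <- function(dir, config, iteration_seeds = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "run_metadata.dcf")
  p <- config$params
  fields <- c(
    package_version = as.character(packageVersion("centersim")),
    beta_mean = p$beta_mean, n_inf = p$n_inf, N_s = p$N_s, N_c = p$N_c,
    n_min = p$n_min, N_g = p$N_g, m = p$m, sigma_y = p$sigma_y,
    scenario = config$scenario, n_reps = config$n_reps,
    root_seed = config$root_seed, n_workers = config$n_workers
  )
  write.dcf(t(as.matrix(fields)), path)
  if (!is.null(iteration_seeds))
    writeLines(as.character(iteration_seeds),
               file.path(dir, "iteration_seeds.txt"))
  invisible(path)
}
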