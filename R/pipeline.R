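#' Pipeline configuration
#'
#' Assembles and validates the configuration of [run_pipeline()].  Each
#' data stream (measurements, spectra) comes either from a CSV file or
#' from the seeded generator -- never both.
#'
#' @param seed root integer seed; per-stage seeds are derived from it.
#' @param dialect equation dialect for the forward/inverse model.  The
#'   pipeline defaults to `"classical"`: it is the injective dialect, so
#'   generated measurements invert back to a unique coefficient pair (see
#'   [km_invert()] for the paper-dialect branch ambiguity).
#' @param measurements_path optional CSV of measurements
#'   (see [read_measurements()]); when `NULL` the generator is used.
#' @param spectra_path optional CSV of spectra (see [read_spectra()]);
#'   when `NULL` the generator is used.
#' @param generator named list of overrides for [generator_config()]
#'   (ignored fields error).
#' @param boundary list with `n_rel` and/or `reff`
#'   (see [boundary_condition()]).
#' @param fem list with `radius_cm`, `h_far`, `h_near`, `source_power`.
#' @param plsr list with `n_components` (cap; effective count is limited
#'   by the centered predictor rank) and `n_samples` (generated samples
#'   per condition).
#' @param output_dir directory for report files.
#' @param export_fields also write per-condition field CSV exports.
#' @param verbose log per-stage progress and timing via [message()].
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L,
                            dialect = c("classical", "paper"),
                            measurements_path = NULL,
                            spectra_path = NULL,
                            generator = list(),
                            boundary = list(n_rel = 1.4),
                            fem = list(radius_cm = 2, h_far = 0.1,
                                       h_near = 0.005, source_power = 1),
                            plsr = list(n_components = 10, n_samples = 5),
                            output_dir = tempfile("tissopt_run_"),
                            export_fields = FALSE,
                            verbose = FALSE) {
  dialect <- match.arg(dialect)
  if (!is.null(measurements_path) && isTRUE(generator$measurements_disabled))
    stop("invalid config")
  stopifnot(is.list(generator), is.list(boundary), is.list(fem), is.list(plsr))
  bad <- setdiff(names(generator), names(formals(generator_config)))
  if (length(bad))
    stop("unknown generator option(s): ", paste(bad, collapse = ", "))
  fem_def <- list(radius_cm = 2, h_far = 0.1, h_near = 0.005, source_power = 1)
  fem <- utils::modifyList(fem_def, fem)
  plsr_def <- list(n_components = 10, n_samples = 5)
  plsr <- utils::modifyList(plsr_def, plsr)
  structure(list(seed = as.integer(seed), dialect = dialect,
                 measurements_path = measurements_path,
                 spectra_path = spectra_path,
                 generator = generator, boundary = boundary, fem = fem,
                 plsr = plsr, output_dir = output_dir,
                 export_fields = isTRUE(export_fields),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; unknown
#' keys are rejected.  A `measurements: {path: ...}` or
#' `spectra: {path: ...}` block selects file input for that stream;
#' giving both a path and `generate: true` for one stream is an error.
#'
#' @param path YAML file path.
#' @param seed optional seed override (e.g. from the command line).
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  known <- c("seed", "dialect", "measurements", "spectra", "generator",
             "boundary", "fem", "plsr", "output_dir", "export_fields",
             "verbose")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  pick_path <- function(block, stream) {
    if (is.null(block)) return(NULL)
    if (!is.null(block$path) && isTRUE(block$generate))
      stop("config error: stream `", stream,
           "` specifies both a file path and generate: true")
    block$path
  }
  args <- list(
    seed = if (!is.null(seed)) seed else if (!is.null(y$seed)) y$seed else 1L,
    measurements_path = pick_path(y$measurements, "measurements"),
    spectra_path = pick_path(y$spectra, "spectra"))
  for (k in c("dialect", "generator", "boundary", "fem", "plsr",
              "output_dir", "export_fields", "verbose"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(pipeline_config, args)
}

# FNV-1a 32-bit hash of a character scalar (config fingerprinting;
# multiplication done in 16-bit halves to stay exact in doubles)
.fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648) , b) + (h - h %% 2147483648)
    # xor on low 31 bits is enough for bytes < 256; keep h in [0, 2^32)
    h <- h %% 4294967296
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# hash of the scientific configuration only: output location and logging
# toggles do not change results
.config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL; cfg$verbose <- NULL; cfg$export_fields <- NULL
  .fnv1a(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                          null = "null", force = TRUE))
}

.stage <- function(name, config, report_so_far, expr) {
  t0 <- proc.time()[3]
  res <- tryCatch(force(expr), error = function(e) {
    qdir <- file.path(config$output_dir, "quarantine")
    dir.create(qdir, recursive = TRUE, showWarnings = FALSE)
    try(jsonlite::write_json(report_so_far,
                             file.path(qdir, "partial_report.json"),
                             auto_unbox = TRUE, digits = NA, force = TRUE),
        silent = TRUE)
    stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
         call. = FALSE)
  })
  if (config$verbose)
    message(sprintf("[tissopt] stage %-12s done in %.2f s", name,
                    proc.time()[3] - t0))
  res
}

# cap PLSR components by the centered predictor rank
.plsr_max_components <- function(x) {
  qr(sweep(as.matrix(x), 2, colMeans(as.matrix(x))))$rank
}

# fit with at most `nc` components, backing off to the extractable count
# when the predictors are (numerically) rank-deficient
.plsr_fit_auto <- function(x, y, nc) {
  repeat {
    m <- tryCatch(plsr_fit(x, y, nc), error = function(e) e)
    if (!inherits(m, "error")) return(m)
    hit <- regmatches(conditionMessage(m),
                      regexpr("only [0-9]+ component", conditionMessage(m)))
    if (!length(hit)) stop(m)
    nc2 <- as.integer(gsub("[^0-9]", "", hit))
    if (nc2 < 1 || nc2 >= nc) stop(m)
    nc <- nc2
  }
}

#' Run the full characterization pipeline
#'
#' Executes measurement acquisition (file or seeded generator), per-row
#' Kubelka-Munk inversion, replicate aggregation (mean and n-1 sd per
#' condition and wavelength), a fluence-rate FEM solve per condition and
#' wavelength at the aggregated coefficients, field summaries, and PLSR of
#' the (replicate-averaged) spectra per tissue type with a binary
#' condition-code response.  Writes the report files to
#' `config$output_dir` and returns the report.
#'
#' All randomness flows from `config$seed` (measurement stream) and
#' `config$seed + 1` (spectra stream, internally); a rerun with the same
#' config yields a byte-identical `report.json`.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `"run_report"` (a named list; see
#'   [write_report()]).
#' @examples
#' \donttest{
#' cfg <- pipeline_config(seed = 7, generator = list(noise_sd_rt = 0),
#'                        output_dir = tempfile())
#' rep <- run_pipeline(cfg)
#' rep$coefficients[1:2, ]
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (config$verbose)
    message(sprintf("[tissopt] seed=%d dialect=%s config=%s",
                    config$seed, config$dialect, .config_hash(config)))
  report <- list(provenance = list(
    seed = config$seed, dialect = config$dialect,
    config_hash = .config_hash(config),
    tool_version = as.character(utils::packageVersion("tissopt"))))

  gcfg <- do.call(generator_config,
                  utils::modifyList(list(seed = config$seed), config$generator))

  meas <- .stage("measurements", config, report, {
    if (!is.null(config$measurements_path))
      read_measurements(config$measurements_path)
    else
      simulate_measurements(make_phantom_panel(), gcfg, config$dialect)
  })

  fit <- .stage("inversion", config, report, km_fit(meas, config$dialect))
  report$coefficients <- fit$aggregates
  report$per_measurement <- fit$coefficients

  bc <- do.call(boundary_condition, config$boundary)
  report$field_summaries <- .stage("fluence", config, report, {
    agg <- fit$aggregates
    if (is.null(agg)) stop("fluence stage needs condition/wavelength columns")
    mesh <- build_disk_mesh(config$fem$radius_cm, config$fem$h_far,
                            config$fem$h_near)
    out <- vector("list", nrow(agg))
    for (i in seq_len(nrow(agg))) {
      props <- optical_properties(agg$mua_mean[i], agg$musp_mean[i])
      fld <- solve_fluence(mesh, props, bc,
                           source_spec(power = config$fem$source_power))
      fs <- field_summary(fld)
      out[[i]] <- data.frame(condition = agg$condition[i],
                             wavelength_nm = agg$wavelength_nm[i],
                             mua_cm1 = agg$mua_mean[i],
                             musp_cm1 = agg$musp_mean[i],
                             mueff_cm1 = sqrt(3 * agg$mua_mean[i] *
                                              (agg$mua_mean[i] + agg$musp_mean[i])),
                             log_min = fs$log_min, log_max = fs$log_max,
                             efold_radius_cm = fs$efold_radius,
                             stringsAsFactors = FALSE)
      if (config$export_fields)
        export_field_csv(fld, file.path(config$output_dir,
          sprintf("field_%s_%g.csv",
                  gsub("[^A-Za-z0-9]+", "_", tolower(agg$condition[i])),
                  agg$wavelength_nm[i])))
    }
    do.call(rbind, out)
  })

  spectra <- .stage("spectra", config, report, {
    if (!is.null(config$spectra_path)) read_spectra(config$spectra_path)
    else {
      panel <- make_phantom_panel()
      simulate_lif(gcfg, unique(panel$condition), config$plsr$n_samples)
    }
  })

  report$plsr <- .stage("plsr", config, report, {
    avg <- average_replicates(spectra)
    panel <- make_phantom_panel()
    cond_tissue <- stats::setNames(panel$tissue, panel$condition)
    tiss <- unname(cond_tissue[avg$labels])
    tiss[is.na(tiss)] <- "unknown"
    # response: binary condition code, 0 = native/hydrated, 1 = altered
    altered <- grepl("dry|boiled", tolower(avg$labels))
    out <- list()
    for (tt in unique(tiss)) {
      sel <- tiss == tt
      x <- avg$intensities[sel, , drop = FALSE]
      y <- as.numeric(altered[sel])
      if (length(unique(y)) < 2L) next
      m <- .plsr_fit_auto(x, y, min(config$plsr$n_components, sum(sel) - 1L,
                                    .plsr_max_components(x)))
      out[[length(out) + 1L]] <-
        data.frame(tissue = tt, n_samples = sum(sel),
                   n_components = m$n_components, r2 = m$r2,
                   stringsAsFactors = FALSE)
    }
    if (!length(out)) stop("no tissue type had both condition codes")
    do.call(rbind, out)
  })

  class(report) <- "run_report"
  write_report(report, config$output_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("tissopt run report (seed %d, %s dialect, config %s)\n",
              x$provenance$seed, x$provenance$dialect,
              x$provenance$config_hash))
  cat(sprintf("  %d aggregated coefficient rows, %d field summaries, %d PLSR fits\n",
              nrow(x$coefficients), nrow(x$field_summaries), nrow(x$plsr)))
  invisible(x)
}

#' Write / read a pipeline report
#'
#' `write_report()` serializes the report to `report.json` (lossless,
#' full-precision numbers) plus CSV side tables (`coefficients.csv`,
#' `field_summaries.csv`, `plsr.csv`).  `read_report()` restores the
#' report object from the JSON file.
#'
#' @param report a `"run_report"` object.
#' @param dir destination directory.
#' @return `write_report()` the directory, `read_report()` the report.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  write_table_csv(report$coefficients, file.path(dir, "coefficients.csv"))
  write_table_csv(report$field_summaries, file.path(dir, "field_summaries.csv"))
  write_table_csv(report$plsr, file.path(dir, "plsr.csv"))
  invisible(dir)
}

#' @param path path to a `report.json` written by `write_report()`.
#' @rdname write_report
#' @export
read_report <- function(path) {
  r <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (nm in c("coefficients", "per_measurement", "field_summaries", "plsr"))
    if (!is.null(r[[nm]])) r[[nm]] <- as.data.frame(r[[nm]])
  class(r) <- "run_report"
  r
}
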