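#' Read a diffuse-measurement table from CSV
#'
#' Expected header: `sample_id,condition,wavelength_nm,rd,td,thickness_cm`
#' (`thickness_mm` is also accepted and converted to cm).  Every row is
#' validated against the measurement invariants; violations are reported
#' with their line number.
#'
#' @param path CSV file path.
#' @return A data frame of validated measurements (thickness in cm).
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurement file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty measurement file: ", path)
  if ("thickness_mm" %in% names(df) && !("thickness_cm" %in% names(df))) {
    df$thickness_cm <- df$thickness_mm / 10
    df$thickness_mm <- NULL
  }
  need <- c("rd", "td", "thickness_cm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("measurement file lacks column(s): ", paste(miss, collapse = ", "))
  for (i in seq_len(nrow(df))) {
    line <- i + 1L  # header is line 1
    for (col in need)
      if (!is.numeric(df[[col]]) || !is.finite(df[[col]][i]))
        stop(sprintf("line %d: column `%s` is not a finite number", line, col))
    if (df$rd[i] <= 0 || df$rd[i] >= 1)
      stop(sprintf("line %d: rd = %g outside (0, 1)", line, df$rd[i]))
    if (df$td[i] <= 0 || df$td[i] >= 1)
      stop(sprintf("line %d: td = %g outside (0, 1)", line, df$td[i]))
    if (df$rd[i] + df$td[i] >= 1)
      stop(sprintf("line %d: energy conservation violated, rd + td = %g >= 1",
                   line, df$rd[i] + df$td[i]))
    if (df$thickness_cm[i] <= 0)
      stop(sprintf("line %d: thickness_cm = %g must be > 0",
                   line, df$thickness_cm[i]))
  }
  df
}

#' Write a measurement or coefficient table to CSV
#'
#' @param df data frame to write.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectra matrix from CSV (wide or long layout)
#'
#' Auto-detects one of two layouts:
#' \describe{
#'   \item{wide}{header `sample_id,condition,replicate,<w1>,<w2>,...` with
#'     numeric wavelength column names (an optional leading `X` inserted by
#'     CSV round-tripping is stripped);}
#'   \item{long}{header containing `wavelength_nm` and `intensity`, one
#'     row per (spectrum, wavelength) pair.}
#' }
#'
#' @param path CSV file path.
#' @return A [spectrum_set()].
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("spectra file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty spectra file: ", path)
  if ("wavelength_nm" %in% names(df)) {
    need <- c("sample_id", "condition", "replicate", "wavelength_nm", "intensity")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("long-layout spectra file lacks column(s): ",
           paste(miss, collapse = ", "))
    wl <- sort(unique(df$wavelength_nm))
    key <- interaction(df$sample_id, df$replicate, drop = TRUE)
    rows <- t(vapply(levels(key), function(k) {
      sub <- df[key == k, ]
      sub <- sub[order(sub$wavelength_nm), ]
      if (!identical(as.numeric(sub$wavelength_nm), as.numeric(wl)))
        stop("spectrum ", k, " does not share the common wavelength grid")
      sub$intensity
    }, numeric(length(wl))))
    first <- match(levels(key), as.character(key))
    return(spectrum_set(wl, rows, df$condition[first], df$sample_id[first]))
  }
  need <- c("sample_id", "condition", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("wide-layout spectra file lacks column(s): ", paste(miss, collapse = ", "))
  wl_cols <- setdiff(names(df), need)
  wl <- suppressWarnings(as.numeric(sub("^X", "", wl_cols)))
  if (any(is.na(wl)))
    stop("wide-layout wavelength columns must have numeric names; offending: ",
         paste(wl_cols[is.na(wl)], collapse = ", "))
  o <- order(wl)
  spectrum_set(wl[o], as.matrix(df[, wl_cols[o]]), df$condition, df$sample_id)
}

#' Write a spectrum set in the wide CSV layout
#'
#' @param spectra a [spectrum_set()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectrum_set"))
  rep_idx <- stats::ave(seq_along(spectra$sample_ids), spectra$sample_ids,
                        FUN = seq_along)
  df <- data.frame(sample_id = spectra$sample_ids,
                   condition = spectra$labels,
                   replicate = rep_idx, stringsAsFactors = FALSE)
  m <- as.data.frame(spectra$intensities)
  names(m) <- as.character(spectra$wavelengths)
  utils::write.csv(cbind(df, m), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a fluence field as CSV
#'
#' Writes `x_cm,y_cm,phi` per node.
#'
#' @param field a [solve_fluence()] result.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
export_field_csv <- function(field, path) {
  stopifnot(inherits(field, "fluence_field"))
  utils::write.csv(as.data.frame(field), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a fluence field as legacy ASCII VTK
#'
#' Writes an UNSTRUCTURED_GRID legacy VTK file with the triangulation and
#' per-node `phi` scalars, loadable by standard visualization tools.
#'
#' @param field a [solve_fluence()] result.
#' @param path destination path (conventionally `.vtk`).
#' @return `path`, invisibly.
#' @export
export_field_vtk <- function(field, path) {
  stopifnot(inherits(field, "fluence_field"))
  nd <- field$mesh$nodes; tr <- field$mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "fluence rate field", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(nd))), con)
  writeLines(sprintf("%.10g %.10g 0", nd[, 1], nd[, 2]), con)
  writeLines(sprintf("CELLS %d %d", nrow(tr), 4 * nrow(tr)), con)
  writeLines(sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(tr)), con)
  writeLines(rep("5", nrow(tr)), con)
  writeLines(c(sprintf("POINT_DATA %d", nrow(nd)),
               "SCALARS phi double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.10g", field$phi), con)
  invisible(path)
}

#' Export a mesh as a node/element CSV pair
#'
#' @param mesh a [build_disk_mesh()] mesh.
#' @param nodes_path,elements_path destination paths.
#' @return The two paths, invisibly.
#' @export
export_mesh_csv <- function(mesh, nodes_path, elements_path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  utils::write.csv(data.frame(x_cm = mesh$nodes[, 1], y_cm = mesh$nodes[, 2]),
                   nodes_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(n1 = mesh$triangles[, 1],
                              n2 = mesh$triangles[, 2],
                              n3 = mesh$triangles[, 3]),
                   elements_path, row.names = FALSE, quote = FALSE)
  invisible(c(nodes_path, elements_path))
}
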