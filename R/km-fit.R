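#' Fit optical properties to a table of diffuse measurements
#'
#' The table-level estimator: applies [km_invert()] row by row to a
#' measurement table and returns a classed fit object carrying per-row
#' recovered coefficients and, when `condition`/`wavelength_nm` columns are
#' present, replicate aggregates (mean and sample standard deviation).
#'
#' @param data a data frame with numeric columns `rd`, `td`, `thickness_cm`
#'   (see [read_measurements()] for the file layout), optionally
#'   `sample_id`, `condition`, `wavelength_nm`.
#' @param dialect equation dialect passed to [km_invert()].
#' @return An object of class `"km_fit"`: a list with `data`,
#'   `coefficients` (data frame with `mua_cm1`, `musp_cm1`, `mueff_cm1`),
#'   `dialect`, and `aggregates` (or `NULL`).
#' @examples
#' panel <- make_phantom_panel()
#' cfg <- generator_config(seed = 1, noise_sd_rt = 0)
#' m <- simulate_measurements(panel, cfg, dialect = "classical")
#' fit <- km_fit(m, dialect = "classical")
#' coef(fit)[1:3, ]
#' @export
km_fit <- function(data, dialect = c("paper", "classical")) {
  dialect <- match.arg(dialect)
  stopifnot(is.data.frame(data))
  need <- c("rd", "td", "thickness_cm")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("`data` lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(data) == 0L) stop("`data` has no rows")

  n <- nrow(data)
  mua <- musp <- numeric(n)
  for (i in seq_len(n)) {
    meas <- diffuse_measurement(data$rd[i], data$td[i], data$thickness_cm[i],
                                if ("wavelength_nm" %in% names(data))
                                  data$wavelength_nm[i] else NA_real_)
    p <- km_invert(meas, dialect)
    mua[i] <- p$mua; musp[i] <- p$musp
  }
  coefs <- data.frame(mua_cm1 = mua, musp_cm1 = musp,
                      mueff_cm1 = sqrt(3 * mua * (mua + musp)))
  for (col in c("sample_id", "condition", "wavelength_nm"))
    if (col %in% names(data)) coefs[[col]] <- data[[col]]

  agg <- NULL
  if (all(c("condition", "wavelength_nm") %in% names(data))) {
    key <- interaction(data$condition, data$wavelength_nm, drop = TRUE)
    agg <- do.call(rbind, lapply(levels(key), function(k) {
      s <- key == k
      data.frame(condition = data$condition[s][1],
                 wavelength_nm = data$wavelength_nm[s][1],
                 n = sum(s),
                 mua_mean = mean(mua[s]), mua_sd = stats::sd(mua[s]),
                 musp_mean = mean(musp[s]), musp_sd = stats::sd(musp[s]),
                 mueff_mean = mean(coefs$mueff_cm1[s]))
    }))
    rownames(agg) <- NULL
  }
  structure(list(data = data, coefficients = coefs, dialect = dialect,
                 aggregates = agg),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kubelka-Munk inversion fit (%s dialect), %d measurement(s)\n",
              x$dialect, nrow(x$coefficients)))
  cat(sprintf("  mua:  %.4g .. %.4g cm^-1\n",
              min(x$coefficients$mua_cm1), max(x$coefficients$mua_cm1)))
  cat(sprintf("  musp: %.4g .. %.4g cm^-1\n",
              min(x$coefficients$musp_cm1), max(x$coefficients$musp_cm1)))
  invisible(x)
}

#' @export
coef.km_fit <- function(object, ...) {
  as.matrix(object$coefficients[, c("mua_cm1", "musp_cm1", "mueff_cm1")])
}

#' @param object a `"km_fit"` object.
#' @rdname km_fit
#' @export
summary.km_fit <- function(object, ...) {
  structure(list(dialect = object$dialect,
                 n = nrow(object$coefficients),
                 aggregates = object$aggregates,
                 coefficients = object$coefficients),
            class = "summary.km_fit")
}

#' @export
print.summary.km_fit <- function(x, ...) {
  cat(sprintf("Kubelka-Munk inversion (%s dialect), %d measurements\n", x$dialect, x$n))
  if (!is.null(x$aggregates)) {
    cat("Replicate aggregates (mean +/- sd):\n")
    a <- x$aggregates
    for (i in seq_len(nrow(a)))
      cat(sprintf("  %-24s %4g nm : mua %6.3f +/- %.3f, musp %6.2f +/- %.2f cm^-1\n",
                  a$condition[i], a$wavelength_nm[i],
                  a$mua_mean[i], a$mua_sd[i], a$musp_mean[i], a$musp_sd[i]))
  } else {
    print(utils::head(x$coefficients))
  }
  invisible(x)
}

#' Predict reflectance/transmittance from a fitted inversion
#'
#' Runs the forward model at the recovered per-row coefficients, for the
#' observed thicknesses (default) or thicknesses supplied in `newdata`.
#'
#' @param object a `"km_fit"` object.
#' @param newdata optional data frame with a `thickness_cm` column, recycled
#'   against the fitted rows.
#' @param ... unused.
#' @return A data frame with columns `rd` and `td`.
#' @export
predict.km_fit <- function(object, newdata = NULL, ...) {
  th <- if (is.null(newdata)) object$data$thickness_cm else newdata$thickness_cm
  if (is.null(th)) stop("`newdata` must contain `thickness_cm`")
  n <- nrow(object$coefficients)
  th <- rep_len(th, n)
  out <- data.frame(rd = numeric(n), td = numeric(n))
  for (i in seq_len(n)) {
    p <- optical_properties(object$coefficients$mua_cm1[i],
                            object$coefficients$musp_cm1[i])
    rt <- km_forward(km_coeffs_from_optical(p), th[i], object$dialect)
    out$rd[i] <- rt$rd; out$td[i] <- rt$td
  }
  out
}

#' @export
residuals.km_fit <- function(object, ...) {
  pr <- predict(object)
  cbind(rd = object$data$rd - pr$rd, td = object$data$td - pr$td)
}
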