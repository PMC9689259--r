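#' A labelled set of spectra on a common wavelength grid
#'
#' @param wavelengths strictly increasing numeric grid, nm.
#' @param intensities numeric matrix, one spectrum per row, columns
#'   matching `wavelengths`; no negative entries.
#' @param labels condition label per row.
#' @param sample_ids grouping key per row (replicates of one physical
#'   sample share a `sample_id`).
#' @return An object of class `"spectrum_set"`.
#' @export
spectrum_set <- function(wavelengths, intensities, labels, sample_ids) {
  intensities <- as.matrix(intensities)
  stopifnot(is.numeric(wavelengths), is.numeric(intensities))
  if (any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be strictly increasing")
  if (ncol(intensities) != length(wavelengths))
    stop("`intensities` has ", ncol(intensities), " columns but ",
         length(wavelengths), " wavelengths")
  if (nrow(intensities) != length(labels) || nrow(intensities) != length(sample_ids))
    stop("`labels` and `sample_ids` must have one entry per spectrum row")
  if (any(intensities < 0))
    stop("negative intensities are not allowed")
  structure(list(wavelengths = as.numeric(wavelengths),
                 intensities = unname(intensities),
                 labels = as.character(labels),
                 sample_ids = as.character(sample_ids)),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("Spectrum set: %d spectra x %d wavelengths (%g-%g nm), %d sample(s)\n",
              nrow(x$intensities), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths),
              length(unique(x$sample_ids))))
  invisible(x)
}

#' Average replicate spectra within each sample
#'
#' Collapses the replicate rows of each `sample_id` to their arithmetic
#' mean per wavelength, the standard treatment of repeated acquisitions
#' from several surface locations of one sample.  All samples must carry
#' the same number of replicates.
#'
#' @param spectra a [spectrum_set()].
#' @return A [spectrum_set()] with one row per sample, labels preserved.
#' @export
average_replicates <- function(spectra) {
  stopifnot(inherits(spectra, "spectrum_set"))
  ids <- unique(spectra$sample_ids)
  counts <- table(spectra$sample_ids)
  if (length(unique(as.integer(counts))) != 1L) {
    bad <- counts[counts != max(counts)]
    stop("incomplete replicate group(s): ",
         paste(sprintf("%s (n=%d)", names(bad), as.integer(bad)), collapse = ", "))
  }
  rows <- t(vapply(ids, function(id) {
    colMeans(spectra$intensities[spectra$sample_ids == id, , drop = FALSE])
  }, numeric(length(spectra$wavelengths))))
  labs <- vapply(ids, function(id) spectra$labels[spectra$sample_ids == id][1],
                 character(1))
  spectrum_set(spectra$wavelengths, rows, labs, ids)
}

#' Locate the dominant emission peak of a spectrum
#'
#' Smooths with a 5-point moving average (shorter windows at the grid
#' edges) and returns the global maximum; ties are broken toward the
#' longer wavelength.
#'
#' @param intensity numeric vector of intensities (>= 5 points).
#' @param wavelengths matching wavelength grid, nm.
#' @return A list with `peak_wavelength` (nm) and `peak_intensity`
#'   (smoothed value at the peak).
#' @examples
#' wl <- 300:900
#' sp <- exp(-(wl - 700)^2 / (2 * 25^2))
#' find_main_peak(sp, wl)$peak_wavelength  # 700
#' @export
find_main_peak <- function(intensity, wavelengths) {
  stopifnot(is.numeric(intensity), is.numeric(wavelengths),
            length(intensity) == length(wavelengths))
  n <- length(intensity)
  if (n < 5L) stop("need at least 5 grid points")
  if (stats::sd(intensity) == 0)
    stop("flat spectrum: no peak defined")
  sm <- vapply(seq_len(n), function(i) {
    w <- max(1L, i - 2L):min(n, i + 2L)
    mean(intensity[w])
  }, numeric(1))
  peak <- max(which(sm == max(sm)))  # tie -> longer wavelength
  list(peak_wavelength = wavelengths[peak], peak_intensity = sm[peak])
}

#' Partial least squares regression (SIMPLS, single response)
#'
#' Fits a single-response PLSR by the SIMPLS algorithm: components are
#' extracted sequentially to maximize covariance with the response under
#' mutual orthogonality of the X-scores.  Predictors and response are
#' centered internally; no scaling is applied.  For a univariate response
#' SIMPLS and NIPALS PLS1 give identical models, and at `n_components =
#' rank(X)` the fitted values coincide with ordinary least squares.
#'
#' @param x predictor matrix (samples x variables), e.g. spectra.
#' @param y numeric response vector.
#' @param n_components number of latent components, between 1 and
#'   `min(nrow(x) - 1, ncol(x))`.
#' @return An object of class `"plsr_model"`: `n_components`,
#'   `x_loadings` (p x A), `y_loadings` (length A), `x_weights`,
#'   `scores`, `coefficients` (for centered data), `x_mean`, `y_mean`,
#'   `fitted`, `r2`, and `r2_by_component`.
#' @examples
#' set.seed(1)
#' t1 <- rnorm(20); t2 <- rnorm(20)
#' x <- outer(t1, rnorm(50)) + outer(t2, rnorm(50))
#' y <- 2 * t1 - t2
#' fit <- plsr_fit(x, y, 2)
#' fit$r2  # 1 up to rounding: y is exactly rank-2 in x
#' @export
plsr_fit <- function(x, y, n_components) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("`y` length must match rows of `x`")
  if (!is.numeric(n_components) || length(n_components) != 1L ||
      n_components < 1 || n_components != round(n_components))
    stop("`n_components` must be a positive integer")
  if (n_components > min(n - 1, p))
    stop("`n_components` = ", n_components, " exceeds min(n_samples - 1, ",
         "n_variables) = ", min(n - 1, p))
  A <- as.integer(n_components)

  x_mean <- colMeans(x); y_mean <- mean(y)
  Xc <- sweep(x, 2, x_mean)
  yc <- y - y_mean

  S <- crossprod(Xc, yc)                      # p x 1 covariance vector
  R <- matrix(0, p, A); P <- matrix(0, p, A); V <- matrix(0, p, A)
  Tm <- matrix(0, n, A); Q <- numeric(A)
  tol <- .Machine$double.eps^0.5 * sqrt(sum(Xc^2) * sum(yc^2) + 1)
  for (a in seq_len(A)) {
    r <- S[, 1]
    t <- Xc %*% r
    nt <- sqrt(sum(t^2))
    if (nt <= tol)
      stop("reduced-rank error: only ", a - 1L,
           " component(s) are extractable from `x` (requested ", A, ")")
    t <- t / nt; r <- r / nt
    p_a <- crossprod(Xc, t)[, 1]
    Q[a] <- sum(yc * t)
    v <- p_a
    if (a > 1L) v <- v - V[, 1:(a - 1), drop = FALSE] %*%
        crossprod(V[, 1:(a - 1), drop = FALSE], p_a)
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; P[, a] <- p_a; V[, a] <- v; Tm[, a] <- t
  }

  coefs <- R %*% Q
  fitted <- as.numeric(Xc %*% coefs) + y_mean
  ss_tot <- sum(yc^2)
  r2_by_component <- vapply(seq_len(A), function(a) {
    fa <- as.numeric(Xc %*% (R[, 1:a, drop = FALSE] %*% Q[1:a])) + y_mean
    1 - sum((y - fa)^2) / ss_tot
  }, numeric(1))

  structure(list(n_components = A, x_loadings = P, y_loadings = Q,
                 x_weights = R, scores = Tm,
                 coefficients = as.numeric(coefs),
                 x_mean = x_mean, y_mean = y_mean,
                 fitted = fitted, y = y,
                 r2 = r2_by_component[A],
                 r2_by_component = r2_by_component),
            class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("PLSR (SIMPLS) model: %d component(s), training R^2 = %.4f\n",
              x$n_components, x$r2))
  invisible(x)
}

#' @export
summary.plsr_model <- function(object, ...) {
  cat(sprintf("PLSR (SIMPLS), %d component(s)\nPer-component training R^2:\n",
              object$n_components))
  print(data.frame(components = seq_len(object$n_components),
                   r2 = object$r2_by_component), row.names = FALSE)
  invisible(object)
}

#' @export
coef.plsr_model <- function(object, ...) object$coefficients

#' @export
fitted.plsr_model <- function(object, ...) object$fitted

#' @export
residuals.plsr_model <- function(object, ...) object$y - object$fitted

#' @param object a `"plsr_model"`.
#' @param newdata predictor matrix with the same columns as the training
#'   `x`; defaults to returning the training fitted values.
#' @rdname plsr_fit
#' @export
predict.plsr_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  newdata <- as.matrix(newdata)
  as.numeric(sweep(newdata, 2, object$x_mean) %*% object$coefficients) +
    object$y_mean
}

#' Coefficient of determination of a PLSR model
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with the total sum of squares taken
#' about the mean of `y` (training-set evaluation by default).
#'
#' @param model a [plsr_fit()] model.
#' @param x predictor matrix.
#' @param y response vector.
#' @return The R-squared value.
#' @export
r_squared <- function(model, x, y) {
  stopifnot(inherits(model, "plsr_model"))
  y <- as.numeric(y)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("zero-variance response: R^2 undefined")
  1 - sum((y - predict(model, x))^2) / ss_tot
}

#' Cross-validated R-squared
#'
#' Optional k-fold cross-validation of [plsr_fit()]; not used by default
#' reporting, which quotes the training fit.
#'
#' @param x predictor matrix.
#' @param y response vector.
#' @param n_components number of components.
#' @param folds number of folds.
#' @param seed seed for the fold split.
#' @return Cross-validated R-squared.
#' @export
cv_r_squared <- function(x, y, n_components, folds = 5, seed = 1) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), n))
  pred <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- fold != f
    m <- plsr_fit(x[tr, , drop = FALSE], y[tr],
                  min(n_components, sum(tr) - 1))
    pred[!tr] <- predict(m, x[!tr, , drop = FALSE])
  }
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}
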