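#' Reference phantom panel of tissue optical properties
#'
#' The fixture panel of four tissue conditions (hydrated/dry chicken skin,
#' native/boiled bovine adipose tissue) at three near-infrared laser
#' wavelengths (808, 830, 980 nm), with reported central values of
#' \eqn{\mu_a} and \eqn{\mu_s'} in cm^-1.  These are measurement-derived
#' literature values used as generator ground truth, not data shipped with
#' raw provenance.
#'
#' @return A data frame with 12 rows and columns `condition`, `tissue`
#'   (`"skin"` or `"adipose"`), `wavelength_nm`, `mua`, `musp`,
#'   `provenance`.
#' @examples
#' p <- make_phantom_panel()
#' subset(p, condition == "Hydrated skin" & wavelength_nm == 808)
#' @export
make_phantom_panel <- function() {
  conditions <- c("Hydrated skin", "Dry skin",
                  "Native adipose tissue", "Boiled adipose tissue")
  tissue <- c("skin", "skin", "adipose", "adipose")
  wl <- c(808, 830, 980)
  mua <- rbind(c(0.84, 2.68, 2.01),
               c(0.50, 0.14, 0.48),
               c(0.34, 1.70, 1.61),
               c(0.13, 0.34, 1.63))
  musp <- rbind(c(26.2, 29.8, 32.5),
                c(24.1, 38.7, 26.1),
                c(11.2, 19.0, 24.0),
                c(13.2, 11.1, 24.2))
  out <- data.frame(
    condition = rep(conditions, each = 3),
    tissue = rep(tissue, each = 3),
    wavelength_nm = rep(wl, times = 4),
    mua = as.vector(t(mua)),
    musp = as.vector(t(musp)),
    provenance = "reported central value",
    stringsAsFactors = FALSE)
  stopifnot(all(out$musp > out$mua / 3))
  out
}

#' Configuration of the synthetic-data generators
#'
#' Collects every tunable of [simulate_measurements()] and
#' [simulate_lif()].  Defaults emulate the study conditions: slab
#' thicknesses 2 +/- 0.5 mm for skin and 3 +/- 0.4 mm for adipose tissue,
#' five repeated reflectance/transmittance acquisitions, emission spectra
#' with a single porphyrin-attributed peak at 700 nm averaged over 10
#' surface locations per sample, and a condition effect that *increases*
#' the peak amplitude for dried/boiled tissue (the sign is configurable
#' through `lif_amp_by_condition`).
#'
#' @param seed integer seed; all generator randomness flows from it.
#' @param noise_sd_rt additive Gaussian standard deviation applied to both
#'   Rd and Td, in absolute fraction units.
#' @param n_replicates repeated measurements per panel entry.
#' @param thickness_mean_cm,thickness_sd_cm named vectors (`skin`,
#'   `adipose`) of slab-thickness mean and sd, cm.
#' @param lif_peak_nm emission peak centre, nm.
#' @param lif_peak_sd_nm Gaussian peak width (sd), nm.
#' @param lif_base_amp peak amplitude of the reference condition,
#'   arbitrary counts.
#' @param lif_baseline flat spectral baseline, counts.
#' @param lif_amp_by_condition named amplitude multipliers per condition
#'   (> 0); unlisted conditions default to 1.
#' @param lif_sample_sd sd of the per-sample multiplicative random effect.
#' @param lif_noise_sd sd of the additive per-point spectral noise, counts.
#' @param n_locations replicate spectra (surface locations) per sample.
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(seed = 1L,
                             noise_sd_rt = 0.01,
                             n_replicates = 5L,
                             thickness_mean_cm = c(skin = 0.2, adipose = 0.3),
                             thickness_sd_cm = c(skin = 0.05, adipose = 0.04),
                             lif_peak_nm = 700,
                             lif_peak_sd_nm = 25,
                             lif_base_amp = 100,
                             lif_baseline = 5,
                             lif_amp_by_condition = c("Hydrated skin" = 1,
                                                      "Dry skin" = 1.5,
                                                      "Native adipose tissue" = 1,
                                                      "Boiled adipose tissue" = 1.5),
                             lif_sample_sd = 0.1,
                             lif_noise_sd = 1,
                             n_locations = 10L) {
  if (noise_sd_rt < 0 || lif_sample_sd < 0 || lif_noise_sd < 0)
    stop("noise standard deviations must be >= 0")
  if (n_replicates < 1) stop("`n_replicates` must be >= 1")
  if (n_locations < 1) stop("`n_locations` must be >= 1")
  if (any(lif_amp_by_condition <= 0))
    stop("amplitude multipliers must be > 0")
  if (any(thickness_mean_cm <= 0) || any(thickness_sd_cm < 0))
    stop("thickness parameters must be positive")
  structure(list(seed = as.integer(seed), noise_sd_rt = noise_sd_rt,
                 n_replicates = as.integer(n_replicates),
                 thickness_mean_cm = thickness_mean_cm,
                 thickness_sd_cm = thickness_sd_cm,
                 lif_peak_nm = lif_peak_nm, lif_peak_sd_nm = lif_peak_sd_nm,
                 lif_base_amp = lif_base_amp, lif_baseline = lif_baseline,
                 lif_amp_by_condition = lif_amp_by_condition,
                 lif_sample_sd = lif_sample_sd, lif_noise_sd = lif_noise_sd,
                 n_locations = as.integer(n_locations)),
            class = "generator_config")
}

# truncated-normal draw (> lower), by redrawing
.rnorm_trunc <- function(n, mean, sd, lower = 0) {
  out <- stats::rnorm(n, mean, sd)
  for (k in 1:1000) {
    bad <- out <= lower
    if (!any(bad)) return(out)
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  stop("generator error: truncated-normal rejection exceeded 1000 rounds")
}

#' Simulate noisy diffuse reflectance/transmittance measurements
#'
#' Forward-models each phantom-panel entry through [km_forward()] at a
#' randomly drawn slab thickness and adds independent Gaussian noise to Rd
#' and Td, redrawing (up to 1000 times per value) until the noisy pair is
#' physical (`0 < rd`, `0 < td`, `rd + td < 1`).  Fully reproducible from
#' the config seed.
#'
#' @param panel a data frame as from [make_phantom_panel()].
#' @param cfg a [generator_config()].
#' @param dialect forward-model dialect, see [km_forward()].
#' @return A data frame of measurements with columns `sample_id`,
#'   `condition`, `tissue`, `wavelength_nm`, `rd`, `td`, `thickness_cm`,
#'   plus ground-truth bookkeeping columns `mua_true`, `musp_true`.
#' @export
simulate_measurements <- function(panel, cfg, dialect = c("paper", "classical")) {
  dialect <- match.arg(dialect)
  stopifnot(is.data.frame(panel), inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  rows <- vector("list", nrow(panel) * cfg$n_replicates)
  k <- 0L
  for (i in seq_len(nrow(panel))) {
    props <- optical_properties(panel$mua[i], panel$musp[i])
    coeffs <- km_coeffs_from_optical(props)
    tiss <- panel$tissue[i]
    tm <- unname(cfg$thickness_mean_cm[tiss])
    ts <- unname(cfg$thickness_sd_cm[tiss])
    if (!length(tm) || is.na(tm))
      stop("no thickness parameters for tissue type '", tiss, "'")
    for (r in seq_len(cfg$n_replicates)) {
      th <- .rnorm_trunc(1, tm, ts)
      rt <- km_forward(coeffs, th, dialect)
      rd <- rt$rd; td <- rt$td
      if (cfg$noise_sd_rt > 0) {
        ok <- FALSE
        for (draw in 1:1000) {
          rd <- rt$rd + stats::rnorm(1, 0, cfg$noise_sd_rt)
          td <- rt$td + stats::rnorm(1, 0, cfg$noise_sd_rt)
          if (rd > 0 && td > 0 && rd + td < 1) { ok <- TRUE; break }
        }
        if (!ok)
          stop("generator error: could not draw a physical (rd, td) pair in ",
               "1000 attempts; `noise_sd_rt` too large")
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        sample_id = sprintf("%s_%gnm_rep%02d",
                            gsub("[^A-Za-z0-9]+", "_", tolower(panel$condition[i])),
                            panel$wavelength_nm[i], r),
        condition = panel$condition[i], tissue = tiss,
        wavelength_nm = panel$wavelength_nm[i],
        rd = rd, td = td, thickness_cm = th,
        mua_true = panel$mua[i], musp_true = panel$musp[i],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate emission spectra with a condition-dependent 700-nm peak
#'
#' Generates laser-induced-fluorescence-like spectra on a 300-900 nm grid
#' (1 nm step): a flat baseline plus a Gaussian peak centred at
#' `lif_peak_nm` whose amplitude is the base amplitude times the condition
#' multiplier times a per-sample lognormal-free multiplicative random
#' effect (truncated normal around 1), plus additive Gaussian noise,
#' clamped at zero.  Each sample contributes `n_locations` replicate rows.
#'
#' @param cfg a [generator_config()].
#' @param conditions character vector of condition labels.
#' @param n_samples samples per condition.
#' @return A [spectrum_set()] with `n_locations` rows per sample; the
#'   per-sample true peak amplitudes are attached as attribute `"truth"`.
#' @export
simulate_lif <- function(cfg, conditions, n_samples) {
  stopifnot(inherits(cfg, "generator_config"))
  if (length(conditions) == 0L) stop("`conditions` must be non-empty")
  set.seed(cfg$seed + 1L)
  wl <- seq(300, 900, by = 1)
  shape <- exp(-(wl - cfg$lif_peak_nm)^2 / (2 * cfg$lif_peak_sd_nm^2))
  rows <- list(); labs <- character(0); ids <- character(0)
  truth <- list()
  for (cond in conditions) {
    mult <- cfg$lif_amp_by_condition[cond]
    if (is.na(mult)) mult <- 1
    for (s in seq_len(n_samples)) {
      eff <- if (cfg$lif_sample_sd > 0)
        .rnorm_trunc(1, 1, cfg$lif_sample_sd, lower = 0.05) else 1
      amp <- cfg$lif_base_amp * unname(mult) * eff
      id <- sprintf("%s_s%02d", gsub("[^A-Za-z0-9]+", "_", tolower(cond)), s)
      truth[[length(truth) + 1L]] <-
        data.frame(sample_id = id, condition = cond, amplitude = amp,
                   stringsAsFactors = FALSE)
      for (loc in seq_len(cfg$n_locations)) {
        sp <- cfg$lif_baseline + amp * shape
        if (cfg$lif_noise_sd > 0)
          sp <- sp + stats::rnorm(length(wl), 0, cfg$lif_noise_sd)
        rows[[length(rows) + 1L]] <- pmax(sp, 0)
        labs <- c(labs, cond); ids <- c(ids, id)
      }
    }
  }
  out <- spectrum_set(wl, do.call(rbind, rows), labs, ids)
  attr(out, "truth") <- do.call(rbind, truth)
  out
}
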