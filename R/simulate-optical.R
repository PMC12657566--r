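#' Modified Beer-Lambert configuration
#'
#' Molar extinction coefficients default to a standard tabulated compilation
#' for whole hemoglobin at 760 and 850 nm (base-10, cm^-1 M^-1): rows are
#' wavelengths, columns are chromophores (HbO, HbR). The partial pathlength
#' factor (PPF) scales the source-detector separation to the effective photon
#' path; the product `separation * ppf` is treated as the total effective
#' pathlength.
#'
#' @param ppf partial pathlength factor per wavelength (default 6.0, 6.0)
#' @param extinction 2x2 extinction matrix, `dimnames` wavelength x chromophore
#' @return list of class `beer_lambert_config`
#' @export
beer_lambert_config <- function(ppf = c(6.0, 6.0),
                                extinction = default_extinction()) {
  if (any(ppf <= 0)) stop_param("ppf must be positive")
  if (!is.matrix(extinction) || any(dim(extinction) != 2))
    stop_param("extinction must be a 2x2 matrix (wavelength x chromophore)")
  if (abs(det(extinction)) < 1e-9) stop_config("extinction matrix is singular")
  structure(list(ppf = ppf, extinction = extinction),
            class = "beer_lambert_config")
}

#' Default molar extinction coefficients at 760 / 850 nm
#'
#' Base-10 molar extinction coefficients (cm^-1 M^-1) for oxy- and
#' deoxyhemoglobin from the widely used compiled in-vitro spectra
#' (Prahl-style tabulation).
#' @return 2x2 matrix, rows = c("760", "850"), cols = c("hbo", "hbr")
#' @export
default_extinction <- function() {
  matrix(c(586, 1548.52,
           1058, 691.32),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("760", "850"), c("hbo", "hbr")))
}

new_optical_recording <- function(intensities, wavelengths, sampling_rate,
                                  montage, annotations = empty_annotations(),
                                  stage = "raw", bad_channels = character(),
                                  truth = NULL) {
  structure(list(
    intensities = intensities, wavelengths = wavelengths,
    sampling_rate = sampling_rate, montage = montage,
    annotations = annotations, stage = stage,
    bad_channels = bad_channels, truth = truth
  ), class = "optical_recording")
}

#' @export
print.optical_recording <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<optical_recording> %d samples x %d channels x %d wavelengths @ %.2f Hz (stage: %s)\n",
              d[1], d[2], d[3], x$sampling_rate, x$stage))
  invisible(x)
}

# forward modified Beer-Lambert: concentrations (micromolar) -> delta OD
forward_mbll <- function(hbo_uM, hbr_uM, separation, bl) {
  eff <- separation * bl$ppf  # cm, per wavelength
  od760 <- (bl$extinction[1, 1] * hbo_uM + bl$extinction[1, 2] * hbr_uM) * 1e-6 * eff[1]
  od850 <- (bl$extinction[2, 1] * hbo_uM + bl$extinction[2, 2] * hbr_uM) * 1e-6 * eff[2]
  list(od760 = od760, od850 = od850)
}

#' Simulate raw dual-wavelength optical intensities
#'
#' Forward-models the hemoglobin series through the modified Beer-Lambert
#' law (`I = I0 * 10^-OD`), mixes a superficial scalp component (shared with
#' dedicated short-separation channels) into the long channels, and injects
#' motion artifacts (half of the events are 1-s half-cosine spikes of 5-20x
#' the signal SD, half are baseline shifts) and saturation episodes that
#' drive the reconstructed HbO beyond the saturation threshold.
#'
#' @param hemo a `hemo_recording` from [simulate_hemo()]
#' @param config a [sim_config()]
#' @param beerlambert a [beer_lambert_config()]
#' @param montage optional `nirs_montage`; built from `config` when missing
#' @return an `optical_recording` at stage `"raw"`; its `truth` field keeps
#'   the generating HbO/HbR and the per-channel superficial series
#' @export
simulate_optical <- function(hemo, config = sim_config(),
                             beerlambert = beer_lambert_config(),
                             montage = NULL) {
  if (!inherits(hemo, "hemo_recording")) stop_param("hemo must be a hemo_recording")
  if (ncol(hemo$hbo) != config$n_long_channels)
    stop_param("hemo channel count must match config$n_long_channels")
  if (is.null(montage)) {
    montage <- frontal_montage(
      n_long = config$n_long_channels, n_short = config$n_short_channels,
      long_separation = config$long_separation,
      short_separation = config$short_separation
    )
  }
  set.seed(child_seed(config$seed, 3))
  fs <- config$sampling_rate
  n <- nrow(hemo$hbo)
  ch <- montage$channels
  n_long <- sum(ch$role == "long")
  n_short <- sum(ch$role == "short")
  C <- n_long + n_short

  # superficial scalp process: one global + one regional slow component,
  # regions indexed by the nearest short channel; systemic respiration and
  # Mayer-wave oscillations ride mainly in this compartment
  tt_s <- (seq_len(n) - 1) / fs
  f_resp <- stats::runif(1, config$respiration_band[1], config$respiration_band[2])
  systemic <- 0.6 * sin(2 * pi * f_resp * tt_s + stats::runif(1, 0, 2 * pi)) +
    0.6 * sin(2 * pi * config$mayer_freq * tt_s + stats::runif(1, 0, 2 * pi))
  sup_global <- sqrt(0.5) * band_limited_noise(n, fs, c(0.01, 0.2)) + systemic
  sup_global <- sup_global / sd(sup_global)
  sup_amp <- 0.4  # micromolar-equivalent amplitude of the scalp signal
  long_idx <- which(ch$role == "long")
  short_idx <- which(ch$role == "short")
  if (n_short > 0) {
    region_of_long <- sapply(long_idx, function(i) {
      d2 <- (ch$x[short_idx] - ch$x[i])^2 + (ch$y[short_idx] - ch$y[i])^2 +
        (ch$z[short_idx] - ch$z[i])^2
      which.min(d2)
    })
    sup_regional <- sapply(seq_len(n_short), function(r) band_limited_noise(n, fs, c(0.01, 0.2)))
    sup_by_region <- sqrt(0.7) * sup_global + sqrt(0.3) * sup_regional
  } else {
    region_of_long <- rep(NA_integer_, n_long)
    sup_by_region <- matrix(sup_global, n, 1)
  }

  # per-channel hemoglobin concentrations including the superficial mix
  hbo_all <- matrix(0, n, C)
  hbr_all <- matrix(0, n, C)
  w <- config$superficial_weight
  for (k in seq_len(n_long)) {
    sup <- if (n_short > 0) sup_by_region[, region_of_long[k]] else 0
    hbo_all[, long_idx[k]] <- hemo$hbo[, k] + w * sup_amp * sup
    hbr_all[, long_idx[k]] <- hemo$hbr[, k] + w * sup_amp * config$hbr_ratio * sup
  }
  sup_of_channel <- matrix(0, n, C)
  if (n_short > 0) {
    sup_of_channel[, long_idx] <- sup_by_region[, region_of_long, drop = FALSE]
    for (r in seq_len(n_short)) {
      sup <- sup_by_region[, r]
      hbo_all[, short_idx[r]] <- sup_amp * sup + rnorm(n, 0, 0.02)
      hbr_all[, short_idx[r]] <- sup_amp * config$hbr_ratio * sup + rnorm(n, 0, 0.02)
      sup_of_channel[, short_idx[r]] <- sup
    }
  }

  # forward Beer-Lambert to OD, then intensities around a per-channel baseline
  od <- array(0, dim = c(n, C, 2))
  for (k in seq_len(C)) {
    f <- forward_mbll(hbo_all[, k], hbr_all[, k], ch$separation[k], beerlambert)
    od[, k, 1] <- f$od760
    od[, k, 2] <- f$od850
  }

  annotations <- empty_annotations()

  # motion artifacts: events hit all channels with random per-channel gains;
  # amplitudes are scaled by the clean (pre-artifact) signal SD
  clean_sds <- apply(od, c(2, 3), sd)
  n_events <- rpois(1, config$artifact_rate * config$duration / 60)
  if (n_events > 0) {
    for (ev in seq_len(n_events)) {
      t0 <- runif(1, 0, config$duration - 1.5)
      i0 <- floor(t0 * fs) + 1
      spike <- runif(1) < 0.5
      gain <- runif(C, 0.5, 1.5) * sample(c(-1, 1), C, replace = TRUE)
      for (wl in 1:2) {
        sds <- clean_sds[, wl]
        a <- runif(1, 5, 20)
        if (spike) {
          len <- round(fs)  # 1-s half-cosine bump
          win <- i0:min(n, i0 + len - 1)
          shape <- sin(pi * seq_along(win) / length(win))
          for (k in seq_len(C)) od[win, k, wl] <- od[win, k, wl] + a * sds[k] * gain[k] * shape
        } else {
          win <- i0:n
          for (k in seq_len(C)) od[win, k, wl] <- od[win, k, wl] + a * sds[k] * gain[k]
        }
      }
    }
  }

  # saturation episodes: slow large excursions on one long channel, sized to
  # push the reconstructed HbO well past the 10 micromolar screening limit
  n_sat <- rpois(1, config$saturation_rate)
  if (n_sat > 0) {
    for (ev in seq_len(n_sat)) {
      k <- sample(long_idx, 1)
      t0 <- runif(1, 0, config$duration - 4)
      win <- (floor(t0 * fs) + 1):min(n, floor((t0 + 3) * fs))
      shape <- sin(pi * seq_along(win) / length(win))
      f <- forward_mbll(15, 15 * config$hbr_ratio, ch$separation[k], beerlambert)
      od[win, k, 1] <- od[win, k, 1] + f$od760 * shape
      od[win, k, 2] <- od[win, k, 2] + f$od850 * shape
    }
  }

  baseline <- matrix(runif(C * 2, 0.9, 1.1), C, 2)
  ints <- array(0, dim = c(n, C, 2))
  for (k in seq_len(C)) for (wl in 1:2) {
    ints[, k, wl] <- baseline[k, wl] * 10^(-od[, k, wl])
  }
  dimnames(ints) <- list(NULL, ch$channel, as.character(config$wavelengths))

  new_optical_recording(
    ints, config$wavelengths, fs, montage,
    annotations = annotations, stage = "raw",
    truth = list(hbo = hemo$hbo, hbr = hemo$hbr,
                 hbo_functional = hemo$truth$hbo_functional,
                 superficial = sup_of_channel)
  )
}
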