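#' Quality-control configuration
#'
#' @param sci_threshold scalp coupling index below which a channel is marked
#'   bad (strict inequality), default 0.7
#' @param cardiac_band band used for the SCI cardiac filter, Hz
#' @param filter_band analysis band-pass, Hz
#' @param transition_widths FIR transition widths for the lower and upper
#'   band edge, Hz
#' @return list of class `quality_config`
#' @export
quality_config <- function(sci_threshold = 0.7, cardiac_band = c(0.7, 1.5),
                           filter_band = c(0.01, 0.20),
                           transition_widths = c(0.01, 0.2)) {
  if (sci_threshold < 0 || sci_threshold > 1) stop_param("sci_threshold must lie in [0, 1]")
  if (cardiac_band[1] >= cardiac_band[2] || filter_band[1] >= filter_band[2])
    stop_param("band edges must be ordered")
  structure(list(sci_threshold = sci_threshold, cardiac_band = cardiac_band,
                 filter_band = filter_band, transition_widths = transition_widths),
            class = "quality_config")
}

#' Convert raw intensities to optical density
#'
#' `OD(t) = -log10(I(t) / mean(I))`, per channel and wavelength, so each
#' series has approximately zero mean optical density.
#'
#' @param rec an `optical_recording` at stage `"raw"`
#' @return the recording with `$od` populated, at stage `"od"`
#' @export
intensity_to_od <- function(rec) {
  check_stage(rec, "raw", "intensity_to_od")
  ints <- rec$intensities
  bad <- which(apply(ints <= 0, 2, any))
  if (length(bad) > 0) {
    stop_data(paste0("non-positive intensities in channel(s): ",
                     paste(rec$montage$channels$channel[bad], collapse = ", ")))
  }
  od <- ints
  for (k in seq_len(dim(ints)[2])) for (wl in seq_len(dim(ints)[3])) {
    od[, k, wl] <- -log10(ints[, k, wl] / mean(ints[, k, wl]))
  }
  rec$od <- od
  rec$stage <- "od"
  rec
}

#' Temporal derivative distribution repair (TDDR)
#'
#' Robust motion-artifact correction: the signal is split at 0.5 Hz
#' (3rd-order zero-phase Butterworth), the temporal derivative of the slow
#' component is iteratively re-weighted with Tukey's biweight (tuning
#' constant 4.685, scale 1.4826 x median absolute deviation) until the
#' weights converge, the corrected derivative is re-integrated, and the
#' untouched fast component and signal mean are restored.
#'
#' @param x a numeric series or an `optical_recording` at stage `"od"`
#' @param sampling_rate sampling rate in Hz (series method)
#' @param ... passed to methods
#' @return object of the same type, corrected
#' @export
tddr <- function(x, ...) UseMethod("tddr")

#' @rdname tddr
#' @param tune biweight tuning constant
#' @param tol convergence tolerance on the maximum weight change
#' @param max_iter iteration cap
#' @export
tddr.numeric <- function(x, sampling_rate, tune = 4.685, tol = 1e-8,
                         max_iter = 50, ...) {
  if (length(x) < 3) stop_data("series too short for TDDR")
  if (any(!is.finite(x))) stop_data("non-finite samples in series")
  mu_x <- mean(x)
  xc <- x - mu_x
  fc <- 0.5 * 2 / sampling_rate
  if (fc < 1) {
    bf <- signal::butter(3, fc)
    xlow <- signal::filtfilt(bf, xc)
  } else {
    xlow <- xc
  }
  xhigh <- xc - xlow
  deriv <- diff(xlow)
  w <- rep(1, length(deriv))
  mu <- 0
  for (iter in seq_len(max_iter)) {
    mu <- sum(w * deriv) / sum(w)
    dev <- abs(deriv - mu)
    s <- 1.4826 * median(dev)
    if (s == 0) break  # homogeneous derivative: nothing to repair
    r <- dev / (s * tune)
    w_new <- ((1 - r^2) * (r < 1))^2
    done <- max(abs(w_new - w)) < tol
    w <- w_new
    if (done) break
  }
  corrected <- cumsum(c(0, w * (deriv - mu)))
  corrected <- corrected - mean(corrected)
  corrected + xhigh + mu_x
}

#' @rdname tddr
#' @export
tddr.optical_recording <- function(x, ...) {
  check_stage(x, "od", "tddr")
  for (k in seq_len(dim(x$od)[2])) for (wl in seq_len(dim(x$od)[3])) {
    x$od[, k, wl] <- tddr.numeric(x$od[, k, wl], x$sampling_rate, ...)
  }
  x$stage <- "tddr"
  x
}

#' Short-separation channel regression
#'
#' Removes superficial (scalp) hemodynamics: each long channel is regressed,
#' per wavelength, on its spatially nearest short channel (Euclidean
#' midpoint distance) and replaced by the least-squares residual, which is
#' orthogonal to the regressor.
#'
#' @param rec an `optical_recording` at stage `"tddr"`
#' @return the recording with long channels residualized, stage `"ssr"`
#' @export
short_channel_regress <- function(rec) {
  check_stage(rec, "tddr", "short_channel_regress")
  ch <- rec$montage$channels
  short_idx <- which(ch$role == "short")
  if (length(short_idx) == 0) stop_config("montage contains no short channels")
  long_idx <- which(ch$role == "long")
  for (k in long_idx) {
    d2 <- (ch$x[short_idx] - ch$x[k])^2 + (ch$y[short_idx] - ch$y[k])^2 +
      (ch$z[short_idx] - ch$z[k])^2
    s <- short_idx[which.min(d2)]
    for (wl in seq_len(dim(rec$od)[3])) {
      y <- rec$od[, k, wl]
      x <- rec$od[, s, wl]
      xc <- x - mean(x)
      denom <- sum(xc^2)
      beta <- if (denom > 0) sum(xc * (y - mean(y))) / denom else 0
      rec$od[, k, wl] <- y - mean(y) - beta * xc + mean(y)
    }
  }
  rec$stage <- "ssr"
  rec
}

#' Scalp coupling index
#'
#' Per-channel signal quality: the zero-lag Pearson correlation between the
#' two wavelengths' optical-density series filtered to the cardiac band.
#' Channels with SCI strictly below the threshold are flagged bad; channels
#' whose filtered series has zero variance get an undefined SCI and are
#' flagged bad with a warning.
#'
#' @param rec an `optical_recording` at stage `"ssr"`
#' @param q a [quality_config()]
#' @return tibble(channel, role, sci, bad)
#' @export
scalp_coupling_index <- function(rec, q = quality_config()) {
  check_stage(rec, "ssr", "scalp_coupling_index")
  n <- dim(rec$od)[1]
  if (n / rec$sampling_rate <= 10 / q$cardiac_band[1])
    stop_data("recording shorter than 10 cardiac periods; SCI unreliable")
  ch <- rec$montage$channels
  sci <- vapply(seq_len(nrow(ch)), function(k) {
    a <- fir_bandpass(rec$od[, k, 1], rec$sampling_rate, q$cardiac_band)
    b <- fir_bandpass(rec$od[, k, 2], rec$sampling_rate, q$cardiac_band)
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1))
  if (any(is.na(sci))) {
    warn(paste0("SCI undefined (zero-variance cardiac signal) for: ",
                paste(ch$channel[is.na(sci)], collapse = ", ")))
  }
  tibble(channel = ch$channel, role = ch$role, sci = sci,
         bad = flag_bad_channels(sci, q$sci_threshold))
}

#' Flag bad channels from SCI values
#'
#' A channel is bad iff its SCI is strictly below the threshold (an SCI
#' exactly at the threshold is kept); undefined SCI is bad.
#'
#' @param sci numeric vector of SCI values (NA allowed)
#' @param threshold SCI threshold, default 0.7
#' @return logical vector
#' @export
flag_bad_channels <- function(sci, threshold = 0.7) {
  is.na(sci) | sci < threshold
}

# best-fit sphere (algebraic linear least squares); returns center and radius
fit_sphere <- function(p) {
  A <- cbind(2 * p, 1)
  b <- rowSums(p^2)
  sol <- qr.solve(A, b)
  list(center = sol[1:3], radius = sqrt(sol[4] + sum(sol[1:3]^2)))
}

legendre_sum <- function(x, m = 4, n_terms = 7) {
  # g(x) = sum_n (2n+1) / (n(n+1))^m  P_n(x), n = 1..n_terms
  p_prev <- rep(1, length(x))  # P0
  p_cur <- x                   # P1
  out <- 3 / 2^m * p_cur
  for (n in 2:n_terms) {
    p_next <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
    out <- out + (2 * n + 1) / (n * (n + 1))^m * p_next
    p_prev <- p_cur
    p_cur <- p_next
  }
  out / (4 * pi)
}

#' Interpolate bad channels by spherical splines
#'
#' Bad channels are replaced by a spherical-spline estimate (order m = 4,
#' 7 Legendre terms, ridge regularization 1e-5) computed from the good
#' long channels' midpoint positions projected onto a best-fit sphere.
#' Good channels are untouched.
#'
#' @param rec an `optical_recording` at stage `"ssr"`
#' @param bad character vector of bad channel names (e.g. from
#'   [scalp_coupling_index()])
#' @param lambda regularization added to the spline kernel diagonal
#' @return the recording with bad channels replaced, stage `"clean"`
#' @export
interpolate_bad_channels <- function(rec, bad = character(), lambda = 1e-5) {
  check_stage(rec, "ssr", "interpolate_bad_channels")
  ch <- rec$montage$channels
  long_names <- ch$channel[ch$role == "long"]
  bad <- intersect(bad, long_names)
  rec$bad_channels <- bad
  if (length(bad) > 0) {
    good <- setdiff(long_names, bad)
    if (length(good) < 3) stop_data("fewer than 3 good channels; cannot interpolate")
    pos <- as.matrix(ch[match(long_names, ch$channel), c("x", "y", "z")])
    rownames(pos) <- long_names
    sph <- fit_sphere(pos)
    unit <- sweep(pos, 2, sph$center)
    unit <- unit / sqrt(rowSums(unit^2))
    gi <- match(good, long_names)
    bi <- match(bad, long_names)
    cos_gg <- tcrossprod(unit[gi, , drop = FALSE])
    cos_bg <- unit[bi, , drop = FALSE] %*% t(unit[gi, , drop = FALSE])
    G <- legendre_sum(pmin(pmax(cos_gg, -1), 1))
    Gb <- legendre_sum(pmin(pmax(cos_bg, -1), 1))
    ng <- length(gi)
    A <- rbind(cbind(G + diag(lambda, ng), rep(1, ng)), c(rep(1, ng), 0))
    ki <- match(long_names, ch$channel)
    for (wl in seq_len(dim(rec$od)[3])) {
      Z <- t(rec$od[, ki[gi], wl, drop = TRUE])          # good x time
      sol <- solve(A, rbind(Z, 0))                        # (ng+1) x time
      est <- Gb %*% sol[seq_len(ng), , drop = FALSE] +
        matrix(sol[ng + 1, ], length(bi), ncol(Z), byrow = TRUE)
      rec$od[, ki[bi], wl] <- t(est)
    }
  }
  rec$stage <- "clean"
  rec
}

#' Attach manual artifact annotations
#'
#' Annotations are an input (intervals marked by visual inspection), not an
#' algorithm; they ride along with the recording and drive epoch exclusion.
#'
#' @param rec an `optical_recording` or `hemo_recording`
#' @param annotations tibble(onset, duration, label), seconds
#' @return the recording with annotations attached
#' @export
attach_annotations <- function(rec, annotations) {
  stopifnot(all(c("onset", "duration") %in% names(annotations)))
  n <- if (inherits(rec, "optical_recording")) dim(rec$od %||% rec$intensities)[1] else nrow(rec$hbo)
  dur <- n / rec$sampling_rate
  if (any(annotations$onset < 0 | annotations$onset + annotations$duration > dur))
    stop_data("annotation intervals fall outside the recording")
  if (is.null(annotations$label)) annotations$label <- "artifact"
  rec$annotations <- as_tibble(annotations)
  rec
}

#' Convert optical density to hemoglobin concentration changes
#'
#' Inverts the modified Beer-Lambert law per channel:
#' `[HbO, HbR]' = E^-1 [OD_760 / (d ppf_760), OD_850 / (d ppf_850)]'`,
#' with `E` the molar extinction matrix and `d` the source-detector
#' separation; output in micromolar. Only long-separation channels are
#' retained.
#'
#' @param rec an `optical_recording` at stage `"clean"`
#' @param b a [beer_lambert_config()]
#' @return a `hemo_recording` at stage `"hemo"`
#' @export
od_to_hemo <- function(rec, b = beer_lambert_config()) {
  check_stage(rec, "clean", "od_to_hemo")
  ch <- rec$montage$channels
  long_idx <- which(ch$role == "long")
  if (any(!is.finite(ch$separation[long_idx]))) stop_config("unknown channel separation")
  Einv <- solve(b$extinction)
  n <- dim(rec$od)[1]
  hbo <- matrix(0, n, length(long_idx))
  hbr <- matrix(0, n, length(long_idx))
  for (j in seq_along(long_idx)) {
    k <- long_idx[j]
    eff <- ch$separation[k] * b$ppf
    od_scaled <- rbind(rec$od[, k, 1] / eff[1], rec$od[, k, 2] / eff[2])
    conc <- Einv %*% od_scaled * 1e6  # M -> micromolar
    hbo[, j] <- conc[1, ]
    hbr[, j] <- conc[2, ]
  }
  new_hemo_recording(
    hbo, hbr, rec$sampling_rate,
    channels = tibble(channel = ch$channel[long_idx], role = "long"),
    stage = "hemo", annotations = rec$annotations,
    bad_channels = rec$bad_channels, truth = rec$truth
  )
}

#' Negative correlation enhancement
#'
#' Exploits the expected anti-correlation of HbO and HbR to suppress common
#' (systemic) noise: per channel, with `a = sd(HbO) / sd(HbR)`,
#' `HbO' = (HbO - a HbR) / 2` and `HbR' = (HbR - HbO / a) / 2`, after which
#' `cor(HbO', HbR') = -1` exactly.
#'
#' @param hemo a `hemo_recording` at stage `"hemo"`
#' @return the enhanced recording, stage `"enhanced"`
#' @export
negative_correlation_enhance <- function(hemo) {
  check_stage(hemo, "hemo", "negative_correlation_enhance")
  for (k in seq_len(ncol(hemo$hbo))) {
    x <- hemo$hbo[, k]; y <- hemo$hbr[, k]
    sx <- sd(x); sy <- sd(y)
    if (sx == 0 || sy == 0) {
      warn(sprintf("channel %s has zero variance; enhancement skipped",
                   hemo$channels$channel[k]))
      next
    }
    a <- sx / sy
    hemo$hbo[, k] <- (x - a * y) / 2
    hemo$hbr[, k] <- (y - x / a) / 2
  }
  hemo$stage <- "enhanced"
  hemo
}

#' Band-pass filter hemoglobin series
#'
#' Zero-phase Hamming windowed-sinc FIR band-pass with independent
#' transition widths per edge (kernel order follows from the transition
#' widths and is capped at the signal length).
#'
#' @param hemo a `hemo_recording` at stage `"enhanced"`
#' @param q a [quality_config()] giving `filter_band` and `transition_widths`
#' @return the filtered recording, stage `"filtered"`
#' @export
bandpass <- function(hemo, q = quality_config()) {
  check_stage(hemo, "enhanced", "bandpass")
  if (q$filter_band[2] >= hemo$sampling_rate / 2)
    stop_config("upper cutoff at or above Nyquist frequency")
  h <- fir_bandpass_kernel(hemo$sampling_rate, q$filter_band,
                           q$transition_widths, max_length = nrow(hemo$hbo))
  for (k in seq_len(ncol(hemo$hbo))) {
    hemo$hbo[, k] <- apply_fir(hemo$hbo[, k], h)
    hemo$hbr[, k] <- apply_fir(hemo$hbr[, k], h)
  }
  hemo$stage <- "filtered"
  hemo
}

# internal: advance the stage marker when a step is deliberately skipped
advance_stage <- function(rec, to) { rec$stage <- to; rec }

#' Run the full preprocessing chain
#'
#' Fixed order: optical density, TDDR motion correction, short-separation
#' regression, SCI screening, spherical-spline interpolation of bad
#' channels, manual annotations attached, modified Beer-Lambert conversion
#' (long channels retained), negative correlation enhancement, band-pass
#' filtering. Individual steps can be disabled; the remaining steps still
#' run in order.
#'
#' @param rec an `optical_recording` at stage `"raw"`
#' @param beerlambert a [beer_lambert_config()]
#' @param quality a [quality_config()]
#' @param annotations optional tibble(onset, duration, label)
#' @param motion_correction,short_regression,interpolation,enhancement,filter
#'   logical switches for the optional steps
#' @param verbose print per-stage summaries?
#' @return a `hemo_recording`; attribute `"sci"` carries the SCI table
#' @export
preprocess <- function(rec, beerlambert = beer_lambert_config(),
                       quality = quality_config(), annotations = NULL,
                       motion_correction = TRUE, short_regression = TRUE,
                       interpolation = TRUE, enhancement = TRUE, filter = TRUE,
                       verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  rec <- intensity_to_od(rec)
  say("optical density computed (%d channels)", dim(rec$od)[2])
  rec <- if (motion_correction) tddr(rec) else advance_stage(rec, "tddr")
  rec <- if (short_regression) short_channel_regress(rec) else advance_stage(rec, "ssr")
  sci_tbl <- scalp_coupling_index(rec, quality)
  bad <- sci_tbl$channel[sci_tbl$bad & sci_tbl$role == "long"]
  say("SCI screening: %d bad channel(s)", length(bad))
  rec <- if (interpolation) interpolate_bad_channels(rec, bad)
         else { rec$bad_channels <- bad; advance_stage(rec, "clean") }
  if (!is.null(annotations)) rec <- attach_annotations(rec, annotations)
  hemo <- od_to_hemo(rec, beerlambert)
  hemo <- if (enhancement) negative_correlation_enhance(hemo) else advance_stage(hemo, "enhanced")
  hemo <- if (filter) bandpass(hemo, quality) else advance_stage(hemo, "filtered")
  say("preprocessing complete: %d samples x %d long channels", nrow(hemo$hbo), ncol(hemo$hbo))
  attr(hemo, "sci") <- sci_tbl
  hemo
}
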