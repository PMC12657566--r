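new_hemo_recording <- function(hbo, hbr, sampling_rate, channels, stage,
                               annotations = empty_annotations(),
                               bad_channels = character(), truth = NULL) {
  stopifnot(identical(dim(hbo), dim(hbr)))
  structure(list(
    hbo = hbo, hbr = hbr, sampling_rate = sampling_rate,
    channels = channels, annotations = annotations,
    bad_channels = bad_channels, stage = stage, truth = truth
  ), class = "hemo_recording")
}

empty_annotations <- function() {
  tibble(onset = numeric(), duration = numeric(), label = character())
}

#' @export
print.hemo_recording <- function(x, ...) {
  cat(sprintf("<hemo_recording> %d samples x %d channels @ %.2f Hz (stage: %s)\n",
              nrow(x$hbo), ncol(x$hbo), x$sampling_rate, x$stage))
  invisible(x)
}

#' @export
as_tibble.hemo_recording <- function(x, ...) {
  n <- nrow(x$hbo)
  C <- ncol(x$hbo)
  tibble(
    time = rep((seq_len(n) - 1) / x$sampling_rate, C),
    channel = rep(x$channels$channel, each = n),
    hbo = as.vector(x$hbo),
    hbr = as.vector(x$hbr)
  )
}

#' Simulate hemoglobin concentration time series with known connectivity
#'
#' Channels joined by an edge of the latent network share a band-limited
#' (0.01-0.2 Hz) slow component whose variance share equals the edge's
#' coupling strength, so the pairwise Pearson correlation of two coupled
#' channels is approximately the coupling. Cardiac, respiratory and
#' Mayer-wave sinusoids (frequency and phase jittered per channel) and white
#' measurement noise are superimposed; HbR is a negatively scaled copy of
#' HbO plus independent noise.
#'
#' @param network a `latent_network` with as many channels as
#'   `config$n_long_channels`
#' @param config a [sim_config()]
#' @return a `hemo_recording` (micromolar HbO/HbR, long channels only) whose
#'   `truth` field carries the noise-free functional HbO component
#' @export
simulate_hemo <- function(network, config = sim_config()) {
  if (!inherits(network, "latent_network")) stop_param("network must be a latent_network")
  if (network$n_channels != config$n_long_channels)
    stop_param("network size must match config$n_long_channels")
  set.seed(child_seed(config$seed, 2))
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  C <- network$n_channels
  band <- c(0.01, 0.20)

  # target correlation structure: unit diagonal, coupling on edges; clipped
  # to the nearest PSD matrix and renormalized, then realized by mixing
  # independent band-limited factors through its square root
  R <- network$coupling
  diag(R) <- 1
  ee <- eigen(R, symmetric = TRUE)
  L <- ee$vectors %*% diag(sqrt(pmax(ee$values, 0)), C)
  rn <- sqrt(rowSums(L^2))
  rn[rn == 0] <- 1
  L <- L / rn
  Z <- sapply(seq_len(C), function(i) band_limited_noise(n, fs, band))
  functional <- config$hemo_amplitude * (Z %*% t(L))

  # physiological sinusoids, frequency/phase jittered per channel
  tt <- (seq_len(n) - 1) / fs
  physio <- matrix(0, n, C)
  amp <- config$physio_amplitudes
  comps <- list(
    cardiac = stats::runif(1, config$cardiac_band[1], config$cardiac_band[2]),
    respiration = stats::runif(1, config$respiration_band[1], config$respiration_band[2]),
    mayer = config$mayer_freq
  )
  for (nm in names(comps)) {
    a <- amp[[nm]] %||% 0
    if (a > 0) {
      f <- comps[[nm]] * (1 + stats::rnorm(C, 0, 0.02))
      ph <- stats::runif(C, 0, 2 * pi)
      ach <- a * (0.8 + 0.4 * stats::runif(C))
      physio <- physio + sapply(seq_len(C), function(i) ach[i] * sin(2 * pi * f[i] * tt + ph[i]))
    }
  }

  noise <- matrix(rnorm(n * C, 0, config$noise_sd), n, C)
  hbo <- functional + physio + noise
  # slow HbR mirrors HbO negatively; the cardiac/respiratory pulsation is
  # arterial and rides in-phase (attenuated) in HbR
  hbr <- config$hbr_ratio * (functional + noise) +
    config$physio_hbr_ratio * physio +
    matrix(rnorm(n * C, 0, config$hbr_noise), n, C)

  channels <- tibble(
    channel = paste0("CH", sprintf("%02d", seq_len(C))),
    role = "long"
  )
  new_hemo_recording(hbo, hbr, fs, channels, stage = "simulated",
                     truth = list(hbo_functional = functional))
}
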