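#' Simulation configuration
#'
#' Collects the acquisition parameters emulated by the synthetic-data
#' generator: a continuous-wave dual-wavelength (760/850 nm) recording at
#' 5.1 Hz with 44 long channels (~3.5 cm separation) and 8 short channels
#' (~0.76 cm), plus the physiological nuisance bands superimposed on the
#' hemodynamics: cardiac pulsation (1-1.5 Hz), respiration (0.2-0.5 Hz), and
#' Mayer waves (~0.1 Hz).
#'
#' @param sampling_rate sampling rate in Hz
#' @param duration recording length in seconds
#' @param wavelengths the two wavelengths in nm
#' @param n_long_channels,n_short_channels channel counts
#' @param long_separation,short_separation mean source-detector distances, cm
#' @param cardiac_band,respiration_band physiological bands, Hz
#' @param mayer_freq Mayer-wave frequency, Hz
#' @param artifact_rate motion-artifact events per minute
#' @param saturation_rate saturation episodes per recording
#' @param hemo_amplitude SD of the functional HbO component, micromolar
#' @param physio_amplitudes named amplitudes (micromolar) of the cardiac,
#'   respiration and Mayer components of the cortical signal; cardiac
#'   pulsation is strong in cortex, while respiration and Mayer waves are
#'   predominantly systemic and enter mainly through the superficial
#'   compartment (see [simulate_optical()])
#' @param hbr_ratio HbR = hbr_ratio * HbO plus noise (typical empirical -0.4)
#' @param physio_hbr_ratio in-phase fraction of the arterial pulsation
#'   (cardiac/respiratory/Mayer) carried by HbR
#' @param hbr_noise SD of independent HbR noise, micromolar
#' @param noise_sd SD of channel-independent HbO noise, micromolar
#' @param superficial_weight mixing weight of the superficial (scalp)
#'   component into long channels, optical-density fraction
#' @param seed integer seed fixing all randomness downstream
#' @return a list of class `sim_config`
#' @export
sim_config <- function(sampling_rate = 5.1, duration = 300,
                       wavelengths = c(760, 850),
                       n_long_channels = 44, n_short_channels = 8,
                       long_separation = 3.5, short_separation = 0.76,
                       cardiac_band = c(1, 1.5), respiration_band = c(0.2, 0.5),
                       mayer_freq = 0.1,
                       artifact_rate = 0, saturation_rate = 0,
                       hemo_amplitude = 0.5,
                       physio_amplitudes = c(cardiac = 0.3, respiration = 0.05, mayer = 0.08),
                       hbr_ratio = -0.4, physio_hbr_ratio = 0.2,
                       hbr_noise = 0.1, noise_sd = 0.15,
                       superficial_weight = 0.3, seed = 1L) {
  if (sampling_rate <= 2 * 0.20) stop_param("sampling_rate must exceed twice the highest analysis frequency")
  if (!is_count(n_long_channels) || n_long_channels < 1) stop_param("n_long_channels must be positive")
  if (!is_count(n_short_channels)) stop_param("n_short_channels must be a count")
  if (duration <= 0) stop_param("duration must be positive")
  structure(list(
    sampling_rate = sampling_rate, duration = duration, wavelengths = wavelengths,
    n_long_channels = as.integer(n_long_channels),
    n_short_channels = as.integer(n_short_channels),
    long_separation = long_separation, short_separation = short_separation,
    cardiac_band = cardiac_band, respiration_band = respiration_band,
    mayer_freq = mayer_freq, artifact_rate = artifact_rate,
    saturation_rate = saturation_rate, hemo_amplitude = hemo_amplitude,
    physio_amplitudes = physio_amplitudes, hbr_ratio = hbr_ratio,
    physio_hbr_ratio = physio_hbr_ratio,
    hbr_noise = hbr_noise, noise_sd = noise_sd,
    superficial_weight = superficial_weight, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a latent functional network
#'
#' Draws an Erdos-Renyi style undirected graph over channels; each realized
#' edge carries a coupling strength in (0, 1] giving the shared-variance
#' fraction of the two channels' slow hemodynamics. This is the ground truth
#' that the connectivity stage tries to recover.
#'
#' @param n_channels number of channels (graph nodes), at least 2
#' @param edge_probability probability of each edge, in \[0, 1\]
#' @param seed integer seed
#' @param coupling_range range from which edge coupling strengths are drawn
#'   uniformly; use `c(k, k)` for a constant coupling
#' @return object of class `latent_network`: list with `n_channels`,
#'   `adjacency` (symmetric 0/1 matrix, zero diagonal) and `coupling`
#'   (symmetric matrix, nonzero only on edges)
#' @export
simulate_latent_network <- function(n_channels, edge_probability, seed = 1L,
                                    coupling_range = c(0.5, 0.9)) {
  if (!is_count(n_channels) || n_channels < 2) stop_param("n_channels must be a count >= 2")
  if (!is.numeric(edge_probability) || edge_probability < 0 || edge_probability > 1)
    stop_param("edge_probability must lie in [0, 1]")
  set.seed(as.integer(seed))
  n <- as.integer(n_channels)
  adj <- matrix(0L, n, n)
  coup <- matrix(0, n, n)
  ut <- upper.tri(adj)
  n_pairs <- sum(ut)
  e <- rbinom(n_pairs, 1L, edge_probability)
  k <- runif(n_pairs, coupling_range[1], coupling_range[2]) * e
  adj[ut] <- e
  coup[ut] <- k
  adj <- adj + t(adj)
  coup <- coup + t(coup)
  dimnames(adj) <- dimnames(coup) <- NULL
  structure(list(n_channels = n, adjacency = adj, coupling = coup),
            class = "latent_network")
}

#' Simulate a clustered (block) latent network
#'
#' Partitions channels into spatially contiguous clusters of roughly
#' `cluster_size` channels, each cluster fully connected internally. A
#' union of cliques is the latent structure whose correlation-matrix
#' realization is exactly consistent (compound symmetry within blocks), so
#' thresholded degree equals cluster size minus one - the block-like
#' organization seen in resting-state connectivity matrices, where a
#' channel's degree reflects the size of its correlated module.
#'
#' @param n_channels number of channels
#' @param cluster_size target channels per cluster (>= 2); the last cluster
#'   absorbs the remainder
#' @param seed integer seed (coupling draws)
#' @param coupling_range range of within-cluster coupling strengths (one
#'   draw per cluster)
#' @return a `latent_network`
#' @export
simulate_clustered_network <- function(n_channels, cluster_size, seed = 1L,
                                       coupling_range = c(0.85, 0.95)) {
  if (!is_count(n_channels) || n_channels < 2) stop_param("n_channels must be a count >= 2")
  if (!is.numeric(cluster_size) || cluster_size < 2) stop_param("cluster_size must be >= 2")
  set.seed(as.integer(seed))
  n <- as.integer(n_channels)
  sizes <- rep(floor(cluster_size), n %/% floor(cluster_size))
  if (sum(sizes) < n) {
    rem <- n - sum(sizes)
    if (rem >= 2 || length(sizes) == 0) sizes <- c(sizes, rem)
    else sizes[length(sizes)] <- sizes[length(sizes)] + rem
  }
  member <- rep(seq_along(sizes), sizes)
  adj <- 1L * outer(member, member, `==`)
  diag(adj) <- 0L
  coup <- matrix(0, n, n)
  k_cl <- runif(length(sizes), coupling_range[1], coupling_range[2])
  coup[adj == 1] <- k_cl[member[row(adj)[adj == 1]]]
  coup <- (coup + t(coup)) / 2
  structure(list(n_channels = n, adjacency = adj, coupling = coup),
            class = "latent_network")
}

#' @export
print.latent_network <- function(x, ...) {
  cat(sprintf("<latent_network> %d channels, %d edges\n",
              x$n_channels, sum(x$adjacency) / 2))
  invisible(x)
}

#' True degree of a latent network
#' @param network a `latent_network`
#' @return tibble(channel, degree)
#' @export
latent_degree <- function(network) {
  tibble(channel = paste0("CH", sprintf("%02d", seq_len(network$n_channels))),
         degree = as.integer(rowSums(network$adjacency)))
}
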