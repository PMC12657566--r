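PIPELINE_FIELDS <- c(
  "sampling_rate", "duration", "n_channels", "n_short_channels",
  "network_model", "edge_probability", "cluster_size", "cluster_size_sd",
  "coupling_range",
  "artifact_rate", "saturation_rate",
  "superficial_weight", "sci_threshold", "filter_band", "transition_widths",
  "epoch_length", "overlap", "saturation_limit", "threshold", "aggregate",
  "n_per_group", "chains", "iter", "warmup", "n_draws", "rope_frac",
  "hdi_mass", "seed"
)

#' Pipeline configuration
#'
#' All tunables of the synthetic cohort, preprocessing, connectivity and
#' inference stages, with the study's values as defaults. The cohort size
#' defaults to the 5 / 5 / 4 split of the emulated recording subset.
#' `edge_probability` may be a single number or a 3 x 3 matrix
#' (rows = DLPFC, VLPFC, Sham; columns = Pre, Post, Post1month) giving each
#' cell its own latent edge density - the handle for injecting group,
#' session or interaction effects into the synthetic cohort.
#'
#' @param sampling_rate Hz
#' @param duration recording length per session, s
#' @param n_channels long channels
#' @param n_short_channels short channels
#' @param network_model `"clustered"` (default; block networks whose
#'   thresholded degree tracks cluster size) or `"erdos_renyi"`
#' @param edge_probability scalar or 3 x 3 matrix of latent edge densities
#'   (Erdos-Renyi model)
#' @param cluster_size scalar or 3 x 3 matrix of latent cluster sizes
#'   (clustered model); cell-wise differences inject group/session effects
#' @param cluster_size_sd SD of the per-recording jitter around the cell's
#'   cluster size (individual variability in module size; also keeps the
#'   model's hierarchical scales identified)
#' @param coupling_range range of latent coupling strengths
#' @param artifact_rate motion artifacts per minute
#' @param saturation_rate saturation episodes per recording
#' @param superficial_weight scalp-signal mixing weight
#' @param sci_threshold SCI screening threshold
#' @param filter_band,transition_widths band-pass specification, Hz
#' @param epoch_length,overlap epoching, s
#' @param saturation_limit epoch exclusion limit, micromolar
#' @param threshold binarization threshold on |r|
#' @param aggregate `"mean_abs_r"` or `"concatenate"`
#' @param n_per_group named participants per group
#' @param chains,iter,warmup MCMC settings
#' @param n_draws marginal-prediction draws
#' @param rope_frac ROPE fraction of the response SD
#' @param hdi_mass HDI probability mass
#' @param seed master seed; all stage seeds derive from it
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(sampling_rate = 5.1, duration = 300,
                            n_channels = 44, n_short_channels = 8,
                            network_model = "clustered",
                            edge_probability = 0.35,
                            cluster_size = 15,
                            cluster_size_sd = 2,
                            coupling_range = c(0.85, 0.95),
                            artifact_rate = 2, saturation_rate = 0.2,
                            superficial_weight = 0.3,
                            sci_threshold = 0.7,
                            filter_band = c(0.01, 0.20),
                            transition_widths = c(0.01, 0.2),
                            epoch_length = 30, overlap = 5,
                            saturation_limit = 10, threshold = 0.5,
                            aggregate = "mean_abs_r",
                            n_per_group = c(DLPFC = 5, VLPFC = 5, Sham = 4),
                            chains = 8, iter = 2000, warmup = 1000,
                            n_draws = 1000, rope_frac = 0.1, hdi_mass = 0.89,
                            seed = 1L) {
  cfg <- structure(mget(PIPELINE_FIELDS), class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  unknown <- setdiff(names(cfg), PIPELINE_FIELDS)
  if (length(unknown) > 0)
    stop_config(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  if (!is.numeric(cfg$threshold) || cfg$threshold <= 0 || cfg$threshold > 1)
    stop_config("threshold must lie in (0, 1]")
  ep <- cfg$edge_probability
  if (any(ep < 0) || any(ep > 1)) stop_config("edge_probability must lie in [0, 1]")
  if (is.matrix(ep) && any(dim(ep) != c(3, 3)))
    stop_config("matrix edge_probability must be 3 x 3 (group x session)")
  if (!cfg$network_model %in% c("clustered", "erdos_renyi"))
    stop_config("network_model must be 'clustered' or 'erdos_renyi'")
  cs <- cfg$cluster_size
  if (any(cs < 2)) stop_config("cluster_size must be >= 2")
  if (is.matrix(cs) && any(dim(cs) != c(3, 3)))
    stop_config("matrix cluster_size must be 3 x 3 (group x session)")
  if (cfg$overlap >= cfg$epoch_length) stop_config("overlap must be below epoch_length")
  if (cfg$warmup >= cfg$iter) stop_config("warmup must be below iter")
  invisible(cfg)
}

#' Serialize / restore a pipeline configuration (JSON)
#' @param cfg a `pipeline_config`
#' @param path file path
#' @export
write_pipeline_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("edge_probability", "cluster_size")) {
    if (!is.null(x[[f]]) && is.matrix(x[[f]])) {
      dimnames(x[[f]]) <- list(c("DLPFC", "VLPFC", "Sham"), SESSION_LEVELS)
    }
  }
  cfg <- structure(x[PIPELINE_FIELDS], class = "pipeline_config")
  names(cfg) <- PIPELINE_FIELDS
  extra <- setdiff(names(x), PIPELINE_FIELDS)
  if (length(extra) > 0)
    stop_config(paste0("unknown config key(s): ", paste(extra, collapse = ", ")))
  validate_pipeline_config(cfg)
  cfg
}

cell_value <- function(x, group, session) {
  if (is.matrix(x)) x[group, as.character(session)] else x
}

cell_network <- function(cfg, group, session, seed) {
  if (cfg$network_model == "clustered") {
    base <- cell_value(cfg$cluster_size, group, session)
    set.seed(seed)
    size <- max(2, round(rnorm(1, base, cfg$cluster_size_sd %||% 0)))
    size <- min(size, cfg$n_channels)
    simulate_clustered_network(cfg$n_channels, size,
                               seed = seed, coupling_range = cfg$coupling_range)
  } else {
    simulate_latent_network(cfg$n_channels,
                            cell_value(cfg$edge_probability, group, session),
                            seed = seed, coupling_range = cfg$coupling_range)
  }
}

#' Run the complete synthetic-cohort pipeline
#'
#' Simulates a cohort of raw optical recordings with known latent
#' connectivity (one latent network per participant-session), preprocesses
#' each recording, computes binarized connectivity degree, fits the
#' multilevel Poisson model, and applies the HDI + ROPE decision layer to
#' all 18 pairwise contrasts. Every stage's randomness derives from the
#' master seed.
#'
#' @param config a [pipeline_config()]
#' @param verbose print per-stage progress
#' @return object of class `pipeline_report`: list with `degree_data`,
#'   `fit`, `convergence`, `comparisons`, `stage_log`, `config`
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  validate_pipeline_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  n_per_group <- config$n_per_group
  groups <- rep(names(n_per_group), n_per_group)
  pid <- paste0("P", sprintf("%02d", seq_along(groups)))
  bl <- beer_lambert_config()
  q <- quality_config(sci_threshold = config$sci_threshold,
                      filter_band = config$filter_band,
                      transition_widths = config$transition_widths)
  rows <- list()
  log <- list(excluded_epochs = 0L, bad_channels = 0L, recordings = 0L)
  r <- 0L
  for (i in seq_along(pid)) {
    for (s in SESSION_LEVELS) {
      r <- r + 1L
      sc <- sim_config(
        sampling_rate = config$sampling_rate, duration = config$duration,
        n_long_channels = config$n_channels,
        n_short_channels = config$n_short_channels,
        artifact_rate = config$artifact_rate,
        saturation_rate = config$saturation_rate,
        superficial_weight = config$superficial_weight,
        seed = child_seed(config$seed, 100 + r)
      )
      net <- cell_network(config, groups[i], s, child_seed(config$seed, 200 + r))
      hemo_true <- simulate_hemo(net, sc)
      rec <- simulate_optical(hemo_true, sc, bl)
      hemo <- preprocess(rec, bl, q)
      log$bad_channels <- log$bad_channels + length(hemo$bad_channels)
      eps <- segment_epochs(hemo, config$epoch_length, config$overlap)
      eps <- exclude_epochs(eps, saturation_limit = config$saturation_limit)
      log$excluded_epochs <- log$excluded_epochs + sum(eps$status != "kept")
      conn <- connectivity_matrix(eps, config$aggregate)
      conn <- binarize_and_degree(conn, config$threshold)
      rows[[r]] <- degree_table(conn, pid[i], groups[i], s)
      say("recording %d/%d: %s %s (%d epochs kept)", r,
          length(pid) * 3, pid[i], s, conn$n_epochs_used)
    }
  }
  log$recordings <- r
  degree_data <- dplyr::bind_rows(rows)
  say("fitting the multilevel Poisson model (%d chains x %d iterations)",
      config$chains, config$iter)
  fit <- fit_poisson_glmm(degree_data, chains = config$chains,
                          iter = config$iter, warmup = config$warmup,
                          seed = child_seed(config$seed, 300))
  conv <- if (config$chains >= 2) check_convergence(fit) else NULL
  cmp <- compare_cells(fit, degree_data, n_draws = config$n_draws,
                       seed = child_seed(config$seed, 400),
                       rope_frac = config$rope_frac,
                       hdi_mass = config$hdi_mass)
  say("decision layer: %d comparisons, %d rejected, %d supported",
      nrow(cmp), sum(cmp$decision == "rejected"), sum(cmp$decision == "supported"))
  structure(list(
    degree_data = degree_data, fit = fit, convergence = conv,
    comparisons = cmp, stage_log = log, config = config
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> seed %s: %d recordings, %d degree rows\n",
              format(x$config$seed), x$stage_log$recordings, nrow(x$degree_data)))
  if (!is.null(x$convergence)) print(x$convergence)
  tab <- table(x$comparisons$decision)
  cat(sprintf("decisions: %d rejected / %d inconclusive / %d supported\n",
              tab[["rejected"]], tab[["inconclusive"]], tab[["supported"]]))
  invisible(x)
}
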