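# JAGS model for the multilevel Poisson degree model: log link; fixed Group,
# Session, Group x Session; channel random intercepts and Group/Session/
# interaction slopes; participant random intercepts and Session slopes.
# Reference levels are absorbed by fixing their coefficients at zero, which
# is exactly treatment (dummy) coding. Priors: Normal(0, 2.5) on the betas,
# Exponential(rate 2) on every random-effect SD.
degree_glmm_code <- "
model {
  for (n in 1:N) {
    y[n] ~ dpois(lam[n])
    log(lam[n]) <- b0 + u0[ch[n]] + w0[p[n]] +
      bG[g[n]] + uG[ch[n], g[n]] +
      bS[s[n]] + uS[ch[n], s[n]] + wS[p[n], s[n]] +
      bGS[g[n], s[n]] + uGS[ch[n], g[n], s[n]]
  }
  b0 ~ dnorm(0, prec_b)
  bG[1] <- 0
  bS[1] <- 0
  for (k in 2:nG) { bG[k] ~ dnorm(0, prec_b) }
  for (k in 2:nS) { bS[k] ~ dnorm(0, prec_b) }
  for (k in 1:nG) { bGS[k, 1] <- 0 }
  for (l in 2:nS) { bGS[1, l] <- 0 }
  for (k in 2:nG) { for (l in 2:nS) { bGS[k, l] ~ dnorm(0, prec_b) } }
  for (c in 1:C) {
    u0[c] ~ dnorm(0, tau_u[1])
    uG[c, 1] <- 0
    uS[c, 1] <- 0
    for (k in 2:nG) { uG[c, k] ~ dnorm(0, tau_u[2]) }
    for (k in 2:nS) { uS[c, k] ~ dnorm(0, tau_u[3]) }
    for (k in 1:nG) { uGS[c, k, 1] <- 0 }
    for (l in 2:nS) { uGS[c, 1, l] <- 0 }
    for (k in 2:nG) { for (l in 2:nS) { uGS[c, k, l] ~ dnorm(0, tau_u[4]) } }
  }
  for (j in 1:P) {
    w0[j] ~ dnorm(0, tau_w[1])
    wS[j, 1] <- 0
    for (k in 2:nS) { wS[j, k] ~ dnorm(0, tau_w[k]) }
  }
  for (m in 1:4) { sigma_u[m] ~ dexp(2); tau_u[m] <- pow(sigma_u[m], -2) }
  for (m in 1:nS) { sigma_w[m] ~ dexp(2); tau_w[m] <- pow(sigma_w[m], -2) }
  prec_b <- pow(2.5, -2)
}
"

validate_degree_table <- function(data) {
  need <- c("participant", "group", "session", "channel", "degree")
  if (!all(need %in% names(data))) {
    stop_data(paste0("degree table must have columns: ", paste(need, collapse = ", ")))
  }
  if (any(!is.finite(data$degree)) || any(data$degree < 0) ||
      any(data$degree != floor(data$degree))) {
    stop_data("degree must be a non-negative integer response")
  }
  data$group <- droplevels(factor(data$group, levels = GROUP_LEVELS))
  data$session <- droplevels(factor(data$session, levels = SESSION_LEVELS))
  if (any(is.na(data$group)) || any(is.na(data$session)))
    stop_data("group/session labels outside the known factor levels")
  data
}

#' Fit the multilevel Poisson model of connectivity degree
#'
#' Bayesian Poisson regression of channel degree on Group, Session and their
#' interaction (treatment coding, reference levels Sham and Pre), with
#' channel-level random intercepts and random slopes for Group, Session and
#' the interaction, and participant-level random intercepts and Session
#' slopes. Priors are Normal(0, 2.5) on the fixed effects and
#' Exponential(rate 2, mean 0.5) on all random-effect SDs. Sampling is MCMC
#' (JAGS with the `glm` block samplers); defaults are 8 chains of 2,000
#' iterations, the first 1,000 of which are warm-up, retaining
#' `chains * (iter - warmup)` draws.
#'
#' @param data a degree table: tibble(participant, group, session, channel,
#'   degree); at least 2 participants per group and 2 sessions
#' @param chains number of MCMC chains (default 8)
#' @param iter iterations per chain (default 2000)
#' @param warmup warm-up (adaptation + burn-in) iterations per chain
#'   (default 1000)
#' @param seed integer seed controlling all chains
#' @param sample_prior if `TRUE` the response is masked and the draws come
#'   from the prior (prior predictive checking)
#' @param quiet suppress JAGS progress output
#' @param monitor parameters to record; `NULL` (default) records everything
#'   (needed for marginal predictions). Restricting, e.g. to `"bGS"`, saves
#'   memory in large simulation studies
#' @return an object of class `degree_glmm`
#' @export
fit_poisson_glmm <- function(data, chains = 8, iter = 2000, warmup = 1000,
                             seed = 1L, sample_prior = FALSE, quiet = TRUE,
                             monitor = NULL) {
  data <- validate_degree_table(data)
  tab <- table(unique(data[c("participant", "group")])$group)
  if (any(tab[tab > 0] < 2)) stop_data("need at least 2 participants per group")
  if (nlevels(data$session) < 2) stop_data("need at least 2 sessions")
  if (nlevels(data$group) < 2) stop_data("need at least 2 groups")

  participants <- sort(unique(data$participant))
  channels <- sort(unique(data$channel))
  jd <- list(
    y = if (sample_prior) rep(NA_real_, nrow(data)) else as.numeric(data$degree),
    ch = match(data$channel, channels),
    p = match(data$participant, participants),
    g = as.integer(data$group),
    s = as.integer(data$session),
    N = nrow(data), C = length(channels), P = length(participants),
    nG = nlevels(data$group), nS = nlevels(data$session)
  )
  rjags::load.module("glm", quiet = TRUE)
  # SDs start at 1: tiny prior-drawn initial scales can trap the centered
  # Gibbs sampler in the sigma ~ 0 corner (random effects and their SD
  # reinforce each other at zero)
  inits <- lapply(seq_len(chains), function(k) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = child_seed(seed, k),
         sigma_u = rep(1, 4), sigma_w = rep(1, jd$nS))
  })
  n_adapt <- max(100L, min(as.integer(warmup) %/% 2L, 500L))
  n_burn <- max(0L, as.integer(warmup) - n_adapt)
  jm <- rjags::jags.model(textConnection(degree_glmm_code), data = jd,
                          inits = inits, n.chains = chains,
                          n.adapt = n_adapt, quiet = quiet)
  if (n_burn > 0) update(jm, n_burn, progress.bar = if (quiet) "none" else "text")
  monitor <- monitor %||% c("b0", "bG", "bS", "bGS", "u0", "uG", "uS", "uGS",
                            "w0", "wS", "sigma_u", "sigma_w")
  draws <- rjags::coda.samples(jm, monitor, n.iter = iter - warmup,
                               progress.bar = if (quiet) "none" else "text")
  structure(list(
    draws = draws, data = data,
    participants = participants, channels = channels,
    group_levels = levels(data$group), session_levels = levels(data$session),
    n_chains = chains, n_iter = iter, n_warmup = warmup, seed = seed,
    sample_prior = sample_prior
  ), class = "degree_glmm")
}

#' @export
print.degree_glmm <- function(x, ...) {
  cat(sprintf("<degree_glmm> %d obs, %d channels, %d participants; %d chains x %d iter (%d warmup)\n",
              nrow(x$data), length(x$channels), length(x$participants),
              x$n_chains, x$n_iter, x$n_warmup))
  invisible(x)
}

# combined draws matrix (rows = retained draws across chains)
draw_matrix <- function(fit) {
  as.matrix(fit$draws)
}

# human-readable names for the structural (fixed + SD) parameters
fixed_effect_map <- function(fit) {
  g <- fit$group_levels; s <- fit$session_levels
  map <- c(b0 = "(Intercept)")
  for (k in seq_along(g)[-1]) map[sprintf("bG[%d]", k)] <- paste0("group", g[k])
  for (k in seq_along(s)[-1]) map[sprintf("bS[%d]", k)] <- paste0("session", s[k])
  for (k in seq_along(g)[-1]) for (l in seq_along(s)[-1])
    map[sprintf("bGS[%d,%d]", k, l)] <- paste0("group", g[k], ":session", s[l])
  sd_names <- c("sd_channel_(Intercept)", "sd_channel_group", "sd_channel_session",
                "sd_channel_group:session")
  for (m in 1:4) map[sprintf("sigma_u[%d]", m)] <- sd_names[m]
  map["sigma_w[1]"] <- "sd_participant_(Intercept)"
  for (k in seq_along(s)[-1])
    map[sprintf("sigma_w[%d]", k)] <- paste0("sd_participant_session", s[k])
  map
}

#' Convergence diagnostics for every monitored parameter
#'
#' R-hat is the potential scale reduction factor across chains; ESS is the
#' autocorrelation-adjusted effective number of draws summed over chains.
#'
#' @param fit a `degree_glmm`
#' @return tibble(parameter, rhat, ess)
#' @export
convergence_diagnostics <- function(fit) {
  if (fit$n_chains < 2) stop_data("R-hat requires at least 2 chains")
  # drop structurally constant columns (reference-level zeros)
  mat1 <- as.matrix(fit$draws[[1]])
  vn <- colnames(mat1)
  varying <- vn[apply(mat1, 2, function(v) stats::var(v) > 0)]
  sub <- fit$draws[, varying, drop = FALSE]
  gd <- coda::gelman.diag(sub, autoburnin = FALSE, multivariate = FALSE)
  ess <- coda::effectiveSize(sub)
  tibble(parameter = varying,
         rhat = gd$psrf[, 1],
         ess = as.numeric(ess[varying]))
}

#' Check MCMC convergence against R-hat and ESS thresholds
#'
#' Passes iff the largest R-hat does not exceed `rhat_max` (default 1.01)
#' and the smallest effective sample size is at least `ess_min`
#' (default 400).
#'
#' @param fit a `degree_glmm` fitted with at least 2 chains
#' @param rhat_max maximum acceptable R-hat
#' @param ess_min minimum acceptable effective sample size
#' @return list of class `convergence_report`: `pass`, `max_rhat`,
#'   `min_ess`, `offending` (tibble of failing parameters), `table`
#' @export
check_convergence <- function(fit, rhat_max = 1.01, ess_min = 400) {
  d <- convergence_diagnostics(fit)
  off <- d[d$rhat > rhat_max | d$ess < ess_min, ]
  structure(list(
    pass = nrow(off) == 0,
    max_rhat = max(d$rhat), min_ess = min(d$ess),
    rhat_max = rhat_max, ess_min = ess_min,
    offending = off, table = d
  ), class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("<convergence_report> %s: max R-hat %.4f (limit %.3f), min ESS %.0f (limit %.0f)\n",
              if (x$pass) "PASS" else "FAIL", x$max_rhat, x$rhat_max,
              x$min_ess, x$ess_min))
  if (!x$pass) {
    cat(sprintf("  %d offending parameter(s), e.g. %s\n", nrow(x$offending),
                paste(utils::head(x$offending$parameter, 5), collapse = ", ")))
  }
  invisible(x)
}

#' @describeIn fit_poisson_glmm posterior summary of the structural
#'   parameters (fixed effects and random-effect SDs): median, MAD,
#'   89% HDI, and (with >= 2 chains) R-hat and ESS
#' @param x a `degree_glmm`
#' @param hdi_mass probability mass of the reported HDI
#' @param diagnostics include R-hat / ESS columns?
#' @param ... unused
#' @method tidy degree_glmm
#' @export
tidy.degree_glmm <- function(x, hdi_mass = 0.89,
                             diagnostics = x$n_chains >= 2, ...) {
  map <- fixed_effect_map(x)
  mat <- draw_matrix(x)[, names(map), drop = FALSE]
  hd <- apply(mat, 2, hdi, mass = hdi_mass)
  out <- tibble(
    term = unname(map),
    estimate = apply(mat, 2, median),
    std.error = apply(mat, 2, stats::mad),
    conf.low = hd[1, ], conf.high = hd[2, ]
  )
  if (diagnostics) {
    d <- convergence_diagnostics(x)
    idx <- match(names(map), d$parameter)
    out$rhat <- d$rhat[idx]
    out$ess <- d$ess[idx]
  }
  out
}

#' @describeIn fit_poisson_glmm one-row fit summary
#' @method glance degree_glmm
#' @export
glance.degree_glmm <- function(x, ...) {
  out <- tibble(
    n_obs = nrow(x$data),
    n_channels = length(x$channels),
    n_participants = length(x$participants),
    n_chains = x$n_chains, n_iter = x$n_iter, n_warmup = x$n_warmup,
    n_draws = x$n_chains * (x$n_iter - x$n_warmup)
  )
  if (x$n_chains >= 2) {
    d <- convergence_diagnostics(x)
    out$max_rhat <- max(d$rhat)
    out$min_ess <- min(d$ess)
  }
  out
}

#' Poisson log-likelihood of a degree table at given parameters
#'
#' Evaluates the model's conditional log-likelihood (sum of Poisson log
#' densities with the log-link linear predictor) at a full parameter
#' configuration: fixed effects from `params` and random effects from
#' `effects` (defaulting to the ground-truth effects attached by
#' [simulate_degree_dataset()]).
#'
#' @param data a degree table
#' @param params a [degree_model_params()]
#' @param effects list with u0, uG, uS, uGS, w0, wS indexed like the
#'   generator's draws
#' @return scalar log-likelihood
#' @export
degree_model_loglik <- function(data, params, effects = attr(data, "effects")) {
  data <- validate_degree_table(data)
  if (is.null(effects)) stop_param("effects must be supplied (or attached to data)")
  ch <- as.integer(factor(data$channel, levels = sort(unique(data$channel))))
  p <- as.integer(factor(data$participant, levels = sort(unique(data$participant))))
  gi <- as.integer(data$group) - 1L
  si <- as.integer(data$session) - 1L
  eta <- params$beta0 + effects$u0[ch] + effects$w0[p]
  hasg <- gi > 0; hass <- si > 0
  eta[hasg] <- eta[hasg] + params$beta_group[gi[hasg]] + effects$uG[cbind(ch[hasg], gi[hasg])]
  eta[hass] <- eta[hass] + params$beta_session[si[hass]] +
    effects$uS[cbind(ch[hass], si[hass])] + effects$wS[cbind(p[hass], si[hass])]
  both <- hasg & hass
  eta[both] <- eta[both] + params$beta_interaction[cbind(gi[both], si[both])] +
    effects$uGS[cbind(ch[both], gi[both], si[both])]
  sum(stats::dpois(data$degree, exp(eta), log = TRUE))
}
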