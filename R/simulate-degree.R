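GROUP_LEVELS <- c("Sham", "DLPFC", "VLPFC")     # Sham is the reference level
SESSION_LEVELS <- c("Pre", "Post", "Post1month") # Pre is the reference level

#' Parameters of the multilevel Poisson degree model
#'
#' Fixed effects are on the log scale with treatment coding (reference
#' levels Sham and Pre). Random-effect SDs: `sigma_u` has four entries for
#' the channel-level intercept, Group slopes, Session slopes, and
#' Group x Session slopes (each block shares one SD); `sigma_w` has three
#' entries for the participant-level intercept and the two Session-contrast
#' slopes.
#'
#' @param beta0 intercept, log expected degree of Sham at Pre
#' @param beta_group named length-2 vector, contrasts `DLPFC`, `VLPFC`
#' @param beta_session named length-2 vector, contrasts `Post`, `Post1month`
#' @param beta_interaction 2x2 matrix, rows = group contrasts, cols = session
#'   contrasts
#' @param sigma_u length-4 non-negative SDs of channel random effects
#' @param sigma_w length-3 non-negative SDs of participant random effects
#' @return list of class `degree_model_params`
#' @export
degree_model_params <- function(beta0 = log(15),
                                beta_group = c(DLPFC = 0, VLPFC = 0),
                                beta_session = c(Post = 0, Post1month = 0),
                                beta_interaction = matrix(0, 2, 2),
                                sigma_u = c(0.3, 0.1, 0.1, 0.1),
                                sigma_w = c(0.2, 0.1, 0.1)) {
  beta_interaction <- matrix(beta_interaction, 2, 2,
                             dimnames = list(c("DLPFC", "VLPFC"), c("Post", "Post1month")))
  if (length(sigma_u) != 4 || length(sigma_w) != 3)
    stop_param("sigma_u must have 4 entries and sigma_w 3")
  if (any(sigma_u < 0) || any(sigma_w < 0))
    stop_param("random-effect SDs must be non-negative")
  structure(list(
    beta0 = beta0,
    beta_group = beta_group[c("DLPFC", "VLPFC")],
    beta_session = beta_session[c("Post", "Post1month")],
    beta_interaction = beta_interaction,
    sigma_u = sigma_u, sigma_w = sigma_w
  ), class = "degree_model_params")
}

#' Simulate a long-format degree-count dataset from the generative model
#'
#' Counts are drawn from the exact multilevel Poisson likelihood (log link,
#' Group, Session and their interaction as fixed effects; channel random
#' intercepts and Group/Session/interaction slopes; participant random
#' intercepts and Session slopes) with known coefficients, so model fitting
#' can be validated by parameter recovery. By default the Poisson support is
#' left unbounded, matching the analysis model; `clip = TRUE` truncates at
#' the graph-theoretic maximum `n_channels - 1` for realism.
#'
#' @param params a [degree_model_params()]
#' @param n_per_group participants per group, named `DLPFC`, `VLPFC`, `Sham`
#'   (an unnamed triple is taken in that order)
#' @param n_channels number of channels
#' @param seed integer seed
#' @param clip truncate counts to `[0, n_channels - 1]`?
#' @return tibble(participant, group, session, channel, degree)
#' @export
simulate_degree_dataset <- function(params = degree_model_params(),
                                    n_per_group = c(DLPFC = 15, VLPFC = 15, Sham = 15),
                                    n_channels = 44, seed = 1L, clip = FALSE) {
  if (!inherits(params, "degree_model_params")) stop_param("params must be degree_model_params")
  if (is.null(names(n_per_group))) names(n_per_group) <- c("DLPFC", "VLPFC", "Sham")
  if (!is_count(n_channels) || n_channels < 1) stop_param("n_channels must be a positive count")
  set.seed(as.integer(seed))

  n_p <- sum(n_per_group)
  pgroup <- factor(rep(names(n_per_group), n_per_group), levels = GROUP_LEVELS)
  pid <- paste0("P", sprintf("%02d", seq_len(n_p)))

  # random effects
  u0 <- rnorm(n_channels, 0, params$sigma_u[1])
  uG <- matrix(rnorm(n_channels * 2, 0, params$sigma_u[2]), n_channels, 2)
  uS <- matrix(rnorm(n_channels * 2, 0, params$sigma_u[3]), n_channels, 2)
  uGS <- array(rnorm(n_channels * 4, 0, params$sigma_u[4]), dim = c(n_channels, 2, 2))
  w0 <- rnorm(n_p, 0, params$sigma_w[1])
  wS <- cbind(rnorm(n_p, 0, params$sigma_w[2]), rnorm(n_p, 0, params$sigma_w[3]))

  d <- tidyr::expand_grid(
    p = seq_len(n_p),
    session = factor(SESSION_LEVELS, levels = SESSION_LEVELS),
    ch = seq_len(n_channels)
  )
  gi <- as.integer(pgroup[d$p]) - 1L   # 0 = Sham (ref), 1 = DLPFC, 2 = VLPFC
  si <- as.integer(d$session) - 1L     # 0 = Pre (ref), 1 = Post, 2 = Post1month
  eta <- params$beta0 + u0[d$ch] + w0[d$p]
  hasg <- gi > 0; hass <- si > 0
  eta[hasg] <- eta[hasg] + params$beta_group[gi[hasg]] + uG[cbind(d$ch[hasg], gi[hasg])]
  eta[hass] <- eta[hass] + params$beta_session[si[hass]] +
    uS[cbind(d$ch[hass], si[hass])] + wS[cbind(d$p[hass], si[hass])]
  both <- hasg & hass
  eta[both] <- eta[both] + params$beta_interaction[cbind(gi[both], si[both])] +
    uGS[cbind(d$ch[both], gi[both], si[both])]

  y <- rpois(nrow(d), exp(eta))
  if (clip) y <- pmin(y, n_channels - 1L)

  out <- tibble(
    participant = pid[d$p],
    group = pgroup[d$p],
    session = d$session,
    channel = paste0("CH", sprintf("%02d", d$ch)),
    degree = as.integer(y)
  )
  # ground-truth parameters and effect draws, for likelihood/recovery checks
  attr(out, "params") <- params
  attr(out, "effects") <- list(u0 = u0, uG = uG, uS = uS, uGS = uGS,
                               w0 = w0, wS = wS)
  out
}
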