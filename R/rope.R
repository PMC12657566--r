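#' Highest density interval
#'
#' The narrowest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws (sorted-window algorithm; ties broken by the earliest
#' window).
#'
#' @param samples numeric vector of posterior draws (at least 50)
#' @param mass probability mass, default 0.89
#' @return named numeric `c(low, high)`
#' @export
hdi <- function(samples, mass = 0.89) {
  n <- length(samples)
  if (n < 50) stop_param("hdi needs at least 50 samples")
  if (!is.numeric(mass) || mass <= 0 || mass >= 1) stop_param("mass must lie in (0, 1)")
  xs <- sort(samples)
  k <- ceiling(mass * n)
  lows <- xs[seq_len(n - k + 1)]
  highs <- xs[seq(k, n)]
  i <- which.min(highs - lows)
  c(low = lows[i], high = highs[i])
}

#' Average marginal posterior predictions per Group x Session cell
#'
#' For each of `n_draws` (seeded, without replacement) posterior draws, the
#' model's expected degree is computed for every observed
#' (participant, channel) unit under each Group x Session cell - including
#' that unit's random effects - and averaged across units, yielding one
#' mean posterior prediction per cell per draw.
#'
#' @param fit a `degree_glmm`
#' @param data degree table defining the unit population; defaults to the
#'   fitted data
#' @param n_draws number of posterior draws to use (default 1000)
#' @param seed seed for the draw subsample
#' @return object of class `marginal_predictions`: tibble(draw, group,
#'   session, .prediction)
#' @export
marginal_predictions <- function(fit, data = fit$data, n_draws = 1000, seed = 1L) {
  mat <- draw_matrix(fit)
  if (n_draws > nrow(mat)) stop_param("n_draws exceeds the number of retained draws")
  set.seed(as.integer(seed))
  idx <- sort(sample.int(nrow(mat), n_draws))
  mat <- mat[idx, , drop = FALSE]

  units <- dplyr::distinct(data, .data$participant, .data$channel)
  ch <- match(units$channel, fit$channels)
  pp <- match(units$participant, fit$participants)
  if (any(is.na(ch)) || any(is.na(pp)))
    stop_param("data contains units unseen by the fit")
  nu <- nrow(units)
  col <- function(nm) mat[, nm, drop = TRUE]

  g_lev <- fit$group_levels; s_lev <- fit$session_levels
  base <- mat[, "b0"] +
    mat[, sprintf("u0[%d]", ch), drop = FALSE] +
    mat[, sprintf("w0[%d]", pp), drop = FALSE]
  out <- list()
  for (gi in seq_along(g_lev)) for (si in seq_along(s_lev)) {
    eta <- base
    if (gi > 1) {
      eta <- eta + col(sprintf("bG[%d]", gi)) +
        mat[, sprintf("uG[%d,%d]", ch, gi), drop = FALSE]
    }
    if (si > 1) {
      eta <- eta + col(sprintf("bS[%d]", si)) +
        mat[, sprintf("uS[%d,%d]", ch, si), drop = FALSE] +
        mat[, sprintf("wS[%d,%d]", pp, si), drop = FALSE]
    }
    if (gi > 1 && si > 1) {
      eta <- eta + col(sprintf("bGS[%d,%d]", gi, si)) +
        mat[, sprintf("uGS[%d,%d,%d]", ch, gi, si), drop = FALSE]
    }
    out[[length(out) + 1]] <- tibble(
      draw = seq_len(n_draws),
      group = factor(g_lev[gi], levels = g_lev),
      session = factor(s_lev[si], levels = s_lev),
      .prediction = rowMeans(exp(eta))
    )
  }
  out <- dplyr::bind_rows(out)
  class(out) <- c("marginal_predictions", class(out))
  out
}

cell_draws <- function(m, group, session) {
  v <- m$.prediction[m$group == group & m$session == session]
  if (length(v) == 0) stop_data(sprintf("missing cell: %s / %s", group, session))
  v
}

#' Pairwise difference distributions between Group x Session cells
#'
#' Along `"session_within_group"`, each group contributes the three session
#' contrasts computed as later minus earlier session; along
#' `"group_within_session"`, each session contributes the three group
#' contrasts computed as first-listed minus second-listed in the order
#' DLPFC, VLPFC, Sham.
#'
#' @param m a `marginal_predictions`
#' @param axis which family of contrasts to form
#' @return object of class `pairwise_comparisons`: tibble(axis, within,
#'   contrast, delta) with the draw-wise difference vector in the `delta`
#'   list-column
#' @export
pairwise_differences <- function(m, axis = c("session_within_group",
                                             "group_within_session")) {
  axis <- match.arg(axis)
  g_lev <- levels(m$group); s_lev <- levels(m$session)
  rows <- list()
  if (axis == "session_within_group") {
    ses_order <- intersect(SESSION_LEVELS, s_lev)
    prs <- utils::combn(seq_along(ses_order), 2)
    for (g in g_lev) {
      for (j in seq_len(ncol(prs))) {
        earlier <- ses_order[prs[1, j]]; later <- ses_order[prs[2, j]]
        delta <- cell_draws(m, g, later) - cell_draws(m, g, earlier)
        rows[[length(rows) + 1]] <- tibble(
          axis = axis, within = g,
          contrast = paste(later, "-", earlier), delta = list(delta)
        )
      }
    }
  } else {
    grp_order <- intersect(c("DLPFC", "VLPFC", "Sham"), g_lev)
    prs <- utils::combn(seq_along(grp_order), 2)
    for (s in s_lev) {
      for (j in seq_len(ncol(prs))) {
        first <- grp_order[prs[1, j]]; second <- grp_order[prs[2, j]]
        delta <- cell_draws(m, first, s) - cell_draws(m, second, s)
        rows[[length(rows) + 1]] <- tibble(
          axis = axis, within = s,
          contrast = paste(first, "-", second), delta = list(delta)
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pairwise_comparisons", class(out))
  out
}

#' ROPE decision for pairwise difference distributions
#'
#' The region of practical equivalence is `[-rope_frac * response_sd,
#' +rope_frac * response_sd]` (one tenth of the response SD by default).
#' For each comparison the 89% HDI of the difference draws is computed and
#' `rope_overlap` is the proportion of the draws inside the HDI that also
#' fall inside the ROPE. The null hypothesis of no difference is `rejected`
#' when the overlap is below 0.025, `supported` when above 0.975, and
#' `inconclusive` otherwise - as well as whenever the HDI crosses both ROPE
#' bounds.
#'
#' @param comparisons a `pairwise_comparisons` (or any tibble with a
#'   `delta` list-column)
#' @param response_sd SD of the response (connectivity degree) defining the
#'   ROPE scale; must be positive
#' @param rope_frac fraction of the response SD (default 0.1)
#' @param hdi_mass HDI probability mass (default 0.89)
#' @param reject_below,support_above decision thresholds on the overlap
#' @return the tibble completed with median, hdi_low, hdi_high, rope_low,
#'   rope_high, rope_overlap and decision columns
#' @export
rope_decision <- function(comparisons, response_sd, rope_frac = 0.1,
                          hdi_mass = 0.89, reject_below = 0.025,
                          support_above = 0.975) {
  if (!is.numeric(response_sd) || response_sd <= 0)
    stop_param("response_sd must be positive")
  rope_high <- rope_frac * response_sd
  rope_low <- -rope_high
  n <- nrow(comparisons)
  med <- hlo <- hhi <- ov <- numeric(n)
  dec <- character(n)
  for (i in seq_len(n)) {
    d <- comparisons$delta[[i]]
    h <- hdi(d, hdi_mass)
    med[i] <- median(d)
    hlo[i] <- h[1]; hhi[i] <- h[2]
    in_hdi <- d >= h[1] & d <= h[2]
    ov[i] <- mean(d[in_hdi] >= rope_low & d[in_hdi] <= rope_high)
    straddle <- h[1] < rope_low && h[2] > rope_high
    dec[i] <- if (straddle) "inconclusive"
      else if (ov[i] < reject_below) "rejected"
      else if (ov[i] > support_above) "supported"
      else "inconclusive"
  }
  comparisons$median <- med
  comparisons$hdi_low <- hlo
  comparisons$hdi_high <- hhi
  comparisons$rope_low <- rope_low
  comparisons$rope_high <- rope_high
  comparisons$rope_overlap <- ov
  comparisons$decision <- factor(dec, levels = c("rejected", "inconclusive", "supported"))
  comparisons
}

#' Response SD used to scale the ROPE
#'
#' Computed empirically from the analyzed degree table (the conventional
#' choice); pass an explicit value to [rope_decision()] to override.
#'
#' @param data a degree table
#' @return scalar SD of the degree column
#' @export
response_sd <- function(data) {
  stats::sd(data$degree)
}

#' @describeIn pairwise_differences drop the draw vectors, keeping the
#'   summary columns
#' @param x a `pairwise_comparisons`
#' @param ... unused
#' @method tidy pairwise_comparisons
#' @export
tidy.pairwise_comparisons <- function(x, ...) {
  out <- as_tibble(x)
  out$delta <- NULL
  out
}

#' Full decision layer from a fitted model
#'
#' Convenience wrapper: average marginal predictions, both families of
#' pairwise contrasts (3 session contrasts per group and 3 group contrasts
#' per session: 18 comparisons for a full 3 x 3 design), and the ROPE
#' decision for each.
#'
#' @param fit a `degree_glmm`
#' @param data degree table (defaults to the fitted data); also provides
#'   the empirical response SD
#' @param n_draws posterior draws for the marginal predictions
#' @param seed seed for the draw subsample
#' @param rope_sd ROPE scale override; defaults to [response_sd()] of `data`
#' @inheritParams rope_decision
#' @return a `pairwise_comparisons` tibble with decisions for all contrasts
#' @export
compare_cells <- function(fit, data = fit$data, n_draws = 1000, seed = 1L,
                          rope_sd = NULL, rope_frac = 0.1, hdi_mass = 0.89) {
  m <- marginal_predictions(fit, data, n_draws = n_draws, seed = seed)
  cmp <- dplyr::bind_rows(
    pairwise_differences(m, "session_within_group"),
    pairwise_differences(m, "group_within_session")
  )
  class(cmp) <- c("pairwise_comparisons", class(tibble()))
  rope_decision(cmp, rope_sd %||% response_sd(data),
                rope_frac = rope_frac, hdi_mass = hdi_mass)
}
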