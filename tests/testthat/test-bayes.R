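# The multilevel Poisson model: defaults, likelihood, prior, convergence
# diagnostics, and simulation-based calibration at reduced scale.

small_cohort <- function(params = degree_model_params(), seed = 1,
                         n_per_group = c(DLPFC = 3, VLPFC = 3, Sham = 3),
                         n_channels = 8) {
  simulate_degree_dataset(params, n_per_group = n_per_group,
                          n_channels = n_channels, seed = seed)
}

test_that("sampler defaults follow the published configuration", {
  fm <- formals(fit_poisson_glmm)
  expect_equal(fm$chains, 8)
  expect_equal(fm$iter, 2000)
  expect_equal(fm$warmup, 1000)
  # retained draws contract: chains * (iter - warmup)
  d <- small_cohort(seed = 51)
  fit <- fit_poisson_glmm(d, chains = 2, iter = 300, warmup = 200, seed = 1)
  expect_equal(nrow(as.matrix(fit$draws)), 2 * 100)
  expect_equal(fm$warmup, 1000)
})

test_that("an intercept-only model recovers the Poisson mean", {
  p <- degree_model_params(beta0 = log(15), sigma_u = rep(0, 4), sigma_w = rep(0, 3))
  d <- simulate_degree_dataset(p, n_per_group = c(5, 5, 5), n_channels = 10, seed = 52)
  fit <- fit_poisson_glmm(d, chains = 1, iter = 700, warmup = 200, seed = 2,
                          monitor = "b0")
  med <- exp(median(as.matrix(fit$draws)[, "b0"]))
  expect_lt(abs(med - 15) / 15, 0.10)
})

test_that("the log-likelihood peaks at the generating parameters", {
  p <- degree_model_params(beta0 = log(12),
                           beta_group = c(DLPFC = 0.2, VLPFC = -0.1),
                           beta_session = c(Post = 0.1, Post1month = 0.3),
                           beta_interaction = matrix(c(0.4, 0, 0, -0.2), 2, 2))
  d <- simulate_degree_dataset(p, n_per_group = c(10, 10, 10), n_channels = 20, seed = 53)
  ll_true <- degree_model_loglik(d, p)
  for (fld in c("beta0", "beta_group", "beta_session")) {
    p2 <- p
    p2[[fld]] <- p2[[fld]] + 1   # +1 SD-scale perturbation on the log scale
    expect_lt(degree_model_loglik(d, p2), ll_true)
  }
  p3 <- p; p3$beta_interaction <- p3$beta_interaction + 1
  expect_lt(degree_model_loglik(d, p3), ll_true)
})

test_that("prior sampling reproduces the stated priors", {
  d <- small_cohort(seed = 54, n_channels = 4,
                    n_per_group = c(DLPFC = 2, VLPFC = 2, Sham = 2))
  pf <- fit_poisson_glmm(d, chains = 1, iter = 4200, warmup = 200, seed = 3,
                         sample_prior = TRUE)
  m <- as.matrix(pf$draws)
  betas <- m[, c("b0", "bG[2]", "bG[3]", "bS[2]", "bS[3]")]
  expect_lt(max(abs(colMeans(betas))), 0.2)          # Normal(0, 2.5) location
  expect_true(all(abs(apply(betas, 2, sd) - 2.5) < 0.2))
  sds <- m[, sprintf("sigma_u[%d]", 1:4)]
  expect_lt(max(abs(colMeans(sds) - 0.5)), 0.05)     # Exponential(rate 2) mean
})

test_that("convergence diagnostics pass for stationary chains and the 1.01 default", {
  fm <- formals(check_convergence)
  expect_equal(fm$rhat_max, 1.01)
  # well-identified setting: larger true SDs keep the hierarchical scales
  # away from the zero funnel so chains genuinely sample one target
  p <- degree_model_params(sigma_u = c(0.3, 0.2, 0.2, 0.2),
                           sigma_w = c(0.3, 0.3, 0.3))
  d <- simulate_degree_dataset(p, n_per_group = c(10, 10, 10), n_channels = 8,
                               seed = 55)
  fit <- fit_poisson_glmm(d, chains = 2, iter = 2300, warmup = 300, seed = 4)
  rep <- check_convergence(fit, rhat_max = 1.01, ess_min = 50)
  expect_lte(rep$max_rhat, 1.01)
  expect_true(rep$pass)
})

test_that("an offset chain inflates R-hat past 1.1 and fails the check", {
  d <- small_cohort(seed = 56, n_channels = 4,
                    n_per_group = c(DLPFC = 2, VLPFC = 2, Sham = 2))
  fit <- fit_poisson_glmm(d, chains = 2, iter = 500, warmup = 200, seed = 5)
  shifted <- fit
  shifted$draws[[2]][, "b0"] <- shifted$draws[[2]][, "b0"] + 5
  diag_tbl <- convergence_diagnostics(shifted)
  expect_gt(diag_tbl$rhat[diag_tbl$parameter == "b0"], 1.1)
  expect_false(check_convergence(shifted)$pass)
})

test_that("single-chain fits cannot produce R-hat", {
  d <- small_cohort(seed = 57, n_channels = 4,
                    n_per_group = c(DLPFC = 2, VLPFC = 2, Sham = 2))
  fit <- fit_poisson_glmm(d, chains = 1, iter = 300, warmup = 200, seed = 6)
  expect_error(convergence_diagnostics(fit), class = "nirsconnect_data_error")
})

test_that("degree tables are validated before fitting", {
  d <- small_cohort(seed = 58)
  bad <- d; bad$degree[1] <- -1L
  expect_error(fit_poisson_glmm(bad), class = "nirsconnect_data_error")
  bad2 <- d; bad2$degree <- bad2$degree + 0.5
  expect_error(fit_poisson_glmm(bad2), class = "nirsconnect_data_error")
  one <- d[d$participant == "P01", ]
  expect_error(fit_poisson_glmm(one), class = "nirsconnect_data_error")
})

test_that("posterior ranks of generating parameters are uniform (SBC, reduced scale)", {
  set.seed(59)
  ranks_b0 <- ranks_b3 <- integer(0)
  for (r in 1:200) {
    p <- degree_model_params(
      beta0 = rnorm(1, 0, 2.5),
      beta_group = setNames(rnorm(2, 0, 2.5), c("DLPFC", "VLPFC")),
      beta_session = setNames(rnorm(2, 0, 2.5), c("Post", "Post1month")),
      beta_interaction = matrix(rnorm(4, 0, 2.5), 2, 2),
      sigma_u = rexp(4, 2), sigma_w = rexp(3, 2))
    dd <- tryCatch(simulate_degree_dataset(
      p, n_per_group = c(DLPFC = 2, VLPFC = 2, Sham = 2), n_channels = 4,
      seed = 20000 + r), error = function(e) NULL)
    if (is.null(dd) || any(is.na(dd$degree))) next
    ff <- tryCatch(fit_poisson_glmm(dd, chains = 1, iter = 2400, warmup = 400,
                                    seed = r, monitor = c("b0", "bGS")),
                   error = function(e) NULL)
    if (is.null(ff)) next
    m <- as.matrix(ff$draws)
    th <- m[seq(1, nrow(m), by = 20), ]          # thin 2000 -> 100 draws
    ranks_b0 <- c(ranks_b0, sum(th[, "b0"] < p$beta0))
    ranks_b3 <- c(ranks_b3, sum(th[, "bGS[2,3]"] < p$beta_interaction[1, 2]))
  }
  expect_gte(length(ranks_b0), 195)   # numerically degenerate draws are rare
  gof <- function(rk) {
    h <- table(cut(rk, breaks = seq(-0.5, 100.5, length.out = 11)))
    suppressWarnings(chisq.test(h)$p.value)
  }
  expect_gt(gof(ranks_b0), 0.01)
  expect_gt(gof(ranks_b3), 0.01)
})

test_that("tidy and glance summarize a fit in broom style", {
  d <- small_cohort(seed = 60)
  fit <- fit_poisson_glmm(d, chains = 2, iter = 500, warmup = 250, seed = 7)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high", "rhat", "ess") %in% names(td)))
  expect_equal(nrow(td), 16)  # 9 fixed effects + 7 random-effect SDs
  expect_true("(Intercept)" %in% td$term)
  gl <- glance(fit)
  expect_equal(gl$n_draws, 2 * 250)
  expect_equal(gl$n_obs, nrow(d))
})
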