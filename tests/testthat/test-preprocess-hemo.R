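# Spherical-spline interpolation, Beer-Lambert conversion, negative
# correlation enhancement, band-pass filtering, and the chain contract.

test_that("interpolation reproduces a common signal and respects good channels", {
  set.seed(21)
  n <- 200
  sig <- nirsconnect:::band_limited_noise(n, 5.1, c(0.01, 0.2))
  od <- array(rep(sig, 8 * 2), dim = c(n, 8, 2))
  rec <- make_od_recording(od, stage = "ssr")
  out <- interpolate_bad_channels(rec, bad = "CH03")
  rms <- sqrt(mean((out$od[, 3, 1] - sig)^2)) / sd(sig)
  expect_lt(rms, 0.01)
  expect_identical(out$od[, -3, ], rec$od[, -3, ])
  # empty bad set: identity
  out0 <- interpolate_bad_channels(rec, bad = character())
  expect_identical(out0$od, rec$od)
})

test_that("spline interpolation beats nearest-neighbour on smooth gradients", {
  m <- frontal_montage(n_long = 12, n_short = 0)
  n <- 100
  set.seed(22)
  base <- nirsconnect:::band_limited_noise(n, 5.1, c(0.01, 0.2))
  ch <- m$channels
  # smooth spatial field: channel amplitude varies linearly with position
  amp <- 1 + 0.25 * scale(ch$x)[, 1] + 0.15 * scale(ch$y)[, 1]
  od <- array(0, dim = c(n, 12, 2))
  for (k in 1:12) od[, k, ] <- amp[k] * base
  rec <- nirsconnect:::new_optical_recording(10^(-od), c(760, 850), 5.1, m, stage = "ssr")
  rec$od <- od
  target <- 5
  out <- interpolate_bad_channels(rec, bad = ch$channel[target])
  err_spline <- sqrt(mean((out$od[, target, 1] - od[, target, 1])^2))
  d2 <- (ch$x - ch$x[target])^2 + (ch$y - ch$y[target])^2 + (ch$z - ch$z[target])^2
  d2[target] <- Inf
  nn <- which.min(d2)
  err_nn <- sqrt(mean((od[, nn, 1] - od[, target, 1])^2))
  expect_lt(err_spline, err_nn)
  # fewer than 3 good channels is refused
  rec2 <- make_od_recording(array(rnorm(100 * 3 * 2), dim = c(100, 3, 2)), stage = "ssr")
  expect_error(interpolate_bad_channels(rec2, bad = c("CH01", "CH02")),
               class = "nirsconnect_data_error")
})

test_that("Beer-Lambert inversion is exact against the forward model", {
  bl <- beer_lambert_config()
  m <- frontal_montage(n_long = 2, n_short = 0)
  set.seed(23)
  n <- 150
  hbo <- matrix(rnorm(n * 2, 0, 0.5), n, 2)
  hbr <- matrix(rnorm(n * 2, 0, 0.2), n, 2)
  od <- array(0, dim = c(n, 2, 2))
  for (k in 1:2) {
    f <- nirsconnect:::forward_mbll(hbo[, k], hbr[, k], m$channels$separation[k], bl)
    od[, k, 1] <- f$od760; od[, k, 2] <- f$od850
  }
  rec <- nirsconnect:::new_optical_recording(10^(-od), c(760, 850), 5.1, m, stage = "clean")
  rec$od <- od
  hemo <- od_to_hemo(rec, bl)
  expect_equal(hemo$hbo, hbo, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(hemo$hbr, hbr, tolerance = 1e-9, ignore_attr = TRUE)
  # zero OD maps to zero concentration
  rec$od[] <- 0
  hemo0 <- od_to_hemo(rec, bl)
  expect_true(all(hemo0$hbo == 0) && all(hemo0$hbr == 0))
  # doubling the PPF halves the recovered concentrations
  rec$od <- od
  hemo2 <- od_to_hemo(rec, beer_lambert_config(ppf = c(12, 12)))
  expect_equal(hemo2$hbo, hbo / 2, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("negative correlation enhancement forces corr(HbO', HbR') = -1", {
  set.seed(24)
  n <- 400
  hbo <- matrix(rnorm(n * 3), n, 3)
  hbr <- matrix(rnorm(n * 3), n, 3)
  hbr[, 2] <- -0.7 * hbo[, 2]                  # already anti-correlated channel
  h <- make_hemo(hbo, hbr = hbr, stage = "hemo")
  out <- negative_correlation_enhance(h)
  for (k in 1:3) {
    expect_equal(cor(out$hbo[, k], out$hbr[, k]), -1, tolerance = 1e-6)
  }
  # proportional HbR leaves the HbO shape untouched
  expect_equal(cor(out$hbo[, 2], hbo[, 2]), 1, tolerance = 1e-12)
  # independent noise: averaging cannot inflate the HbO variance
  expect_lte(var(out$hbo[, 1]), var(hbo[, 1]))
  # zero-variance channel skipped with a warning
  hbo0 <- hbo; hbo0[, 3] <- 0
  expect_warning(negative_correlation_enhance(make_hemo(hbo0, hbr = hbr, stage = "hemo")),
                 "zero variance")
})

test_that("the band-pass keeps the analysis band and rejects cardiac/DC", {
  fs <- 5.1; n <- 3000
  tt <- (0:(n - 1)) / fs
  hbo <- cbind(sin(2 * pi * 0.05 * tt),        # passband
               sin(2 * pi * 1.2 * tt),          # cardiac
               rep(1, n) + 0.2 * sin(2 * pi * 0.05 * tt))  # DC offset
  h <- make_hemo(hbo, stage = "enhanced")
  out <- bandpass(h)
  amp <- function(x) sqrt(2 * mean(x^2))
  expect_equal(amp(out$hbo[, 1]), 1, tolerance = 0.1)
  expect_lt(amp(out$hbo[, 2]), 0.1)
  expect_lt(abs(mean(out$hbo[, 3])), 0.02)
  expect_equal(nrow(out$hbo), n)
  bad_q <- quality_config(filter_band = c(0.01, 3))
  expect_error(bandpass(make_hemo(hbo, stage = "enhanced"), bad_q),
               class = "nirsconnect_config_error")
})

test_that("the preprocessing chain enforces its fixed stage order", {
  net <- simulate_latent_network(4, 0, seed = 31)
  cfg <- sim_config(duration = 60, n_long_channels = 4, n_short_channels = 2, seed = 31)
  rec <- simulate_optical(simulate_hemo(net, cfg), cfg)
  expect_error(tddr(rec), class = "nirsconnect_state_error")               # needs OD first
  od <- intensity_to_od(rec)
  expect_error(intensity_to_od(od), class = "nirsconnect_state_error")     # no double OD
  expect_error(short_channel_regress(od), class = "nirsconnect_state_error")  # needs TDDR
  expect_error(od_to_hemo(od), class = "nirsconnect_state_error")          # needs clean stage
  cor_od <- tddr(od)
  expect_error(scalp_coupling_index(cor_od), class = "nirsconnect_state_error")
})

test_that("no preprocessing stage changes the number of samples", {
  net <- simulate_latent_network(6, 0.3, seed = 32)
  cfg <- sim_config(duration = 90, n_long_channels = 6, n_short_channels = 2, seed = 32)
  rec <- simulate_optical(simulate_hemo(net, cfg), cfg)
  n <- dim(rec$intensities)[1]
  hemo <- quiet_preprocess(rec)
  expect_equal(nrow(hemo$hbo), n)
  expect_equal(ncol(hemo$hbo), 6)  # long channels retained only
})

test_that("artifact-free recordings are recovered almost perfectly end to end", {
  net <- simulate_clustered_network(44, 15, seed = 33)
  cfg <- sim_config(duration = 300, seed = 33)
  rec <- simulate_optical(simulate_hemo(net, cfg), cfg)
  hemo <- quiet_preprocess(rec, motion_correction = FALSE)
  bp <- function(x) nirsconnect:::fir_bandpass(x, cfg$sampling_rate, c(0.01, 0.2),
                                               c(0.01, 0.2))
  truth <- apply(rec$truth$hbo, 2, bp)
  cc <- vapply(1:44, function(k) cor(hemo$hbo[, k], truth[, k]), numeric(1))
  expect_gt(median(cc), 0.95)
  expect_gt(min(cc), 0.85)
})
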