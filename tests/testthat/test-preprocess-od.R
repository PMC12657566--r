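# Optical density, TDDR, short-separation regression, and SCI screening.

test_that("optical density is zero for constant intensity and inverts exactly", {
  m <- frontal_montage(n_long = 2, n_short = 0)
  ints <- array(0, dim = c(50, 2, 2))
  ints[, 1, ] <- 2.5                            # constant channel
  set.seed(1)
  ints[, 2, ] <- exp(rnorm(100, 0, 0.1))        # random positive channel
  rec <- nirsconnect:::new_optical_recording(ints, c(760, 850), 5.1, m)
  od <- intensity_to_od(rec)
  expect_equal(od$od[, 1, 1], rep(0, 50))
  # exp10(-OD) * mean(I) reproduces I
  recon <- 10^(-od$od[, 2, 1]) * mean(ints[, 2, 1])
  expect_equal(recon, ints[, 2, 1], tolerance = 1e-12)
})

test_that("a sample at one tenth of the mean intensity has OD exactly 1", {
  m <- frontal_montage(n_long = 1, n_short = 0)
  x <- c(0.1, rep(10.9 / 10, 10))               # mean exactly 1
  ints <- array(rep(x, 2), dim = c(11, 1, 2))
  od <- intensity_to_od(nirsconnect:::new_optical_recording(ints, c(760, 850), 5.1, m))
  expect_equal(od$od[1, 1, 1], 1, tolerance = 1e-12)
})

test_that("non-positive intensities raise a data error naming the channel", {
  m <- frontal_montage(n_long = 2, n_short = 0)
  ints <- array(1, dim = c(10, 2, 2))
  ints[4, 2, 1] <- 0
  rec <- nirsconnect:::new_optical_recording(ints, c(760, 850), 5.1, m)
  expect_error(intensity_to_od(rec), "CH02", class = "nirsconnect_data_error")
})

test_that("TDDR matches a literal transcription of the published algorithm", {
  set.seed(7)
  fs <- 5.1
  x <- nirsconnect:::band_limited_noise(500, fs, c(0.01, 0.2)) * 0.5 +
    0.3 * sin(2 * pi * 1.2 * (0:499) / fs) + rnorm(500, 0, 0.1)
  x[250] <- x[250] + 20 * sd(x)
  expect_equal(tddr(x, fs), oracle_tddr(x, fs), tolerance = 1e-8)
})

test_that("TDDR strongly attenuates motion spikes and baseline shifts", {
  set.seed(8)
  fs <- 5.1
  smooth <- nirsconnect:::band_limited_noise(800, fs, c(0.01, 0.2))
  # 2.5-s half-cosine motion spike peaking at 20 SD
  len <- round(2.5 * fs); i0 <- 400
  spike_sig <- smooth
  spike_sig[i0:(i0 + len - 1)] <- spike_sig[i0:(i0 + len - 1)] +
    20 * sd(smooth) * sin(pi * seq_len(len) / len)
  out <- tddr(spike_sig, fs)
  spike_before <- max(abs(spike_sig - median(spike_sig)))
  spike_after <- max(abs(out[i0:(i0 + len - 1)] - median(out)))
  expect_lt(spike_after, 0.2 * spike_before)   # >= 80% amplitude reduction
  # baseline shift flattened
  shift_sig <- smooth
  shift_sig[400:800] <- shift_sig[400:800] + 20 * sd(smooth)
  out2 <- tddr(shift_sig, fs)
  jump <- abs(mean(out2[500:800]) - mean(out2[1:300]))
  expect_lt(jump, 0.1 * 20 * sd(smooth))
  # artifact-free smooth signal: the repair compresses amplitude but
  # preserves the band-passed shape (what correlation-based connectivity
  # consumes) almost exactly
  y <- tddr(smooth, fs)
  bp <- function(v) nirsconnect:::fir_bandpass(v, fs, c(0.01, 0.2))
  expect_gt(cor(bp(y), bp(smooth)), 0.94)
})

test_that("TDDR edge cases: constant input unchanged, non-finite rejected", {
  expect_equal(tddr(rep(3.2, 40), 5.1), rep(3.2, 40))
  expect_error(tddr(c(1, NA, 2), 5.1), class = "nirsconnect_data_error")
  expect_error(tddr(c(1, 2), 5.1), class = "nirsconnect_data_error")
})

test_that("short-channel regression residualizes against the nearest short channel", {
  m <- frontal_montage(n_long = 4, n_short = 2)
  set.seed(9)
  n <- 300
  od <- array(rnorm(n * 6 * 2, 0, 0.05), dim = c(n, 6, 2))
  # long channel 1: copy of its nearest short channel's series
  # find which short channel is nearest to long channel 1
  ch <- m$channels
  d2 <- (ch$x[5:6] - ch$x[1])^2 + (ch$y[5:6] - ch$y[1])^2 + (ch$z[5:6] - ch$z[1])^2
  s_near <- 4 + which.min(d2)
  od[, 1, 1] <- od[, s_near, 1]
  # long channel 2: orthogonal to both short channels by construction
  sh <- cbind(od[, 5, 1], od[, 6, 1], 1)
  od[, 2, 1] <- stats::residuals(stats::lm(od[, 2, 1] ~ od[, 5, 1] + od[, 6, 1]))
  rec <- make_od_recording(od, stage = "tddr", n_short = 2)
  out <- short_channel_regress(rec)
  expect_lt(sd(out$od[, 1, 1]), 1e-10)                 # perfect regressor
  expect_equal(out$od[, 2, 1], od[, 2, 1], tolerance = 1e-8)  # zero projection
  # residual orthogonal to the regressor
  r <- out$od[, 3, 1] - mean(out$od[, 3, 1])
  ds <- (ch$x[5:6] - ch$x[3])^2 + (ch$y[5:6] - ch$y[3])^2 + (ch$z[5:6] - ch$z[3])^2
  reg <- od[, 4 + which.min(ds), 1]
  expect_lt(abs(sum(r * (reg - mean(reg)))) / (sd(r) * sd(reg) * length(r)), 1e-8)
})

test_that("regression removes most of the mixed superficial component", {
  net <- simulate_latent_network(16, 0.3, seed = 12)
  cfg <- sim_config(duration = 300, n_long_channels = 16, n_short_channels = 8,
                    superficial_weight = 0.3, seed = 13)
  rec <- simulate_optical(simulate_hemo(net, cfg), cfg)
  od <- nirsconnect:::advance_stage(intensity_to_od(rec), "tddr")
  before <- vapply(1:16, function(k) abs(cor(od$od[, k, 2], rec$truth$superficial[, k])),
                   numeric(1))
  out <- short_channel_regress(od)
  after <- vapply(1:16, function(k) abs(cor(out$od[, k, 2], rec$truth$superficial[, k])),
                  numeric(1))
  expect_lt(mean(after), 0.1)
  expect_lt(mean(after), mean(before) / 2)
  # a montage without short channels cannot be residualized
  cfg0 <- sim_config(duration = 60, n_long_channels = 4, n_short_channels = 0, seed = 1)
  rec0 <- simulate_optical(simulate_hemo(simulate_latent_network(4, 0, seed = 1), cfg0), cfg0)
  expect_error(short_channel_regress(tddr(intensity_to_od(rec0))),
               class = "nirsconnect_config_error")
})

test_that("SCI is the cardiac-band inter-wavelength correlation", {
  fs <- 5.1; n <- 1600
  tt <- (0:(n - 1)) / fs
  card <- sin(2 * pi * 1.1 * tt)
  set.seed(14)
  od <- array(0, dim = c(n, 3, 2))
  od[, 1, 1] <- card + 0.3 * sin(2 * pi * 0.05 * tt)   # shared cardiac
  od[, 1, 2] <- card + 0.2 * sin(2 * pi * 0.07 * tt)
  od[, 2, 1] <- rnorm(n, 0, 1)                          # independent noise
  od[, 2, 2] <- rnorm(n, 0, 1)
  od[, 3, 1] <- card; od[, 3, 2] <- card
  rec <- make_od_recording(od, fs = fs, stage = "ssr")
  sci <- scalp_coupling_index(rec)
  expect_gt(sci$sci[1], 0.99)
  expect_lt(abs(sci$sci[2]), 0.3)
  expect_equal(sci$sci[3], 1, tolerance = 1e-9)
  expect_false(sci$bad[1])
  expect_true(sci$bad[2])
})

test_that("the SCI threshold is a strict inequality at 0.7", {
  expect_identical(flag_bad_channels(c(0.69, 0.70, 0.71), 0.7),
                   c(TRUE, FALSE, FALSE))
  expect_true(flag_bad_channels(NA_real_, 0.7))
})

test_that("zero-variance cardiac signal flags the channel with a warning", {
  fs <- 5.1; n <- 1600
  od <- array(0, dim = c(n, 2, 2))
  od[, 1, 1] <- sin(2 * pi * 1.1 * (0:(n - 1)) / fs)
  od[, 1, 2] <- od[, 1, 1]
  # channel 2 stays exactly constant
  rec <- make_od_recording(od, fs = fs, stage = "ssr")
  expect_warning(sci <- scalp_coupling_index(rec), "zero-variance")
  expect_true(is.na(sci$sci[2]))
  expect_true(sci$bad[2])
})
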