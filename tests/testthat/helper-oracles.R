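# Independent oracles and small fixture builders used across the suite.
# Each oracle is written directly from the defining formula/algorithm,
# independently of the package implementation it checks.

# literal step-by-step transcription of the published TDDR algorithm
oracle_tddr <- function(x, fs) {
  mu_x <- mean(x)
  xc <- x - mu_x
  fc <- 0.5 * 2 / fs
  if (fc < 1) {
    bf <- signal::butter(3, fc)
    low <- signal::filtfilt(bf, xc)
  } else low <- xc
  high <- xc - low
  dv <- diff(low)
  w <- rep(1, length(dv))
  mu <- 0
  for (it in 1:50) {
    mu <- sum(w * dv) / sum(w)
    dev <- abs(dv - mu)
    s <- 1.4826 * median(dev)
    if (s == 0) break
    r <- dev / (s * 4.685)
    w_new <- ((1 - r^2) * (r < 1))^2
    conv <- max(abs(w_new - w)) < 1e-8
    w <- w_new
    if (conv) break
  }
  corr <- cumsum(c(0, w * (dv - mu)))
  corr <- corr - mean(corr)
  corr + high + mu_x
}

# textbook Pearson correlation
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  num / den
}

# exhaustive edge count / degree from a weighted matrix and threshold
oracle_degree <- function(W, thr) {
  C <- nrow(W)
  deg <- integer(C)
  for (i in seq_len(C)) for (j in seq_len(C)) {
    if (i != j && W[i, j] >= thr) deg[i] <- deg[i] + 1L
  }
  deg
}

# enumerate epoch windows [s, s + len) fitting in a recording of T seconds
oracle_epoch_starts <- function(T, len, hop) {
  starts <- c()
  s <- 0
  while (s + len <= T + 1e-9) {
    starts <- c(starts, s)
    s <- s + hop
  }
  starts
}

excess_kurtosis <- function(x) {
  z <- x - mean(x)
  length(x) * sum(z^4) / sum(z^2)^2 - 3
}

# hemo_recording wrapper around a plain HbO matrix (stage filtered)
make_hemo <- function(hbo, fs = 5.1, hbr = -0.4 * hbo, stage = "filtered",
                      annotations = NULL) {
  ch <- tibble::tibble(channel = paste0("CH", sprintf("%02d", seq_len(ncol(hbo)))),
                       role = "long")
  rec <- nirsconnect:::new_hemo_recording(hbo, hbr, fs, ch, stage = stage)
  if (!is.null(annotations)) rec$annotations <- annotations
  rec
}

# latent network with explicit edges: edge list of (i, j, coupling)
make_network <- function(n, edges) {
  adj <- matrix(0L, n, n)
  coup <- matrix(0, n, n)
  for (e in edges) {
    adj[e[1], e[2]] <- adj[e[2], e[1]] <- 1L
    coup[e[1], e[2]] <- coup[e[2], e[1]] <- e[3]
  }
  structure(list(n_channels = as.integer(n), adjacency = adj, coupling = coup),
            class = "latent_network")
}

# optical recording with prescribed OD arrays, for testing mid-chain ops
make_od_recording <- function(od, fs = 5.1, stage = "ssr", n_short = 0) {
  C <- dim(od)[2]
  montage <- frontal_montage(n_long = C - n_short, n_short = n_short)
  rec <- nirsconnect:::new_optical_recording(
    10^(-od), c(760, 850), fs, montage, stage = stage
  )
  rec$od <- od
  rec
}

quiet_preprocess <- function(...) suppressWarnings(preprocess(...))
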