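#' Segment a recording into overlapping epochs
#'
#' Epochs of `epoch_length` seconds start at 0, hop, 2 hop, ... with
#' `hop = epoch_length - overlap`, so consecutive epochs share `overlap`
#' seconds. The epoch count is `floor((T - epoch_length) / hop) + 1`.
#'
#' @param hemo a `hemo_recording` at stage `"filtered"`
#' @param epoch_length epoch length, seconds (default 30)
#' @param overlap overlap between consecutive epochs, seconds (default 5)
#' @return an `epoch_set`: tibble(epoch, start, end, data) with the HbO
#'   segment (time x channel matrix) in the `data` list-column and
#'   exclusion bookkeeping columns `status`/`reason` initialized to "kept"
#' @export
segment_epochs <- function(hemo, epoch_length = 30, overlap = 5) {
  if (!inherits(hemo, "hemo_recording")) stop_param("hemo must be a hemo_recording")
  if (overlap >= epoch_length) stop_param("overlap must be smaller than epoch_length")
  fs <- hemo$sampling_rate
  total <- nrow(hemo$hbo) / fs
  hop <- epoch_length - overlap
  n_ep <- floor((total - epoch_length) / hop) + 1
  if (n_ep < 1) {
    warn("recording shorter than one epoch; returning an empty epoch set")
    n_ep <- 0
  }
  len <- round(epoch_length * fs)
  starts <- (seq_len(n_ep) - 1) * hop
  data <- lapply(starts, function(s) {
    i0 <- round(s * fs) + 1
    hemo$hbo[i0:(i0 + len - 1), , drop = FALSE]
  })
  out <- tibble(
    epoch = seq_len(n_ep), start = starts, end = starts + epoch_length,
    data = data, status = rep("kept", n_ep), reason = rep("kept", n_ep)
  )
  structure(out, class = c("epoch_set", class(out)),
            epoch_length = epoch_length, overlap = overlap, hop = hop,
            sampling_rate = fs, channels = hemo$channels$channel,
            annotations = hemo$annotations)
}

#' Exclude epochs overlapping annotations or reaching saturation
#'
#' An epoch is dropped when its interval intersects any annotated artifact
#' segment with positive measure, or when any HbO sample of any channel
#' reaches the saturation limit in absolute value (the limit itself counts
#' as saturated).
#'
#' @param eps an `epoch_set`
#' @param annotations tibble(onset, duration, ...); defaults to the
#'   annotations carried by the recording
#' @param saturation_limit micromolar, default 10
#' @return the epoch set with `status`/`reason` updated
#' @export
exclude_epochs <- function(eps, annotations = NULL, saturation_limit = 10) {
  if (saturation_limit <= 0) stop_param("saturation_limit must be positive")
  ann <- annotations %||% attr(eps, "annotations") %||% empty_annotations()
  for (i in seq_len(nrow(eps))) {
    s <- eps$start[i]; e <- eps$end[i]
    annotated <- nrow(ann) > 0 &&
      any(ann$onset < e & (ann$onset + ann$duration) > s)
    if (annotated) {
      eps$status[i] <- "excluded"; eps$reason[i] <- "annotated"
    } else if (any(abs(eps$data[[i]]) >= saturation_limit)) {
      eps$status[i] <- "excluded"; eps$reason[i] <- "saturated"
    } else {
      eps$status[i] <- "kept"; eps$reason[i] <- "kept"
    }
  }
  eps
}

#' Epoch-averaged absolute-correlation connectivity matrix
#'
#' Within each retained epoch, the pairwise Pearson correlation between the
#' HbO series of all channels is computed and its absolute value taken; the
#' matrices are then averaged element-wise across epochs (alternatively the
#' retained epochs can be concatenated first). The diagonal is stored as 0.
#'
#' @param eps an `epoch_set` (after [exclude_epochs()]; all epochs are used
#'   if no exclusion was run)
#' @param aggregate `"mean_abs_r"` (default) or `"concatenate"`
#' @return a `connectivity_result` with the `weighted` matrix populated
#' @export
connectivity_matrix <- function(eps, aggregate = c("mean_abs_r", "concatenate")) {
  aggregate <- match.arg(aggregate)
  kept <- which(eps$status == "kept")
  if (length(kept) == 0) stop_data("no retained epochs")
  channels <- attr(eps, "channels")
  C <- length(channels)
  if (aggregate == "concatenate") {
    big <- do.call(rbind, eps$data[kept])
    zv <- which(apply(big, 2, sd) == 0)
    W <- abs(suppressWarnings(cor(big)))
    if (length(zv) > 0) {
      warn(paste0("zero-variance channel(s): ", paste(channels[zv], collapse = ", ")))
      W[zv, ] <- 0; W[, zv] <- 0
    }
  } else {
    acc <- matrix(0, C, C)
    for (i in kept) {
      seg <- eps$data[[i]]
      zv <- which(apply(seg, 2, sd) == 0)
      r <- abs(suppressWarnings(cor(seg)))
      if (length(zv) > 0) {
        warn(sprintf("zero-variance channel(s) in epoch %d: %s",
                     eps$epoch[i], paste(channels[zv], collapse = ", ")))
        r[zv, ] <- 0; r[, zv] <- 0
      }
      acc <- acc + r
    }
    W <- acc / length(kept)
  }
  diag(W) <- 0
  dimnames(W) <- list(channels, channels)
  structure(list(
    weighted = W, binary = NULL, degree = NULL, threshold = NA_real_,
    n_epochs_used = length(kept), channels = channels
  ), class = "connectivity_result")
}

#' Binarize a connectivity matrix and extract channel degree
#'
#' Entries greater than or equal to the threshold become 1, others 0
#' (inclusive thresholding); a channel's degree is the number of
#' supra-threshold edges it participates in (diagonal excluded).
#'
#' @param conn a `connectivity_result` with `weighted` present
#' @param threshold correlation threshold in (0, 1], default 0.5
#' @return the completed `connectivity_result` (`binary`, `degree`,
#'   `threshold` populated); `degree` is a tibble(channel, degree)
#' @export
binarize_and_degree <- function(conn, threshold = 0.5) {
  if (!inherits(conn, "connectivity_result") || is.null(conn$weighted))
    stop_param("conn must be a connectivity_result with a weighted matrix")
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1)
    stop_param("threshold must lie in (0, 1]")
  B <- (conn$weighted >= threshold) * 1L
  diag(B) <- 0L
  conn$binary <- B
  conn$threshold <- threshold
  conn$degree <- tibble(channel = conn$channels,
                        degree = as.integer(rowSums(B)))
  conn
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf("<connectivity_result> %d channels, %d epochs used",
              length(x$channels), x$n_epochs_used))
  if (!is.null(x$degree)) {
    cat(sprintf(", threshold %.2f, %d edges", x$threshold, sum(x$binary) / 2))
  }
  cat("\n")
  invisible(x)
}

#' @describeIn connectivity_matrix tidy edge list of a connectivity result
#' @param x a `connectivity_result`
#' @param ... unused
#' @method tidy connectivity_result
#' @export
tidy.connectivity_result <- function(x, ...) {
  W <- x$weighted
  ut <- which(upper.tri(W), arr.ind = TRUE)
  out <- tibble(
    from = x$channels[ut[, 1]], to = x$channels[ut[, 2]],
    weight = W[ut]
  )
  if (!is.null(x$binary)) out$connected <- x$binary[ut] == 1L
  out
}

#' One-call connectivity from a preprocessed recording
#'
#' Chains [segment_epochs()], [exclude_epochs()], [connectivity_matrix()]
#' and [binarize_and_degree()] with the standard settings (30-s epochs, 5-s
#' overlap, 10 micromolar saturation limit, 0.5 threshold).
#'
#' @inheritParams segment_epochs
#' @inheritParams exclude_epochs
#' @inheritParams binarize_and_degree
#' @inheritParams connectivity_matrix
#' @return a completed `connectivity_result`
#' @export
connectivity <- function(hemo, epoch_length = 30, overlap = 5,
                         annotations = NULL, saturation_limit = 10,
                         threshold = 0.5, aggregate = "mean_abs_r") {
  eps <- segment_epochs(hemo, epoch_length, overlap)
  eps <- exclude_epochs(eps, annotations, saturation_limit)
  conn <- connectivity_matrix(eps, aggregate)
  binarize_and_degree(conn, threshold)
}

#' Assemble a long-format degree table row block
#'
#' @param conn a completed `connectivity_result`
#' @param participant participant id
#' @param group group label (DLPFC, VLPFC or Sham)
#' @param session session label (Pre, Post or Post1month)
#' @return tibble(participant, group, session, channel, degree)
#' @export
degree_table <- function(conn, participant, group, session) {
  if (is.null(conn$degree)) stop_param("conn has no degree; run binarize_and_degree()")
  tibble(
    participant = participant,
    group = factor(group, levels = GROUP_LEVELS),
    session = factor(session, levels = SESSION_LEVELS),
    channel = conn$degree$channel,
    degree = conn$degree$degree
  )
}
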