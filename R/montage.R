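#' Construct a frontal optode montage
#'
#' Builds a deterministic 16-source / 16-detector layout over a spherical
#' scalp patch emulating a frontal 10-20 style cap: optodes sit on a
#' checkerboard grid wrapped onto a sphere so that adjacent source-detector
#' pairs form long channels (~3.5 cm separation), plus dedicated
#' short-separation detectors placed ~0.76 cm from a subset of sources.
#'
#' @param n_long number of long channels (default 44)
#' @param n_short number of short channels (default 8)
#' @param long_separation target long-channel source-detector distance, cm
#' @param short_separation short-channel source-detector distance, cm
#' @param head_radius scalp sphere radius, cm
#' @return an object of class `nirs_montage`: a list with `optodes`
#'   (tibble: optode, type, x, y, z) and `channels` (tibble: channel, source,
#'   detector, role, separation, and midpoint x, y, z)
#' @export
frontal_montage <- function(n_long = 44, n_short = 8,
                            long_separation = 3.5, short_separation = 0.76,
                            head_radius = 8.7) {
  if (!is_count(n_long) || n_long < 1) stop_param("n_long must be a positive count")
  if (!is_count(n_short) || n_short < 0) stop_param("n_short must be a non-negative count")
  # 8 x 4 checkerboard grid in arc-length coordinates, spacing = separation
  ncol_g <- 8; nrow_g <- 4
  grid <- expand.grid(i = seq_len(ncol_g), j = seq_len(nrow_g))
  grid$sx <- (grid$i - (ncol_g + 1) / 2) * long_separation
  grid$sy <- (grid$j - (nrow_g + 1) / 2) * long_separation
  grid$type <- ifelse((grid$i + grid$j) %% 2 == 0, "source", "detector")

  to_sphere <- function(sx, sy, r = head_radius) {
    phi <- sy / r
    theta <- sx / (r * cos(phi))  # keep horizontal arc lengths at higher rows
    cbind(x = r * sin(theta) * cos(phi), y = r * sin(phi), z = r * cos(theta) * cos(phi))
  }
  pos <- to_sphere(grid$sx, grid$sy)
  optodes <- tibble(
    optode = paste0(ifelse(grid$type == "source", "S", "D"),
                    stats::ave(seq_len(nrow(grid)), grid$type, FUN = seq_along)),
    type = grid$type, x = pos[, 1], y = pos[, 2], z = pos[, 3]
  )

  # long channels: horizontally/vertically adjacent source-detector pairs
  key <- function(i, j) paste(i, j, sep = ",")
  lut <- setNames(seq_len(nrow(grid)), key(grid$i, grid$j))
  pairs <- list()
  for (r in seq_len(nrow(grid))) {
    i <- grid$i[r]; j <- grid$j[r]
    for (d in list(c(1, 0), c(0, 1))) {
      k <- lut[key(i + d[1], j + d[2])]
      if (!is.na(k)) pairs[[length(pairs) + 1]] <- c(r, k)
    }
  }
  pairs <- do.call(rbind, pairs)
  is_src <- grid$type[pairs[, 1]] == "source"
  src <- ifelse(is_src, pairs[, 1], pairs[, 2])
  det <- ifelse(is_src, pairs[, 2], pairs[, 1])
  # deterministic ordering: anterior (large y) to posterior, then left to right
  mid <- (pos[src, , drop = FALSE] + pos[det, , drop = FALSE]) / 2
  ord <- order(-round(mid[, 2], 6), mid[, 1])
  src <- src[ord]; det <- det[ord]; mid <- mid[ord, , drop = FALSE]
  if (length(src) < n_long) stop_param("grid supports at most 52 long channels")
  keep <- seq_len(n_long)
  sep_long <- sqrt(rowSums((pos[src[keep], , drop = FALSE] - pos[det[keep], , drop = FALSE])^2))

  long_ch <- tibble(
    channel = paste0("CH", sprintf("%02d", keep)),
    source = optodes$optode[src[keep]],
    detector = optodes$optode[det[keep]],
    role = "long",
    separation = sep_long,
    x = mid[keep, 1], y = mid[keep, 2], z = mid[keep, 3]
  )

  if (n_short == 0) {
    out <- list(optodes = optodes, channels = long_ch, head_radius = head_radius)
    class(out) <- "nirs_montage"
    return(out)
  }
  # short channels: extra detectors a small arc away from the first n_short sources
  src_rows <- which(grid$type == "source")[seq_len(n_short)]
  spos <- to_sphere(grid$sx[src_rows] + short_separation, grid$sy[src_rows])
  short_det <- tibble(
    optode = paste0("SD", seq_len(n_short)), type = "detector",
    x = spos[, 1], y = spos[, 2], z = spos[, 3]
  )
  sep_short <- sqrt(rowSums((pos[src_rows, , drop = FALSE] - spos)^2))
  short_ch <- tibble(
    channel = paste0("SC", sprintf("%02d", seq_len(n_short))),
    source = optodes$optode[src_rows],
    detector = short_det$optode,
    role = "short",
    separation = sep_short,
    x = (pos[src_rows, 1] + spos[, 1]) / 2,
    y = (pos[src_rows, 2] + spos[, 2]) / 2,
    z = (pos[src_rows, 3] + spos[, 3]) / 2
  )

  out <- list(
    optodes = dplyr::bind_rows(optodes, short_det),
    channels = dplyr::bind_rows(long_ch, short_ch),
    head_radius = head_radius
  )
  class(out) <- "nirs_montage"
  out
}

#' @export
print.nirs_montage <- function(x, ...) {
  n_long <- sum(x$channels$role == "long")
  n_short <- sum(x$channels$role == "short")
  cat(sprintf(
    "<nirs_montage> %d optodes, %d long channels (mean sep %.2f cm), %d short (mean sep %.2f cm)\n",
    nrow(x$optodes), n_long, mean(x$channels$separation[x$channels$role == "long"]),
    n_short, mean(x$channels$separation[x$channels$role == "short"])
  ))
  invisible(x)
}

#' Assign channel roles from separations
#'
#' A channel is `short` iff its source-detector separation is below the cut
#' (default 1.5 cm), otherwise `long`.
#'
#' @param montage a `nirs_montage`
#' @param cut separation cut in cm
#' @return the montage with roles recomputed
#' @export
assign_roles <- function(montage, cut = 1.5) {
  montage$channels$role <- ifelse(montage$channels$separation < cut, "short", "long")
  montage
}
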