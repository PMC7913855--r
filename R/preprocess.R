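# Signal conditioning applied to each recording before synergy
# extraction: zero-phase low-pass filtering, static lead-in/lead-out
# trimming, time normalization to a fixed frame count, and per-subject
# z-scoring of the task-concatenated ensemble.

#' Zero-phase low-pass Butterworth filtering
#'
#' Applies a 2nd-order low-pass Butterworth filter forwards and backwards
#' (two-way, so zero phase lag; effective attenuation is the squared
#' one-pass magnitude response) to every DoF trace of every recording.
#' Edges are handled by odd-reflection padding before the two passes, so
#' short transients at the boundaries are suppressed.
#'
#' @param data Recordings tibble (`subject`, `task`, `frame`, 16 DoF columns).
#' @param cutoff Cut-off frequency in Hz (default 5, below which hand
#'   motion during daily activities lives).
#' @param order Filter order (default 2).
#' @param sample_rate Sampling rate in Hz (default 100).
#' @return Filtered recordings tibble, same shape.
#' @export
lowpass_filter <- function(data, cutoff = 5, order = 2, sample_rate = 100) {
  if (sample_rate <= 2 * cutoff) {
    abort("`sample_rate` must exceed twice the cut-off frequency.")
  }
  bf <- signal::butter(order, 2 * cutoff / sample_rate, type = "low")
  # odd-reflection padding must outlast the zero-state transient of both
  # passes; ~9 cutoff periods leaves a negligible (<1e-12) remnant
  min_frames <- 3 * 2 * order
  map_recordings(data, function(m) {
    n <- nrow(m)
    if (n <= min_frames) {
      abort(sprintf(
        "recording too short for two-pass filtering (%d frames, need > %d)",
        n, min_frames
      ), class = "handsyn_short_recording")
    }
    pad <- min(n - 1, 9 * ceiling(sample_rate / cutoff))
    apply(m, 2, function(x) filtfilt_padded(bf, x, pad))
  })
}

# Forward-backward filtering with odd (point-mirrored) padding, the
# standard zero-phase recipe: y = filtfilt over [2*x1 - rev(head), x,
# 2*xn - rev(tail)], then strip the pad.
filtfilt_padded <- function(bf, x, pad) {
  n <- length(x)
  lead <- 2 * x[1] - x[(pad + 1):2]
  trail <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(lead, x, trail)
  yp <- rev(signal::filter(bf, rev(signal::filter(bf, xp))))
  yp[(pad + 1):(pad + n)]
}

#' Trim static lead-in and lead-out segments
#'
#' Recordings start and end with the hand at rest; those frozen segments
#' carry no movement information and would bias the time normalization.
#' A frame is static when every DoF's absolute angular velocity (central
#' difference) is below `vel_threshold`. The maximal leading and trailing
#' static runs are removed, provided they last at least `min_run` seconds
#' (shorter lulls are kept, as they can occur inside genuine motion).
#'
#' @param data Recordings tibble.
#' @param vel_threshold Velocity threshold in degrees/second (default 2).
#' @param min_run Minimum duration in seconds a static run must last to be
#'   trimmed (default 0.2).
#' @param sample_rate Sampling rate in Hz (default 100).
#' @return Trimmed recordings tibble; frames renumbered from 1.
#' @export
trim_static <- function(data, vel_threshold = 2, min_run = 0.2,
                        sample_rate = 100) {
  min_frames <- max(1L, round(min_run * sample_rate))
  map_recordings(data, function(m) {
    n <- nrow(m)
    if (n < 2) return(m)
    vel <- frame_velocity(m, sample_rate)
    static <- apply(abs(vel) < vel_threshold, 1, all)
    if (all(static)) {
      abort("no motion detected: recording is static throughout",
            class = "handsyn_no_motion")
    }
    lead <- run_length_from(static, forward = TRUE)
    trail <- run_length_from(static, forward = FALSE)
    from <- if (lead >= min_frames) lead + 1L else 1L
    to <- if (trail >= min_frames) n - trail else n
    m[from:to, , drop = FALSE]
  })
}

frame_velocity <- function(m, sample_rate) {
  n <- nrow(m)
  v <- matrix(0, n, ncol(m))
  if (n >= 3) {
    v[2:(n - 1), ] <- (m[3:n, , drop = FALSE] - m[1:(n - 2), , drop = FALSE]) *
      (sample_rate / 2)
  }
  v[1, ] <- (m[2, ] - m[1, ]) * sample_rate
  v[n, ] <- (m[n, ] - m[n - 1, ]) * sample_rate
  v
}

run_length_from <- function(flags, forward = TRUE) {
  if (!forward) flags <- rev(flags)
  r <- which(!flags)
  if (length(r) == 0) length(flags) else r[1] - 1L
}

#' Resample every recording to a fixed frame count
#'
#' Linearly interpolates each DoF trace onto `n_frames` equally spaced
#' points spanning the original duration, so every task contributes the
#' same number of frames (and hence the same weight) to the per-subject
#' synergy extraction. First and last frames are preserved exactly.
#'
#' @param data Recordings tibble.
#' @param n_frames Target frame count per recording (default 1000).
#' @return Recordings tibble with `n_frames` rows per (subject, task).
#' @export
resample_frames <- function(data, n_frames = 1000) {
  if (!is.numeric(n_frames) || n_frames < 2) {
    abort("`n_frames` must be at least 2.")
  }
  n_frames <- as.integer(n_frames)
  map_recordings(data, function(m) {
    n <- nrow(m)
    if (n < 2) abort("recording must have at least 2 frames to resample")
    t_old <- seq(0, 1, length.out = n)
    t_new <- seq(0, 1, length.out = n_frames)
    apply(m, 2, function(x) approx(t_old, x, xout = t_new)$y)
  })
}

#' Standardize and concatenate one subject's recordings
#'
#' Concatenates a subject's resampled tasks into a single 16 x (frames x
#' tasks) matrix (DoF in rows, frames task-major in columns) and rescales
#' every DoF row to mean 0, SD 1. Standardization stops the angles with
#' the largest excursions from dominating the principal components, so
#' small-range joints such as the finger abductions contribute equally.
#'
#' @param data Recordings tibble for a single subject (all tasks resampled
#'   to a common frame count).
#' @return A list with `z` (the standardized 16 x N matrix), `params`
#'   (tibble `dof`, `mean`, `sd` in degrees, invertible via
#'   `z * sd + mean`), and `tasks` (task ids in concatenation order).
#' @export
zscore_concat <- function(data) {
  data <- check_recordings(data)
  if (dplyr::n_distinct(data$subject) != 1) {
    abort("`data` must contain recordings of exactly one subject.")
  }
  counts <- dplyr::count(data, .data$task)
  if (dplyr::n_distinct(counts$n) != 1) {
    abort("all tasks must be resampled to the same frame count.")
  }
  tasks <- unique(data$task)
  data <- dplyr::arrange(data, match(.data$task, tasks), .data$frame)
  x <- t(angles_matrix(data)) # 16 x N
  rownames(x) <- dof_labels()
  mu <- rowMeans(x)
  sdv <- apply(x, 1, sd)
  if (any(sdv <= .Machine$double.eps^0.5)) {
    bad <- dof_labels()[sdv <= .Machine$double.eps^0.5]
    abort(sprintf("degenerate DoF with zero variance: %s",
                  paste(bad, collapse = ", ")),
          class = "handsyn_degenerate_dof")
  }
  z <- (x - mu) / sdv
  list(
    z = z,
    params = tibble::tibble(dof = dof_labels(), mean = mu, sd = sdv),
    tasks = tasks
  )
}

#' Full preprocessing chain
#'
#' Convenience wrapper: filter, trim, resample — the conditioning applied
#' to training data before synergy extraction.
#'
#' @inheritParams lowpass_filter
#' @inheritParams trim_static
#' @inheritParams resample_frames
#' @param resample If `FALSE`, skip time normalization (held-out
#'   evaluation uses native frames so long tasks weigh more, matching
#'   their true frame counts).
#' @return Preprocessed recordings tibble.
#' @export
preprocess_recordings <- function(data, cutoff = 5, order = 2,
                                  sample_rate = 100, vel_threshold = 2,
                                  min_run = 0.2, n_frames = 1000,
                                  resample = TRUE) {
  out <- data |>
    lowpass_filter(cutoff = cutoff, order = order, sample_rate = sample_rate) |>
    trim_static(vel_threshold = vel_threshold, min_run = min_run,
                sample_rate = sample_rate)
  if (resample) out <- resample_frames(out, n_frames = n_frames)
  out
}
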