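## Four-step screening of raw paired gyroscope segments:
##   1. remove physically impossible readings (electronic recording errors),
##   2. align the two devices on their first common timestamp,
##   3. down-sample to 5 frames/s by 200 ms bin means,
##   4. per-axis z-scores scaled by 1000 and rounded to integers.

AXES <- c("gx", "gy", "gz")

#' Remove out-of-range readings
#'
#' Drops samples in which any gyroscope axis falls outside the sensor's
#' representable range; such values are electronic recording errors, not
#' movement.
#'
#' @param samples raw sample data frame (`t_ms`, `gx`, `gy`, `gz`).
#' @param valid_range closed interval, either `c(lo, hi)` applied to all
#'   three axes or a 3x2 matrix of per-axis bounds.
#' @return list with `samples` (the surviving rows) and `removed` (count).
#' @export
remove_impossible_values <- function(samples, valid_range) {
  rng <- if (is.matrix(valid_range)) valid_range else
    matrix(rep(valid_range, each = 3), nrow = 3)
  if (any(!is.finite(rng))) stop("valid_range must be finite", call. = FALSE)
  ok <- samples$gx >= rng[1, 1] & samples$gx <= rng[1, 2] &
        samples$gy >= rng[2, 1] & samples$gy <= rng[2, 2] &
        samples$gz >= rng[3, 1] & samples$gz <= rng[3, 2]
  if (!any(ok)) stop("all samples out of range; segment unusable",
                     call. = FALSE)
  out <- if (all(ok)) samples else
    fast_df(list(t_ms = samples$t_ms[ok], gx = samples$gx[ok],
                 gy = samples$gy[ok], gz = samples$gz[ok]))
  list(samples = out, removed = sum(!ok))
}

#' Align two device streams on a common clock
#'
#' Both devices are timestamped by the capture host but may have begun
#' recording at different moments; alignment drops the leading samples of
#' the earlier stream so that both start at the first timestamp present on
#' both recordings.
#'
#' @param a,b sorted raw sample data frames.
#' @return list with `a`, `b` (trimmed streams) and `t0_common`
#'   (millisecond start of the common support).
#' @export
align_streams <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty stream", call. = FALSE)
  t0 <- max(a$t_ms[1], b$t_ms[1])
  if (t0 > min(a$t_ms[nrow(a)], b$t_ms[nrow(b)])) {
    stop("streams have no overlapping time support", call. = FALSE)
  }
  list(a = a[a$t_ms >= t0, , drop = FALSE],
       b = b[b$t_ms >= t0, , drop = FALSE],
       t0_common = t0)
}

#' Down-sample an aligned stream to 5 frames per second
#'
#' Frame `k` is the per-axis mean of the samples in the 200 ms bin
#' `[t0 + 200k, t0 + 200(k+1))`; bin means are robust to the samples lost
#' in the error-removal step. The trailing partial bin is dropped. Interior
#' bins left empty by error removal are filled by linear interpolation of
#' the neighbouring bin means (with a warning); more than
#' `max_empty_fraction` empty bins is fatal.
#'
#' @param samples aligned raw sample data frame.
#' @param t0 bin origin in ms; defaults to the first timestamp.
#' @param target_rate_hz output frame rate (default 5).
#' @param max_empty_fraction maximum tolerated fraction of empty bins.
#' @return numeric matrix with one row per frame and columns gx, gy, gz.
#' @export
downsample_5hz <- function(samples, t0 = samples$t_ms[1], target_rate_hz = 5,
                           max_empty_fraction = 0.10) {
  if (nrow(samples) < 2) stop("too few samples to down-sample", call. = FALSE)
  bin_ms <- 1000 / target_rate_hz
  dt_nom <- stats::median(diff(samples$t_ms))
  duration <- samples$t_ms[nrow(samples)] - t0 + dt_nom
  nf <- floor(duration / bin_ms)
  if (nf < 1) stop("segment shorter than one frame", call. = FALSE)
  bin <- floor((samples$t_ms - t0) / bin_ms)
  keep <- bin >= 0 & bin < nf
  bin <- bin[keep]
  g <- as.matrix(samples[keep, AXES])
  counts <- tabulate(bin + 1L, nbins = nf)
  sums <- rowsum(g, bin, reorder = TRUE)
  frames <- matrix(NA_real_, nf, 3, dimnames = list(NULL, AXES))
  frames[counts > 0, ] <- sums / counts[counts > 0]
  empty <- which(counts == 0)
  if (length(empty)) {
    if (length(empty) / nf > max_empty_fraction) {
      stop("more than ", round(100 * max_empty_fraction), "% empty bins (",
           length(empty), "/", nf, ")", call. = FALSE)
    }
    warning(length(empty), " empty bin(s) filled by interpolation",
            call. = FALSE)
    filled <- which(counts > 0)
    for (ax in 1:3) {
      frames[empty, ax] <- stats::approx(filled, frames[filled, ax],
                                         xout = empty, rule = 2)$y
    }
  }
  frames
}

#' Standardize frames to z-scores times 1000
#'
#' Per axis: subtract the mean, divide by the sample standard deviation
#' (n-1 denominator), multiply by 1000 and round to the nearest integer
#' (ties away from zero). Device placement affects absolute output levels,
#' so only the standardized shape of the movement is retained.
#'
#' @param frames numeric matrix of down-sampled frames (columns gx,gy,gz).
#' @param scale multiplier applied to the z-scores before rounding.
#' @return integer-valued matrix of the same shape.
#' @export
standardize_z1000 <- function(frames, scale = 1000) {
  if (nrow(frames) < 3) stop("need at least 3 frames to standardize",
                             call. = FALSE)
  mu <- colMeans(frames)
  sdv <- apply(frames, 2, stats::sd)
  if (any(sdv == 0)) {
    stop("zero variance on axis ", paste(AXES[sdv == 0], collapse = ","),
         "; frozen or faulty sensor, segment excluded", call. = FALSE)
  }
  z <- sweep(sweep(frames, 2, mu), 2, sdv, "/")
  out <- round_half_away(z * scale)
  storage.mode(out) <- "double"
  out
}

new_clean_segment <- function(frames, site, role, task, t0_common,
                              rate_hz = 5) {
  structure(list(site = site, role = role, task = task, rate_hz = rate_hz,
                 frames = frames, t0_common = t0_common),
            class = "clean_segment")
}

## Shared worker: run the four screening steps on one raw stream pair.
## Used both for same-site pairs (preprocess_pair) and cross-hand pairs.
preprocess_stream_pair <- function(a, b, valid_range,
                                   target_rate_hz = 5, zscore_scale = 1000,
                                   max_empty_bin_fraction = 0.10,
                                   meta_a = list(), meta_b = list()) {
  ra <- remove_impossible_values(a, valid_range)
  rb <- remove_impossible_values(b, valid_range)
  al <- align_streams(ra$samples, rb$samples)
  fa <- downsample_5hz(al$a, t0 = al$t0_common, target_rate_hz,
                       max_empty_bin_fraction)
  fb <- downsample_5hz(al$b, t0 = al$t0_common, target_rate_hz,
                       max_empty_bin_fraction)
  n <- min(nrow(fa), nrow(fb))
  za <- standardize_z1000(fa[seq_len(n), , drop = FALSE], zscore_scale)
  zb <- standardize_z1000(fb[seq_len(n), , drop = FALSE], zscore_scale)
  list(
    a = new_clean_segment(za, meta_a$site, meta_a$role, meta_a$task,
                          al$t0_common, target_rate_hz),
    b = new_clean_segment(zb, meta_b$site, meta_b$role, meta_b$task,
                          al$t0_common, target_rate_hz),
    removed = c(a = ra$removed, b = rb$removed))
}

#' Screen one task/site stream pair
#'
#' Applies the four screening steps in their fixed order (remove
#' impossible values, align, down-sample, standardize) to the interviewer
#' and interviewee streams of one body site within one task segment, then
#' truncates both to the common frame count.
#'
#' @param session a [dyad_session()].
#' @param task task label.
#' @param site body site, one of head, torso, left_wrist, right_wrist.
#' @param valid_range see [remove_impossible_values()].
#' @param target_rate_hz,zscore_scale,max_empty_bin_fraction screening
#'   parameters.
#' @return list with clean segments `a` (interviewer), `b` (interviewee)
#'   and the per-stream `removed` counts.
#' @export
preprocess_pair <- function(session, task, site, valid_range,
                            target_rate_hz = 5, zscore_scale = 1000,
                            max_empty_bin_fraction = 0.10) {
  segs <- segment_tasks(session)
  if (is.null(segs[[task]][[site]])) {
    stop("no stream pair for task '", task, "', site '", site, "'",
         call. = FALSE)
  }
  pr <- segs[[task]][[site]]
  preprocess_stream_pair(
    pr$interviewer, pr$interviewee, valid_range,
    target_rate_hz, zscore_scale, max_empty_bin_fraction,
    meta_a = list(site = site, role = "interviewer", task = task),
    meta_b = list(site = site, role = "interviewee", task = task))
}
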