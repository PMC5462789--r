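# Preprocessing, instantaneous phase extraction and phase-locking-value
# connectivity (static and sliding-window).

#' Band-pass filter, epoch and reject a multichannel recording
#'
#' Zero-phase FIR band-pass filtering (order `3 * fs / low_cut`, applied
#' forward and backward), segmentation into non-overlapping epochs (a
#' trailing remainder shorter than `epoch_len` is discarded), and amplitude
#' artifact rejection: an epoch containing any sample exceeding
#' `reject_uv` in absolute value is dropped.
#'
#' @param ts a [region_ts()] or `scalp_rec`.
#' @param band numeric length-2 pass band in Hz (default the 3-45 Hz
#'   broadband used for raw recordings).
#' @param epoch_len epoch length in seconds (default 40).
#' @param reject_uv rejection threshold in signal units (default 80);
#'   `Inf` disables rejection.
#' @return list of [region_ts()] epochs (possibly empty, with a warning,
#'   if every epoch is rejected). The filter's half-length is recorded in
#'   attribute `edge_samples` of each epoch.
#' @export
bandpass_epoch_reject <- function(ts, band = c(3, 45), epoch_len = 40,
                                  reject_uv = 80) {
  x <- ts$data
  fs <- ts$fs
  if (band[1] <= 0 || band[2] >= fs / 2)
    stop("band must lie strictly inside (0, fs/2)")
  ord <- round(3 * fs / band[1])
  n_ep <- floor(ncol(x) / (epoch_len * fs))
  if (n_ep < 1) stop("recording shorter than one epoch")
  if (ncol(x) <= 3 * ord)
    stop("recording too short for the filter length")
  filt <- signal::fir1(ord, band / (fs / 2), type = "pass")
  xf <- t(apply(x, 1L, function(ch) signal::filtfilt(filt, ch)))
  ep_len <- round(epoch_len * fs)
  labs <- ts$region_labels %||% ts$channel_labels
  # artifact rejection is judged on the raw amplitudes (a filtered spike
  # is smeared below threshold); the returned epochs are filtered
  keep <- vapply(seq_len(n_ep), function(k)
    max(abs(x[, ((k - 1L) * ep_len + 1L):(k * ep_len)])) <= reject_uv,
    TRUE)
  if (!any(keep))
    warning("all epochs rejected by the amplitude criterion")
  lapply(which(keep), function(k) {
    seg <- xf[, ((k - 1L) * ep_len + 1L):(k * ep_len), drop = FALSE]
    e <- region_ts(seg, fs, band, labs)
    attr(e, "edge_samples") <- ceiling(ord / 2)
    e
  })
}

#' Instantaneous phase of band-limited signals
#'
#' Extracts the analytic-signal angle of each channel (Hilbert-transform
#' construction in the frequency domain) and unwraps it along time.
#'
#' @param ts a [region_ts()]; channels should already be band-limited.
#' @return object of class `phase_series` with elements `phases`
#'   (channels x samples, unwrapped radians), `fs`, `band`.
#' @export
instantaneous_phase <- function(ts) {
  stopifnot(inherits(ts, "region_ts"))
  x <- ts$data
  if (any(apply(x, 1L, function(r) all(r == 0))))
    stop("all-zero channel: phase undefined")
  ph <- t(apply(x, 1L, function(r)
    unwrap_phase(Arg(analytic_signal(r)))))
  structure(list(phases = ph, fs = ts$fs, band = ts$band,
                 labels = ts$region_labels),
            class = "phase_series")
}

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1L], d))
}

#' Static phase-locking value matrix
#'
#' For each channel pair computes
#' \eqn{PLV_{xy} = | \mathrm{mean}_t\, e^{j(\phi_y(t) - \phi_x(t))} |},
#' the magnitude of the time-averaged unit phasor of the phase difference:
#' 1 for perfectly locked pairs, near 0 for independent ones.
#'
#' @param ph a `phase_series`.
#' @return symmetric numeric matrix in \[0, 1\] with zero diagonal.
#' @export
plv_static <- function(ph) {
  stopifnot(inherits(ph, "phase_series"))
  p <- ph$phases
  if (!all(is.finite(p))) stop("non-finite phases")
  if (ncol(p) < 2L) stop("need at least 2 samples")
  z <- exp(1i * p)
  m <- Mod(tcrossprod(Conj(z), z)) / ncol(p)
  m <- pmin(m, 1)
  diag(m) <- 0
  dimnames(m) <- list(ph$labels, ph$labels)
  m
}

#' Sliding-window phase-locking value
#'
#' Computes one PLV matrix per fully contained window. Windows start at 0
#' and advance by `step`; the number of windows is
#' `floor((T/fs - window) / step) + 1`.
#'
#' @param ph a `phase_series`.
#' @param window window length delta in seconds.
#' @param step hop between window starts in seconds (default `window`,
#'   i.e. non-overlapping).
#' @param n_cycles minimum-cycle rule used to vet `window` (default 6);
#'   a shorter window triggers a warning (or an error when
#'   `short_window = "error"`).
#' @param short_window `"warn"` or `"error"`.
#' @return object of class `windowed_plv`: list of PLV matrices plus
#'   `window`, `step` and `start_times` (seconds).
#' @export
plv_dynamic <- function(ph, window, step = window, n_cycles = 6,
                        short_window = c("warn", "error")) {
  stopifnot(inherits(ph, "phase_series"))
  short_window <- match.arg(short_window)
  if (step <= 0) stop("step must be positive")
  if (is.numeric(ph$band)) {
    wmin <- round_window_ms(check_window_rule(ph$band, n_cycles)) / 1000
    if (window < wmin) {
      msg <- sprintf(
        "window %.3f s shorter than the %d-cycle minimum %.3f s", window,
        n_cycles, wmin)
      if (short_window == "error") stop(msg) else warning(msg)
    }
  }
  n_t <- ncol(ph$phases)
  fs <- ph$fs
  win <- round(window * fs)
  n_w <- floor((n_t / fs - window) / step + 1e-9) + 1
  if (n_w < 1) stop("signal shorter than one window")
  starts <- round((seq_len(n_w) - 1) * step * fs)
  starts <- starts[starts + win <= n_t]
  mats <- lapply(starts, function(s0) {
    sub <- structure(list(
      phases = ph$phases[, (s0 + 1L):(s0 + win), drop = FALSE],
      fs = fs, band = ph$band, labels = ph$labels),
      class = "phase_series")
    plv_static(sub)
  })
  structure(list(matrices = mats, window = window, step = step,
                 start_times = starts / fs),
            class = "windowed_plv")
}

#' @export
print.windowed_plv <- function(x, ...) {
  cat(sprintf("windowed_plv: %d windows of %g s (step %g s), %d nodes\n",
              length(x$matrices), x$window, x$step, nrow(x$matrices[[1]])))
  invisible(x)
}

#' Minimal PLV window length for a frequency band
#'
#' The window must span at least `n_cycles` cycles of the band's central
#' frequency `(low + high) / 2`; the default 6 cycles in the beta band
#' (14-25 Hz, central frequency 19.5 Hz) gives 0.308 s, i.e. 300 ms after
#' rounding to the nearest 100 ms.
#'
#' @param band numeric length-2 band edges in Hz.
#' @param n_cycles number of cycles required (default 6).
#' @return minimal window length in seconds (unrounded; see
#'   [round_window_ms()]).
#' @export
check_window_rule <- function(band, n_cycles = 6) {
  n_cycles / mean(band)
}

#' Round a window length to the nearest 100 ms
#'
#' @param window_s window length in seconds.
#' @return window length in milliseconds, rounded half-up to a multiple
#'   of 100.
#' @export
round_window_ms <- function(window_s) {
  round_half_up(window_s * 1000, 100)
}
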