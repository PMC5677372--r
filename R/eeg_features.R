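#' Epoched multi-channel signal container
#'
#' @param data Numeric array, channels x time x epochs. Each epoch is a
#'   stimulus-locked segment (3 s in the reference study design).
#' @param fs Sampling rate in Hz; at least 200 Hz is required so that the
#'   63--99 Hz band and the 100 Hz waveform resampling are defined.
#' @param channel_names Optional channel labels.
#' @return An `epoched_signal`.
#' @export
epoched_signal <- function(data, fs, channel_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    rlang::abort("`data` must be a 3-d array: channels x time x epochs")
  }
  if (!is.numeric(fs) || fs < 200) {
    rlang::abort("`fs` must be >= 200 Hz")
  }
  epoch_duration <- dim(data)[2] / fs
  if (abs(epoch_duration * fs - dim(data)[2]) > 1e-9) {
    rlang::abort("time-axis length must equal fs * epoch_duration exactly")
  }
  channel_names <- channel_names %||% paste0("ch", sprintf("%02d", seq_len(dim(data)[1])))
  structure(
    list(data = data, fs = fs, epoch_duration = epoch_duration,
         channel_names = channel_names),
    class = "epoched_signal"
  )
}

#' @export
print.epoched_signal <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoched_signal> ", d[1], " channels x ", d[2], " samples (",
      x$epoch_duration, " s @ ", x$fs, " Hz) x ", d[3], " epochs\n", sep = "")
  invisible(x)
}

#' Canonical EEG frequency bands
#'
#' Five traditional bands (delta 1--3, theta 5--7, alpha 9--12, beta 14--31,
#' gamma 33--42 Hz) plus two expanded gamma bands (33--57, 63--99 Hz).
#'
#' @return Tibble with `band`, `low`, `high` (Hz).
#' @export
eeg_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "gamma", "gamma1", "gamma2"),
    low = c(1, 5, 9, 14, 33, 33, 63),
    high = c(3, 7, 12, 31, 42, 57, 99)
  )
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward and backward (`filtfilt`), removing
#' DC and content outside `[low, high]`. Applied independently to every
#' channel and epoch.
#'
#' @param x An `epoched_signal` or a numeric vector.
#' @param fs Sampling rate (taken from the object for `epoched_signal`).
#' @param low,high Band edges in Hz; requires `fs > 2 * high`.
#' @export
eeg_bandpass <- function(x, fs = NULL, low = 0.5, high = 100) {
  if (inherits(x, "epoched_signal")) {
    filt <- make_bandpass(x$fs, low, high)
    out <- x
    for (ch in seq_len(dim(x$data)[1])) {
      for (ep in seq_len(dim(x$data)[3])) {
        out$data[ch, , ep] <- signal::filtfilt(filt, x$data[ch, , ep])
      }
    }
    return(out)
  }
  if (is.null(fs)) rlang::abort("`fs` is required for a plain vector")
  signal::filtfilt(make_bandpass(fs, low, high), x)
}

make_bandpass <- function(fs, low, high) {
  if (fs <= 2 * high) {
    rlang::abort("sampling rate too low: need fs > 2 * high")
  }
  signal::butter(4, c(low, high) / (fs / 2), type = "pass")
}

#' Sliding-window index ranges over epochs
#'
#' Samples are built from consecutive epochs: a window of `window_epochs`
#' epochs advanced by `step_epochs` (30 epochs with a 1-epoch step in the
#' reference timeline, so 200 epochs yield 171 windows — the same count as
#' 600 s of signal cut into 90 s windows with a 3 s step).
#'
#' @param n_epochs Total number of epochs available.
#' @param window_epochs Epochs per window.
#' @param step_epochs Stride between window starts.
#' @return Tibble with `window`, `start`, `end` (1-based, inclusive).
#' @export
epoch_windows <- function(n_epochs, window_epochs = 30L, step_epochs = 1L) {
  n_epochs <- as.integer(n_epochs)
  window_epochs <- as.integer(window_epochs)
  step_epochs <- as.integer(step_epochs)
  if (n_epochs < window_epochs) {
    rlang::abort("too few epochs: `n_epochs` must be >= `window_epochs`")
  }
  if (step_epochs < 1L) rlang::abort("`step_epochs` must be >= 1")
  starts <- seq.int(1L, n_epochs - window_epochs + 1L, by = step_epochs)
  tibble::tibble(
    window = seq_along(starts),
    start = starts,
    end = starts + window_epochs - 1L
  )
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: the signal is cut into Hamming-windowed
#' segments (2 s, 50% overlap by default), each segment's one-sided
#' periodogram is computed, and the results are averaged. Densities are
#' scaled so that `sum(power) * df` approximates the signal variance
#' (detrended by the segment mean).
#'
#' @param x Numeric vector (one channel; typically the concatenated epochs
#'   of one window).
#' @param fs Sampling rate in Hz.
#' @param segment_sec Segment length in seconds; must not exceed the signal.
#' @param overlap Fractional overlap between segments in `[0, 1)`.
#' @return Tibble with `frequency` (Hz) and `power` (density, unit^2/Hz).
#' @export
welch_psd <- function(x, fs, segment_sec = 2, overlap = 0.5) {
  nseg <- round(segment_sec * fs)
  if (nseg > length(x)) {
    rlang::abort("Welch segment longer than the signal")
  }
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq.int(1L, length(x) - nseg + 1L, by = step)
  win <- signal::hamming(nseg)
  u <- sum(win^2)
  nfreq <- nseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- abs(stats::fft(seg)[seq_len(nfreq)])^2 / (fs * u)
    # one-sided: double everything except DC (and Nyquist when nseg is even)
    sp[-1] <- 2 * sp[-1]
    if (nseg %% 2L == 0L) sp[nfreq] <- sp[nfreq] / 2
    acc <- acc + sp
  }
  tibble::tibble(
    frequency = (seq_len(nfreq) - 1L) * fs / nseg,
    power = acc / length(starts)
  )
}

# mean PSD density over (low, high]; unit-stable across fs for fixed bins
band_power <- function(psd, low, high) {
  sel <- psd$frequency > low & psd$frequency <= high
  if (!any(sel)) rlang::abort("band contains no frequency bins")
  mean(psd$power[sel])
}

#' Spectral power features of one window
#'
#' Per channel: the mean PSD density over each of the 7 canonical bands plus
#' 39 narrowband powers over the 1 Hz intervals `[i, i+1]` for i = 1..39 —
#' 46 features per channel, so a 16-channel montage yields 736. Feature
#' names encode channel and band (`psd_<ch>_<band>` / `psd_<ch>_nb<i>`).
#'
#' @param x An `epoched_signal` whose epochs form one sample window (epochs
#'   are concatenated per channel before spectrum estimation).
#' @param bands Band definition tibble, see [eeg_bands()].
#' @param segment_sec,overlap Welch parameters.
#' @param log10_power Optionally log10-transform the band powers.
#' @return One-row tibble of `46 * n_channels` features.
#' @export
psd_features <- function(x, bands = eeg_bands(), segment_sec = 2,
                         overlap = 0.5, log10_power = FALSE) {
  stopifnot(inherits(x, "epoched_signal"))
  if (max(bands$high) >= x$fs / 2) {
    rlang::abort("band edge beyond Nyquist frequency")
  }
  narrow <- tibble::tibble(
    band = paste0("nb", sprintf("%02d", 1:39)),
    low = 1:39, high = 2:40
  )
  all_bands <- dplyr::bind_rows(bands, narrow)
  vals <- purrr::map(seq_len(dim(x$data)[1]), function(ch) {
    sig <- as.vector(x$data[ch, , ])
    psd <- welch_psd(sig, x$fs, segment_sec = segment_sec, overlap = overlap)
    v <- purrr::map2_dbl(all_bands$low, all_bands$high,
                         function(lo, hi) band_power(psd, lo, hi))
    if (log10_power) v <- log10(v + .Machine$double.xmin)
    stats::setNames(v, paste0("psd_", x$channel_names[ch], "_", all_bands$band))
  })
  tibble::as_tibble_row(unlist(vals))
}

#' Event-related potential features of one window
#'
#' The stimulus-locked epochs of the window are averaged per channel and the
#' average waveform is resampled to 100 Hz: a zero-phase antialiasing
#' low-pass (8th-order Butterworth at 40 Hz, applied forward and backward so
#' latencies are not shifted) followed by interpolation at the exact
#' 0, 10, ..., 1000 ms grid — endpoints inclusive, 101 points. The waveform
#' points are complemented by the peak value, valley value, and their
#' latencies in ms — 105 features per channel, 1680 for 16 channels.
#'
#' @param x An `epoched_signal` window; epochs must span at least 1 s.
#' @return One-row tibble of `105 * n_channels` features.
#' @export
erp_features <- function(x) {
  stopifnot(inherits(x, "epoched_signal"))
  if (x$epoch_duration < 1) {
    rlang::abort("epochs shorter than 1 s: cannot form the 0-1000 ms waveform")
  }
  t_grid <- seq(0, 1, by = 0.01)
  lp <- if (x$fs > 100) signal::butter(8, 40 / (x$fs / 2), type = "low")
  vals <- purrr::map(seq_len(dim(x$data)[1]), function(ch) {
    avg <- rowMeans(x$data[ch, , , drop = FALSE], dims = 2)[1, ]
    t_src <- (seq_along(avg) - 1L) / x$fs
    if (x$fs > 100) avg <- signal::filtfilt(lp, avg)
    wave <- stats::approx(t_src, avg, xout = t_grid, rule = 2)$y
    t_ms <- (0:100) * 10
    pk <- which.max(wave)
    vl <- which.min(wave)
    stats::setNames(
      c(wave, wave[pk], wave[vl], t_ms[pk], t_ms[vl]),
      paste0("erp_", x$channel_names[ch], "_",
             c(sprintf("t%04d", t_ms), "peak", "valley",
               "peak_lat", "valley_lat"))
    )
  })
  tibble::as_tibble_row(unlist(vals))
}


#' Extract the full EEG feature block for every sliding window
#'
#' Runs [psd_features()] and [erp_features()] over every window of
#' [epoch_windows()] and stacks the rows. Column counts emerge from the
#' extractor configuration: 46 + 105 = 151 per channel, 2416 for 16
#' channels.
#'
#' @param x An `epoched_signal` for one subject-task.
#' @param window_epochs,step_epochs Sliding-window parameters.
#' @param ... Passed to [psd_features()].
#' @return List with `psd` and `erp` tibbles (one row per window) and the
#'   window index tibble.
#' @export
extract_eeg_features <- function(x, window_epochs = 30L, step_epochs = 1L,
                                 ...) {
  stopifnot(inherits(x, "epoched_signal"))
  wins <- epoch_windows(dim(x$data)[3], window_epochs, step_epochs)
  psd_rows <- vector("list", nrow(wins))
  erp_rows <- vector("list", nrow(wins))
  for (i in seq_len(nrow(wins))) {
    sub <- epoched_signal(
      x$data[, , wins$start[i]:wins$end[i], drop = FALSE],
      fs = x$fs, channel_names = x$channel_names
    )
    psd_rows[[i]] <- psd_features(sub, ...)
    erp_rows[[i]] <- erp_features(sub)
  }
  list(
    psd = purrr::list_rbind(psd_rows),
    erp = purrr::list_rbind(erp_rows),
    windows = wins
  )
}
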