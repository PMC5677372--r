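#' R-R interval series
#'
#' @param rr Successive R-R intervals in seconds (all > 0). Intervals
#'   shorter than 0.5 s are physiologically suspicious at rest and trigger a
#'   warning, not an error.
#' @param t Optional cumulative occurrence times in seconds (defaults to
#'   `cumsum(rr)`).
#' @return An `rr_series`.
#' @export
rr_series <- function(rr, t = NULL) {
  if (!is.numeric(rr) || length(rr) < 1L || any(!is.finite(rr))) {
    rlang::abort("`rr` must be a finite numeric vector")
  }
  if (any(rr <= 0)) rlang::abort("R-R intervals must be positive")
  if (any(rr < 0.5)) {
    rlang::warn("some R-R intervals are shorter than 0.5 s")
  }
  t <- t %||% cumsum(rr)
  if (length(t) != length(rr)) {
    rlang::abort("`t` must have one entry per interval")
  }
  structure(list(rr = rr, t = t), class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat("<rr_series> ", length(x$rr), " beats over ",
      format(diff(range(x$t)), digits = 4), " s\n", sep = "")
  invisible(x)
}

#' Time-domain HRV features
#'
#' Classic short-term descriptors: mean R-R interval, SDNN (sample SD of the
#' intervals, seconds), RMSSD (root mean square of successive differences,
#' seconds), pNN50 (fraction of successive differences exceeding 50 ms —
#' the comparison is in absolute milliseconds regardless of any rescaling of
#' the intervals), and the mean heart rate `60 / meanRR` in bpm.
#'
#' @param x An [rr_series()] with >= 2 intervals.
#' @return One-row tibble: `mean_rr`, `sdnn`, `rmssd`, `pnn50`, `mean_hr`.
#' @export
rr_time_features <- function(x) {
  stopifnot(inherits(x, "rr_series"))
  rr <- x$rr
  if (length(rr) < 2L) rlang::abort("need >= 2 intervals")
  d <- diff(rr)
  tibble::tibble(
    mean_rr = mean(rr),
    sdnn = stats::sd(rr),
    rmssd = sqrt(mean(d^2)),
    pnn50 = mean(abs(d) > 0.050),
    mean_hr = 60 / mean(rr)
  )
}

# Classic Lomb periodogram (with the phase offset tau) of an irregularly
# sampled series; returns spectral power at the requested frequencies.
lomb_periodogram <- function(t, y, freq) {
  y <- y - mean(y)
  vr <- stats::var(y)
  if (vr == 0) {
    return(rep(0, length(freq)))
  }
  vapply(freq, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau))
    st <- sin(w * (t - tau))
    0.5 * (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2))
  }, numeric(1))
}

#' Frequency-domain HRV features
#'
#' The R-R tachogram is spectrally analyzed directly on its irregular beat
#' times with the Lomb--Scargle periodogram (no interpolation/resampling of
#' the series). Band powers are accumulated over VLF 0.003--0.04, LF
#' 0.04--0.15, HF 0.15--0.4 Hz; normalized units are LFnu = LF / (LF + HF)
#' and HFnu = 1 - LFnu.
#'
#' @param x An [rr_series()] with >= 4 intervals. Spans shorter than 120 s
#'   give unreliable LF estimates and trigger a warning unless
#'   `check_span = FALSE` (the sliding-window pipeline uses 90 s windows and
#'   disables the warning).
#' @param freq_step Frequency grid resolution in Hz.
#' @param check_span Warn when the series spans < 120 s.
#' @return One-row tibble: `vlf`, `lf`, `hf`, `lf_hf`, `lf_nu`, `hf_nu`.
#' @export
rr_freq_features <- function(x, freq_step = 0.001, check_span = TRUE) {
  stopifnot(inherits(x, "rr_series"))
  if (length(x$rr) < 4L) rlang::abort("need >= 4 intervals")
  span <- diff(range(x$t))
  if (check_span && span < 120) {
    rlang::warn("series spans < 120 s; LF estimates may be unreliable")
  }
  freq <- seq(0.003, 0.4, by = freq_step)
  pw <- lomb_periodogram(x$t, x$rr, freq)
  bp <- function(lo, hi) sum(pw[freq > lo & freq <= hi]) * freq_step
  vlf <- bp(0.003, 0.04)
  lf <- bp(0.04, 0.15)
  hf <- bp(0.15, 0.4)
  tibble::tibble(
    vlf = vlf, lf = lf, hf = hf,
    lf_hf = if (hf > 0) lf / hf else NA_real_,
    lf_nu = if (lf + hf > 0) lf / (lf + hf) else NA_real_,
    hf_nu = if (lf + hf > 0) hf / (lf + hf) else NA_real_
  )
}

#' Poincare-plot descriptors
#'
#' SD1 is the SD of `(rr[i+1] - rr[i]) / sqrt(2)` (short-term variability,
#' the spread perpendicular to the identity line); SD2 is the SD of
#' `(rr[i+1] + rr[i]) / sqrt(2)` (long-term variability, the spread along
#' it).
#'
#' @param x An [rr_series()] with >= 3 intervals.
#' @return One-row tibble: `sd1`, `sd2`, `sd1_sd2`.
#' @export
rr_poincare <- function(x) {
  stopifnot(inherits(x, "rr_series"))
  rr <- x$rr
  if (length(rr) < 3L) rlang::abort("need >= 3 intervals")
  a <- utils::head(rr, -1)
  b <- utils::tail(rr, -1)
  sd1 <- stats::sd((b - a) / sqrt(2))
  sd2 <- stats::sd((b + a) / sqrt(2))
  tibble::tibble(sd1 = sd1, sd2 = sd2,
                 sd1_sd2 = if (sd2 > 0) sd1 / sd2 else NA_real_)
}

#' Sample entropy of an interval series
#'
#' Standard template-matching estimate: with embedding dimension `m` and
#' tolerance `r` (Chebyshev distance, self-matches excluded), SampEn =
#' `-log(A / B)` where `B` counts matching templates of length `m` and `A`
#' those of length `m + 1`. A constant (or otherwise degenerate) series has
#' no defined value and returns `NA`.
#'
#' @param x An [rr_series()]; fewer than 20 intervals triggers a warning.
#' @param m Embedding dimension.
#' @param r Tolerance; defaults to `0.2 * sd(rr)`.
#' @export
rr_sample_entropy <- function(x, m = 2L, r = NULL) {
  stopifnot(inherits(x, "rr_series"))
  rr <- x$rr
  if (length(rr) < m + 2L) rlang::abort("series too short for sample entropy")
  if (length(rr) < 20L) {
    rlang::warn("fewer than 20 intervals; sample entropy is unstable")
  }
  r <- r %||% (0.2 * stats::sd(rr))
  if (!is.finite(r) || r <= 0) {
    return(NA_real_)
  }
  count_matches <- function(mm) {
    n_t <- length(rr) - mm + 1L
    emb <- sapply(seq_len(mm), function(j) rr[j:(j + n_t - 1L)])
    emb <- matrix(emb, nrow = n_t)
    cnt <- 0L
    for (i in seq_len(n_t - 1L)) {
      d <- abs(sweep(emb[(i + 1L):n_t, , drop = FALSE], 2, emb[i, ], "-"))
      cnt <- cnt + sum(apply(d, 1, max) < r)
    }
    cnt
  }
  b <- count_matches(m)
  a <- count_matches(m + 1L)
  if (a == 0L || b == 0L) {
    return(NA_real_)
  }
  -log(a / b)
}

#' Full HRV feature block for one window
#'
#' Bundles the time-domain, frequency-domain, Poincare and sample-entropy
#' descriptors into one row (15 features). This documented compact block
#' stands in for exhaustive HRV tool output; the feature-table schema does
#' not assume any particular width.
#'
#' @param x An [rr_series()].
#' @param check_span Passed to [rr_freq_features()].
#' @return One-row tibble of 15 `ecg_*` features.
#' @export
rr_features <- function(x, check_span = TRUE) {
  out <- dplyr::bind_cols(
    rr_time_features(x),
    rr_freq_features(x, check_span = check_span),
    rr_poincare(x),
    tibble::tibble(sampen = rr_sample_entropy(x))
  )
  stats::setNames(out, paste0("ecg_", names(out)))
}

#' Sliding-window HRV features over a task recording
#'
#' Windows the beat series on the same wall-clock timeline as the EEG
#' samples (90 s windows advanced by 3 s over a 600 s task by default, so
#' the rows align across modalities) and extracts [rr_features()] per
#' window. Beats are assigned to a window when their occurrence time falls
#' in `[start, start + window_sec)`.
#'
#' @param x An [rr_series()] covering the task.
#' @param task_sec,window_sec,step_sec Timeline parameters in seconds.
#' @return Tibble with one row per window (plus a `window` index column
#'   attribute-free); windows with fewer than 4 beats are filled with the
#'   features of the nearest valid window.
#' @export
extract_rr_features <- function(x, task_sec = 600, window_sec = 90,
                                step_sec = 3) {
  stopifnot(inherits(x, "rr_series"))
  starts <- seq(0, task_sec - window_sec, by = step_sec)
  rows <- purrr::map(starts, function(s) {
    sel <- x$t >= s & x$t < s + window_sec
    if (sum(sel) < 4L) {
      return(NULL)
    }
    sub <- suppressWarnings(rr_series(x$rr[sel], t = x$t[sel]))
    rr_features(sub, check_span = FALSE)
  })
  empty <- purrr::map_lgl(rows, is.null)
  if (all(empty)) rlang::abort("no window contains enough beats")
  if (any(empty)) {
    valid <- which(!empty)
    for (i in which(empty)) {
      rows[[i]] <- rows[[valid[which.min(abs(valid - i))]]]
    }
  }
  purrr::list_rbind(rows)
}

#' Read R-R intervals from a plain-text file
#'
#' Accepts either one interval (seconds) per line, or a two-column CSV with
#' `time` and `rr` columns.
#'
#' @param path File path.
#' @export
read_rr <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl(",", first, fixed = TRUE)) {
    data <- utils::read.csv(path)
    if (!all(c("time", "rr") %in% names(data))) {
      rlang::abort("CSV R-R input needs `time` and `rr` columns")
    }
    rr_series(data$rr, t = data$time)
  } else {
    rr_series(scan(path, quiet = TRUE))
  }
}
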