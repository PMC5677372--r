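#' Configuration of the synthetic workload study
#'
#' Defines the conditions of the emulated three-level n-back experiment:
#' 10 subjects, 3 workload classes, 200 stimulus-locked 3 s epochs per task
#' (600 s of signal), 16 EEG channels, plus the effect sizes that connect
#' workload level to signal physiology — alpha suppression and theta
#' increase with load, a P300-like positive bump at ~300 ms whose amplitude
#' decreases with load, and R-R intervals that shorten (heart rate rises)
#' and lose variability under load. The abstract feature-table generator is
#' configured by the informative/redundant/noise counts and its effect size.
#'
#' @param n_subjects Number of subjects.
#' @param epochs_per_task Stimulus epochs per subject-task.
#' @param epoch_duration Epoch length in seconds.
#' @param fs EEG sampling rate in Hz (250 by default, a desk-scale rate;
#'   1000 Hz is supported).
#' @param n_channels EEG channel count.
#' @param task_sec Task duration in seconds.
#' @param alpha_mult,theta_mult Per-class band-power multipliers (length 3,
#'   classes low/medium/high).
#' @param erp_amp Per-class ERP bump amplitude (arbitrary units).
#' @param rr_mean,rr_sdnn Per-class mean R-R interval and its SD (seconds).
#' @param n_informative Number of class-informative abstract features.
#' @param n_redundant_copies Noisy copies made of each informative feature.
#' @param n_noise Number of pure-noise abstract features.
#' @param n_per_class Abstract-table samples per subject and class; 171 by
#'   default, the number of sliding-window samples one subject-task yields
#'   on the reference timeline (600 s, 90 s window, 3 s step).
#' @param effect_size Class-mean separation of informative features, in
#'   within-class SD units.
#' @param subject_sd Subject-level mean offset, in within-class SD units
#'   (makes leave-one-subject-out generalization imperfect but learnable).
#' @param copy_noise_sd SD of the noise added to redundant copies.
#' @param noise_sd SD of pure-noise features.
#' @param seed Mandatory integer seed; all generators are deterministic
#'   given the config.
#' @return A `synth_config`.
#' @export
synth_config <- function(n_subjects = 10L, epochs_per_task = 200L,
                         epoch_duration = 3, fs = 250, n_channels = 16L,
                         task_sec = 600,
                         alpha_mult = c(1.4, 1.0, 0.7),
                         theta_mult = c(0.8, 1.0, 1.3),
                         erp_amp = c(8, 6, 4),
                         rr_mean = c(0.9, 0.8, 0.7),
                         rr_sdnn = c(0.06, 0.05, 0.035),
                         n_informative = 6L, n_redundant_copies = 2L,
                         n_noise = 12L, n_per_class = 171L,
                         effect_size = 0.8, subject_sd = 0.3,
                         copy_noise_sd = 0.3, noise_sd = 1,
                         seed = 20261L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_classes = 3L,
    epochs_per_task = as.integer(epochs_per_task),
    epoch_duration = epoch_duration, fs = fs,
    n_channels = as.integer(n_channels), task_sec = task_sec,
    alpha_mult = alpha_mult, theta_mult = theta_mult, erp_amp = erp_amp,
    rr_mean = rr_mean, rr_sdnn = rr_sdnn,
    n_informative = as.integer(n_informative),
    n_redundant_copies = as.integer(n_redundant_copies),
    n_noise = as.integer(n_noise), n_per_class = as.integer(n_per_class),
    effect_size = effect_size, subject_sd = subject_sd,
    copy_noise_sd = copy_noise_sd, noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  counts <- c("n_subjects", "epochs_per_task", "n_channels",
              "n_informative", "n_noise", "n_per_class")
  if (any(vapply(cfg[counts], function(v) v < 1L, logical(1)))) {
    rlang::abort("all counts must be >= 1")
  }
  if (cfg$n_redundant_copies < 0L) {
    rlang::abort("`n_redundant_copies` must be >= 0")
  }
  per_class <- c("alpha_mult", "theta_mult", "erp_amp", "rr_mean", "rr_sdnn")
  if (any(vapply(cfg[per_class], length, integer(1)) != 3L)) {
    rlang::abort("per-class parameter vectors must have length 3")
  }
  if (is.na(cfg$seed)) rlang::abort("`seed` is mandatory")
  structure(cfg, class = "synth_config")
}

workload_levels <- function() c("low", "medium", "high")

# deterministic per-(subject, class) stream seed, kept well below 2^31
stream_seed <- function(cfg, subject, class_idx, salt = 0L) {
  (cfg$seed %% 100000L) * 10000L + subject * 100L + class_idx * 10L + salt
}

#' Generate an abstract feature table with known ground truth
#'
#' Informative features are drawn class-conditionally (unit-variance
#' Gaussians whose class means are spaced `effect_size` apart, with
#' per-subject mean offsets of `subject_sd`); redundant features are noisy
#' copies of informative ones; noise features are class-independent. The
#' features are spread over the three modality tags (eeg_psd, eeg_erp, ecg)
#' in round-robin order so that both fusion levels are exercised. Class
#' priors are exactly balanced within every subject.
#'
#' @param config A [synth_config()].
#' @return List with `table` (a [feature_table()]) and `truth` (tibble:
#'   `feature`, `modality`, `role`, `source`).
#' @export
gen_feature_table <- function(config = synth_config()) {
  cfg <- config
  withr::with_seed(cfg$seed, {
    n_rows <- cfg$n_subjects * cfg$n_classes * cfg$n_per_class
    subject <- rep(sprintf("S%02d", seq_len(cfg$n_subjects)),
                   each = cfg$n_classes * cfg$n_per_class)
    label <- rep(rep(workload_levels(), each = cfg$n_per_class),
                 times = cfg$n_subjects)
    class_idx <- match(label, workload_levels())
    mods <- c("eeg_psd", "eeg_erp", "ecg")

    info_names <- sprintf("inf%02d", seq_len(cfg$n_informative))
    info_mod <- mods[(seq_len(cfg$n_informative) - 1L) %% 3L + 1L]
    # class means spaced effect_size apart, direction alternating per feature
    info <- matrix(0, n_rows, cfg$n_informative,
                   dimnames = list(NULL, info_names))
    for (j in seq_len(cfg$n_informative)) {
      dir <- if (j %% 2L == 0L) -1 else 1
      shift <- dir * cfg$effect_size * (class_idx - 2)
      offs <- stats::rnorm(cfg$n_subjects, 0, cfg$subject_sd)
      info[, j] <- shift + offs[match(subject, unique(subject))] +
        stats::rnorm(n_rows)
    }

    red_list <- list()
    red_src <- character(0)
    if (cfg$n_redundant_copies > 0L) {
      for (j in seq_len(cfg$n_informative)) {
        for (c_i in seq_len(cfg$n_redundant_copies)) {
          nm <- sprintf("red%02d_%d", j, c_i)
          red_list[[nm]] <- info[, j] +
            stats::rnorm(n_rows, 0, cfg$copy_noise_sd)
          red_src <- c(red_src, info_names[j])
        }
      }
    }
    red <- if (length(red_list)) do.call(cbind, red_list) else
      matrix(0, n_rows, 0)
    red_mod <- info_mod[rep(seq_len(cfg$n_informative),
                            each = cfg$n_redundant_copies)]

    noise_names <- sprintf("noi%02d", seq_len(cfg$n_noise))
    noise <- matrix(stats::rnorm(n_rows * cfg$n_noise, 0, cfg$noise_sd),
                    n_rows, cfg$n_noise, dimnames = list(NULL, noise_names))
    noise_mod <- mods[(seq_len(cfg$n_noise) - 1L) %% 3L + 1L]

    values <- cbind(info, red, noise)
    modality <- c(info_mod, red_mod, noise_mod)
    truth <- tibble::tibble(
      feature = colnames(values),
      modality = modality,
      role = c(rep("informative", cfg$n_informative),
               rep("redundant", ncol(red)),
               rep("noise", cfg$n_noise)),
      source = c(info_names, red_src, rep(NA_character_, cfg$n_noise))
    )
    list(
      table = feature_table(values, subject, label, modality = modality),
      truth = truth
    )
  })
}

# one epoch of band-limited noise: white noise filtered into [lo, hi]
band_noise <- function(n, fs, lo, hi, sd_target) {
  filt <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(filt, stats::rnorm(n + 2 * fs))
  x <- x[(fs + 1):(fs + n)] # discard filter edges
  s <- stats::sd(x)
  if (s > 0) x * sd_target / s else x
}

#' Generate stimulus-locked EEG epochs for one subject-task
#'
#' Each epoch is the sum of band-limited noise in the five traditional bands
#' (alpha and theta power scaled by the class multipliers), a positive
#' Gaussian ERP bump centred near 300 ms whose amplitude decreases with
#' workload class, and white measurement noise. Bit-identical under the
#' config seed.
#'
#' @param config A [synth_config()].
#' @param subject Subject index (1-based).
#' @param class_idx Workload class index (1 = low .. 3 = high).
#' @param white_sd Measurement-noise SD.
#' @param band_scale Global multiplier on the band-limited background
#'   activity (0 yields a noise-free ERP template).
#' @return An [epoched_signal()].
#' @export
gen_eeg_epochs <- function(config = synth_config(), subject = 1L,
                           class_idx = 1L, white_sd = 1, band_scale = 1) {
  cfg <- config
  nt <- round(cfg$fs * cfg$epoch_duration)
  withr::with_seed(stream_seed(cfg, subject, class_idx, salt = 1L), {
    band_sd <- c(delta = 1.5, theta = 1.2, alpha = 1.5, beta = 0.8,
                 gamma = 0.4)
    band_sd["alpha"] <- band_sd["alpha"] * sqrt(cfg$alpha_mult[class_idx])
    band_sd["theta"] <- band_sd["theta"] * sqrt(cfg$theta_mult[class_idx])
    bands <- eeg_bands()[1:5, ]
    tt <- (seq_len(nt) - 1L) / cfg$fs
    bump <- exp(-((tt - 0.3)^2) / (2 * 0.05^2))
    arr <- array(0, dim = c(cfg$n_channels, nt, cfg$epochs_per_task))
    for (ep in seq_len(cfg$epochs_per_task)) {
      for (ch in seq_len(cfg$n_channels)) {
        sig <- numeric(nt)
        if (band_scale > 0) {
          for (b in seq_len(nrow(bands))) {
            sig <- sig + band_noise(nt, cfg$fs, bands$low[b], bands$high[b],
                                    band_scale * band_sd[[b]])
          }
        }
        sig <- sig + cfg$erp_amp[class_idx] * bump
        if (white_sd > 0) sig <- sig + stats::rnorm(nt, 0, white_sd)
        arr[ch, , ep] <- sig
      }
    }
    epoched_signal(arr, fs = cfg$fs)
  })
}

#' Generate an R-R interval series for one subject-task
#'
#' First-order autoregressive Gaussian intervals around a class-dependent
#' mean (higher workload: shorter intervals, less variability), with a
#' small subject-level offset, truncated at a 0.4 s floor; the cumulative
#' beat times cover the task duration.
#'
#' @inheritParams gen_eeg_epochs
#' @param phi AR(1) coefficient.
#' @return An [rr_series()].
#' @export
gen_rr_series <- function(config = synth_config(), subject = 1L,
                          class_idx = 1L, phi = 0.4) {
  cfg <- config
  withr::with_seed(stream_seed(cfg, subject, class_idx, salt = 2L), {
    mu <- cfg$rr_mean[class_idx] + stats::rnorm(1, 0, 0.02)
    sd_rr <- cfg$rr_sdnn[class_idx]
    innov_sd <- sd_rr * sqrt(1 - phi^2)
    n_max <- ceiling(cfg$task_sec / 0.4) + 10L
    rr <- numeric(n_max)
    prev <- mu
    total <- 0
    n <- 0L
    while (total < cfg$task_sec && n < n_max) {
      n <- n + 1L
      val <- mu + phi * (prev - mu) +
        (if (innov_sd > 0) stats::rnorm(1, 0, innov_sd) else 0)
      val <- max(val, 0.4)
      rr[n] <- val
      prev <- val
      total <- total + val
    }
    suppressWarnings(rr_series(rr[seq_len(n)]))
  })
}

#' Run the full signal pipeline for one subject-task
#'
#' Generates EEG epochs and an R-R series, band-pass filters the EEG,
#' extracts the PSD, ERP and HRV blocks per sliding window, and returns the
#' aligned per-window rows as a [feature_table()].
#'
#' @inheritParams gen_eeg_epochs
#' @param window_epochs,step_epochs EEG sliding-window parameters.
#' @param bandpass Apply the 0.5--100 Hz zero-phase band-pass first.
#' @export
extract_subject_task <- function(config = synth_config(), subject = 1L,
                                 class_idx = 1L, window_epochs = 30L,
                                 step_epochs = 1L, bandpass = TRUE) {
  cfg <- config
  eeg <- gen_eeg_epochs(cfg, subject, class_idx)
  if (bandpass) eeg <- eeg_bandpass(eeg)
  rr <- gen_rr_series(cfg, subject, class_idx)
  eeg_feats <- extract_eeg_features(eeg, window_epochs, step_epochs)
  window_sec <- window_epochs * cfg$epoch_duration
  step_sec <- step_epochs * cfg$epoch_duration
  ecg_feats <- extract_rr_features(
    rr, task_sec = cfg$epochs_per_task * cfg$epoch_duration,
    window_sec = window_sec, step_sec = step_sec
  )
  stopifnot(nrow(eeg_feats$psd) == nrow(ecg_feats))
  values <- cbind(as.matrix(eeg_feats$psd), as.matrix(eeg_feats$erp),
                  as.matrix(ecg_feats))
  modality <- c(rep("eeg_psd", ncol(eeg_feats$psd)),
                rep("eeg_erp", ncol(eeg_feats$erp)),
                rep("ecg", ncol(ecg_feats)))
  feature_table(
    values,
    subject_id = rep(sprintf("S%02d", subject), nrow(values)),
    label = rep(workload_levels()[class_idx], nrow(values)),
    modality = modality
  )
}
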