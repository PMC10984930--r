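#' Simulate a tri-axial tremor-like accelerometer signal
#'
#' Each axis is a sinusoid at `tremor_freq` with an axis-specific phase
#' (0, 2\eqn{\pi}/3, 4\eqn{\pi}/3) plus independent Gaussian noise,
#' sampled at `fs` Hz.  The default sampling rate of 62.5 Hz matches
#' wireless wearable accelerometer deployments; a 4-6 Hz tremor frequency
#' is the usual physiological convention for resting tremor, but the
#' frequency is a free parameter here.
#'
#' @param duration signal length in seconds (> 0).
#' @param fs sampling rate in Hz (default 62.5).
#' @param tremor_freq oscillation frequency in Hz; must be below the
#'   Nyquist frequency `fs / 2`.
#' @param amplitude sinusoid amplitude (acceleration units).
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed integer seed (noise only).
#' @return an object of class `"triaxial_signal"`: `fs`, `duration`, `t`
#'   (time stamps) and `axes` (list `x`, `y`, `z`, each of length
#'   `round(fs * duration)`).
#' @export
#' @examples
#' sig <- simulate_tremor_signal(duration = 4, tremor_freq = 5, seed = 1)
#' length(sig$axes$x)  # 250 samples at 62.5 Hz
simulate_tremor_signal <- function(duration, fs = 62.5, tremor_freq = 5,
                                   amplitude = 1, noise_sd = 0.1, seed = 1) {
  if (!is_number(duration) || duration <= 0) stop_config("'duration' must be > 0")
  if (!is_number(fs) || fs <= 0) stop_config("'fs' must be > 0")
  if (!is_number(tremor_freq) || tremor_freq < 0)
    stop_config("'tremor_freq' must be >= 0")
  if (tremor_freq >= fs / 2)
    stop_config("'tremor_freq' (", tremor_freq, " Hz) is at or above the Nyquist frequency ",
                fs / 2, " Hz")
  if (!is_number(amplitude) || !is_number(noise_sd) || noise_sd < 0)
    stop_config("'amplitude' must be finite and 'noise_sd' >= 0")
  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs
  phases <- c(x = 0, y = 2 * pi / 3, z = 4 * pi / 3)
  axes <- with_seed(seed, {
    lapply(phases, function(ph)
      amplitude * sin(2 * pi * tremor_freq * t + ph) + stats::rnorm(n, 0, noise_sd))
  })
  structure(list(fs = fs, duration = duration, t = t, axes = axes),
            class = "triaxial_signal")
}

#' @export
print.triaxial_signal <- function(x, ...) {
  cat(sprintf("Tri-axial signal: %g s at %g Hz (%d samples per axis)\n",
              x$duration, x$fs, length(x$t)))
  invisible(x)
}

#' @export
as.data.frame.triaxial_signal <- function(x, ...) {
  data.frame(t = x$t, x = x$axes$x, y = x$axes$y, z = x$axes$z)
}

#' @export
plot.triaxial_signal <- function(x, ...) {
  graphics::matplot(x$t, cbind(x$axes$x, x$axes$y, x$axes$z), type = "l",
                    lty = 1, xlab = "time (s)", ylab = "acceleration", ...)
  invisible(x)
}

#' Spectral features of a tri-axial signal
#'
#' Applies the FFT (rectangular window, one-sided reading of the two-sided
#' periodogram) to each axis and emits one all-numeric record per signal:
#' per axis, the dominant frequency in Hz (the non-DC bin of maximal
#' power; 0 for an all-zero axis), the total power (the time-domain mean
#' square, by Parseval's identity), and the fraction of power falling in
#' each requested band `[lo, hi)`.  Band fractions per axis sum to at most
#' 1.
#'
#' @param signal a `"triaxial_signal"`.
#' @param bands list of `c(lo, hi)` frequency bands in Hz, non-overlapping
#'   and within `[0, fs / 2]`.
#' @return a one-row data frame of numeric features named
#'   `<axis>_dom_freq`, `<axis>_power`, `<axis>_band_<lo>_<hi>`.
#' @export
#' @examples
#' sig <- simulate_tremor_signal(4, tremor_freq = 5, noise_sd = 0, seed = 1)
#' extract_fft_features(sig)[, c("x_dom_freq", "x_power")]
extract_fft_features <- function(signal,
                                 bands = list(c(0, 4), c(4, 8), c(8, 16))) {
  if (!inherits(signal, "triaxial_signal"))
    stop_contract("'signal' must be a triaxial_signal")
  nyq <- signal$fs / 2
  for (b in bands) {
    if (length(b) != 2L || b[1] < 0 || b[2] > nyq || b[1] >= b[2])
      stop_config("each band must be c(lo, hi) with 0 <= lo < hi <= ", nyq, " Hz")
  }
  if (length(bands) > 1L) {
    o <- order(vapply(bands, `[`, numeric(1), 1L))
    sb <- bands[o]
    for (i in seq_len(length(sb) - 1L)) {
      if (sb[[i]][2] > sb[[i + 1L]][1])
        stop_config("bands must be non-overlapping")
    }
  }
  out <- list()
  for (ax in names(signal$axes)) {
    v <- signal$axes[[ax]]
    n <- length(v)
    # Two-sided per-bin power |X_k|^2 / n^2 sums to mean(v^2) (Parseval).
    P <- Mod(stats::fft(v))^2 / n^2
    k <- seq_len(n) - 1
    f_eff <- pmin(k, n - k) * signal$fs / n
    total <- sum(P)
    dom <- if (total > 0) {
      pos <- which(f_eff > 0)
      f_eff[pos[which.max(P[pos])]]
    } else 0
    out[[paste0(ax, "_dom_freq")]] <- dom
    out[[paste0(ax, "_power")]] <- total
    for (b in bands) {
      sel <- f_eff >= b[1] & f_eff < b[2]
      out[[sprintf("%s_band_%g_%g", ax, b[1], b[2])]] <-
        if (total > 0) sum(P[sel]) / total else 0
    }
  }
  as.data.frame(out)
}

#' Simulate a labeled feature table of tremor and control signals
#'
#' The desk-scale analogue of an accelerometer testbed experiment: two (or
#' more) populations of tri-axial signals whose tremor amplitudes differ,
#' each signal featurized by [extract_fft_features()], stacked into a
#' labeled all-numeric `"hybrid_table"` ready for [anrs()] or [cv_anrs()].
#' Per-signal tremor frequencies are drawn uniformly from `freq_range` and
#' each signal gets its own noise realization; everything is deterministic
#' given `seed`.
#'
#' @param n_per_class signals per class.
#' @param amplitudes named numeric vector, one amplitude per class; the
#'   names are the class labels (default `c(low = 0.2, high = 1)`).
#' @param duration,fs,noise_sd signal parameters, see
#'   [simulate_tremor_signal()].
#' @param freq_range length-2 range (Hz) for per-signal tremor
#'   frequencies; default the physiological 4-6 Hz resting-tremor band.
#' @param bands feature bands, see [extract_fft_features()].
#' @param seed integer seed.
#' @return a labeled `"hybrid_table"` with decision attribute `"class"`.
#' @export
simulate_tremor_dataset <- function(n_per_class, amplitudes = c(low = 0.2, high = 1),
                                    duration = 4, fs = 62.5, noise_sd = 0.1,
                                    freq_range = c(4, 6),
                                    bands = list(c(0, 4), c(4, 8), c(8, 16)),
                                    seed = 1) {
  if (!is_count(n_per_class)) stop_config("'n_per_class' must be a positive integer")
  if (is.null(names(amplitudes)) || length(amplitudes) < 2L)
    stop_config("'amplitudes' must be a named vector with >= 2 classes")
  if (length(freq_range) != 2L || freq_range[1] > freq_range[2])
    stop_config("'freq_range' must be c(lo, hi)")
  n_total <- n_per_class * length(amplitudes)
  draws <- with_seed(seed, list(
    sub_seeds = sample.int(.Machine$integer.max - 1L, n_total),
    freqs = stats::runif(n_total, freq_range[1], freq_range[2])
  ))
  rows <- vector("list", n_total)
  labels <- character(n_total)
  i <- 0L
  for (cl in names(amplitudes)) {
    for (rep in seq_len(n_per_class)) {
      i <- i + 1L
      sig <- simulate_tremor_signal(duration, fs, draws$freqs[i],
                                    amplitude = amplitudes[[cl]],
                                    noise_sd = noise_sd,
                                    seed = draws$sub_seeds[i])
      rows[[i]] <- extract_fft_features(sig, bands)
      labels[i] <- cl
    }
  }
  df <- do.call(rbind, rows)
  df$class <- labels
  as_hybrid_table(df, decision = "class")
}
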