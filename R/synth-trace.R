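#' Voltage trace objects
#'
#' A uniformly sampled single-channel extracellular signal.
#'
#' @param samples numeric vector of amplitudes (microvolts).
#' @param fs_hz sampling rate, Hz.
#' @param band_hz optional length-2 band-pass edges already applied, Hz.
#' @param ground_truth optional list of ground-truth spike trains (`ss`, `cs`)
#'   stored alongside synthetic traces for detection validation.
#' @return a `voltage_trace` object.
#' @export
voltage_trace <- function(samples, fs_hz, band_hz = NULL, ground_truth = NULL) {
  if (fs_hz <= 0) stop_invalid("fs_hz must be positive")
  structure(as.numeric(samples), fs_hz = fs_hz, band_hz = band_hz,
            ground_truth = ground_truth, class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %d samples @ %g kHz (%.2f s)\n",
              length(x), attr(x, "fs_hz") / 1000,
              length(x) / attr(x, "fs_hz")))
  invisible(x)
}

#' Sampling rate of a voltage trace
#' @param x a `voltage_trace`.
#' @return sampling rate in Hz.
#' @export
sampling_rate <- function(x) attr(x, "fs_hz")

#' Parametric extracellular waveform templates
#'
#' Builds unit-amplitude (trough = -1) templates sampled at `fs_hz`. The
#' simple-spike template is a brief biphasic transient (~1.5 ms). The
#' complex-spike template carries the initial somatic spike followed by
#' decaying spikelets (default 3, 1.2 ms apart), so it is longer than the
#' simple template and carries extra energy after the trough -- the feature
#' used to sort the two spike classes.
#'
#' @param kind `"simple"` or `"complex"`.
#' @param fs_hz sampling rate, Hz.
#' @param n_spikelets number of spikelets on the complex template.
#' @param spikelet_amp spikelet trough amplitudes relative to the main trough.
#' @return a `waveform_template`: numeric samples with `fs_hz`, `kind` and
#'   `trough_idx` attributes.
#' @export
waveform_template <- function(kind = c("simple", "complex"), fs_hz = 25000,
                              n_spikelets = 3,
                              spikelet_amp = c(0.40, 0.32, 0.25)) {
  kind <- match.arg(kind)
  ms <- function(x) round(x * fs_hz / 1000)
  biphasic <- function(t0_ms, amp, width_ms, n) {
    t <- (seq_len(n) - 1) / fs_hz * 1000
    -amp * exp(-((t - t0_ms)^2) / (2 * (width_ms * 0.35)^2)) +
      0.35 * amp * exp(-((t - t0_ms - width_ms * 0.9)^2) / (2 * (width_ms * 0.6)^2))
  }
  if (kind == "simple") {
    n <- ms(2.0)
    w <- biphasic(0.5, 1, 0.5, n)
  } else {
    n <- ms(2.0 + 1.2 * n_spikelets + 1.0)
    w <- biphasic(0.5, 1, 0.5, n)
    for (i in seq_len(n_spikelets))
      w <- w + biphasic(0.5 + 1.2 * i, spikelet_amp[i], 0.7, n)
  }
  w <- w / abs(min(w))  # normalise trough to -1
  structure(w, fs_hz = fs_hz, kind = kind, trough_idx = which.min(w),
            class = "waveform_template")
}

#' Band-pass filter an extracellular trace
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass, by default
#' 0.3-13 kHz, the band used for the recordings this package emulates. If the
#' upper edge reaches the Nyquist frequency it is capped at `0.45 * fs` with a
#' message.
#'
#' @param x a [voltage_trace()] or numeric vector.
#' @param band_hz length-2 numeric, filter edges in Hz.
#' @param fs_hz sampling rate (taken from `x` when it is a `voltage_trace`).
#' @return filtered trace of the same class as the input.
#' @export
bandpass_trace <- function(x, band_hz = c(300, 13000),
                           fs_hz = sampling_rate(x)) {
  nyq <- fs_hz / 2
  if (band_hz[2] >= nyq) {
    band_hz[2] <- 0.45 * fs_hz
    message(sprintf("upper band edge capped at %.0f Hz (Nyquist %.0f Hz)",
                    band_hz[2], nyq))
  }
  bf <- signal::butter(2, band_hz / nyq, type = "pass")  # order 4 after filtfilt
  y <- signal::filtfilt(bf, as.numeric(x))
  if (inherits(x, "voltage_trace"))
    voltage_trace(y, fs_hz, band_hz, attr(x, "ground_truth"))
  else y
}

#' Synthesise an extracellular voltage trace for a simulated cell
#'
#' Places spike templates at the cell's ground-truth spike times (trough
#' aligned on the spike time), sums overlaps, adds white Gaussian noise and
#' band-pass filters the result. The ground-truth trains are stored on the
#' returned trace for detection validation.
#'
#' @param cell a cell record from [gen_cohort()], or a list of spike trains
#'   (named `ss`/`cs`/`cn`).
#' @param templates named list of [waveform_template()]s; defaults to the
#'   built-in simple/complex pair at `fs_hz` (the `cn` train uses the simple
#'   template).
#' @param amplitude_uv trough amplitude of the simple spike, microvolts. The
#'   complex-spike trough is drawn 10% larger.
#' @param noise_sd_uv Gaussian noise standard deviation before filtering,
#'   microvolts (the delivered SNR is `amplitude_uv / noise_sd_uv` up to the
#'   mild attenuation of the band-pass).
#' @param fs_hz sampling rate, Hz; must exceed twice the filter upper edge for
#'   the full 0.3-13 kHz band to be representable.
#' @param band_hz band-pass edges applied to the summed trace, Hz.
#' @param seed optional seed for the noise.
#' @return a band-passed [voltage_trace()] with ground truth attached.
#' @export
synth_trace <- function(cell, templates = NULL, amplitude_uv = 100,
                        noise_sd_uv = 12.5, fs_hz = 25000,
                        band_hz = c(300, 13000), seed = NULL) {
  trains <- if (inherits(cell, "cell_record")) cell$trains else cell
  dur <- max(vapply(trains, duration, numeric(1)))
  n <- ceiling(dur * fs_hz)
  v <- numeric(n)
  if (is.null(templates))
    templates <- list(simple = waveform_template("simple", fs_hz),
                      complex = waveform_template("complex", fs_hz))
  place <- function(times, tmpl, amp) {
    ti <- attr(tmpl, "trough_idx")
    for (t in as.numeric(times)) {
      i0 <- round(t * fs_hz) - ti + 1L
      ix <- i0:(i0 + length(tmpl) - 1L)
      keep <- ix >= 1L & ix <= n
      v[ix[keep]] <<- v[ix[keep]] + amp * as.numeric(tmpl)[keep]
    }
  }
  for (nm in names(trains)) {
    if (nm == "cs") place(trains[[nm]], templates$complex, amplitude_uv * 1.1)
    else place(trains[[nm]], templates$simple, amplitude_uv)
  }
  if (noise_sd_uv > 0)
    v <- v + with_seed(seed, rnorm(n, 0, noise_sd_uv))
  out <- voltage_trace(v, fs_hz, ground_truth = trains)
  if (noise_sd_uv > 0 || any(v != 0)) out <- bandpass_trace(out, band_hz)
  out
}
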