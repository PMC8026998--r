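#' Firing-rate model for simulated retinal ganglion cell activity
#'
#' Holds the generative firing rates used by the count-tier and trace-tier
#' spike simulators: a spontaneous (dark) rate plus per-intensity rates during
#' the light-ON and light-OFF analysis windows. Rates may be given as a single
#' number (recycled over intensities) or as a vector matching the protocol's
#' intensity list, in ascending intensity order.
#'
#' @param spont_rate spontaneous firing rate, events/s.
#' @param on_rates firing rate during the flash, events/s; scalar or one value
#'   per protocol intensity.
#' @param off_rates firing rate in the window after light offset; defaults to
#'   the spontaneous rate (no OFF response).
#' @param latency response latency in seconds (reserved; windows are aligned
#'   to flash boundaries by default).
#' @return object of class `rate_model`.
#' @examples
#' rate_model(spont_rate = 5, on_rates = 50)
#' @export
rate_model <- function(spont_rate, on_rates, off_rates = NULL, latency = 0) {
  if (is.null(off_rates)) off_rates <- spont_rate
  rates <- c(spont_rate, on_rates, off_rates, latency)
  if (anyNA(rates) || any(!is.finite(rates)) || any(rates < 0)) {
    stop("all rates and the latency must be finite and >= 0", call. = FALSE)
  }
  structure(list(spont_rate = spont_rate, on_rates = on_rates,
                 off_rates = off_rates, latency = latency),
            class = "rate_model")
}

# Expand a rate model against a protocol's intensity list, validating shapes.
resolve_rates <- function(model, intensities) {
  stretch <- function(r, what) {
    if (length(r) == 1L) r <- rep(r, length(intensities))
    if (length(r) != length(intensities)) {
      stop(sprintf("'%s' must have length 1 or match the %d protocol intensities",
                   what, length(intensities)), call. = FALSE)
    }
    names(r) <- as.character(intensities)
    r
  }
  list(spont = model$spont_rate,
       on = stretch(model$on_rates, "on_rates"),
       off = stretch(model$off_rates, "off_rates"))
}

#' Saturating intensity-to-rate mapping (Naka-Rushton)
#'
#' Optional helper producing a physiologically shaped ON-rate vector from a
#' protocol's intensities: `r(I) = r_max * I^n / (I^n + I50^n) + base`.
#' The spike generators take explicit per-intensity rates; this is a
#' convenience for building them.
#'
#' @param intensities stimulus intensities (photons/cm2/s).
#' @param r_max maximal evoked rate, events/s.
#' @param i50 semi-saturation intensity.
#' @param n Hill exponent.
#' @param base rate added at all intensities (events/s).
#' @return numeric vector of rates, one per intensity.
#' @export
naka_rushton_rates <- function(intensities, r_max, i50, n = 1, base = 0) {
  stop_if_not_scalar_pos(i50, "i50")
  base + r_max * intensities^n / (intensities^n + i50^n)
}

#' Simulate windowed trial spike counts (count tier)
#'
#' Fast-tier generator: for every channel, intensity and repetition draws
#' independent Poisson spike counts for the ON, OFF and spontaneous analysis
#' windows, each of the protocol's flash duration (0.35 s by default), with
#' mean `rate * window`. Poisson is the physiological null for spike counts;
#' no extra dispersion is added. Channels use independent substreams of
#' `seed`, so any channel subset is reproducible.
#'
#' @param protocol a [make_protocol()] stimulus protocol.
#' @param model a [rate_model()].
#' @param n_channels number of electrodes to simulate.
#' @param seed integer seed.
#' @return A data frame of class `trial_counts` with columns `channel`,
#'   `intensity`, `rep_index`, `count_on`, `count_off`, `count_spont` and
#'   attribute `window_len` (seconds).
#' @examples
#' tc <- simulate_trial_counts(make_protocol(), rate_model(5, 50),
#'                             n_channels = 4, seed = 1)
#' mean(tc$count_on) / attr(tc, "window_len")  # ~ 50 events/s
#' @export
simulate_trial_counts <- function(protocol, model, n_channels, seed) {
  stopifnot(inherits(protocol, "stim_protocol"), inherits(model, "rate_model"))
  if (n_channels < 1) stop("'n_channels' must be >= 1", call. = FALSE)
  window <- attr(protocol, "flash_dur")
  intensities <- attr(protocol, "intensities")
  reps <- max(protocol$rep_index)
  r <- resolve_rates(model, intensities)
  n_cell <- length(intensities) * reps
  per_channel <- function(ch) {
    with_seed(sub_seed(seed, ch), {
      lam_on <- rep(r$on, times = reps) * window
      lam_off <- rep(r$off, times = reps) * window
      data.frame(
        channel = ch,
        intensity = rep(intensities, times = reps),
        rep_index = rep(seq_len(reps), each = length(intensities)),
        count_on = stats::rpois(n_cell, lam_on),
        count_off = stats::rpois(n_cell, lam_off),
        count_spont = stats::rpois(n_cell, r$spont * window)
      )
    })
  }
  out <- do.call(rbind, lapply(seq_len(n_channels), per_channel))
  structure(out, window_len = window, class = c("trial_counts", "data.frame"))
}

#' Biphasic extracellular spike template
#'
#' A one-cycle biphasic waveform whose peak amplitude is expressed in units
#' of the trace noise standard deviation. The template must be shorter than
#' the detector's refractory pause so that consecutive ground-truth spikes
#' remain separable.
#'
#' @param amplitude_sd peak amplitude as a multiple of the noise SD.
#' @param duration_s template duration in seconds (default 1 ms).
#' @return object of class `spike_template`.
#' @export
spike_template <- function(amplitude_sd = 8, duration_s = 0.001) {
  stop_if_not_scalar_pos(amplitude_sd, "amplitude_sd")
  stop_if_not_scalar_pos(duration_s, "duration_s")
  structure(list(amplitude_sd = amplitude_sd, duration_s = duration_s),
            class = "spike_template")
}

# Render the template at a given sampling rate and noise scale.
render_template <- function(template, sampling_rate, noise_sd) {
  n <- max(4L, round(template$duration_s * sampling_rate))
  w <- sin(2 * pi * seq(0, n - 1) / n)
  w / max(abs(w)) * template$amplitude_sd * noise_sd
}

#' Simulate a raw multi-channel voltage trace (trace tier)
#'
#' Full-fidelity generator used to exercise filtering and spike detection:
#' inhomogeneous-Poisson spike times (piecewise-constant rate switching at
#' flash boundaries, minimum inter-spike interval equal to the template
#' duration) are convolved with a biphasic template and embedded in white
#' Gaussian noise. Ground-truth spike times are returned alongside.
#'
#' @param protocol a [make_protocol()] protocol.
#' @param model a [rate_model()].
#' @param template a [spike_template()].
#' @param noise_sd noise standard deviation in volts; must be > 0.
#' @param sampling_rate samples per second (default 25 kHz).
#' @param duration recording length in seconds; defaults to covering the
#'   whole protocol plus one dark gap.
#' @param n_channels number of electrodes.
#' @param seed integer seed; channels use independent substreams.
#' @return list with elements `recording` (a [raw_recording()]) and `truth`
#'   (data frame `channel`, `t_s` of ground-truth spike times).
#' @export
simulate_trace <- function(protocol, model, template = spike_template(),
                           noise_sd, sampling_rate = 25000, duration = NULL,
                           n_channels = 1, seed = 1) {
  stopifnot(inherits(protocol, "stim_protocol"), inherits(model, "rate_model"),
            inherits(template, "spike_template"))
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop("'noise_sd' must be > 0 (use a tiny value for near-noiseless traces)",
         call. = FALSE)
  }
  stop_if_not_scalar_pos(sampling_rate, "sampling_rate")
  flash <- attr(protocol, "flash_dur")
  last_end <- max(protocol$onset_s) + 2 * flash
  if (is.null(duration)) duration <- last_end + attr(protocol, "dark_gap")
  if (duration < last_end) {
    warning("recording duration truncates the protocol; trailing epochs are cut")
  }
  intensities <- attr(protocol, "intensities")
  r <- resolve_rates(model, intensities)

  # Piecewise-constant rate: spontaneous everywhere, ON during each flash,
  # OFF rate in the window after light shut-off. Partition [0, duration).
  cuts <- sort(unique(c(0, protocol$onset_s, protocol$onset_s + flash,
                        protocol$onset_s + 2 * flash, duration)))
  cuts <- cuts[cuts <= duration]
  if (max(cuts) < duration) cuts <- c(cuts, duration)
  seg_a <- utils::head(cuts, -1)
  seg_b <- utils::tail(cuts, -1)
  seg_rate <- rep(r$spont, length(seg_a))
  for (i in seq_len(nrow(protocol))) {
    on_a <- protocol$onset_s[i]
    key <- as.character(protocol$intensity[i])
    seg_rate[seg_a >= on_a & seg_b <= on_a + flash] <- r$on[[key]]
    seg_rate[seg_a >= on_a + flash & seg_b <= on_a + 2 * flash] <- r$off[[key]]
  }

  min_isi <- template$duration_s
  n_samp <- round(duration * sampling_rate)
  truth <- vector("list", n_channels)
  volt <- matrix(0, nrow = n_channels, ncol = n_samp)
  wave <- render_template(template, sampling_rate, noise_sd)
  nw <- length(wave)

  for (ch in seq_len(n_channels)) {
    with_seed(sub_seed(seed, ch), {
      times <- unlist(lapply(seq_along(seg_a), function(k) {
        len <- seg_b[k] - seg_a[k]
        n_k <- stats::rpois(1, seg_rate[k] * len)
        if (n_k == 0) return(numeric(0))
        seg_a[k] + sort(stats::runif(n_k, 0, len))
      }))
      times <- sort(times)
      # enforce minimum inter-spike interval (refractory = template length)
      if (length(times) > 1) {
        keep <- logical(length(times))
        last <- -Inf
        for (j in seq_along(times)) {
          if (times[j] - last >= min_isi) {
            keep[j] <- TRUE
            last <- times[j]
          }
        }
        times <- times[keep]
      }
      times <- times[times < duration - template$duration_s]
      x <- stats::rnorm(n_samp, 0, noise_sd)
      if (length(times)) {
        i0 <- floor(times * sampling_rate) + 1L
        for (j in seq_along(i0)) {
          sl <- i0[j]:(i0[j] + nw - 1L)
          x[sl] <- x[sl] + wave
        }
      }
      volt[ch, ] <- x
      truth[[ch]] <- data.frame(channel = rep(ch, length(times)), t_s = times)
    })
  }
  list(recording = raw_recording(volt, sampling_rate),
       truth = do.call(rbind, truth))
}
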