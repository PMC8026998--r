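#' Spike-detection specification
#'
#' Threshold-crossing detection at `k` times the standard deviation of the
#' filtered signal, with a refractory pause (`dead_time`) after each event
#' during which further crossings are suppressed. Defaults follow the
#' standard MEA analysis: k = 5, pause 1.5 ms.
#'
#' @param k threshold multiplier (> 0).
#' @param dead_time refractory pause in seconds (>= 0).
#' @param polarity `"absolute"` (either-sign crossings, default),
#'   `"negative"` or `"positive"`.
#' @param sd_scope `"global"` (plain SD of the whole filtered channel,
#'   default) or `"robust"` (median-absolute-deviation-based SD, resistant
#'   to the spikes themselves inflating the threshold).
#' @return object of class `detection_spec`.
#' @export
detection_spec <- function(k = 5, dead_time = 0.0015,
                           polarity = c("absolute", "negative", "positive"),
                           sd_scope = c("global", "robust")) {
  polarity <- match.arg(polarity)
  sd_scope <- match.arg(sd_scope)
  if (k <= 0) stop("'k' must be > 0", call. = FALSE)
  if (dead_time < 0) stop("'dead_time' must be >= 0", call. = FALSE)
  structure(list(k = k, dead_time = dead_time, polarity = polarity,
                 sd_scope = sd_scope),
            class = "detection_spec")
}

#' Detect spikes by threshold crossing
#'
#' Per channel, the threshold is `k` times that channel's SD (plain or
#' MAD-based). An event is logged whenever the signal crosses the threshold
#' in the configured polarity coming from below; after an event, crossings
#' within the refractory pause are suppressed. The recording is expected to
#' be band-pass filtered already — this function does not filter.
#'
#' Channels with zero variance cannot define a threshold; they are flagged
#' (attribute `flagged_channels`) and emit no spikes.
#'
#' @param rec a filtered [raw_recording()].
#' @param spec a [detection_spec()].
#' @return object of class `spike_train`: a named list (one numeric vector of
#'   strictly increasing spike times in seconds per channel), with attributes
#'   `sampling_rate`, `duration`, `dead_time`, `flagged_channels`.
#' @export
detect_spikes <- function(rec, spec = detection_spec()) {
  stopifnot(inherits(rec, "raw_recording"), inherits(spec, "detection_spec"))
  fs <- rec$sampling_rate
  dt_samp <- spec$dead_time * fs
  flagged <- character(0)
  trains <- vector("list", nrow(rec$voltage))
  names(trains) <- rec$channel_ids
  for (ch in seq_len(nrow(rec$voltage))) {
    x <- rec$voltage[ch, ]
    sdv <- if (spec$sd_scope == "robust") stats::mad(x) else stats::sd(x)
    if (!is.finite(sdv) || sdv == 0) {
      flagged <- c(flagged, rec$channel_ids[ch])
      trains[[ch]] <- numeric(0)
      next
    }
    thr <- spec$k * sdv
    sig <- switch(spec$polarity,
                  absolute = abs(x),
                  negative = -x,
                  positive = x)
    above <- sig >= thr
    # crossings from below (first sample counts if it starts above)
    idx <- which(above & !c(FALSE, above[-length(above)]))
    if (length(idx) > 1L && dt_samp > 0) {
      keep <- logical(length(idx))
      last <- -Inf
      for (j in seq_along(idx)) {
        if (idx[j] - last > dt_samp) {
          keep[j] <- TRUE
          last <- idx[j]
        }
      }
      idx <- idx[keep]
    }
    trains[[ch]] <- (idx - 1L) / fs
  }
  structure(trains,
            sampling_rate = fs,
            duration = ncol(rec$voltage) / fs,
            dead_time = spec$dead_time,
            flagged_channels = flagged,
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  n <- vapply(x, length, integer(1))
  cat(sprintf("Spike trains: %d channels, %d spikes over %.2f s (%.2f /s/channel)\n",
              length(x), sum(n), attr(x, "duration"),
              mean(n) / attr(x, "duration")))
  if (length(attr(x, "flagged_channels"))) {
    cat("Flagged (zero-variance) channels:",
        paste(attr(x, "flagged_channels"), collapse = ", "), "\n")
  }
  invisible(x)
}
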