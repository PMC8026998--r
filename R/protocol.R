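#' Build a flash stimulus protocol
#'
#' Constructs the chronologically ordered sequence of light-flash epochs used
#' throughout the MEA pipeline: `reps` sweeps, each presenting every intensity
#' in ascending order, flashes separated by a dark interval. The defaults are
#' the standard explant protocol: 20 repetitions of 350 ms flashes at six
#' increasing intensities separated by 2 s of dark.
#'
#' The five highest intensities form the photopic subset (cone-driven range)
#' used by the 3-of-5 channel-inclusion rule; with the default intensity list
#' the dimmest flash (8.6e12 photons/cm2/s) is scotopic and excluded.
#'
#' @param intensities strictly increasing light intensities
#'   (photons/cm2/s). Default: the six-step explant series.
#' @param reps number of repetitions of the full intensity sweep.
#' @param flash_dur flash (light-ON) duration in seconds; the OFF and
#'   spontaneous analysis windows have the same length.
#' @param dark_gap dark interval between flashes in seconds. Must be at least
#'   `2 * flash_dur` so the OFF window of one flash cannot overlap the
#'   spontaneous window of the next.
#' @return A data frame of class `stim_protocol` with columns `onset_s`,
#'   `duration_s`, `intensity`, `rep_index`, one row per flash epoch, ordered
#'   by onset. Attributes: `intensities`, `flash_dur`, `dark_gap`.
#' @examples
#' pr <- make_protocol()
#' nrow(pr)                  # 120 epochs = 6 intensities x 20 reps
#' photopic_intensities(pr)  # top five intensities
#' @export
make_protocol <- function(intensities = c(8.6e12, 5.3e13, 3e14, 8.7e14, 1.6e15, 2.3e15),
                          reps = 20, flash_dur = 0.35, dark_gap = 2) {
  if (length(intensities) < 1L || anyNA(intensities)) {
    stop("'intensities' must be a nonempty numeric vector", call. = FALSE)
  }
  if (length(intensities) > 1L && any(diff(intensities) <= 0)) {
    stop("'intensities' must be strictly increasing", call. = FALSE)
  }
  stop_if_not_scalar_pos(flash_dur, "flash_dur")
  stop_if_not_scalar_pos(dark_gap, "dark_gap")
  stop_if_not_scalar_pos(reps, "reps")
  if (dark_gap < 2 * flash_dur) {
    stop("'dark_gap' must be >= 2 * flash_dur so analysis windows cannot overlap",
         call. = FALSE)
  }
  n_i <- length(intensities)
  idx <- seq_len(n_i * reps) - 1L           # epoch counter, rep-major
  onset <- dark_gap + idx * (flash_dur + dark_gap)
  pr <- data.frame(
    onset_s = onset,
    duration_s = flash_dur,
    intensity = rep(intensities, times = reps),
    rep_index = rep(seq_len(reps), each = n_i)
  )
  structure(pr,
            intensities = intensities,
            flash_dur = flash_dur,
            dark_gap = dark_gap,
            class = c("stim_protocol", "data.frame"))
}

#' Photopic intensity subset of a protocol
#'
#' Returns the (up to) five highest intensities of a protocol — the photopic,
#' cone-driven range over which the 3-of-5 inclusion rule is evaluated.
#'
#' @param protocol a `stim_protocol`.
#' @return numeric vector of intensities, ascending.
#' @export
photopic_intensities <- function(protocol) {
  ints <- attr(protocol, "intensities")
  if (is.null(ints)) ints <- sort(unique(protocol$intensity))
  utils::tail(ints, 5L)
}

#' @export
print.stim_protocol <- function(x, ...) {
  ints <- attr(x, "intensities")
  cat(sprintf("Flash protocol: %d epochs (%d intensities x %d reps), %.3g s flashes, %.3g s dark\n",
              nrow(x), length(ints), max(x$rep_index), attr(x, "flash_dur"),
              attr(x, "dark_gap")))
  cat("Intensities (photons/cm2/s):", format(ints, digits = 3), "\n")
  invisible(x)
}
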