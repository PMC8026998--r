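#' Count spikes in stimulus-aligned windows
#'
#' For every channel and flash epoch, counts spikes in three half-open
#' windows of the flash duration each: light-ON `[onset, onset + d)`,
#' light-OFF `[onset + d, onset + 2d)` (the window after light shut-off) and
#' spontaneous `[onset - d, onset)` (immediately before light onset). With
#' the default 2 s dark gap these windows never overlap; overlapping or
#' out-of-range epochs raise an error naming the offending epochs.
#'
#' @param spikes a [detect_spikes()] spike train.
#' @param protocol the [make_protocol()] protocol used during the recording.
#' @return a `trial_counts` data frame (same layout as
#'   [simulate_trial_counts()]), channels identified by name.
#' @export
window_counts <- function(spikes, protocol) {
  stopifnot(inherits(spikes, "spike_train"), inherits(protocol, "stim_protocol"))
  d <- attr(protocol, "flash_dur")
  onset <- protocol$onset_s
  bad <- which(onset - d < 0)
  if (nrow(protocol) > 1L) {
    gap_ok <- onset[-1L] - d >= onset[-nrow(protocol)] + 2 * d
    bad <- c(bad, which(!gap_ok) + 1L)
  }
  dur <- attr(spikes, "duration")
  if (!is.null(dur)) bad <- c(bad, which(onset + 2 * d > dur))
  if (length(bad)) {
    stop("analysis windows overlap or leave the recording for epoch(s): ",
         paste(sort(unique(bad)), collapse = ", "), call. = FALSE)
  }
  count_in <- function(t, a, b) {
    # number of spikes in [a, b); t sorted ascending
    findInterval(b - 1e-12, t) - findInterval(a - 1e-12, t)
  }
  per_channel <- function(ch) {
    t <- sort(spikes[[ch]])
    data.frame(
      channel = names(spikes)[ch] %||% ch,
      intensity = protocol$intensity,
      rep_index = protocol$rep_index,
      count_on = count_in(t, onset, onset + d),
      count_off = count_in(t, onset + d, onset + 2 * d),
      count_spont = count_in(t, onset - d, onset)
    )
  }
  out <- do.call(rbind, lapply(seq_along(spikes), per_channel))
  structure(out, window_len = d,
            intensities = attr(protocol, "intensities"),
            class = c("trial_counts", "data.frame"))
}
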