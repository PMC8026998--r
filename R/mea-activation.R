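#' Classify light-activated electrodes with paired t tests
#'
#' For every (channel, intensity) pair, a two-tailed paired Student's t test
#' compares the per-repetition ON (and OFF) spike counts against the matched
#' spontaneous counts (df = reps - 1). A channel/intensity is ON-activated
#' when `p < 0.01` and the signed t statistic exceeds 2 — so only firing-rate
#' increases qualify, never suppression; OFF activation is analogous on the
#' OFF - spontaneous differences.
#'
#' Degenerate cases: when all repetition differences are identical, the t
#' statistic is reported as signed infinity (p = 0) when the common
#' difference is nonzero — a perfectly consistent increase is the strongest
#' possible response — and as t = 0 (p = 1) when the differences are all 0.
#'
#' @param counts a `trial_counts` table ([simulate_trial_counts()] or
#'   [window_counts()]).
#' @param p_crit significance level (default 0.01).
#' @param t_crit t-statistic cutoff (default 2).
#' @return data frame of class `activation_result`: `channel`, `intensity`,
#'   `t_on`, `p_on`, `on_activated`, `t_off`, `p_off`, `off_activated`.
#' @export
test_activation <- function(counts, p_crit = 0.01, t_crit = 2) {
  stopifnot(inherits(counts, "trial_counts"))
  key <- factor(paste(counts$channel, counts$intensity, sep = "\r"),
                levels = unique(paste(counts$channel, counts$intensity,
                                      sep = "\r")))
  n <- as.vector(table(key)[levels(key)])
  if (any(n < 2)) stop("need >= 2 repetitions per (channel, intensity)",
                       call. = FALSE)
  paired_t <- function(d) {
    s <- rowsum(d, key)[levels(key), 1L]
    s2 <- rowsum(d^2, key)[levels(key), 1L]
    m <- s / n
    vard <- pmax(0, (s2 - n * m^2) / (n - 1))
    tt <- ifelse(vard > 0, m / sqrt(vard / n),
                 ifelse(m == 0, 0, sign(m) * Inf))
    p <- ifelse(vard > 0, 2 * stats::pt(-abs(tt), df = n - 1),
                ifelse(m == 0, 1, 0))
    list(t = tt, p = p)
  }
  on <- paired_t(cbind(counts$count_on - counts$count_spont))
  off <- paired_t(cbind(counts$count_off - counts$count_spont))
  first <- !duplicated(key)
  out <- data.frame(
    channel = counts$channel[first],
    intensity = counts$intensity[first],
    t_on = on$t, p_on = on$p,
    on_activated = on$p < p_crit & on$t > t_crit,
    t_off = off$t, p_off = off$p,
    off_activated = off$p < p_crit & off$t > t_crit
  )
  structure(out, p_crit = p_crit, t_crit = t_crit,
            intensities = attr(counts, "intensities"),
            window_len = attr(counts, "window_len"),
            class = c("activation_result", "data.frame"))
}

#' Select channels by the 3-of-5 photopic activation rule
#'
#' A channel enters the response-ratio analysis only if it is ON-activated at
#' a minimum number of photopic intensities — at least 3 of the 5 highest
#' intensities under the standard protocol. This eliminates unstable
#' recordings. If the protocol carries fewer than 5 photopic intensities the
#' threshold rescales to `ceiling(3/5 * n_photopic)` with a warning.
#'
#' @param activation a [test_activation()] result.
#' @param protocol the stimulus protocol (supplies the photopic subset).
#' @return data frame of class `channel_selection`: `channel`,
#'   `n_photopic_activated`, `included`; attribute `threshold`.
#' @export
select_channels <- function(activation, protocol) {
  stopifnot(inherits(activation, "activation_result"),
            inherits(protocol, "stim_protocol"))
  phot <- photopic_intensities(protocol)
  if (!all(phot %in% activation$intensity)) {
    stop("activation table does not cover all photopic intensities",
         call. = FALSE)
  }
  n_phot <- length(phot)
  threshold <- 3L
  if (n_phot < 5L) {
    threshold <- as.integer(ceiling(3 / 5 * n_phot))
    warning(sprintf(
      "protocol has only %d photopic intensities; inclusion threshold rescaled to %d",
      n_phot, threshold))
  }
  sub <- activation[activation$intensity %in% phot, ]
  ch <- unique(activation$channel)
  n_act <- vapply(split(sub$on_activated, factor(sub$channel, levels = ch)),
                  sum, integer(1))
  out <- data.frame(channel = ch, n_photopic_activated = as.integer(n_act),
                    included = n_act >= threshold, row.names = NULL)
  structure(out, threshold = threshold, photopic = phot,
            class = c("channel_selection", "data.frame"))
}
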