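#' Light-induced response ratio
#'
#' For every included channel and intensity, firing rates are the mean spike
#' count over repetitions divided by the window length, and the response
#' ratio is the Michelson-contrast-style index
#'
#'   `ratio = (rate_ON - rate_spont) / (rate_ON + rate_spont)`
#'
#' bounded in \[-1, 1\], quantifying how much light onset changes firing
#' without over-weighting electrodes with low spontaneous activity. When both
#' rates are 0 the ratio is undefined (`NA`): a silent channel carries no
#' light information and is dropped from summaries.
#'
#' @param counts a `trial_counts` table.
#' @param selection a [select_channels()] result computed on the same
#'   channels; only included channels are retained. Omit to keep all.
#' @return data frame of class `response_ratio`: `channel`, `intensity`,
#'   `rate_on`, `rate_spont`, `ratio`.
#' @examples
#' # rate_on 50/s vs spont 5/s gives 45/55 = 0.8182
#' @export
response_ratio <- function(counts, selection = NULL) {
  stopifnot(inherits(counts, "trial_counts"))
  window <- attr(counts, "window_len")
  if (!is.null(selection)) {
    stopifnot(inherits(selection, "channel_selection"))
    keep <- selection$channel[selection$included]
    counts <- counts[counts$channel %in% keep, , drop = FALSE]
    if (nrow(counts) == 0) {
      out <- data.frame(channel = character(0), intensity = numeric(0),
                        rate_on = numeric(0), rate_spont = numeric(0),
                        ratio = numeric(0))
      return(structure(out, window_len = window,
                       class = c("response_ratio", "data.frame")))
    }
  }
  key <- factor(paste(counts$channel, counts$intensity, sep = "\r"),
                levels = unique(paste(counts$channel, counts$intensity,
                                      sep = "\r")))
  n <- as.vector(table(key)[levels(key)])
  rate_on <- rowsum(counts$count_on, key)[levels(key), 1L] / n / window
  rate_sp <- rowsum(counts$count_spont, key)[levels(key), 1L] / n / window
  denom <- rate_on + rate_sp
  first <- !duplicated(key)
  out <- data.frame(
    channel = counts$channel[first],
    intensity = counts$intensity[first],
    rate_on = rate_on,
    rate_spont = rate_sp,
    ratio = ifelse(denom > 0, (rate_on - rate_sp) / denom, NA_real_),
    row.names = NULL
  )
  structure(out, window_len = window,
            class = c("response_ratio", "data.frame"))
}

#' Compare response ratios between groups
#'
#' Per intensity, a two-sided Wilcoxon rank-sum (Mann-Whitney) test compares
#' the per-channel response ratios of two groups (e.g. control vs treated
#' retinas, electrodes pooled across retinas). Exact when both groups are
#' small, tie-corrected normal approximation otherwise (see
#' [rank_sum_test()]). Undefined ratios are dropped; an intensity with an
#' empty group raises an error naming it.
#'
#' @param control,treated [response_ratio()] results for the two groups.
#' @return data frame of class `group_comparison`: `intensity`, `statistic`
#'   (Mann-Whitney U), `p_value`, `n_control`, `n_treated`,
#'   `median_control`, `median_treated`.
#' @export
compare_groups <- function(control, treated) {
  stopifnot(inherits(control, "response_ratio"),
            inherits(treated, "response_ratio"))
  ints <- sort(unique(c(control$intensity, treated$intensity)))
  rows <- lapply(ints, function(i) {
    x <- control$ratio[control$intensity == i]
    y <- treated$ratio[treated$intensity == i]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) == 0 || length(y) == 0) {
      stop(sprintf("no included channels in one group at intensity %g", i),
           call. = FALSE)
    }
    ts <- rank_sum_test(x, y)
    data.frame(intensity = i, statistic = ts$statistic, p_value = ts$p.value,
               n_control = length(x), n_treated = length(y),
               median_control = stats::median(x),
               median_treated = stats::median(y))
  })
  structure(do.call(rbind, rows),
            class = c("group_comparison", "data.frame"))
}
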