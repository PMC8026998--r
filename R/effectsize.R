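#' Hedges' g standardized mean difference
#'
#' Small-sample-corrected standardized difference between two groups:
#' `g = J * (mean(b) - mean(a)) / s_pooled` with
#' `s_pooled^2 = ((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2)` and the
#' correction `J = 1 - 3 / (4 (n_a + n_b - 2) - 1)`.
#'
#' When the pooled SD is 0, g is 0 for equal means and signed infinity (with
#' a warning) for unequal means.
#'
#' @param group_a,group_b numeric vectors, each with >= 2 values.
#' @return Hedges' g (numeric scalar); positive when `group_b` exceeds
#'   `group_a`.
#' @examples
#' hedges_g(c(1, 2, 3), c(3, 4, 5))  # J = 0.8, g = 1.6
#' @export
hedges_g <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  stopifnot(na >= 2, nb >= 2)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) / df
  J <- 1 - 3 / (4 * df - 1)
  md <- mean(group_b) - mean(group_a)
  if (sp2 == 0) {
    if (md == 0) return(0)
    warning("zero pooled variance with unequal means: g is infinite")
    return(sign(md) * Inf)
  }
  J * md / sqrt(sp2)
}

# g from running sums — used by the vectorized bootstrap and jackknife.
g_from_sums <- function(sa, sa2, na, sb, sb2, nb) {
  va <- (sa2 - sa^2 / na) / (na - 1)
  vb <- (sb2 - sb^2 / nb) / (nb - 1)
  df <- na + nb - 2
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  J <- 1 - 3 / (4 * df - 1)
  md <- sb / nb - sa / na
  ifelse(sp2 > 0, J * md / sqrt(sp2), ifelse(md == 0, 0, sign(md) * Inf))
}

# BCa bootstrap CI for Hedges' g of (a -> b). Falls back to the percentile
# interval when the bias correction or acceleration is degenerate.
boot_ci_g <- function(a, b, n_boot, conf = 0.95) {
  na <- length(a); nb <- length(b)
  g_hat <- hedges_g(a, b)
  ia <- matrix(sample.int(na, na * n_boot, replace = TRUE), nrow = na)
  ib <- matrix(sample.int(nb, nb * n_boot, replace = TRUE), nrow = nb)
  am <- matrix(a[ia], nrow = na); bm <- matrix(b[ib], nrow = nb)
  gb <- g_from_sums(colSums(am), colSums(am^2), na,
                    colSums(bm), colSums(bm^2), nb)
  gb <- gb[is.finite(gb)]
  alpha <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  perc <- unname(stats::quantile(gb, alpha, names = FALSE))
  # jackknife over the combined observations for the acceleration
  sa <- sum(a); sa2 <- sum(a^2); sb <- sum(b); sb2 <- sum(b^2)
  g_jack <- c(
    g_from_sums(sa - a, sa2 - a^2, na - 1, sb, sb2, nb),
    g_from_sums(sa, sa2, na, sb - b, sb2 - b^2, nb - 1)
  )
  prop_less <- mean(gb < g_hat)
  if (!all(is.finite(g_jack)) || prop_less == 0 || prop_less == 1) {
    return(list(ci = perc, method = "percentile", boot = gb))
  }
  z0 <- stats::qnorm(prop_less)
  dj <- mean(g_jack) - g_jack
  denom <- sum(dj^2)^1.5
  if (denom == 0) {
    return(list(ci = perc, method = "percentile", boot = gb))
  }
  acc <- sum(dj^3) / (6 * denom)
  zal <- stats::qnorm(alpha)
  adj <- stats::pnorm(z0 + (z0 + zal) / (1 - acc * (z0 + zal)))
  ci <- unname(stats::quantile(gb, adj, names = FALSE))
  list(ci = ci, method = "BCa", boot = gb)
}

# Two-sided permutation p for the unpaired equal-variance t statistic,
# with +1 smoothing: (b + 1) / (n_perm + 1).
perm_t_p <- function(a, b, n_perm) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  t_stat <- function(ia) {
    x <- pooled[ia]; y <- pooled[-ia]
    sp2 <- ((na - 1) * stats::var(x) + (nb - 1) * stats::var(y)) / (na + nb - 2)
    if (sp2 == 0) return(0)
    (mean(y) - mean(x)) / sqrt(sp2 * (1 / na + 1 / nb))
  }
  t_obs <- t_stat(seq_len(na))
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    tp <- t_stat(sample.int(na + nb, na))
    if (abs(tp) >= abs(t_obs) - 1e-12) exceed <- exceed + 1L
  }
  (exceed + 1) / (n_perm + 1)
}

#' Shared-control effect-size estimation
#'
#' Estimation-statistics analysis in which several test groups are each
#' compared against one shared control: per group, Hedges' g with a
#' bootstrap confidence interval (default 5000 resamples, BCa with a
#' percentile fallback) and a two-sided unpaired permutation t test p value
#' with +1 smoothing. This is the shared-control Cummings-plot analysis used
#' for log2 cone-survival ratios, where the earliest post-treatment age
#' serves as the shared control.
#'
#' Each test group runs on its own seed substream, so results for a group do
#' not depend on which other groups are present.
#'
#' @param shared_control numeric vector (>= 2 values).
#' @param test_groups named list of numeric vectors (>= 2 values each).
#' @param n_boot bootstrap resamples (default 5000).
#' @param n_perm label permutations (default 5000).
#' @param conf confidence level of the bootstrap interval.
#' @param seed integer seed.
#' @return data frame of class `effect_size_result`, one row per test group:
#'   `comparison`, `n_control`, `n_test`, `hedges_g`, `ci_low`, `ci_high`,
#'   `ci_method`, `p_perm`, `n_boot`, `n_perm`.
#' @examples
#' res <- shared_control_estimation(rnorm(10), list(shift = rnorm(10) + 2),
#'                                  n_boot = 200, n_perm = 99, seed = 1)
#' @export
shared_control_estimation <- function(shared_control, test_groups,
                                      n_boot = 5000, n_perm = 5000,
                                      conf = 0.95, seed = 1) {
  stopifnot(length(shared_control) >= 2, is.list(test_groups),
            length(test_groups) >= 1)
  labels <- names(test_groups) %||% as.character(seq_along(test_groups))
  rows <- lapply(seq_along(test_groups), function(gi) {
    grp <- test_groups[[gi]]
    stopifnot(length(grp) >= 2)
    with_seed(sub_seed(seed, gi), {
      g <- hedges_g(shared_control, grp)
      bc <- boot_ci_g(shared_control, grp, n_boot, conf)
      p <- perm_t_p(shared_control, grp, n_perm)
      data.frame(comparison = labels[gi],
                 n_control = length(shared_control), n_test = length(grp),
                 hedges_g = g, ci_low = bc$ci[1], ci_high = bc$ci[2],
                 ci_method = bc$method, p_perm = p,
                 n_boot = n_boot, n_perm = n_perm)
    })
  })
  structure(do.call(rbind, rows),
            conf = conf, seed = seed,
            class = c("effect_size_result", "data.frame"))
}
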