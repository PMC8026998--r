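#' Aggregate cone counts into a survival series
#'
#' Averages all position-level densities from all animals per arm and age:
#' mean, SEM (`sd/sqrt(n)`) and n over the flat list of records at each
#' (arm, age). A single record yields SEM 0 with a warning.
#'
#' @param records a `cone_counts` data frame ([simulate_survival()] or
#'   [read_survival_table()]).
#' @return data frame of class `survival_series`: `arm`, `age_pn`,
#'   `mean_density`, `sem`, `n`, ordered by arm then age.
#' @examples
#' recs <- simulate_survival(list(decay_model(5, 0.05, 0.1)), c(26, 60),
#'                           n_eyes = 3, seed = 1)
#' aggregate_survival(recs)
#' @export
aggregate_survival <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop("'records' must be nonempty", call. = FALSE)
  }
  key <- paste(records$arm, records$age_pn, sep = "\r")
  split_d <- split(records$cones_per_100um, key)
  rows <- lapply(names(split_d), function(k) {
    d <- split_d[[k]]
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    sem <- if (length(d) > 1) stats::sd(d) / sqrt(length(d)) else {
      warning("single record at (", parts[1], ", PN", parts[2],
              "): SEM reported as 0", call. = FALSE)
      0
    }
    data.frame(arm = parts[1], age_pn = as.numeric(parts[2]),
               mean_density = mean(d), sem = sem, n = length(d))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$arm, out$age_pn), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("survival_series", "data.frame"))
}

#' Fit exponential decay to a survival series
#'
#' Cone loss follows an exponential decay; on a log2 axis it is a straight
#' line. This fits ordinary least squares of `log2(mean density)` on age for
#' one arm and extrapolates the postnatal day at which the fitted density
#' crosses a threshold `theta` (default 1 cone/100 um, i.e. log2 = 0): the
#' "x-axis intersection" of the survival curve,
#' `x_intercept = (a - log2(theta)) / b`. A pure exponential never reaches
#' zero, so the threshold makes the extrapolated extinction day finite and
#' interpretable.
#'
#' @param series a [aggregate_survival()] series, or a `cone_counts` table
#'   (aggregated internally, or fitted on all records with
#'   `per_record = TRUE`).
#' @param arm which arm to fit.
#' @param theta density threshold defining the x-intercept.
#' @param per_record fit on individual records instead of per-age means.
#' @return object of class `decay_fit`: `a` (log2 density at day 0), `b`
#'   (decay slope, log2 units/day, > 0 when density declines), `x_intercept`
#'   (NA with `intercept_defined = FALSE` when `b <= 0`), `r2`, `theta`,
#'   `arm`, `n_ages`.
#' @examples
#' s <- aggregate_survival(simulate_survival(
#'   list(decay_model(5.541, 0.05832)), c(26, 30, 37, 45, 60, 90),
#'   n_eyes = 1, seed = 1))
#' fit_decay(s, "control")$x_intercept  # 5.541/0.05832 = 95.01
#' @export
fit_decay <- function(series, arm, theta = 1, per_record = FALSE) {
  if (inherits(series, "cone_counts")) {
    if (per_record) {
      sub <- series[series$arm == arm, ]
      dat <- data.frame(age = sub$age_pn, dens = sub$cones_per_100um)
    } else {
      series <- suppressWarnings(aggregate_survival(series))
    }
  }
  if (inherits(series, "survival_series")) {
    sub <- series[series$arm == arm, ]
    dat <- data.frame(age = sub$age_pn, dens = sub$mean_density)
  }
  if (!exists("dat", inherits = FALSE) || nrow(dat) == 0) {
    stop(sprintf("no data for arm '%s'", arm), call. = FALSE)
  }
  stop_if_not_scalar_pos(theta, "theta")
  drop <- dat$dens <= 0
  if (any(drop)) {
    warning(sprintf("%d nonpositive densities excluded from the log2 fit",
                    sum(drop)))
    dat <- dat[!drop, ]
  }
  if (length(unique(dat$age)) < 2) {
    stop("need >= 2 distinct ages with positive mean density", call. = FALSE)
  }
  fit <- stats::lm(log2(dens) ~ age, data = dat)
  # R2 computed directly (summary.lm warns on noiseless, perfect fits)
  y <- log2(dat$dens)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  a <- unname(stats::coef(fit)[1])
  b <- -unname(stats::coef(fit)[2])   # stored as decline rate, > 0 when falling
  # slopes indistinguishable from 0 (numerical noise on flat series) do not
  # define a finite, meaningful extinction day
  defined <- is.finite(b) && b > 1e-8
  x0 <- if (defined) (a - log2(theta)) / b else NA_real_
  structure(list(a = a, b = b, x_intercept = x0, intercept_defined = defined,
                 r2 = r2, theta = theta, arm = arm,
                 n_ages = length(unique(dat$age))),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Decay fit [%s]: density = 2^(%.4g - %.4g * day), R2 = %.3f\n",
              x$arm, x$a, x$b, x$r2))
  if (x$intercept_defined) {
    cat(sprintf("x-intercept (density = %g): PN%.2f\n", x$theta, x$x_intercept))
  } else {
    cat("x-intercept undefined (non-declining fit)\n")
  }
  invisible(x)
}

#' Delay between two extrapolated extinction days
#'
#' Difference between the x-intercepts of two decay fits, i.e. the number of
#' days by which one arm's extrapolated extinction is delayed relative to the
#' other.
#'
#' @param fit_1,fit_2 [fit_decay()] results with defined intercepts.
#' @param signed return `fit_2 - fit_1` instead of the absolute difference.
#' @return days (numeric scalar).
#' @export
intercept_delay <- function(fit_1, fit_2, signed = FALSE) {
  stopifnot(inherits(fit_1, "decay_fit"), inherits(fit_2, "decay_fit"))
  if (!fit_1$intercept_defined || !fit_2$intercept_defined) {
    stop("both fits must have a defined x-intercept", call. = FALSE)
  }
  d <- fit_2$x_intercept - fit_1$x_intercept
  if (signed) d else abs(d)
}

#' Per-animal log2 cone-survival ratios
#'
#' For each animal with both a treated and a control (contralateral) eye,
#' densities are first averaged over positions within each eye, then the
#' log2 ratio `log2(treated / control)` is computed. Animals whose control
#' density is 0 get an undefined (`NA`) ratio with a warning; animals missing
#' one arm are skipped.
#'
#' @param records a `cone_counts` table with arms `control` and `treated`.
#' @param treated,control arm labels.
#' @return data frame: `animal_id`, `age_pn`, `log2_ratio`.
#' @export
survival_ratio <- function(records, treated = "treated", control = "control") {
  stopifnot(nrow(records) > 0)
  agg <- stats::aggregate(cones_per_100um ~ animal_id + age_pn + arm,
                          data = records, FUN = mean)
  tr <- agg[agg$arm == treated, ]
  co <- agg[agg$arm == control, ]
  m <- merge(tr, co, by = c("animal_id", "age_pn"),
             suffixes = c("_treated", "_control"))
  if (nrow(m) == 0) stop("no animal has both arms", call. = FALSE)
  ratio <- ifelse(m$cones_per_100um_control > 0,
                  log2(m$cones_per_100um_treated / m$cones_per_100um_control),
                  NA_real_)
  if (anyNA(ratio)) {
    warning(sum(is.na(ratio)), " animal(s) with zero control density: ratio undefined")
  }
  out <- data.frame(animal_id = m$animal_id, age_pn = m$age_pn,
                    log2_ratio = ratio)
  out[order(out$age_pn, out$animal_id), , drop = FALSE]
}
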