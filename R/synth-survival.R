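#' Log2-linear exponential decay model of cone density
#'
#' Parametrizes cone survival as `density(t) = 2^(a - b * t)` cones per
#' 100 um of outer nuclear layer at postnatal day `t`: `a` is the log2
#' density extrapolated to day 0 and `b` the decay slope in log2 units/day
#' (> 0 for a declining arm). Multiplicative lognormal noise with a given
#' coefficient of variation models between-eye variability; on the log2
#' scale the fitting model therefore sees additive Gaussian noise.
#'
#' @param a log2 cone density at day 0.
#' @param b decay slope, log2 units per day.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (0 = noiseless).
#' @param arm arm label, e.g. `"control"` or `"treated"`.
#' @return object of class `decay_model`.
#' @examples
#' m <- decay_model(a = 5.541, b = 0.05832, noise_cv = 0.1, arm = "control")
#' decay_density(m, c(26, 90))
#' @export
decay_model <- function(a, b, noise_cv = 0, arm = "control") {
  stopifnot(is.finite(a), is.finite(b), is.finite(noise_cv), noise_cv >= 0)
  structure(list(a = a, b = b, noise_cv = noise_cv, arm = as.character(arm)),
            class = "decay_model")
}

#' @rdname decay_model
#' @param model a `decay_model`.
#' @param t ages in postnatal days.
#' @return `decay_density`: the noiseless expected density at each age.
#' @export
decay_density <- function(model, t) 2^(model$a - model$b * t)

#' Simulate cone-survival count records
#'
#' Generates per-eye, per-position cone-density measurements (cones per
#' 100 um ONL) from one or more decay models. Every position of an eye
#' receives the same expectation (positional gradients are deliberately not
#' modelled); each record gets independent multiplicative lognormal noise
#' `LogNormal(0, sigma)` with `sigma` chosen so the coefficient of variation
#' equals the model's `noise_cv`. Animal identifiers are shared across arms
#' at the same age/eye index, emulating contralateral treated/control eyes
#' of one animal, which makes per-animal survival ratios well defined.
#'
#' @param models list of [decay_model()]s (one per arm).
#' @param ages postnatal days at which eyes are sampled.
#' @param positions retinal eccentricities in degrees (spider-diagram
#'   positions; default -80, -10, 10, 80).
#' @param n_eyes eyes per arm per age.
#' @param seed integer seed.
#' @return data frame of class `cone_counts` with columns `animal_id`, `arm`,
#'   `eye`, `age_pn`, `position_deg`, `cones_per_100um`.
#' @examples
#' recs <- simulate_survival(list(decay_model(3, 0.1)), ages = 30,
#'                           n_eyes = 1, seed = 1)
#' recs$cones_per_100um  # exactly 2^(3 - 0.1*30) = 1 at noise_cv = 0
#' @export
simulate_survival <- function(models, ages, positions = c(-80, -10, 10, 80),
                              n_eyes = 6, seed = 1) {
  if (inherits(models, "decay_model")) models <- list(models)
  if (length(models) == 0) stop("'models' must be a nonempty list", call. = FALSE)
  stopifnot(length(ages) >= 1, all(ages > 0), n_eyes >= 1)
  with_seed(seed, {
    out <- lapply(seq_along(models), function(mi) {
      m <- models[[mi]]
      sdlog <- sqrt(log(1 + m$noise_cv^2))
      grid <- expand.grid(position_deg = positions, eye_i = seq_len(n_eyes),
                          age_pn = ages, KEEP.OUT.ATTRS = FALSE)
      mu <- 2^(m$a - m$b * grid$age_pn)
      noise <- if (sdlog > 0) stats::rlnorm(nrow(grid), 0, sdlog) else 1
      data.frame(
        animal_id = sprintf("PN%g_a%02d", grid$age_pn, grid$eye_i),
        arm = m$arm,
        eye = sprintf("%s_e%02d", m$arm, grid$eye_i),
        age_pn = grid$age_pn,
        position_deg = grid$position_deg,
        cones_per_100um = mu * noise
      )
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    structure(res, class = c("cone_counts", "data.frame"))
  })
}
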