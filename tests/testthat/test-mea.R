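test_that("band-pass filter: passband gain, DC rejection, closed-form edge gain", {
  fs <- 25000
  t <- seq(0, 2, by = 1 / fs)
  amp_of <- function(y) sqrt(2) * stats::sd(y[fs:(2 * fs)])  # steady state

  mid <- raw_recording(matrix(sin(2 * pi * 1500 * t), 1), fs)
  expect_equal(amp_of(bandpass_filter(mid, filter_spec())$voltage[1, ]), 1,
               tolerance = 0.02)

  dc <- raw_recording(matrix(rep(1, length(t)), 1), fs)
  expect_lt(max(abs(bandpass_filter(dc, filter_spec())$voltage[1, fs:(2 * fs)])),
            1e-3)

  # single-pass order-2 gain at 50 Hz: Butterworth magnitude 1/sqrt(1+(400/50)^4)
  low <- raw_recording(matrix(sin(2 * pi * 50 * t), 1), fs)
  g <- amp_of(bandpass_filter(low, filter_spec(direction = "forward"))$voltage[1, ])
  expect_equal(g, 1 / sqrt(1 + (400 / 50)^4), tolerance = 0.01)

  # shape preserved, band edge above Nyquist rejected
  expect_identical(dim(bandpass_filter(mid, filter_spec())$voltage),
                   dim(mid$voltage))
  expect_error(bandpass_filter(raw_recording(matrix(rnorm(100), 1), 8000),
                               filter_spec()), "Nyquist")
})

test_that("spike detection: timing accuracy, refractory pause, zero-variance flag", {
  # 3 clean template spikes recovered within 0.2 ms of ground truth
  fs <- 25000
  n <- fs  # 1 s
  x <- rnorm(n, 0, 1e-6)
  wave <- sin(2 * pi * seq(0, 24) / 25) * 8e-6
  t_true <- c(0.2, 0.5, 0.8)
  for (tt in t_true) {
    i0 <- round(tt * fs) + 1
    x[i0:(i0 + 24)] <- x[i0:(i0 + 24)] + wave
  }
  spk <- detect_spikes(raw_recording(matrix(x, 1), fs), detection_spec())
  expect_length(spk[[1]], 3)
  expect_true(all(abs(spk[[1]] - t_true) <= 2e-4))

  # two suprathreshold deflections 1.0 ms apart collapse to one event
  y <- rnorm(n, 0, 1e-6)
  y[1000] <- 1e-3
  y[1000 + 25] <- 1e-3  # 1 ms later at 25 kHz
  spk2 <- detect_spikes(raw_recording(matrix(y, 1), fs), detection_spec())
  expect_length(spk2[[1]], 1)
  # and survives with the pause disabled
  spk2b <- detect_spikes(raw_recording(matrix(y, 1), fs),
                         detection_spec(dead_time = 0))
  expect_length(spk2b[[1]], 2)

  # zero-variance channel flagged, no spikes
  flat <- raw_recording(matrix(0, 2, 1000) + c(0, 1) * 0, fs)
  flat$voltage[2, ] <- rnorm(1000, 0, 1e-6)
  spk3 <- detect_spikes(flat, detection_spec())
  expect_length(spk3[[1]], 0)
  expect_equal(attr(spk3, "flagged_channels"), flat$channel_ids[1])
})

test_that("false-event rate on pure noise stays near the Gaussian-tail bound", {
  fs <- 25000
  n <- 20 * fs
  x <- withr::with_seed(21, rnorm(n))
  spk <- detect_spikes(raw_recording(matrix(x, 1), fs), detection_spec(k = 5))
  # Monte-Carlo oracle on the same noise model: count 5-sigma upcrossings of
  # |z| directly on fresh noise (one-liner, independent of detect_spikes)
  oracle <- withr::with_seed(22, {
    z <- abs(rnorm(n))
    sum(z[-1] >= 5 & z[-n] < 5)
  })
  # anchor: P(|z| > 5) ~ 5.7e-7 per sample
  expected <- n * 2 * pnorm(-5)
  bound <- qpois(0.999, 2 * expected) + oracle
  expect_lte(length(spk[[1]]), bound)
})

test_that("window counts equal brute-force interval membership", {
  pr <- small_protocol(reps = 3)
  # hand-placed spikes
  on1 <- pr$onset_s[1]
  train <- structure(list(ch1 = c(on1 + 0.1)),
                     duration = max(pr$onset_s) + 3, class = "spike_train")
  wc <- window_counts(train, pr)
  expect_equal(wc$count_on[1], 1)
  expect_equal(sum(wc$count_on), 1)
  expect_equal(sum(wc$count_off) + sum(wc$count_spont), 0)

  empty <- structure(list(ch1 = numeric(0)),
                     duration = max(pr$onset_s) + 3, class = "spike_train")
  expect_true(all(as.matrix(window_counts(empty, pr)[4:6]) == 0))

  # 500 random spikes vs exhaustive per-interval loop
  dur <- max(pr$onset_s) + 2
  t_s <- withr::with_seed(31, sort(runif(500, 0, dur)))
  train2 <- structure(list(chA = t_s), duration = dur, class = "spike_train")
  wc2 <- window_counts(train2, pr)
  d <- attr(pr, "flash_dur")
  brute <- t(vapply(seq_len(nrow(pr)), function(i) {
    a <- pr$onset_s[i]
    c(on = sum(t_s >= a & t_s < a + d),
      off = sum(t_s >= a + d & t_s < a + 2 * d),
      sp = sum(t_s >= a - d & t_s < a))
  }, numeric(3)))
  expect_equal(wc2$count_on, unname(brute[, "on"]))
  expect_equal(wc2$count_off, unname(brute[, "off"]))
  expect_equal(wc2$count_spont, unname(brute[, "sp"]))

  # overlapping windows are refused with the epoch named
  bad <- make_protocol(intensities = 1e14, reps = 2, flash_dur = 0.35,
                       dark_gap = 0.7)
  attr(bad, "dark_gap") <- 0.5
  bad$onset_s <- c(2, 2.9)  # spont window of epoch 2 overlaps OFF of epoch 1
  expect_error(window_counts(train, bad), "epoch")
})

test_that("activation classification: degenerate cases and Monte-Carlo power", {
  pr <- make_protocol(intensities = c(1e14, 2e14), reps = 10)
  base <- simulate_trial_counts(pr, rate_model(5, 5), 1, seed = 1)

  # identical ON and spont counts -> t = 0, never activated
  same <- base
  same$count_on <- same$count_spont
  act <- test_activation(same)
  expect_true(all(act$t_on == 0))
  expect_false(any(act$on_activated))

  # constant +5 increase: zero-variance differences, infinitely strong
  up <- base
  up$count_on <- up$count_spont + 5L
  act_up <- test_activation(up)
  expect_true(all(is.infinite(act_up$t_on) & act_up$t_on > 0))
  expect_true(all(act_up$on_activated))
  # constant decrease is never ON activation
  down <- base
  down$count_on <- down$count_spont - 5L
  expect_false(any(test_activation(down)$on_activated))

  # ON ~ Poisson(10) vs spont ~ Poisson(2) at 20 reps: essentially always caught
  pr20 <- make_protocol(intensities = 1e14, reps = 20)
  m <- rate_model(2 / 0.35, 10 / 0.35)  # rates chosen to give those window means
  tcp <- simulate_trial_counts(pr20, m, n_channels = 400, seed = 2)
  actp <- test_activation(tcp)
  expect_gt(mean(actp$on_activated), 0.99)
})

test_that("channel selection implements the 3-of-5 photopic rule", {
  pr <- make_protocol()
  phot <- photopic_intensities(pr)
  mk_act <- function(flags) {
    structure(data.frame(channel = 1, intensity = c(8.6e12, phot),
                         t_on = 3, p_on = 0.001,
                         on_activated = c(FALSE, flags),
                         t_off = 0, p_off = 1, off_activated = FALSE),
              class = c("activation_result", "data.frame"))
  }
  expect_true(select_channels(mk_act(c(TRUE, TRUE, TRUE, FALSE, FALSE)), pr)$included)
  expect_false(select_channels(mk_act(c(TRUE, TRUE, FALSE, FALSE, FALSE)), pr)$included)
  expect_false(select_channels(mk_act(rep(FALSE, 5)), pr)$included)

  # fewer than 5 photopic intensities: threshold rescales with a warning
  pr3 <- make_protocol(intensities = c(1e14, 2e14, 3e14), reps = 2)
  act3 <- structure(data.frame(channel = 1, intensity = c(1e14, 2e14, 3e14),
                               t_on = 3, p_on = 0.001,
                               on_activated = c(TRUE, TRUE, FALSE),
                               t_off = 0, p_off = 1, off_activated = FALSE),
                    class = c("activation_result", "data.frame"))
  expect_warning(sel3 <- select_channels(act3, pr3), "rescaled")
  expect_equal(attr(sel3, "threshold"), 2L)
  expect_true(sel3$included)
})

test_that("response ratio: formula, undefined cases, scale invariance", {
  pr <- make_protocol(intensities = 1e14, reps = 4)
  mk_counts <- function(on, sp) {
    structure(data.frame(channel = 1, intensity = 1e14, rep_index = 1:4,
                         count_on = on, count_off = 0, count_spont = sp),
              window_len = 0.35, class = c("trial_counts", "data.frame"))
  }
  expect_equal(response_ratio(mk_counts(7, 7))$ratio, 0)
  expect_equal(response_ratio(mk_counts(7, 0))$ratio, 1)
  # 50 /s vs 5 /s: (50-5)/(50+5) = 0.8182
  r <- response_ratio(mk_counts(rep(50 * 0.35, 4), rep(5 * 0.35, 4)))
  expect_equal(r$ratio, 45 / 55, tolerance = 1e-12)
  expect_equal(r$rate_on, 50)
  # both rates zero -> undefined, excluded from medians
  expect_true(is.na(response_ratio(mk_counts(0, 0))$ratio))
  # invariance under rescaling both rates
  r10 <- response_ratio(mk_counts(rep(500 * 0.35, 4), rep(50 * 0.35, 4)))
  expect_equal(r10$ratio, r$ratio[1])
})

test_that("group comparison: identical groups, exact enumeration, uniform null p", {
  mk_rr <- function(vals) {
    structure(data.frame(channel = seq_along(vals), intensity = 1e14,
                         rate_on = 1, rate_spont = 1, ratio = vals),
              window_len = 0.35, class = c("response_ratio", "data.frame"))
  }
  same <- compare_groups(mk_rr(c(0.5, 0.5, 0.5)), mk_rr(c(0.5, 0.5, 0.5)))
  expect_equal(same$p_value, 1)

  cmp <- compare_groups(mk_rr(c(1, 2)), mk_rr(c(3, 4)))
  expect_equal(cmp$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(cmp$median_control, 1.5)
  expect_equal(cmp$n_treated, 2)

  # null uniformity of the large-sample p value
  ps <- withr::with_seed(41, vapply(1:500, function(i) {
    rank_sum_test(rnorm(150), rnorm(150))$p.value
  }, numeric(1)))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)

  # empty group errors with the intensity named
  expect_error(compare_groups(mk_rr(NA_real_), mk_rr(c(1, 2))), "1e\\+14")
})

test_that("median response ratio rises monotonically with the ON/spont rate ratio", {
  pr <- make_protocol(intensities = 1e14, reps = 20)
  meds <- vapply(seq_along(c(2, 4, 8, 16)), function(i) {
    on <- 5 * c(2, 4, 8, 16)[i]
    tc <- simulate_trial_counts(pr, rate_model(5, on), 60, seed = 50 + i)
    stats::median(response_ratio(tc)$ratio, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("end-to-end trace pipeline recovers >= 99% of 8-sigma spikes", {
  pr <- trace_protocol(reps = 8)
  tr <- simulate_trace(pr, rate_model(5, 25), spike_template(8, 0.001),
                       noise_sd = 1e-5, n_channels = 2, seed = 11)
  rec <- bandpass_filter(tr$recording, filter_spec())
  spk <- detect_spikes(rec, detection_spec())
  stats_ <- match_spikes(tr$truth, spike_train_df(spk))
  expect_gte(stats_["sensitivity"], 0.99)
  expect_gte(stats_["precision"], 0.99)
})
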