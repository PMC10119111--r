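test_that("spike detection counts a synthetic regular train exactly", {
  t <- seq(0, 50, by = 0.01)
  ca <- 0.05 + Reduce(`+`, lapply(seq(5, 45, by = 10), function(m) {
    0.5 * exp(-(t - m)^2 / (2 * 0.4^2))
  }))
  sp <- detect_ca_spikes(data.frame(time = t, Ca = ca), basal = 0.05)
  expect_equal(nrow(sp), 5)
  expect_equal(attr(sp, "f_ca"), 0.1, tolerance = 1e-3)
  expect_equal(attr(sp, "a_ca"), 0.55, tolerance = 1e-2)
})

test_that("subthreshold traces contain no spikes and empty traces error", {
  t <- seq(0, 50, by = 0.01)
  flat <- data.frame(time = t, Ca = 0.05 + 0.01 * sin(t))
  expect_equal(nrow(detect_ca_spikes(flat, basal = 0.05)), 0)
  expect_error(detect_ca_spikes(data.frame(time = numeric(), Ca = numeric())),
               "empty")
})

test_that("hysteresis detection agrees with a naive local-maxima scan", {
  sim <- sustained_sim()
  sp <- detect_ca_spikes(sim, basal = basal_ca(), window = c(5, 75))
  # brute force: local maxima above basal + half the largest excursion
  keep <- sim$time >= 5 & sim$time <= 75
  t <- sim$time[keep]; ca <- sim$Ca[keep]
  thr <- basal_ca() + 0.5 * (max(ca) - basal_ca())
  pk <- which(diff(sign(diff(ca))) == -2) + 1
  pk <- pk[ca[pk] > thr]
  pk <- pk[c(TRUE, diff(t[pk]) > 0.5)]
  expect_equal(nrow(sp), length(pk))
  expect_equal(sp$time, t[pk], tolerance = 0.05)
})

test_that("HRF features recover the analytic mode of a canonical input", {
  t <- seq(0, 40, by = 0.01)
  # with shape a1 and scale b1 tied by a1 b1 = d1 the positive lobe peaks at d1
  tr <- data.frame(time = t, BOLD = canonical_hrf(t, d1 = 6, a1 = 6, b1 = 1))
  hf <- hrf_features(tr, stim_onset = 0)
  expect_equal(hf$t_peak, 6, tolerance = 0.02)
  expect_lt(hf$undershoot, 0)  # undershoot lobe present
  # translation equivariance
  tr2 <- data.frame(time = t + 3, BOLD = tr$BOLD)
  hf2 <- hrf_features(tr2, stim_onset = 3)
  expect_equal(hf2$t_peak, hf$t_peak)
  expect_equal(hf2$t_on, hf$t_on)
  flat <- data.frame(time = t, BOLD = rep(0, length(t)))
  expect_error(hrf_features(flat, stim_onset = 0), "flat")
})

test_that("canonical HRF fit recovers its own coefficients", {
  t <- seq(0, 40, by = 0.05)
  y <- canonical_hrf(t, d1 = 6, a1 = 6, b1 = 1, c = 0.07,
                     d2 = 18, a2 = 12, b2 = 1.5)
  fit <- fit_canonical_hrf(data.frame(time = t, hrf = y))
  expect_gt(fit$r_squared, 0.9999)
  expect_equal(unname(fit$coef[["d1"]]), 6, tolerance = 0.02)
  expect_equal(unname(fit$coef[["d2"]]), 18, tolerance = 0.02)
  expect_equal(unname(fit$coef[["c"]]), 0.07, tolerance = 0.05)
  # multi-start robustness: a denser start grid lands on the same optimum
  fit2 <- fit_canonical_hrf(data.frame(time = t, hrf = y), n_starts = 6)
  expect_equal(fit2$coef[["d2"]], fit$coef[["d2"]], tolerance = 1e-3)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 7)
  expect_equal(glance(fit)$r_squared, fit$r_squared)
})

test_that("logarithmic coding fit recovers noiseless coefficients", {
  x <- seq(0.7, 2.4, length.out = 12)
  f <- 0.12 * log((x - 0.58) / 0.05)
  fit <- fit_log_curve(x, f)
  expect_equal(unname(fit$coef[["A"]]), 0.12, tolerance = 1e-5)
  expect_equal(unname(fit$coef[["x_o"]]), 0.58, tolerance = 1e-5)
  expect_equal(unname(fit$coef[["B"]]), 0.05, tolerance = 1e-4)
  expect_gt(fit$r_squared, 1 - 1e-10)
})

test_that("saturating fit recovers the exponent at the reported noise level", {
  x <- seq(0.5, 8, length.out = 12)
  y0 <- 3.69 * x^1.08 / (x^1.08 + 0.95)
  exact <- fit_saturating(x, y0)
  expect_equal(unname(exact$coef[["p"]]), 1.08, tolerance = 1e-5)
  set.seed(202)
  p_hat <- replicate(100, {
    y <- y0 + stats::rnorm(length(y0), 0, 0.01 * max(y0))
    fit_saturating(x, y)$coef[["p"]]
  })
  expect_lt(abs(mean(p_hat) - 1.08), 0.05)
})

test_that("convolution prediction is linear, time invariant and causal", {
  k <- canonical_hrf(seq(0, 30, by = 0.01))
  n <- 4000
  imp <- rep(0, n); imp[200] <- 1
  out <- convolve_predict(k, imp, 0.01, gain = 3)
  m <- min(n - 199, length(k))
  expect_equal(out[200:(199 + m)], 3 * 0.01 * k[1:m], tolerance = 1e-12)
  expect_true(all(abs(out[(200 + length(k)):n]) < 1e-12))
  expect_true(all(abs(out[1:199]) < 1e-12))
  set.seed(5)
  d1 <- stats::runif(n); d2 <- stats::runif(n)
  expect_equal(convolve_predict(k, d1 + d2, 0.01),
               convolve_predict(k, d1, 0.01) + convolve_predict(k, d2, 0.01),
               tolerance = 1e-9)
  shift <- 150
  ds <- c(rep(0, shift), d1[1:(n - shift)])
  os <- convolve_predict(k, ds, 0.01)
  o1 <- convolve_predict(k, d1, 0.01)
  expect_equal(os[(shift + 1):n], o1[1:(n - shift)], tolerance = 1e-9)
  expect_error(convolve_predict(extract_hrf(event_sim()), d1, 0.02),
               "different grids")
})

test_that("linear-fraction summary behaves on a constructed curve", {
  # straight rise to 80% of the range, then an abrupt plateau
  set.seed(9)
  fake <- list(curve = tibble::tibble(
    nu_ext = 1:10, nu_e = 1:10,
    n_spikes = c(0, 0, rep(5, 8)),
    bold_amp = c(seq(1, 1.8, length.out = 9), 2.0) +
      stats::rnorm(10, 0, 1e-4)
  ))
  fake$curve$bold_amp[10] <- fake$curve$bold_amp[9]  # saturate
  lf <- linear_fraction(fake)
  expect_gt(lf$fraction, 70)
  expect_gt(lf$r_squared, 0.95)
})
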