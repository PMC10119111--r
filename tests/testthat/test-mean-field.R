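test_that("transfer function is silent at rest and shuts down under adaptation", {
  p <- default_params()
  expect_lt(adex_transfer(0, 0, 0, p, pop = "e"), 0.1)
  expect_lt(adex_transfer(0, 0, 0, p, pop = "i"), 0.1)
  expect_equal(adex_transfer(4, 8, Inf, p, pop = "e"), 0)
  # very large finite adaptation also suppresses firing
  expect_lt(adex_transfer(4, 8, 1e5, p, pop = "e"), 1e-6)
})

test_that("transfer function is monotone in excitation and adaptation", {
  p <- default_params()
  nu_grid <- seq(0.5, 12, length.out = 25)
  f <- vapply(nu_grid, function(nu) adex_transfer(nu, 8, 40, p, pop = "e"),
              numeric(1))
  expect_true(all(diff(f) >= -1e-12))
  w_grid <- seq(0, 200, length.out = 25)
  fw <- vapply(w_grid, function(w) adex_transfer(6, 8, w, p, pop = "e"),
               numeric(1))
  expect_true(all(diff(fw) <= 1e-12))
})

test_that("invalid transfer-function inputs raise errors", {
  p <- default_params()
  expect_error(adex_transfer(NaN, 1, 0, p), "non-finite")
  expect_error(adex_transfer(-1, 1, 0, p), ">= 0")
  expect_error(adex_transfer(1, 1, NaN, p), "non-finite")
})

test_that("a tabulated transfer function can replace the semi-analytic form", {
  p <- default_params()
  tab <- function(ne, ni, W) 0.5 * ne
  expect_equal(adex_transfer(4, 8, 0, p, table_fn = tab), 2)
})

test_that("the quiescent state is a fixed point of the mean-field equations", {
  p <- default_params()
  d <- mean_field_deriv(c(nu_e = 0, nu_i = 0, W = 0), 0, p)
  expect_true(all(abs(d) < 1e-6))
})

test_that("adaptation decays exponentially when firing is absent", {
  p <- nvc_params(neuronal = utils::modifyList(default_params()$neuronal,
                                               list(b = 0)))
  d <- mean_field_deriv(c(nu_e = 0, nu_i = 0, W = 80), 0, p)
  expect_equal(unname(d[["W"]]), -80 / p$neuronal$tau_w, tolerance = 1e-12)
})

test_that("steady state matches the long-run plateau of a forward integration", {
  p <- default_params()
  st <- mean_field_steady(4, p, tol = 1e-8)
  # residual by contract
  d <- mean_field_deriv(st, 4, p)
  expect_lt(max(abs(d) / c(1, 1, p$neuronal$b)), 1e-7)
  # independent forward integration through the compiled core
  sim <- simulate_nvc(stim_event(4, 60, onset = 1, t_total = 62),
                      p, rest = default_rest())
  plateau <- sim$nu_e[sim$time == 60]
  expect_equal(unname(st[["nu_e"]]), plateau, tolerance = 1e-5)
  expect_equal(unname(mean_field_steady(0, p)), c(0, 0, 0), tolerance = 1e-9)
})

test_that("steady excitatory rate grows sublinearly with external drive", {
  p <- default_params()
  nus <- c(2, 4, 6, 8)
  ne <- vapply(nus, function(nu) mean_field_steady(nu, p, tol = 1e-7)[["nu_e"]],
               numeric(1))
  expect_true(all(diff(ne) > 0))
  slopes <- diff(ne) / diff(nus)
  expect_true(all(diff(slopes) < 0))  # saturation at high input
})

test_that("glutamate release is exactly linear in both rates", {
  p <- default_params()
  expect_equal(glutamate_release(0, 0, p), 0)
  g1 <- glutamate_release(1.3, 0.7, p)
  g2 <- glutamate_release(2.1, 1.9, p)
  expect_equal(glutamate_release(3.4, 2.6, p), g1 + g2, tolerance = 1e-15)
  expect_equal(glutamate_release(2.6, 1.4, p), 2 * g1, tolerance = 1e-15)
  # with g_ext = 0 (default) the release tracks recurrent activity only
  expect_equal(glutamate_release(1, 5, p), glutamate_release(1, 0, p))
})

test_that("semi-analytic rate agrees with a single-cell Monte-Carlo estimate", {
  p <- default_params()
  nu_e <- 4; nu_i <- 8; W <- 60
  tf <- adex_transfer(nu_e, nu_i, W, p, pop = "e")
  mc <- vapply(1:3, function(s) {
    nvcsim:::.cpp_adex_mc_rate(nu_e, nu_i, W, unclass(p), 60, 5, 5e-5, s, "e")
  }, numeric(1))
  se <- stats::sd(mc) / sqrt(length(mc))
  # the phenomenological threshold polynomial carries a systematic fit error
  # of several percent, so the sampling band is widened by a 15% margin
  expect_lt(abs(mean(mc) - tf), max(2 * se, 0.15 * tf))
})
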