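test_that("event protocol is a rectangle with the right area", {
  pr <- stim_event(4, 2, onset = 10, t_total = 50)
  t <- seq(0, 50, by = 0.001)
  tr <- protocol_trace(pr, t)
  expect_equal(sum(tr$nu_ext) * 0.001, 4 * 2, tolerance = 1e-2)
  expect_true(all(tr$nu_ext[t < 10] == 0))
  expect_true(all(tr$nu_ext[t >= 10 & t < 12] == 4))
  z <- protocol_trace(stim_event(0, 2, onset = 10, t_total = 50), t)
  expect_true(all(z$nu_ext == 0))
  expect_error(stim_event(4, 10, onset = 45, t_total = 50), "past t_total")
})

test_that("block protocol has the right span, edges and degenerate case", {
  pr <- stim_block(4, 2, 1, 10, onset = 10)
  expect_equal(pr$meta$duration, 10 * 2 + 9 * 1)  # 29 s span, 20 s active
  t <- seq(0, pr$t_total, by = 0.001)
  tr <- protocol_trace(pr, t)
  expect_equal(sum(tr$nu_ext) * 0.001, 4 * 20, tolerance = 1e-2)
  rising <- sum(diff(tr$nu_ext) > 0)
  expect_equal(rising, 10)
  # a single-pulse block is exactly an event
  b1 <- protocol_trace(stim_block(4, 2, 1, 1, onset = 10, t_total = 50), t)
  e1 <- protocol_trace(stim_event(4, 2, onset = 10, t_total = 50), t)
  expect_identical(b1$nu_ext, e1$nu_ext)
  expect_error(stim_block(4, 2, 1, 30, onset = 10, t_total = 50), "past t_total")
})

test_that("sinusoid protocol is centered, clipped and validated", {
  pr <- stim_sinusoid(4.2, 1.6, 20, onset = 0, duration = 20, t_total = 60)
  t <- seq(0, 20 - 0.001, by = 0.001)
  expect_equal(mean(protocol_trace(pr, t)$nu_ext), 4.2, tolerance = 1e-3)
  cst <- stim_sinusoid(4.2, 0, 20, onset = 0, duration = 20, t_total = 60)
  expect_true(all(protocol_trace(cst, t)$nu_ext == 4.2))
  expect_error(stim_sinusoid(-1, 0.5, 20), ">= 0")
  expect_error(stim_sinusoid(1, 2, 20), "center must be >= amplitude")
})

test_that("a zero protocol leaves every variable at the resting fixed point", {
  sim <- simulate_nvc(stim_event(0, 1, onset = 1, t_total = 40),
                      default_params(), rest = default_rest())
  expect_true(all(abs(sim$BOLD) < 1e-9))
  drift <- vapply(setdiff(names(sim), "time"),
                  function(v) max(abs(sim[[v]] - sim[[v]][1])), numeric(1))
  expect_true(all(drift < 1e-6))
})

test_that("simulation runs are deterministic", {
  pr <- stim_event(4, 2, onset = 5, t_total = 20)
  s1 <- simulate_nvc(pr, default_params(), rest = default_rest())
  s2 <- simulate_nvc(pr, default_params(), rest = default_rest())
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})

test_that("no variable leaves rest before stimulus onset", {
  sim <- event_sim()
  pre <- sim[sim$time < 10, ]
  drift <- vapply(setdiff(names(pre), "time"),
                  function(v) max(abs(pre[[v]] - pre[[v]][1])), numeric(1))
  expect_true(all(drift < 1e-6))
})

test_that("halving the step changes the solution by less than 1e-4 relative", {
  p <- default_params()
  s1 <- simulate_nvc(stim_event(4, 2, onset = 3, t_total = 13), p,
                     dt = 2e-4, rest = default_rest())
  s2 <- simulate_nvc(stim_event(4, 2, onset = 3, t_total = 13), p,
                     dt = 1e-4, rest = default_rest())
  rel <- vapply(setdiff(names(s1), "time"), function(v) {
    max(abs(s1[[v]] - s2[[v]])) / max(abs(s1[[v]]), 1e-8)
  }, numeric(1))
  expect_lt(max(rel), 1e-4)
})

test_that("compiled and R-level right-hand sides agree", {
  p <- default_params()
  pp <- unclass(p)
  pp$vascular$cAMP_o <- default_rest()$cAMP_o
  p_resolved <- structure(pp, class = "nvc_params")
  set.seed(11)
  for (i in 1:12) {
    y <- c(runif(1, 0, 6), runif(1, 0, 15), runif(1, 0, 120),
           runif(1, 0.02, 0.8), runif(1, 0.2, 1), runif(1, 0.02, 1.5),
           runif(1, 0, 1), runif(1, 0, 1), runif(1, 0.05, 0.9),
           runif(1, 0.05, 0.8), runif(1, 0.9, 1.3), runif(1, 0.8, 1.2))
    nu <- runif(1, 0, 8)
    d_cpp <- nvcsim:::.cpp_rhs_nvc(y, nu, 0, pp, list())
    d_r <- r_full_rhs(y, nu, p_resolved)
    expect_equal(unname(d_r), as.numeric(d_cpp), tolerance = 1e-10)
  }
})

test_that("the event stimulus drives the canonical activation cascade", {
  sim <- event_sim()
  pk <- vapply(c("nu_e", "Glu", "Ca", "PG", "CBF_in", "BOLD"),
               function(v) sim$time[which.max(sim[[v]])], numeric(1))
  # glutamate tracks the excitatory rate instantaneously; everything
  # downstream peaks strictly later, in pathway order
  expect_true(pk[["nu_e"]] <= pk[["Glu"]])
  expect_true(pk[["Glu"]] < pk[["Ca"]])
  expect_true(pk[["Ca"]] < pk[["PG"]])
  expect_true(pk[["PG"]] < pk[["CBF_in"]])
  expect_true(pk[["CBF_in"]] < pk[["BOLD"]])
})

test_that("CSV export is faithful", {
  sim <- simulate_nvc(stim_event(3, 1, onset = 2, t_total = 10),
                      default_params(), rest = default_rest())
  f <- tempfile(fileext = ".csv")
  write_nvc_csv(sim, f)
  back <- utils::read.csv(f)
  expect_equal(names(back), names(sim))
  expect_equal(back$BOLD, sim$BOLD, tolerance = 1e-10)
  unlink(f)
})
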