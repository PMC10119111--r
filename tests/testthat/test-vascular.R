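test_that("receptor fraction saturates and cAMP reaches its closed form", {
  p <- default_params()
  v <- p$vascular
  # equilibrium receptor occupancy approaches 1 for large PG
  pg <- 1e6
  r_eq <- v$O_R * pg / (v$O_R * pg + 1 / v$tau_R)
  expect_gt(r_eq, 0.999)
  expect_equal(unname(receptor_camp_deriv(r_eq, 0, pg, p)[["R_PG"]]), 0,
               tolerance = 1e-6 * pg)
  # closed-form steady cAMP for constant PG vs explicit integration
  pg_c <- 0.4
  r_ss <- v$O_R * pg_c * v$tau_R / (v$O_R * pg_c * v$tau_R + 1)
  camp_ss <- v$tau_cAMP * v$O_cAMP * r_ss
  st <- c(R = 0, cAMP = 0)
  dt <- 1e-3
  for (i in seq_len(40000)) {
    d <- receptor_camp_deriv(st[1], st[2], pg_c, p)
    st <- st + dt * d
  }
  expect_equal(unname(st[2]), camp_ss, tolerance = 1e-4)
})

test_that("arteriole volume has baseline, extremum and constriction branch", {
  p <- default_params()
  v <- p$vascular
  o <- 0.3
  expect_equal(arteriole_volume(o, p, cAMP_o = o), 1)
  expect_equal(arteriole_volume(o + v$K_VA, p, cAMP_o = o),
               1 + v$D_A / (2 * v$K_VA), tolerance = 1e-12)
  # any other excursion dilates less than the extremum
  dc <- seq(0.01, 3, length.out = 60)
  cv <- arteriole_volume(o + dc, p, cAMP_o = o)
  expect_true(all(cv <= 1 + v$D_A / (2 * v$K_VA) + 1e-12))
  expect_true(all(arteriole_volume(o - dc[dc < o], p, cAMP_o = o) < 1))
  expect_error(arteriole_volume(0.3, nvc_params()), "unresolved")
})

test_that("flow-volume power law is exact and validated", {
  expect_equal(cbf_from_cbv(1, 0.38), 1)
  expect_equal(cbf_from_cbv(1.7, 1), 1.7)
  expect_equal(cbf_from_cbv(1.2, 0.38), exp(log(1.2) / 0.38), tolerance = 1e-14)
  expect_error(cbf_from_cbv(1.2, 0), "alpha_A")
  expect_error(cbf_from_cbv(1.2, -1), "alpha_A")
})

test_that("the resting point is an exact fixed point of the Balloon model", {
  p <- default_params()
  d <- balloon_deriv(1, 1, 1, p)
  expect_equal(d$dv, 0)
  expect_equal(d$dq, 0)
  expect_equal(d$CBF_out, 1)
  expect_equal(bold_from_balloon(1, 1, p), 0)
})

test_that("a flow step drives venous volume toward its power-law fixed point", {
  p <- nvc_params(balloon = utils::modifyList(default_params()$balloon,
                                              list(tau_v = 0)))
  f <- 1.3
  st <- c(v = 1, q = 1)
  dt <- 1e-3
  for (i in seq_len(60000)) {
    d <- balloon_deriv(st[1], st[2], f, p)
    st <- st + dt * c(d$dv, d$dq)
  }
  expect_equal(unname(st[1]), f^p$balloon$alpha_V, tolerance = 1e-5)
})

test_that("venous volume recovers more slowly than inflow after offset", {
  sim <- event_sim()
  post <- sim[sim$time > 12, ]
  half_time <- function(x) {
    exc <- x - 1
    pk <- which.max(exc)
    rest <- exc[pk:length(exc)]
    post$time[pk - 1 + which(rest <= exc[pk] / 2)[1]]
  }
  expect_gt(half_time(post$v), half_time(post$CBF_in))
})

test_that("less deoxyhemoglobin means a positive BOLD signal", {
  p <- default_params()
  expect_gt(bold_from_balloon(1, 0.9, p), 0)
  expect_lt(bold_from_balloon(1, 1.1, p), 0)
})

test_that("the linearized BOLD approximates the full Balloon plateau", {
  p <- default_params()
  f <- 1.1
  st <- c(v = 1, q = 1)
  dt <- 1e-3
  for (i in seq_len(80000)) {
    d <- balloon_deriv(st[1], st[2], f, p)
    st <- st + dt * c(d$dv, d$dq)
  }
  full <- bold_from_balloon(st[1], st[2], p)
  lin <- bold_linear(f, p)
  expect_lt(abs(full - lin) / abs(lin), 0.2)
})
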