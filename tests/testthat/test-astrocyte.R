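test_that("hill function has the defining values and is monotone", {
  expect_equal(hill(0, 0.5), 0)
  expect_equal(hill(0.5, 0.5), 0.5)
  expect_equal(hill(2, 2, n = 2), 0.5)
  x <- seq(0, 10, length.out = 50)
  expect_true(all(diff(hill(x, 1.3)) > 0))
  expect_error(hill(1, 0), "K must be")
  expect_error(hill(-1, 1), ">= 0")
})

test_that("calcium fluxes vanish where their driving terms vanish", {
  p <- default_params()
  a <- p$astrocyte
  ca_exhaust <- a$C_T / (1 + a$rho_A)
  J <- calcium_fluxes(c(Ca = ca_exhaust, h = 0.7, IP3 = 0.5), p)
  expect_equal(unname(J[["J_C"]]), 0, tolerance = 1e-12)
  J0 <- calcium_fluxes(c(Ca = 0, h = 0.7, IP3 = 0.5), p)
  expect_equal(unname(J0[["J_P"]]), 0)
})

test_that("the resting state balances release, leak and pump fluxes", {
  p <- default_params()
  st <- default_rest()$state
  J <- calcium_fluxes(st[c("Ca", "h", "IP3")], p)
  expect_lt(abs(J[["J_C"]] + J[["J_L"]] - J[["J_P"]]), 1e-6)
  # and the IP3 budget is closed too
  dIP3 <- ip3_deriv(st[["IP3"]], st[["Ca"]], 0, p)
  expect_lt(abs(dIP3), 1e-6)
})

test_that("the printed leak variant is reproducible through leak_sign", {
  p <- nvc_params(astrocyte = utils::modifyList(default_params()$astrocyte,
                                                list(leak_sign = -1)))
  a <- p$astrocyte
  st <- c(Ca = 0.2, h = 0.8, IP3 = 0.4)
  J <- calcium_fluxes(st, p)
  expect_equal(unname(J[["J_L"]]),
               a$Gamma_L * (a$C_T - (1 - a$rho_A) * 0.2), tolerance = 1e-12)
})

test_that("gate kinetics: full deinactivation at zero calcium, O_2 scaling", {
  p <- default_params()
  g <- ip3r_gating(c(Ca = 0, IP3 = 0.4), p)
  expect_equal(g$h_inf, 1)
  p10 <- nvc_params(astrocyte = utils::modifyList(p$astrocyte,
                                                  list(O_2 = p$astrocyte$O_2 * 10)))
  g10 <- ip3r_gating(c(Ca = 0.3, IP3 = 0.4), p10)
  g1 <- ip3r_gating(c(Ca = 0.3, IP3 = 0.4), p)
  expect_equal(g10$tau_h, g1$tau_h / 10, tolerance = 1e-12)
  expect_equal(g10$h_inf, g1$h_inf)
  expect_true(g1$tau_h > 0 && g1$h_inf > 0 && g1$h_inf <= 1)
})

test_that("IP3 production saturates at extreme glutamate", {
  p <- default_params()
  d_inf <- ip3_deriv(0.4, 0.2, 1e12, p)
  d_hi <- ip3_deriv(0.4, 0.2, 500, p)
  expect_true(is.finite(d_inf))
  expect_lt(d_inf - d_hi, p$astrocyte$v_beta * 0.05)
})

test_that("a glutamate step above the bifurcation elicits repetitive spiking", {
  p <- default_params()
  run_astro <- function(Glu, t_total = 120, dt = 2e-3) {
    st <- c(Ca = basal_ca(), h = 0.97, IP3 = 0.01, AA = 0, PG = 0)
    n <- round(t_total / dt)
    keep <- numeric(n %/% 25)
    j <- 0
    for (i in seq_len(n)) {
      st <- nvcsim:::rk4_step(function(s) astrocyte_deriv(s, Glu, p), st, dt)
      if (i %% 25 == 0) { j <- j + 1; keep[j] <- max(0, st[["Ca"]]) }
    }
    data.frame(time = seq_along(keep) * dt * 25, Ca = keep)
  }
  n_spikes <- function(Glu) nrow(detect_ca_spikes(run_astro(Glu),
                                                  basal = basal_ca()))
  expect_equal(n_spikes(0.005), 0)
  expect_gt(n_spikes(0.06), 3)
  # locate the bifurcation by bisection: it must sit strictly inside
  lo <- 0.005; hi <- 0.06
  for (k in 1:5) {
    mid <- sqrt(lo * hi)
    if (n_spikes(mid) >= 2) hi <- mid else lo <- mid
  }
  expect_gt(hi, 0.005)
  expect_lt(hi, 0.06)
})

test_that("AA and PGE2 follow their closed-form steady states", {
  p <- default_params()
  a <- p$astrocyte
  d0 <- aa_pg_deriv(0, 0, 0, p)
  expect_equal(unname(d0), c(0, 0))
  ca_c <- 0.4
  aa_ss <- a$tau_AA * a$O_AA * ca_c / (a$K_AA + ca_c)
  expect_equal(unname(aa_pg_deriv(aa_ss, 0, ca_c, p)[["AA"]]), 0,
               tolerance = 1e-12)
  pg_ss <- a$tau_PG * a$O_PG * aa_ss / (a$K_PG + aa_ss)
  expect_equal(unname(aa_pg_deriv(aa_ss, pg_ss, ca_c, p)[["PG"]]), 0,
               tolerance = 1e-12)
})

test_that("a calcium spike propagates with increasing lag through AA and PG", {
  sim <- event_sim()
  t_pk <- function(v) sim$time[which.max(sim[[v]])]
  expect_lt(t_pk("Ca"), t_pk("AA"))
  expect_lt(t_pk("AA"), t_pk("PG"))
})

test_that("the gate stays inside [0, 1] along a strong stimulation", {
  sim <- sustained_sim()
  expect_true(all(sim$h >= 0 & sim$h <= 1))
  expect_true(all(sim$Ca >= 0))
  expect_true(all(sim$Ca <= default_params()$astrocyte$C_T /
                    (1 + default_params()$astrocyte$rho_A) + 1e-9))
})
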