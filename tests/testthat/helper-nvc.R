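# Shared fixtures, computed lazily and cached for the whole test session.
.shared <- new.env(parent = emptyenv())

shared <- function(name, expr) {
  if (is.null(.shared[[name]])) .shared[[name]] <- force(expr)
  .shared[[name]]
}

default_params <- function() shared("params", nvc_params())

default_rest <- function() shared("rest", resting_state(default_params()))

basal_ca <- function() default_rest()$state[["Ca"]]

# the reference single-event run (2 s stimulus at 4 Hz)
event_sim <- function() shared("event_sim", {
  simulate_nvc(stim_event(4, 2, onset = 10, t_total = 70),
               default_params(), rest = default_rest())
})

# a strong sustained-stimulation run
sustained_sim <- function() shared("sustained_sim", {
  simulate_nvc(stim_event(6, 60, onset = 5, t_total = 75),
               default_params(), rest = default_rest())
})

coding <- function() shared("coding", coding_curve(params = default_params()))

# full R-side right-hand side of the coupled system, assembled from the
# stage-level derivative functions (used to cross-check the compiled core)
r_full_rhs <- function(y, nu_ext, params) {
  st_n <- c(nu_e = max(0, y[1]), nu_i = max(0, y[2]), W = y[3])
  dn <- mean_field_deriv(st_n, nu_ext, params)
  Glu <- glutamate_release(max(0, y[1]), nu_ext, params)
  st_a <- c(Ca = y[4], h = y[5], IP3 = y[6], AA = y[7], PG = y[8])
  da <- astrocyte_deriv(st_a, Glu, params)
  dv <- receptor_camp_deriv(min(1, max(0, y[9])), y[10], max(0, y[8]), params)
  cbva <- arteriole_volume(y[10], params)
  f_in <- cbf_from_cbv(cbva, params$vascular$alpha_A)
  db <- balloon_deriv(y[11], y[12], f_in, params)
  c(dn, da, dv, db$dv, db$dq)
}
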