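#' Default parameter registry for the neurovascular coupling model
#'
#' Returns the full nested parameter list used by [simulate_nvc()] and the
#' stage-level derivative functions. The registry has four blocks:
#'
#' \describe{
#'   \item{`neuronal`}{AdEx mean-field population constants: response time `T`
#'     (s), adaptation time `tau_w` (s), subthreshold adaptation `a` (nS,
#'     default 0) and spike-triggered adaptation `b` (pA), single-cell
#'     constants (`C_m` F, `g_L` S, reversal potentials V, quantal
#'     conductances `Q_e`/`Q_i` S, synaptic decay times `tau_e`/`tau_i` s),
#'     network size (`N_e`, `N_i`, connection probability `p_conn`), the
#'     fitted phenomenological-threshold polynomials `P_e`/`P_i` of the
#'     semi-analytic transfer function, and the glutamate proportionality
#'     constants `g_r`, `g_ext` (uM per nS s Hz of synaptic drive).}
#'   \item{`astrocyte`}{Li-Rinzel calcium-store constants (`C_T` uM, `rho_A`,
#'     `Gamma_C`/`Gamma_L` 1/s, SERCA `O_P` uM/s and `K_P` uM with Hill
#'     exponent `pump_hill`), IP3-receptor dissociation constants `d1`, `d2`,
#'     `d3`, `d5` (uM) and binding rate `O_2` (1/(uM s)), the agonist-driven
#'     IP3 metabolism (PLC-beta `v_beta`/`K_R`/`K_p`/`K_pi`, PLC-delta
#'     `v_delta`/`kappa_delta`/`K_delta`, IP3-3-kinase `v_3K`/`K_D`/`K_3`,
#'     5-phosphatase `r_5P`), and the arachidonic-acid/PGE2 cascade
#'     (`tau_AA`, `tau_PG` s; `O_AA`, `O_PG` uM/s; `K_AA`, `K_PG` uM).}
#'   \item{`vascular`}{PGE2-receptor and cAMP stage (`tau_R`, `O_R`,
#'     `tau_cAMP`, `O_cAMP`), basal cAMP `cAMP_o` (uM; `NULL` means "derive
#'     from the resting state", which makes the resting point exactly
#'     self-consistent), arteriole dilation constants `D_A` (uM) and `K_VA`
#'     (uM), and the arteriole flow-volume exponent `alpha_A`.}
#'   \item{`balloon`}{Venous Balloon constants: mean transit time `tau_0` (s),
#'     viscoelastic time `tau_v` (s), resting oxygen extraction `E_0`, venous
#'     volume exponent `alpha_V`, resting venous volume fraction `V_0`, and
#'     BOLD weights `k1`, `k2`, `k3`.}
#' }
#'
#' Overrides are supplied as a nested list and merged recursively, e.g.
#' `nvc_params(neuronal = list(b = 0), balloon = list(tau_v = 0))`.
#'
#' @param ... Nested overrides, one argument per block (see examples).
#' @return A named list of class `nvc_params`.
#' @examples
#' p <- nvc_params(neuronal = list(tau_w = 5, b = 20))
#' p$neuronal$tau_w
#' @export
nvc_params <- function(...) {
  defaults <- list(
    neuronal = list(
      T        = 5e-3,    # population response time (s)
      tau_w    = 1.0,     # adaptation time constant (s)
      a        = 0,       # subthreshold adaptation (nS); 0 disables the mu_V term
      b        = 60,      # spike-triggered adaptation increment (pA)
      C_m      = 200e-12, # membrane capacitance (F)
      g_L      = 10e-9,   # leak conductance (S)
      E_L      = -65e-3,  # leak reversal (V)
      E_e      = 0,       # excitatory reversal (V)
      E_i      = -80e-3,  # inhibitory reversal (V)
      Q_e      = 1.5e-9,  # excitatory quantal conductance (S)
      Q_i      = 5e-9,    # inhibitory quantal conductance (S)
      tau_e    = 5e-3,    # excitatory conductance decay (s)
      tau_i    = 5e-3,    # inhibitory conductance decay (s)
      N_e      = 8000,
      N_i      = 2000,
      p_conn   = 0.05,
      # second-order phenomenological threshold polynomials (V), fitted for
      # regular-spiking (excitatory) and fast-spiking (inhibitory) AdEx cells
      P_e = c(-0.0498, 0.00506, -0.025, 0.0014, -0.00041,
              0.0105, -0.036, 0.0074, 0.0012, -0.0407),
      P_i = c(-0.0514, 0.004, -0.0083, 0.0002, -0.0005,
              0.0014, -0.0146, 0.0045, 0.0028, -0.0153),
      # normalisation of the polynomial inputs
      muV0 = -60e-3, DmuV0 = 10e-3, sV0 = 4e-3, DsV0 = 6e-3,
      TvN0 = 0.5, DTvN0 = 1,
      # glutamate proportionality constants (uM per nS*s*Hz of mean drive)
      g_r   = 0.00747,
      g_ext = 0
    ),
    astrocyte = list(
      C_T     = 2,       # total ER-referenced calcium (uM)
      rho_A   = 0.18,    # ER-to-cytosol volume ratio
      Gamma_C = 12,      # max IP3R channel rate (1/s)
      Gamma_L = 0.11,    # ER leak rate (1/s)
      O_P     = 1.5,     # max SERCA pump rate (uM/s)
      K_P     = 0.1,     # SERCA affinity (uM)
      pump_hill = 2,     # SERCA Hill exponent
      leak_sign = 1,     # +1: (1+rho_A) reservoir in the leak; -1: (1-rho_A)
      d1 = 0.13, d2 = 1.049, d3 = 0.9434, d5 = 0.08234, # IP3R dissociation (uM)
      O_2 = 0.2,         # IP3R Ca binding rate (1/(uM s)); 2.0 shortens the refractory period
      # IP3 metabolism (agonist-dependent G-ChI formulation)
      v_beta = 1.5,      # max PLC-beta production (uM/s)
      K_R = 0.26, K_p = 2, K_pi = 0.6,   # PLC-beta glutamate/calcium constants (uM)
      v_delta = 0.02, kappa_delta = 1.5, K_delta = 0.1, # PLC-delta (uM/s, uM, uM)
      v_3K = 4, K_D = 0.5, K_3 = 1,      # IP3-3K (uM/s, uM, uM)
      r_5P = 0.6,        # 5-phosphatase linear rate (1/s)
      # arachidonic acid / PGE2 cascade
      tau_AA = 0.9, O_AA = 1.69, K_AA = 0.45,  # s, uM/s, uM
      tau_PG = 0.9, O_PG = 1.33, K_PG = 1.5     # s, uM/s, uM
    ),
    vascular = list(
      tau_R    = 0.9,    # receptor relaxation time (s)
      O_R      = 1.07,   # receptor binding rate (1/(uM s))
      tau_cAMP = 0.9,    # cAMP relaxation time (s)
      O_cAMP   = 2.84,   # max cAMP production (uM/s)
      cAMP_o   = NULL,   # basal cAMP (uM); NULL = derive from the resting state
      D_A      = 1.41,   # arteriole dilation strength (uM)
      K_VA     = 0.80,   # arteriole dilation half-width (uM)
      alpha_A  = 0.85    # arteriole flow-volume exponent
    ),
    balloon = list(
      tau_0   = 2,       # mean venous transit time (s)
      tau_v   = 18,      # viscoelastic (slow volume recovery) time (s)
      E_0     = 0.4,     # resting oxygen extraction fraction
      alpha_V = 0.38,    # venous volume exponent (Grubb)
      V_0     = 0.018,   # resting venous volume fraction
      k1      = 2.8, k2 = 2, k3 = 0.6   # BOLD weights (k1 = 7 E_0, k3 = 2 E_0 - 0.2)
    )
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad) > 0) {
    stop("unknown parameter block(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (blk in names(overrides)) {
    ov <- overrides[[blk]]
    if (!is.list(ov)) stop("block '", blk, "' must be a named list", call. = FALSE)
    unknown <- setdiff(names(ov), names(defaults[[blk]]))
    if (length(unknown) > 0) {
      stop("unknown parameter(s) in block '", blk, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    defaults[[blk]][names(ov)] <- ov
  }
  out <- structure(defaults, class = "nvc_params")
  validate_nvc_params(out)
  out
}

validate_nvc_params <- function(p) {
  n <- p$neuronal; a <- p$astrocyte; v <- p$vascular; b <- p$balloon
  stopifnot(
    n$T > 0, n$tau_w > 0, n$tau_e > 0, n$tau_i > 0,
    n$N_e > 0, n$N_i > 0,
    n$p_conn > 0, n$p_conn <= 1,
    n$g_r >= 0, n$g_ext >= 0,
    length(n$P_e) == 10, length(n$P_i) == 10,
    a$C_T > 0, a$rho_A > 0, a$rho_A < 1,
    a$Gamma_C > 0, a$Gamma_L > 0, a$O_P > 0, a$K_P > 0,
    a$d1 > 0, a$d2 > 0, a$d3 > 0, a$d5 > 0, a$O_2 > 0,
    a$tau_AA > 0, a$tau_PG > 0, a$O_AA >= 0, a$O_PG >= 0,
    a$K_AA > 0, a$K_PG > 0,
    v$tau_R > 0, v$tau_cAMP > 0, v$O_R >= 0, v$O_cAMP >= 0,
    v$D_A >= 0, v$K_VA > 0, v$alpha_A > 0, v$alpha_A <= 1,
    b$tau_0 > 0, b$tau_v >= 0, b$E_0 > 0, b$E_0 < 1,
    b$alpha_V > 0, b$alpha_V <= 1, b$V_0 > 0
  )
  if (abs(n$N_e / (n$N_e + n$N_i) - 0.8) > 1e-9) {
    stop("N_e/(N_e+N_i) must equal 0.8 (80% excitatory population)", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.nvc_params <- function(x, ...) {
  cat("<nvc_params>\n")
  for (blk in names(x)) {
    vals <- x[[blk]]
    scal <- vals[vapply(vals, function(v) is.numeric(v) && length(v) == 1, logical(1))]
    cat("  $", blk, ": ", paste0(names(scal), "=", signif(unlist(scal), 4),
                                 collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Read or write a parameter configuration file
#'
#' Configurations are stored as nested JSON (or YAML if the file extension is
#' `.yml`/`.yaml` and the yaml package is installed) mirroring the blocks of
#' [nvc_params()]. Only overrides need to be present; missing entries take
#' their defaults, so a round trip through [write_nvc_config()] and
#' [read_nvc_config()] reproduces the parameter set exactly.
#'
#' @param path File path.
#' @return For `read_nvc_config`, an `nvc_params` object.
#' @export
read_nvc_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  raw <- lapply(raw, function(blk) {
    if (!is.null(blk$cAMP_o) && length(blk$cAMP_o) == 0) blk$cAMP_o <- NULL
    blk
  })
  do.call(nvc_params, raw)
}

#' @param params An `nvc_params` object.
#' @rdname read_nvc_config
#' @export
write_nvc_config <- function(params, path) {
  stopifnot(inherits(params, "nvc_params"))
  ext <- tolower(tools::file_ext(path))
  x <- unclass(params)
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to write YAML configs", call. = FALSE)
    }
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  invisible(path)
}
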