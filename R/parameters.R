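#' Reference kinetic parameters
#'
#' Returns the full set of kinetic constants of the coupled
#' calcium-signaling / mitochondrial-metabolism model: limiting rates of the
#' TCA-cycle enzymes, oxidative phosphorylation pump densities, transporter
#' rates, Michaelis/activation/inhibition constants, Hill coefficients,
#' equilibrium constants, membrane-potential offsets and conserved pool
#' totals. Names are ASCII transliterations of the conventional symbols
#' (e.g. `Vmax_SERCA`, `kf_ACO`, `DeltaPsi_star`).
#'
#' Units: concentrations and Michaelis constants in mM except those acting on
#' Ca2+ pools, which are in uM; first-order rates in 1/s; limiting rates in
#' mM/s; membrane potentials in mV; conserved Ca2+ total `c_tot` in uM
#' normalized to cytosolic volume.
#'
#' @param ... named overrides, e.g. `mito_parameters(Vmax_SERCA = 0.096)`.
#'   Unknown names are an error.
#' @return a named list of class `mito_parameters`.
#' @export
#' @examples
#' p <- mito_parameters()
#' p$Vmax_SERCA
mito_parameters <- function(...) {
  p <- list(
    # conserved totals
    A_tot   = 3,      # mM, cytosolic adenine nucleotides
    Am_tot  = 15,     # mM, mitochondrial adenine nucleotides
    N_tot   = 0.8,    # mM, mitochondrial pyridine nucleotides
    cK_tot  = 1,      # mM, TCA-cycle intermediates
    c_tot   = 1500,   # uM, total free Ca2+ normalized by Vc

    # limiting rates / leading constants
    Vmax_SERCA = 0.12,    # mM/s
    Vmax_UNI   = 0.30,    # mM/s
    Vmax_NCX   = 2e-3,    # mM/s
    Vmax_IP3R  = 30,      # 1/s
    V_LEAK     = 0.15,    # 1/s
    Vmax_ANT   = 4,       # mM/s
    Vmax_CS    = 104,     # mM/s
    Vmax_IDH   = 1.7767,  # mM/s
    Vmax_KGDH  = 2.5,     # mM/s
    Vmax_SDH   = 0.5,     # mM/s
    Vmax_MDH   = 128,     # mM/s
    rho_res    = 1.00,    # mM, respiration-driven H+ pumps
    rho_f1     = 0.23,    # mM, F1F0-ATPase pumps
    kf_ACO     = 12.5,    # 1/s
    kf_FH      = 8.3,     # 1/s
    kf_SL      = 0.127,   # 1/(mM^2 s)
    k_Hyd      = 9e-2,    # mM/s
    g_H        = 1e-5,    # mM/(mV s)

    # Michaelis / activation / inhibition / dissociation constants
    K_M_AcCoA   = 1.2614e-2, # mM (CS)
    K_M_OAA_CS  = 5e-3,      # mM
    K_i_AcCoA   = 3.7068e-2, # mM (CS)
    K_s_AcCoA   = 8.0749e-2, # mM (CS)
    K_M_ISOC    = 1.52,      # mM (IDH)
    K_M_NAD_IDH = 0.923,     # mM
    K_a_ADP     = 0.062,     # mM (IDH)
    K_a_Cam     = 1.41,      # uM (IDH)
    K_i_NADH    = 0.19,      # mM (IDH)
    k_h_1       = 8.1e-5,    # mM (IDH ionization)
    k_h_2       = 5.98e-5,   # mM (IDH ionization)
    K_M_aKG     = 1.94,      # mM (KGDH)
    K_M_NAD_KGDH = 3.87e-2,  # mM
    K_D_Mg      = 0.0308,    # mM (KGDH)
    K_D_Ca      = 1.27,      # uM (KGDH)
    K_M_SUC     = 3e-2,      # mM (SDH)
    K_i_OAA     = 0.15,      # mM (SDH)
    K_i_FUM     = 1.3,       # mM (SDH)
    K_M_MAL     = 0.145,     # mM (MDH)
    K_M_NAD_MDH = 0.06,      # mM
    K_M_OAA_MDH = 0.017,     # mM
    K_M_NADH    = 0.044,     # mM (MDH)
    K_M_Na      = 9.4,       # mM (NCX)
    K_M_Ca      = 0.375,     # uM (NCX)
    K_trans     = 19,        # uM (uniporter translocation site)
    K_act       = 0.38,      # uM (uniporter activation site)
    L_uni       = 110,       # uniporter conformational equilibrium
    K_Ca        = 0.35,      # uM (SERCA)
    K_ATPc      = 0.05,      # mM (SERCA)
    K_M_ATPc    = 1,         # mM (Hyd)
    K_a_IP3     = 1.00,      # uM (IP3R)
    K_a_Cac     = 0.70,      # uM (IP3R activation)
    K_i_Ca      = 1.40,      # uM (IP3R inhibition)

    # equilibrium constants
    K_ACO = 0.067,
    K_FH  = 3.942,
    K_MDH = 2.756e-5,
    K_SL  = 0.724,
    K_F1  = 1.71e6,
    K_res = 1.35e18,

    # Hill coefficients / exponents
    n_i   = 2,    # IDH isocitrate
    n_aKG = 1.2,  # KGDH
    n_a   = 2.8,  # uniporter activation cooperativity
    n_Na  = 3,    # NCX Na+ stoichiometric exponent
    b_NCX = 0.5,  # NCX voltage dependence
    f_ANT = 0.5,  # ANT effective voltage fraction
    g_Ox  = 0.85, # respiration voltage fitting factor

    # Magnus-Keizer 6-state pump constants
    p1 = 1.346e-8,  p2 = 7.739e-7,  p3 = 6.65e-15,
    pa = 1.656e-5,  pc1 = 9.651e-14, pc2 = 4.845e-19,
    r1 = 2.077e-18, r2 = 1.728e-9,  r3 = 1.059e-26,
    ra = 6.394e-10, rc1 = 2.656e-19, rc2 = 8.632e-27,

    # membrane potential offsets
    DeltaPsi_star = 91,  # mV
    DeltaPsi_B    = 50,  # mV

    # structural switches (transcription ambiguities, documented in vignette)
    ares_sqrt     = TRUE,       # A_res = K_res * sqrt(NADH/NAD) vs plain ratio
    kgdh_form     = "product",  # "product" or "additive" denominator
    ox_half       = FALSE,      # leading 1/2 on respiration; absorbed in rho_res by default
    serca_coupled = TRUE        # SERCA ATP-dependence + ATP cost (FALSE = uncoupled variant)
  )
  apply_overrides(p, list(...), "mito_parameters")
}

#' Compartment geometry and physical constants
#'
#' Volume ratios, free-Ca2+ fractions, membrane capacitance and the physical
#' constants entering the rate laws and forces.
#'
#' @param ... named overrides.
#' @return a named list of class `mito_geometry`.
#' @export
mito_geometry <- function(...) {
  g <- list(
    alpha = 0.10,       # V_ER / V_c
    delta = 0.15,       # V_m / V_c
    f_c   = 0.01,       # free Ca2+ fraction, cytosol
    f_ER  = 0.01,       # free Ca2+ fraction, ER
    f_m   = 0.0003,     # free Ca2+ fraction, mitochondria
    C_m   = 1.812e-3,   # mM/mV, inner-membrane capacitance
    gamma = 1e3,        # uM per mM
    R     = 8.314,      # J/(mol K)
    T     = 310,        # K
    F     = 96.485      # kC/mol: F * DeltaPsi[mV] is in J/mol
  )
  g <- apply_overrides(g, list(...), "mito_geometry")
  stopifnot(g$alpha > 0, g$delta > 0, g$f_c > 0, g$f_ER > 0, g$f_m > 0,
            g$alpha <= 1, g$delta <= 1, g$f_c <= 1, g$f_ER <= 1, g$f_m <= 1,
            g$C_m > 0, g$gamma > 0)
  g
}

#' Controlled (buffered) species concentrations
#'
#' Species whose concentrations are held constant: phosphate, sodium,
#' magnesium and proton pools, oxygen, the CO2/CoA/CoQ pools, the TCA
#' substrate acetyl-CoA, and the IP3 stimulation level. All in mM except
#' `IP3` (uM). `DeltapH` is pH_c - pH_m.
#'
#' @param ... named overrides; most often `IP3` (stimulation, uM) and
#'   `AcCoA` (substrate, mM; 10 uM = 0.01 mM is the reference level).
#' @return a named list of class `mito_controls`.
#' @export
#' @examples
#' ctrl <- mito_controls(IP3 = 0.3)
mito_controls <- function(...) {
  ctrl <- list(
    Pi_c  = 1,        # mM
    Pi_m  = 20,       # mM
    Na_c  = 10,       # mM
    Na_m  = 5,        # mM
    Mg_m  = 0.4,      # mM
    H_c   = 6.31e-5,  # mM (pH 7.2)
    H_m   = 1e-5,     # mM (pH 8.0)
    O2    = 0.026,    # mM (2.6e-5 M)
    AcCoA = 0.010,    # mM (10 uM reference substrate level)
    CoA   = 0.02,     # mM
    CO2   = 21.4,     # mM
    CoQ   = 0.97,     # mM
    CoQH2 = 0.38,     # mM
    IP3   = 0.1,      # uM (basal, unstimulated)
    DeltapH = -0.80,  # pH_c - pH_m
    H2O   = 1         # water activity
  )
  apply_overrides(ctrl, list(...), "mito_controls")
}

apply_overrides <- function(base, overrides, cls) {
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(nm == "")) {
      stop("all overrides must be named", call. = FALSE)
    }
    bad <- setdiff(nm, names(base))
    if (length(bad)) {
      stop(sprintf("unknown %s name(s): %s", cls, paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    base[nm] <- overrides
  }
  structure(base, class = c(cls, "list"))
}

#' Validate a parameter/control/geometry triple
#'
#' Checks positivity and range invariants: nonnegative kinetic constants,
#' Hill coefficients at least 1, strictly positive conserved totals, free
#' fractions and volume ratios in (0, 1].
#'
#' @param p kinetic parameters from [mito_parameters()]
#' @param ctrl controlled species from [mito_controls()]
#' @param geom geometry from [mito_geometry()]
#' @return invisibly `TRUE`; errors describe the offending entries.
#' @export
validate_model_inputs <- function(p = mito_parameters(),
                                  ctrl = mito_controls(),
                                  geom = mito_geometry()) {
  num <- vapply(p, is.numeric, logical(1))
  vals <- unlist(p[num])
  if (any(vals < 0)) {
    stop("negative kinetic constant(s): ",
         paste(names(vals)[vals < 0], collapse = ", "), call. = FALSE)
  }
  hills <- c("n_i", "n_aKG", "n_a", "n_Na")
  if (any(unlist(p[hills]) < 1)) stop("Hill coefficients must be >= 1", call. = FALSE)
  totals <- c("A_tot", "Am_tot", "N_tot", "cK_tot", "c_tot")
  if (any(unlist(p[totals]) <= 0)) stop("conserved totals must be > 0", call. = FALSE)
  cvals <- unlist(ctrl[setdiff(names(ctrl), "DeltapH")])
  if (any(cvals < 0)) {
    stop("negative controlled concentration(s): ",
         paste(names(cvals)[cvals < 0], collapse = ", "), call. = FALSE)
  }
  if (!p$kgdh_form %in% c("additive", "product")) {
    stop("kgdh_form must be 'additive' or 'product'", call. = FALSE)
  }
  invisible(TRUE)
}

#' Default initial condition
#'
#' A state inside all physiological calibration windows, with the conserved
#' pools split consistently with the totals in `p`: cytosolic ATP:ADP = 2,
#' mitochondrial adenine pool mostly ADP, NADH:NAD = 0.25, the TCA pool
#' uniform over its eight intermediates, basal cytosolic and mitochondrial
#' Ca2+, the remainder of the cellular Ca2+ total in the ER, and an
#' energized membrane.
#'
#' @inheritParams validate_model_inputs
#' @return named numeric vector in the canonical state ordering
#'   (see [state_names()]).
#' @export
default_initial_state <- function(p = mito_parameters(), geom = mito_geometry()) {
  tca <- p$cK_tot / 8
  Cac <- 0.1
  Cam <- 0.1
  CaER <- (p$c_tot - Cac / geom$f_c - geom$delta * Cam / geom$f_m) *
    geom$f_ER / geom$alpha
  s <- c(
    ADPc = p$A_tot / 3, ADPm = p$Am_tot * 2 / 3,
    aKG = tca,
    ATPc = p$A_tot * 2 / 3, ATPm = p$Am_tot / 3,
    CIT = tca, FUM = tca, ISOC = tca, MAL = tca,
    NAD = p$N_tot * 0.8, NADH = p$N_tot * 0.2,
    OAA = tca, SCoA = tca, SUC = tca,
    Cac = Cac, Cam = Cam, CaER = CaER,
    DPsi = 150
  )
  s[state_names()]
}

#' Canonical state-variable ordering
#'
#' The 18 dynamic variables: 14 concentrations in mM, the three Ca2+ pools
#' in uM, and the inner-membrane potential in mV.
#'
#' @return character vector of length 18.
#' @export
state_names <- function() {
  c("ADPc", "ADPm", "aKG", "ATPc", "ATPm", "CIT", "FUM", "ISOC", "MAL",
    "NAD", "NADH", "OAA", "SCoA", "SUC", "Cac", "Cam", "CaER", "DPsi")
}

#' Conserved pool sums of a state
#'
#' Evaluates the five conserved quantities: cytosolic and mitochondrial
#' adenine totals, the pyridine total, the TCA intermediate total, and the
#' volume-weighted cellular Ca2+ total.
#'
#' @param state named state vector (or matrix with state columns)
#' @inheritParams validate_model_inputs
#' @return tibble with one row per state and columns `A_c`, `A_m`, `N`,
#'   `cK`, `Ca`.
#' @export
conserved_sums <- function(state, p = mito_parameters(), geom = mito_geometry()) {
  m <- if (is.matrix(state)) state else matrix(state, nrow = 1,
                                               dimnames = list(NULL, names(state)))
  tibble::tibble(
    A_c = m[, "ATPc"] + m[, "ADPc"],
    A_m = m[, "ATPm"] + m[, "ADPm"],
    N   = m[, "NAD"] + m[, "NADH"],
    cK  = m[, "CIT"] + m[, "ISOC"] + m[, "aKG"] + m[, "SCoA"] +
          m[, "SUC"] + m[, "FUM"] + m[, "MAL"] + m[, "OAA"],
    Ca  = m[, "Cac"] / geom$f_c + geom$delta * m[, "Cam"] / geom$f_m +
          geom$alpha * m[, "CaER"] / geom$f_ER
  )
}
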