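# Rate laws for the 17 processes and the 18 rate equations.
#
# All fluxes are in mM/s in the reference volume of their compartment
# (cytosol for ERout, SERCA, Hyd; mitochondria for the rest). Concentrations
# are mM except the Ca2+ pools (uM); the Ca2+ rate equations carry the
# gamma = 1e3 uM/mM conversion. The ER release law multiplies a first-order
# rate by a Ca2+ difference in uM and is divided by gamma so that it, too,
# is numerically in mM/s.

flux_names <- function() {
  c("ERout", "SERCA", "NCX", "UNI", "Hyd", "Ox", "F1", "CS", "ACO", "IDH",
    "KGDH", "SL", "SDH", "FH", "MDH", "ANT", "Hl")
}

#' Reference volumes of the 17 processes
#'
#' @return named character vector: `"cytosol"` or `"mitochondria"` per flux.
#' @export
flux_reference_volumes <- function() {
  v <- rep("mitochondria", 17)
  names(v) <- flux_names()
  v[c("ERout", "SERCA", "Hyd")] <- "cytosol"
  v
}

# exp with overflow guard; |DPsi| up to ~1500 mV stays exact, beyond is clamped
.gexp <- function(x) exp(pmin(x, 700))

# x / (1 - exp(-x)) with a series branch through the removable singularity
.bernoulli_factor <- function(x) {
  if (abs(x) < 1e-4) 1 + x / 2 + x * x / 12 else x / (1 - exp(-x))
}

#' Build fast evaluators for the model
#'
#' Returns closures over a fixed parameter set: `fluxes(y)` evaluates all 17
#' rate laws at a state vector and `deriv(t, y)` the 18 rate equations (in
#' the form deSolve expects). States probed marginally below zero by the
#' integrator are clamped to the nonnegative orthant before evaluation.
#'
#' @inheritParams validate_model_inputs
#' @return list with elements `fluxes` and `deriv`.
#' @export
build_model <- function(p = mito_parameters(), ctrl = mito_controls(),
                        geom = mito_geometry()) {
  force(p); force(ctrl); force(geom)
  RT <- geom$R * geom$T
  FoRT <- geom$F / RT            # 1/mV
  pH_fac <- 10^(6 * ctrl$DeltapH)
  pH_fac3 <- 10^(3 * ctrl$DeltapH)
  eB6 <- .gexp(6 * p$DeltaPsi_B * FoRT)
  eB3 <- .gexp(3 * p$DeltaPsi_B * FoRT)
  hl_zero <- 2.303 * ctrl$DeltapH / FoRT   # mV at which proton leak vanishes
  na_term <- (1 + p$K_M_Na / ctrl$Na_c)^p$n_Na
  ip3_gate <- ctrl$IP3^2 / (ctrl$IP3^2 + p$K_a_IP3^2)
  kgdh_additive <- identical(p$kgdh_form, "additive")
  coupled <- isTRUE(p$serca_coupled)
  ox_pref <- if (isTRUE(p$ox_half)) 0.5 else 1

  fluxes <- function(y) {
    y <- pmax(y, c(rep(0, 17), -Inf))
    ADPc <- y[[1L]]; ADPm <- y[[2L]]; aKG <- y[[3L]]; ATPc <- y[[4L]]
    ATPm <- y[[5L]]; CIT <- y[[6L]]; FUM <- y[[7L]]; ISOC <- y[[8L]]
    MAL <- y[[9L]]; NAD <- y[[10L]]; NADH <- y[[11L]]; OAA <- y[[12L]]
    SCoA <- y[[13L]]; SUC <- y[[14L]]; Cac <- y[[15L]]; Cam <- y[[16L]]
    CaER <- y[[17L]]; DPsi <- y[[18L]]

    # --- calcium exchanges and cytosolic ATP hydrolysis (cytosolic volume)
    J_ERout <- (p$Vmax_IP3R * ip3_gate *
                  Cac^2 / (Cac^2 + p$K_a_Cac^2) *
                  p$K_i_Ca^4 / (p$K_i_Ca^4 + Cac^4) +
                  p$V_LEAK) * (CaER - Cac) / geom$gamma
    serca_gate <- Cac^2 / (Cac^2 + p$K_Ca^2)
    J_SERCA <- if (coupled) {
      p$Vmax_SERCA * serca_gate * ATPc / (ATPc + p$K_ATPc)
    } else {
      p$Vmax_SERCA * serca_gate
    }
    J_Hyd <- p$k_Hyd * ATPc / (ATPc + p$K_M_ATPc)

    # --- mitochondrial Ca2+ transport
    x_uni <- 2 * (DPsi - p$DeltaPsi_star) * FoRT
    ctr <- Cac / p$K_trans
    J_UNI <- p$Vmax_UNI * .bernoulli_factor(x_uni) *
      ctr * (1 + ctr)^3 /
      ((1 + ctr)^4 + p$L_uni / (1 + Cac / p$K_act)^p$n_a)
    J_NCX <- p$Vmax_NCX * .gexp(p$b_NCX * (DPsi - p$DeltaPsi_star) * FoRT) *
      (Cam / max(Cac, 1e-12)) / (na_term * (1 + p$K_M_Ca / Cam))
    if (Cam == 0) J_NCX <- 0

    # --- oxidative phosphorylation (Magnus-Keizer 6-state reductions)
    Ares <- if (p$ares_sqrt) p$K_res * sqrt(NADH / NAD) else p$K_res * NADH / NAD
    eg6 <- .gexp(p$g_Ox * 6 * DPsi * FoRT)
    J_Ox <- ox_pref * p$rho_res *
      ((p$ra * pH_fac + p$rc1 * eB6) * Ares - p$ra * eg6 + p$rc2 * Ares * eg6) /
      ((1 + p$r1 * Ares) * eB6 + (p$r2 + p$r3 * Ares) * eg6)
    AF1 <- p$K_F1 * ATPm / (ADPm * ctrl$Pi_m)
    e3 <- .gexp(3 * DPsi * FoRT)
    J_F1 <- -p$rho_f1 *
      ((p$pa * pH_fac3 + p$pc1 * eB3) * AF1 - p$pa * e3 + p$pc2 * AF1 * e3) /
      ((1 + p$p1 * AF1) * eB3 + (p$p2 + p$p3 * AF1) * e3)

    # --- TCA cycle
    J_CS <- p$Vmax_CS /
      (1 + p$K_M_AcCoA / ctrl$AcCoA +
         (p$K_M_OAA_CS / OAA) * (1 + ctrl$AcCoA / p$K_i_AcCoA) +
         p$K_s_AcCoA * p$K_M_OAA_CS / (OAA * ctrl$AcCoA))
    J_ACO <- p$kf_ACO * (CIT - ISOC / p$K_ACO)
    act_IDH <- (1 + ADPm / p$K_a_ADP) * (1 + Cam / p$K_a_Cam)
    isoc_term <- (p$K_M_ISOC / ISOC)^p$n_i
    nad_term_idh <- (p$K_M_NAD_IDH / NAD) * (1 + NADH / p$K_i_NADH)
    J_IDH <- p$Vmax_IDH /
      (1 + ctrl$H_m / p$k_h_1 + p$k_h_2 / ctrl$H_m +
         isoc_term / act_IDH + nad_term_idh +
         isoc_term * nad_term_idh / act_IDH)
    act_KGDH <- (1 + ctrl$Mg_m / p$K_D_Mg) * (1 + Cam / p$K_D_Ca)
    nad_term_kgdh <- (p$K_M_NAD_KGDH / NAD)^p$n_aKG
    J_KGDH <- if (kgdh_additive) {
      p$Vmax_KGDH / (1 + p$K_M_aKG / aKG + nad_term_kgdh / act_KGDH)
    } else {
      p$Vmax_KGDH / (1 + (p$K_M_aKG / aKG) * nad_term_kgdh / act_KGDH)
    }
    J_SL <- p$kf_SL * (SCoA * ADPm * ctrl$Pi_m - SUC * ATPm * ctrl$CoA / p$K_SL)
    J_SDH <- p$Vmax_SDH /
      (1 + (p$K_M_SUC / SUC) * (1 + OAA / p$K_i_OAA) * (1 + FUM / p$K_i_FUM))
    J_FH <- p$kf_FH * (FUM - MAL / p$K_FH)
    J_MDH <- p$Vmax_MDH * (MAL * NAD - OAA * NADH / p$K_MDH) /
      ((1 + MAL / p$K_M_MAL) * (1 + NAD / p$K_M_NAD_MDH) +
         (1 + OAA / p$K_M_OAA_MDH) * (1 + NADH / p$K_M_NADH) - 1)

    # --- other exchanges
    emf <- .gexp(-p$f_ANT * DPsi * FoRT)
    em1 <- .gexp(-DPsi * FoRT)
    ATP4c <- 0.05 * ATPc; ATP4m <- 0.05 * ATPm
    ADP3c <- 0.45 * ADPc; ADP3m <- 0.36 * ADPm
    J_ANT <- p$Vmax_ANT * (ADP3c * ATP4m - ATP4c * ADP3m * em1) /
      ((ADP3c + ATP4c * emf) * (ATP4m + ADP3m))
    J_Hl <- p$g_H * (DPsi - hl_zero)

    c(ERout = J_ERout, SERCA = J_SERCA, NCX = J_NCX, UNI = J_UNI,
      Hyd = J_Hyd, Ox = J_Ox, F1 = J_F1, CS = J_CS, ACO = J_ACO,
      IDH = J_IDH, KGDH = J_KGDH, SL = J_SL, SDH = J_SDH, FH = J_FH,
      MDH = J_MDH, ANT = J_ANT, Hl = J_Hl)
  }

  half_serca <- if (coupled) 0.5 else 0
  deriv <- function(t, y, parms = NULL) {
    J <- fluxes(y)
    dy <- c(
      -geom$delta * J[[16L]] + J[[5L]] + half_serca * J[[2L]],     # ADPc
      J[[16L]] - J[[7L]] - J[[12L]],                               # ADPm
      J[[10L]] - J[[11L]],                                         # aKG
      geom$delta * J[[16L]] - J[[5L]] - half_serca * J[[2L]],      # ATPc
      -J[[16L]] + J[[7L]] + J[[12L]],                              # ATPm
      J[[8L]] - J[[9L]],                                           # CIT
      J[[13L]] - J[[14L]],                                         # FUM
      J[[9L]] - J[[10L]],                                          # ISOC
      J[[14L]] - J[[15L]],                                         # MAL
      J[[6L]] - J[[10L]] - J[[11L]] - J[[15L]],                    # NAD
      -J[[6L]] + J[[10L]] + J[[11L]] + J[[15L]],                   # NADH
      J[[15L]] - J[[8L]],                                          # OAA
      J[[11L]] - J[[12L]],                                         # SCoA
      J[[12L]] - J[[13L]],                                         # SUC
      geom$f_c * geom$gamma *
        (-J[[2L]] + J[[1L]] + geom$delta * (J[[3L]] - J[[4L]])),   # Cac
      geom$f_m * geom$gamma * (J[[4L]] - J[[3L]]),                 # Cam
      geom$f_ER * geom$gamma / geom$alpha * (J[[2L]] - J[[1L]]),   # CaER
      (10 * J[[6L]] - 3 * J[[7L]] - J[[16L]] - J[[17L]] -
         J[[3L]] - 2 * J[[4L]]) / geom$C_m                         # DPsi
    )
    list(dy)
  }

  list(fluxes = fluxes, deriv = deriv)
}

.check_state <- function(state) {
  if (length(state) != 18L) stop("state must have 18 entries", call. = FALSE)
  if (is.null(names(state))) names(state) <- state_names()
  state <- state[state_names()]
  if (anyNA(state)) stop("state contains NA", call. = FALSE)
  # integrator round-off can leave marginal negatives; clamp them
  tiny <- state[1:17] < 0 & state[1:17] > -1e-9
  state[1:17][tiny] <- 0
  if (any(state[1:17] < 0)) {
    stop("negative concentration(s): ",
         paste(names(state)[1:17][state[1:17] < 0], collapse = ", "),
         call. = FALSE)
  }
  state
}

#' Evaluate all 17 reaction rates at a state
#'
#' @param state named numeric state vector (see [state_names()])
#' @inheritParams validate_model_inputs
#' @return tibble with columns `reaction`, `flux` (mM/s) and `ref_volume`.
#' @export
#' @examples
#' mito_fluxes(default_initial_state())
mito_fluxes <- function(state, p = mito_parameters(), ctrl = mito_controls(),
                        geom = mito_geometry()) {
  state <- .check_state(state)
  J <- build_model(p, ctrl, geom)$fluxes(unname(state))
  tibble::tibble(reaction = names(J), flux = unname(J),
                 ref_volume = unname(flux_reference_volumes()[names(J)]))
}

.flux_subset <- function(state, p, ctrl, geom, keep) {
  res <- mito_fluxes(state, p, ctrl, geom)
  res[match(keep, res$reaction), ]
}

#' TCA-cycle reaction rates
#'
#' The eight matrix-enzyme rates (citrate synthase through malate
#' dehydrogenase), including the Ca2+ activation of isocitrate and
#' alpha-ketoglutarate dehydrogenase.
#'
#' @inheritParams mito_fluxes
#' @return tibble of the CS, ACO, IDH, KGDH, SL, SDH, FH, MDH rows.
#' @export
tca_fluxes <- function(state, p = mito_parameters(), ctrl = mito_controls(),
                       geom = mito_geometry()) {
  .flux_subset(state, p, ctrl, geom,
               c("CS", "ACO", "IDH", "KGDH", "SL", "SDH", "FH", "MDH"))
}

#' Oxidative phosphorylation rates
#'
#' Respiration (Ox: NADH oxidation pumping 10 H+ per event) and the
#' F1F0-ATPase (F1: positive = ATP synthesis, 3 H+ re-entering per event),
#' from the Magnus-Keizer six-state reductions.
#'
#' @inheritParams mito_fluxes
#' @return tibble of the Ox and F1 rows.
#' @export
oxphos_fluxes <- function(state, p = mito_parameters(), ctrl = mito_controls(),
                          geom = mito_geometry()) {
  s <- .check_state(state)
  if (s[["NAD"]] <= 0 || s[["ADPm"]] <= 0) {
    stop("oxphos rates need [NAD]m > 0 and [ADP]m > 0", call. = FALSE)
  }
  .flux_subset(state, p, ctrl, geom, c("Ox", "F1"))
}

#' Mitochondrial membrane transport rates
#'
#' Adenine nucleotide translocator, Ca2+ uniporter, Na+/Ca2+ exchanger and
#' the proton leak. The uniporter's voltage factor is continuous through
#' its removable singularity at `DeltaPsi_star`.
#'
#' @inheritParams mito_fluxes
#' @return tibble of the ANT, UNI, NCX, Hl rows.
#' @export
membrane_transport_fluxes <- function(state, p = mito_parameters(),
                                      ctrl = mito_controls(),
                                      geom = mito_geometry()) {
  .flux_subset(state, p, ctrl, geom, c("ANT", "UNI", "NCX", "Hl"))
}

#' ER Ca2+ exchange and cytosolic ATP consumption rates
#'
#' IP3-receptor/leak release from the ER, SERCA uptake (2 Ca2+ per ATP),
#' and ATP hydrolysis by bulk cellular activity.
#'
#' @inheritParams mito_fluxes
#' @return tibble of the ERout, SERCA, Hyd rows.
#' @export
signaling_and_hydrolysis_fluxes <- function(state, p = mito_parameters(),
                                            ctrl = mito_controls(),
                                            geom = mito_geometry()) {
  .flux_subset(state, p, ctrl, geom, c("ERout", "SERCA", "Hyd"))
}

#' Time derivatives of the 18 state variables
#'
#' The rate equations, including the half-SERCA stoichiometric ATP cost
#' (2 Ca2+ transported per ATP), the volume ratios and free-Ca2+ fractions
#' in the Ca2+ equations, and the charge balance
#' `dPsi/dt = (10 J_Ox - 3 J_F1 - J_ANT - J_Hl - J_NCX - 2 J_UNI) / C_m`.
#'
#' @inheritParams mito_fluxes
#' @return named numeric vector of d(state)/dt.
#' @export
time_derivatives <- function(state, p = mito_parameters(),
                             ctrl = mito_controls(), geom = mito_geometry()) {
  state <- .check_state(state)
  dy <- build_model(p, ctrl, geom)$deriv(0, unname(state))[[1]]
  names(dy) <- state_names()
  dy
}
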