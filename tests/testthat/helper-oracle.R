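# Independent transcription of the 17 rate laws, kept deliberately separate
# from the package implementation (different structure: one function per
# reaction over a named state list). Used to cross-check the implementation
# on random states.

oracle_fluxes <- function(s, p, ctrl, geom) {
  RT <- geom$R * geom$T
  FoRT <- geom$F / RT
  with(as.list(c(s)), {
    erout_rate <- p$Vmax_IP3R *
      (ctrl$IP3^2 / (ctrl$IP3^2 + p$K_a_IP3^2)) *
      (Cac^2 / (Cac^2 + p$K_a_Cac^2)) *
      (p$K_i_Ca^4 / (p$K_i_Ca^4 + Cac^4)) + p$V_LEAK
    ERout <- erout_rate * (CaER - Cac) / geom$gamma

    SERCA <- p$Vmax_SERCA * Cac^2 / (Cac^2 + p$K_Ca^2)
    if (isTRUE(p$serca_coupled)) SERCA <- SERCA * ATPc / (ATPc + p$K_ATPc)

    Hyd <- p$k_Hyd * ATPc / (ATPc + p$K_M_ATPc)

    x <- 2 * FoRT * (DPsi - p$DeltaPsi_star)
    vfac <- if (abs(x) < 1e-4) 1 + x / 2 + x^2 / 12 else x / (1 - exp(-x))
    r <- Cac / p$K_trans
    UNI <- p$Vmax_UNI * vfac * r * (1 + r)^3 /
      ((1 + r)^4 + p$L_uni * (1 + Cac / p$K_act)^(-p$n_a))

    NCX <- p$Vmax_NCX * exp(p$b_NCX * FoRT * (DPsi - p$DeltaPsi_star)) *
      (Cam / Cac) /
      ((1 + p$K_M_Na / ctrl$Na_c)^p$n_Na * (1 + p$K_M_Ca / Cam))

    Ares <- if (isTRUE(p$ares_sqrt)) p$K_res * sqrt(NADH / NAD)
            else p$K_res * NADH / NAD
    a <- exp(6 * FoRT * p$DeltaPsi_B)
    b <- exp(p$g_Ox * 6 * FoRT * DPsi)
    pref <- if (isTRUE(p$ox_half)) 0.5 else 1
    Ox <- pref * p$rho_res *
      ((p$ra * 10^(6 * ctrl$DeltapH) + p$rc1 * a) * Ares -
         p$ra * b + p$rc2 * Ares * b) /
      ((1 + p$r1 * Ares) * a + (p$r2 + p$r3 * Ares) * b)

    AF1 <- p$K_F1 * ATPm / (ADPm * ctrl$Pi_m)
    a3 <- exp(3 * FoRT * p$DeltaPsi_B)
    b3 <- exp(3 * FoRT * DPsi)
    F1 <- -p$rho_f1 *
      ((p$pa * 10^(3 * ctrl$DeltapH) + p$pc1 * a3) * AF1 -
         p$pa * b3 + p$pc2 * AF1 * b3) /
      ((1 + p$p1 * AF1) * a3 + (p$p2 + p$p3 * AF1) * b3)

    CS <- p$Vmax_CS / (1 + p$K_M_AcCoA / ctrl$AcCoA +
                         (p$K_M_OAA_CS / OAA) * (1 + ctrl$AcCoA / p$K_i_AcCoA) +
                         p$K_s_AcCoA * p$K_M_OAA_CS / (OAA * ctrl$AcCoA))
    ACO <- p$kf_ACO * (CIT - ISOC / p$K_ACO)

    fa <- (1 + ADPm / p$K_a_ADP) * (1 + Cam / p$K_a_Cam)
    ti <- (p$K_M_ISOC / ISOC)^p$n_i
    tn <- (p$K_M_NAD_IDH / NAD) * (1 + NADH / p$K_i_NADH)
    IDH <- p$Vmax_IDH / (1 + ctrl$H_m / p$k_h_1 + p$k_h_2 / ctrl$H_m +
                           ti / fa + tn + ti * tn / fa)

    fk <- (1 + ctrl$Mg_m / p$K_D_Mg) * (1 + Cam / p$K_D_Ca)
    nk <- (p$K_M_NAD_KGDH / NAD)^p$n_aKG
    KGDH <- if (identical(p$kgdh_form, "additive")) {
      p$Vmax_KGDH / (1 + p$K_M_aKG / aKG + nk / fk)
    } else {
      p$Vmax_KGDH / (1 + (p$K_M_aKG / aKG) * nk / fk)
    }

    SL <- p$kf_SL * (SCoA * ADPm * ctrl$Pi_m -
                       SUC * ATPm * ctrl$CoA / p$K_SL)
    SDH <- p$Vmax_SDH / (1 + (p$K_M_SUC / SUC) *
                           (1 + OAA / p$K_i_OAA) * (1 + FUM / p$K_i_FUM))
    FH <- p$kf_FH * (FUM - MAL / p$K_FH)
    MDH <- p$Vmax_MDH * (MAL * NAD - OAA * NADH / p$K_MDH) /
      ((1 + MAL / p$K_M_MAL) * (1 + NAD / p$K_M_NAD_MDH) +
         (1 + OAA / p$K_M_OAA_MDH) * (1 + NADH / p$K_M_NADH) - 1)

    num <- 1 - (0.05 * ATPc * 0.36 * ADPm) / (0.05 * ATPm * 0.45 * ADPc) *
      exp(-FoRT * DPsi)
    den <- (1 + (0.05 * ATPc) / (0.45 * ADPc) * exp(-p$f_ANT * FoRT * DPsi)) *
      (1 + (0.36 * ADPm) / (0.05 * ATPm))
    ANT <- p$Vmax_ANT * num / den

    Hl <- p$g_H * (DPsi - 2.303 * RT * ctrl$DeltapH / geom$F)

    c(ERout = ERout, SERCA = SERCA, NCX = NCX, UNI = UNI, Hyd = Hyd,
      Ox = Ox, F1 = F1, CS = CS, ACO = ACO, IDH = IDH, KGDH = KGDH,
      SL = SL, SDH = SDH, FH = FH, MDH = MDH, ANT = ANT, Hl = Hl)
  })
}

# random strictly-positive state around the default, reproducible
random_state <- function(p = mito_parameters(), geom = mito_geometry()) {
  s <- default_initial_state(p, geom)
  s[1:17] <- s[1:17] * exp(stats::runif(17, -0.7, 0.7))
  s[["DPsi"]] <- stats::runif(1, 60, 200)
  s
}

# session-level cache for expensive shared computations
.camito_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .camito_cache)) {
    assign(key, force(expr), envir = .camito_cache)
  }
  get(key, envir = .camito_cache)
}

baseline_steady <- function() {
  cached("baseline_steady", find_steady_state(mito_parameters()))
}
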