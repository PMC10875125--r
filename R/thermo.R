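# Transformed Gibbs energies, entropy production, work decomposition and
# thermodynamic efficiency.
#
# Unit convention for work/EPR: fluxes in mM/s multiplied directly by
# reaction Gibbs energies in J/mol. This is the scale on which the model's
# total dissipation is reported (the saturating value at strong stimulation
# is ~2.66e4); the SI-strict value in W/L is this divided by 1e3 (mM -> M),
# and is exported alongside as `Tsigma_SI`.

#' Thermodynamic constants
#'
#' Gas constant, temperature, Faraday constant, the standard transformed
#' Gibbs energies of reaction (J/mol, at compartmental pH, ionic strength
#' 0.12 M and pMg 3.4), the pseudoisomer fractions of the adenine
#' nucleotides and the transmembrane pH difference.
#'
#' @param ... named overrides.
#' @return named list of class `thermo_constants`.
#' @export
thermo_constants <- function(...) {
  tc <- list(
    R = 8.314, T = 310, F = 96.485,
    DrG0_ACO   = 6700,
    DrG0_CS    = -41200,
    DrG0_FH    = -3400,
    DrG0_Hyd_c = -28300,   # cytosolic pH 7.2
    DrG0_Hyd_m = -32200,   # mitochondrial pH 8.0
    DrG0_IDH   = 5100,
    DrG0_KGDH  = -27600,
    DrG0_MDH   = 24200,
    DrG0_Ox    = -225300,
    DrG0_SDH   = -24200,
    DrG0_SL    = 800,
    frac_ATP4_c = 0.05, frac_ATP4_m = 0.05,
    frac_ADP3_c = 0.45, frac_ADP3_m = 0.36,
    DeltapH = -0.80,
    # phosphate pool entering the output effective-reaction force
    # ("cytosolic": r1out is the exact reverse of cytosolic hydrolysis;
    #  "matrix": phosphate taken from the matrix pool as in Eq r1out's
    #  mass balance)
    r1out_phosphate = "cytosolic"
  )
  apply_overrides(tc, list(...), "thermo_constants")
}

#' Names of the 11 internal reactions
#'
#' The mitochondrial engine's internal reaction set: nucleotide exchange,
#' OXPHOS and the eight TCA-cycle steps. Entropy production of the engine
#' is summed over exactly this set.
#'
#' @return character vector.
#' @export
internal_reactions <- function() {
  c("ANT", "F1", "Ox", "CS", "ACO", "IDH", "KGDH", "SL", "SDH", "FH", "MDH")
}

# vectorized Gibbs energies over a state matrix; returns matrix (n x 17)
.gibbs_matrix <- function(Y, ctrl, tc) {
  RT <- tc$R * tc$T
  Fv <- tc$F
  ln <- function(x) log(pmax(x, 0))
  ADPc <- Y[, 1]; ADPm <- Y[, 2]; aKG <- Y[, 3]; ATPc <- Y[, 4]
  ATPm <- Y[, 5]; CIT <- Y[, 6]; FUM <- Y[, 7]; ISOC <- Y[, 8]
  MAL <- Y[, 9]; NAD <- Y[, 10]; NADH <- Y[, 11]; OAA <- Y[, 12]
  SCoA <- Y[, 13]; SUC <- Y[, 14]; Cac <- Y[, 15]; Cam <- Y[, 16]
  CaER <- Y[, 17]; DPsi <- Y[, 18]

  out <- cbind(
    ERout = RT * ln(Cac / CaER),
    SERCA = tc$DrG0_Hyd_c +
      RT * ln(ADPc * ctrl$Pi_c * CaER^2 / (ATPc * Cac^2)),
    NCX = RT * ln(Cac * ctrl$Na_m^3 / (Cam * ctrl$Na_c^3)) - Fv * DPsi,
    UNI = RT * ln(Cam / Cac) - 2 * Fv * DPsi,
    Hyd = tc$DrG0_Hyd_c + RT * ln(ADPc * ctrl$Pi_c / ATPc),
    Ox = tc$DrG0_Ox +
      RT * ln(ctrl$H_c^10 * NAD / (ctrl$H_m^10 * NADH * ctrl$O2^0.5)) +
      10 * Fv * DPsi,
    F1 = -tc$DrG0_Hyd_m +
      RT * ln(ctrl$H_m^3 * ATPm / (ctrl$H_c^3 * ADPm * ctrl$Pi_m)) -
      3 * Fv * DPsi,
    CS = tc$DrG0_CS + RT * ln(CIT * ctrl$CoA / (OAA * ctrl$AcCoA)),
    ACO = tc$DrG0_ACO + RT * ln(ISOC / CIT),
    IDH = tc$DrG0_IDH + RT * ln(aKG * ctrl$CO2 * NADH / (ISOC * NAD)),
    KGDH = tc$DrG0_KGDH +
      RT * ln(SCoA * NADH * ctrl$CO2 / (aKG * NAD * ctrl$CoA)),
    SL = tc$DrG0_SL +
      RT * ln(SUC * ctrl$CoA * ATPm / (SCoA * ADPm * ctrl$Pi_m)),
    SDH = tc$DrG0_SDH + RT * ln(FUM * ctrl$CoQH2 / (SUC * ctrl$CoQ)),
    FH = tc$DrG0_FH + RT * ln(MAL / FUM),
    MDH = tc$DrG0_MDH + RT * ln(OAA * NADH / (NAD * MAL)),
    ANT = RT * ln((tc$frac_ATP4_c * ATPc) * (tc$frac_ADP3_m * ADPm) /
                    ((tc$frac_ATP4_m * ATPm) * (tc$frac_ADP3_c * ADPc))) -
      Fv * DPsi,
    Hl = RT * ln(ctrl$H_m / ctrl$H_c) - Fv * DPsi
  )
  out[, flux_names(), drop = FALSE]
}

#' Transformed Gibbs energies of reaction at a state
#'
#' Evaluates all 17 reaction forces, including the membrane-potential terms
#' of the electrogenic processes (ANT, NCX, UNI, Hl, F1, Ox) and the
#' pseudoisomer fractions entering the translocator force. Concentrations
#' are used on the model's mM scale (Ca2+ enters only as ratios).
#'
#' @inheritParams mito_fluxes
#' @param tc thermodynamic constants from [thermo_constants()]
#' @return tibble with columns `reaction` and `DrG` (J/mol). A
#'   zero concentration in a logarithm yields a signed infinity and a
#'   warning, never a silent NaN.
#' @export
#' @examples
#' reaction_gibbs(default_initial_state())
reaction_gibbs <- function(state, ctrl = mito_controls(),
                           tc = thermo_constants()) {
  state <- .check_state(state)
  g <- .gibbs_matrix(matrix(unname(state), nrow = 1), ctrl, tc)[1, ]
  if (any(!is.finite(g))) {
    warning("nonpositive concentration in a force logarithm: ",
            paste(names(g)[!is.finite(g)], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(reaction = names(g), DrG = unname(g))
}

#' Per-reaction entropy production rates
#'
#' `T * sigma_dot_k = -J_k * DrG_k` for each of the 17 processes, in the
#' model's volumetric convention (mM/s times J/mol).
#'
#' @inheritParams reaction_gibbs
#' @inheritParams mito_fluxes
#' @return tibble: `reaction`, `flux`, `DrG`, `Tsigma` and the second-law
#'   flag `feasible = (Tsigma >= 0)`.
#' @export
reaction_epr <- function(state, p = mito_parameters(), ctrl = mito_controls(),
                         geom = mito_geometry(), tc = thermo_constants()) {
  J <- mito_fluxes(state, p, ctrl, geom)
  G <- reaction_gibbs(state, ctrl, tc)
  dplyr::mutate(dplyr::left_join(J[, c("reaction", "flux")], G,
                                 by = "reaction"),
                Tsigma = -.data$flux * .data$DrG,
                feasible = .data$Tsigma >= -1e-9)
}

#' Total entropy production rate of the mitochondrial engine
#'
#' Sum of `-J_k * DrG_k` over the 11 internal reactions.
#'
#' @param fluxes named flux vector (mM/s) or tibble from [mito_fluxes()]
#' @param gibbs named force vector (J/mol) or tibble from [reaction_gibbs()]
#' @return scalar `T*sigma_dot` in the model's volumetric convention.
#' @export
total_epr <- function(fluxes, gibbs) {
  J <- if (is.data.frame(fluxes)) stats::setNames(fluxes$flux, fluxes$reaction) else fluxes
  G <- if (is.data.frame(gibbs)) stats::setNames(gibbs$DrG, gibbs$reaction) else gibbs
  ir <- internal_reactions()
  -sum(G[ir] * J[ir])
}

#' Exchange currents of the force species
#'
#' The two currents through which the engine exchanges free energy with its
#' surroundings, in the mitochondrial reference volume:
#' `I_ATPc = (-J_Hyd - J_SERCA/2) / delta` (the SERCA term is absent in the
#' uncoupled-pump variant) and `I_Hc = 3 J_F1 - 10 J_Ox`.
#'
#' @inheritParams total_epr
#' @inheritParams validate_model_inputs
#' @return named numeric vector `c(I_ATPc=, I_Hc=)` (mM/s).
#' @export
exchange_currents <- function(fluxes, geom = mito_geometry(),
                              p = mito_parameters()) {
  J <- if (is.data.frame(fluxes)) stats::setNames(fluxes$flux, fluxes$reaction) else fluxes
  half <- if (isTRUE(p$serca_coupled)) 0.5 else 0
  c(I_ATPc = unname((-J[["Hyd"]] - half * J[["SERCA"]]) / geom$delta),
    I_Hc = unname(3 * J[["F1"]] - 10 * J[["Ox"]]))
}

# effective-reaction forces from the cycle-weighted reaction forces
.effective_forces <- function(G) {
  tca <- G[c("CS", "ACO", "IDH", "KGDH", "SL", "SDH", "FH", "MDH")]
  DrG_TCA <- sum(tca)
  c(r1 = unname(G[["ANT"]] + 10 / 11 * G[["F1"]] + 3 / 11 * G[["Ox"]] +
                  DrG_TCA / 11),
    r2 = unname(-G[["F1"]] / 33 + G[["Ox"]] / 11 + DrG_TCA / 33))
}

# force of the output effective reaction (cytosolic ATP synthesis)
.r1out_force <- function(state, ctrl, tc) {
  RT <- tc$R * tc$T
  Pi <- if (identical(tc$r1out_phosphate, "matrix")) ctrl$Pi_m else ctrl$Pi_c
  -tc$DrG0_Hyd_c + RT * log(state[["ATPc"]] / (state[["ADPc"]] * Pi))
}

#' Instantaneous work ledger at a state
#'
#' Assembles the engine's free-energy bookkeeping at one state: the two
#' exchange currents, the effective-reaction forces (cycle-weighted sums of
#' the reaction forces), the output/input split of the first effective
#' reaction (`r1out`: cytosolic ATP synthesis from ADPc and matrix
#' phosphate; `r1in = r1 - r1out` by construction, so the split is exact),
#' the three nonconservative work rates, their sum, the total entropy
#' production rate and the instantaneous efficiency.
#'
#' @inheritParams reaction_epr
#' @return one-row tibble with columns `I_ATPc`, `I_Hc`, `DrG_r1`,
#'   `DrG_r2`, `DrG_r1out`, `DrG_r1in`, `w_r1out`, `w_r1in`, `w_r2`,
#'   `w_nc`, `Tsigma`, `Tsigma_SI`, `eta`.
#' @export
work_ledger <- function(state, p = mito_parameters(), ctrl = mito_controls(),
                        geom = mito_geometry(), tc = thermo_constants()) {
  state <- .check_state(state)
  J <- stats::setNames(mito_fluxes(state, p, ctrl, geom)$flux, flux_names())
  G <- stats::setNames(reaction_gibbs(state, ctrl, tc)$DrG, flux_names())
  I <- exchange_currents(J, geom, p)
  eff <- .effective_forces(G)
  r1out <- .r1out_force(state, ctrl, tc)
  w_r1out <- r1out * I[["I_ATPc"]]
  w_r1in <- (eff[["r1"]] - r1out) * I[["I_ATPc"]]
  w_r2 <- eff[["r2"]] * I[["I_Hc"]]
  Ts <- total_epr(J, G)
  den <- w_r1in + w_r2
  tibble::tibble(
    I_ATPc = I[["I_ATPc"]], I_Hc = I[["I_Hc"]],
    DrG_r1 = eff[["r1"]], DrG_r2 = eff[["r2"]],
    DrG_r1out = r1out, DrG_r1in = eff[["r1"]] - r1out,
    w_r1out = w_r1out, w_r1in = w_r1in, w_r2 = w_r2,
    w_nc = w_r1out + w_r1in + w_r2,
    Tsigma = Ts, Tsigma_SI = Ts / 1e3,
    eta = if (den > 0) -w_r1out / den else NA_real_
  )
}

# instantaneous ledger columns along a sampled trajectory (vectorized)
.ledger_series <- function(traj, p, ctrl, geom, tc) {
  Y <- as.matrix(traj[, state_names()])
  G <- .gibbs_matrix(Y, ctrl, tc)
  Jm <- as.matrix(traj[, flux_names()])
  half <- if (isTRUE(p$serca_coupled)) 0.5 else 0
  I_ATPc <- (-Jm[, "Hyd"] - half * Jm[, "SERCA"]) / geom$delta
  I_Hc <- 3 * Jm[, "F1"] - 10 * Jm[, "Ox"]
  tca <- rowSums(G[, c("CS", "ACO", "IDH", "KGDH", "SL", "SDH", "FH", "MDH")])
  r1 <- G[, "ANT"] + 10 / 11 * G[, "F1"] + 3 / 11 * G[, "Ox"] + tca / 11
  r2 <- -G[, "F1"] / 33 + G[, "Ox"] / 11 + tca / 33
  RT <- tc$R * tc$T
  Pi <- if (identical(tc$r1out_phosphate, "matrix")) ctrl$Pi_m else ctrl$Pi_c
  r1out <- -tc$DrG0_Hyd_c + RT * log(Y[, 4] / (Y[, 1] * Pi))
  ir <- internal_reactions()
  Tsig <- -rowSums(Jm[, ir] * G[, ir])
  w_r1out <- r1out * I_ATPc
  w_r1in <- (r1 - r1out) * I_ATPc
  w_r2 <- r2 * I_Hc
  tibble::tibble(time = traj$time, I_ATPc = I_ATPc, I_Hc = I_Hc,
                 w_r1out = w_r1out, w_r1in = w_r1in, w_r2 = w_r2,
                 w_nc = w_r1out + w_r1in + w_r2, Tsigma = Tsig)
}

.trapz_mean <- function(t, x) {
  dt <- diff(t)
  sum(dt * (x[-1] + x[-length(x)]) / 2) / (t[length(t)] - t[1])
}

# trapezoidal mean over [a, b] with linear interpolation at the endpoints,
# so averaging windows can end exactly at (refined) peak times
.trapz_window <- function(t, x, a, b) {
  a <- max(a, t[1])
  b <- min(b, t[length(t)])
  xi <- stats::approx(t, x, xout = c(a, b))$y
  keep <- t > a & t < b
  tt <- c(a, t[keep], b)
  xx <- c(xi[1], x[keep], xi[2])
  dt <- diff(tt)
  sum(dt * (xx[-1] + xx[-length(xx)]) / 2) / (b - a)
}

#' Period-averaged driving work rate
#'
#' The driving work over one period is the residual of the second law once
#' the nonconservative work is subtracted from the dissipation:
#' `w_driv = (1/t_p) * integral(Tsigma - w_nc) dt` over an integer number
#' of periods (the internal Gibbs energy is a state function, so its
#' variation integrates to zero). Applied to a steady-state window the
#' result is zero to integration tolerance.
#'
#' @param traj a `mito_trajectory` containing the averaging window
#' @param summary the matching [classify_and_measure()] result (its
#'   `window` element defines the integer-period span)
#' @inheritParams work_ledger
#' @return scalar `w_driv` in the volumetric convention.
#' @export
driving_work_over_period <- function(traj, summary, p = mito_parameters(),
                                     ctrl = mito_controls(),
                                     geom = mito_geometry(),
                                     tc = thermo_constants()) {
  if (!inherits(summary, "oscillation_summary")) {
    stop("`summary` must come from classify_and_measure()", call. = FALSE)
  }
  if (identical(summary$regime, "transient")) {
    stop("driving work is only defined on a classified attractor",
         call. = FALSE)
  }
  ls <- .ledger_series(traj, p, ctrl, geom, tc)
  .trapz_window(ls$time, ls$Tsigma - ls$w_nc,
                summary$window[1], summary$window[2])
}

#' Period-averaged work ledger
#'
#' Averages every work-ledger component over an integer number of periods
#' (trapezoidal rule) and computes the period-averaged efficiency with the
#' numerator and denominator integrated separately; the driving work enters
#' the denominator as the free energy supplied by the time-dependent
#' driving.
#'
#' @inheritParams driving_work_over_period
#' @return one-row tibble matching [work_ledger()] plus `w_driv`.
#' @export
period_work_ledger <- function(traj, summary, p = mito_parameters(),
                               ctrl = mito_controls(), geom = mito_geometry(),
                               tc = thermo_constants()) {
  ls <- .ledger_series(traj, p, ctrl, geom, tc)
  av <- function(x) .trapz_window(ls$time, x,
                                  summary$window[1], summary$window[2])
  w_r1out <- av(ls$w_r1out); w_r1in <- av(ls$w_r1in); w_r2 <- av(ls$w_r2)
  Ts <- av(ls$Tsigma); w_nc <- av(ls$w_nc)
  w_driv <- Ts - w_nc
  den <- w_r1in + w_r2 + w_driv
  tibble::tibble(
    I_ATPc = av(ls$I_ATPc), I_Hc = av(ls$I_Hc),
    DrG_r1 = NA_real_, DrG_r2 = NA_real_,
    DrG_r1out = NA_real_, DrG_r1in = NA_real_,
    w_r1out = w_r1out, w_r1in = w_r1in, w_r2 = w_r2, w_nc = w_nc,
    Tsigma = Ts, Tsigma_SI = Ts / 1e3,
    eta = if (den > 0) -w_r1out / den else NA_real_,
    w_driv = w_driv
  )
}

#' Thermodynamic efficiency from a work ledger
#'
#' `eta = -w_r1out / (w_r1in + w_r2 + w_driv)`; the driving-work term is
#' zero at steady state. Undefined (NA, with a warning) when the input side
#' is not positive, i.e. the engine is not in a transducing regime.
#'
#' @param ledger one-row tibble from [work_ledger()] or
#'   [period_work_ledger()]
#' @return scalar efficiency in (0, 1) for a transducing engine.
#' @export
efficiency <- function(ledger) {
  w_driv <- if ("w_driv" %in% names(ledger)) ledger$w_driv else 0
  den <- ledger$w_r1in + ledger$w_r2 + w_driv
  if (!is.finite(den) || den <= 0) {
    warning("input work is not positive: efficiency undefined", call. = FALSE)
    return(NA_real_)
  }
  -ledger$w_r1out / den
}

# ledger for one scan point (steady state or averaged limit cycle)
point_ledger <- function(res, p, ctrl, geom, tc = thermo_constants()) {
  if (res$summary$regime == "steady") {
    led <- work_ledger(res$end_state, p, ctrl, geom, tc)
    led$w_driv <- 0
    led
  } else {
    period_work_ledger(res$traj, res$summary, p, ctrl, geom, tc)
  }
}

#' Second-law audit of a state or trajectory
#'
#' Per-reaction sign check of the entropy production: every process of the
#' calibrated model should dissipate (`Tsigma >= 0`). Violations are listed,
#' never dropped.
#'
#' @param x a state vector or a `mito_trajectory`
#' @inheritParams reaction_epr
#' @param path optional file path: the audit is also written there as JSON
#' @return tibble: per reaction, the minimal `Tsigma` encountered and
#'   `feasible`; attribute `pass` is TRUE when all reactions pass.
#' @export
thermo_audit <- function(x, p = mito_parameters(), ctrl = mito_controls(),
                         geom = mito_geometry(), tc = thermo_constants(),
                         path = NULL) {
  if (inherits(x, "mito_trajectory")) {
    Y <- as.matrix(x[, state_names()])
    G <- .gibbs_matrix(Y, ctrl, tc)
    Jm <- as.matrix(x[, flux_names()])
    Ts <- -Jm * G
    out <- tibble::tibble(
      reaction = flux_names(),
      min_Tsigma = apply(Ts, 2, min),
      max_DrG = apply(G, 2, max)
    )
  } else {
    e <- reaction_epr(x, p, ctrl, geom, tc)
    out <- tibble::tibble(reaction = e$reaction, min_Tsigma = e$Tsigma,
                          max_DrG = e$DrG)
  }
  out$feasible <- out$min_Tsigma >= -1e-9
  attr(out, "pass") <- all(out$feasible)
  if (!is.null(path)) {
    jsonlite::write_json(list(pass = all(out$feasible),
                              reactions = as.data.frame(out)),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
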