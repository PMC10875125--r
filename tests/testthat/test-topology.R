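# Stoichiometric topology in exact arithmetic.

sm <- build_stoichiometric_model()
laws <- conservation_laws(sm)
cyc <- emergent_cycles(sm)

test_that("the stoichiometric matrix encodes the reaction catalogue", {
  expect_equal(dim(sm$S), c(24, 11))
  # nucleotide exchange column
  ant <- sm$S[, "ANT"]
  expect_equal(ant[ant != 0],
               c(ATPm = -1, ADPm = 1, ATPc = 1, ADPc = -1)[names(ant[ant != 0])])
  # respiration column carries the half-integer oxygen coefficient
  ox <- sm$S[, "Ox"]
  expect_identical(ox[["O2"]], -0.5)
  expect_identical(ox[["Hm"]], -10)
  expect_identical(ox[["Hc"]], 10)
  expect_identical(ox[["NADH"]], -1)
  expect_identical(ox[["NAD"]], 1)
  expect_identical(ox[["H2Om"]], 1)
  # elemental-moiety balance: adenine, nicotinamide and CoA moieties
  moiety <- function(members) {
    w <- stats::setNames(rep(0, 24), sm$species); w[members] <- 1
    as.numeric(w %*% sm$S)
  }
  expect_equal(moiety(c("ATPm", "ADPm", "ATPc", "ADPc")), rep(0, 11))
  expect_equal(moiety(c("NAD", "NADH")), rep(0, 11))
  expect_equal(moiety(c("AcCoA", "CoA", "SCoA")), rep(0, 11))
})

test_that("conservation-law and cycle spaces have the expected dimensions", {
  expect_equal(laws$n_laws, 13)
  expect_equal(length(laws$unbroken), 3)
  expect_equal(cyc$n_cycles, 2)
  # rank-nullity in exact arithmetic
  rk_S <- camito:::.rref(sm$S_rat)$rank
  expect_equal(rk_S + laws$n_laws, 24)
  SX <- camito:::.rat_submat(sm$S_rat, rows = sm$X_rows)
  expect_equal(camito:::.rref(SX)$rank + cyc$n_cycles, 11)
})

test_that("every law annihilates S and the unbroken laws span the three pools", {
  resid <- laws$L %*% sm$S
  expect_true(all(abs(resid) < 1e-12))
  U <- laws$L[laws$unbroken, , drop = FALSE]
  expect_true(all(U[, sm$exchanged] == 0))
  # the three unbroken pools: mitochondrial adenine, pyridine, TCA carbon
  pools <- rbind(
    adenine = stats::setNames(colnames(U) %in% c("ATPm", "ADPm"), colnames(U)),
    pyridine = colnames(U) %in% c("NAD", "NADH"),
    tca = colnames(U) %in% c("OAA", "CIT", "ISOC", "aKG", "SCoA", "SUC",
                             "FUM", "MAL"))
  storage.mode(pools) <- "double"
  # each pool vector lies in the span of the unbroken basis
  for (i in 1:3) {
    fit <- qr.solve(t(U), pools[i, ])
    expect_equal(as.numeric(t(U) %*% fit), unname(pools[i, ]),
                 tolerance = 1e-10)
  }
})

test_that("cycle generators match the printed fractions exactly", {
  Cn <- cyc$C_rat$num; Cd <- cyc$C_rat$den
  want_r1 <- c(ANT = 1, F1 = 10 / 11, Ox = 3 / 11, CS = 1 / 11, ACO = 1 / 11,
               IDH = 1 / 11, KGDH = 1 / 11, SL = 1 / 11, SDH = 1 / 11,
               FH = 1 / 11, MDH = 1 / 11)
  want_r2 <- c(ANT = 0, F1 = -1 / 33, Ox = 1 / 11, CS = 1 / 33, ACO = 1 / 33,
               IDH = 1 / 33, KGDH = 1 / 33, SL = 1 / 33, SDH = 1 / 33,
               FH = 1 / 33, MDH = 1 / 33)
  expect_identical(Cn[, "r1"] / Cd[, "r1"], want_r1[rownames(Cn)])
  expect_identical(Cn[, "r2"] / Cd[, "r2"], want_r2[rownames(Cn)])
  # S^X annihilates the generators exactly
  SX <- sm$S[sm$X_rows, ]
  expect_true(all(abs(SX %*% cyc$C) < 1e-14))
})

test_that("effective reactions have the printed exact stoichiometries", {
  eff <- cyc$effective
  g <- function(cycle, species) {
    i <- match(species, eff$species)
    eff[[paste0(cycle, "_num")]][i] / eff[[paste0(cycle, "_den")]][i]
  }
  # ATP output: ADPc + Pim -> ATPc + H2Om plus 1/11 of acetyl oxidation
  expect_identical(g("r1", "ATPc"), 1)
  expect_identical(g("r1", "ADPc"), -1)
  expect_identical(g("r1", "Pim"), -1)
  expect_identical(g("r1", "H2Om"), 1)
  expect_identical(g("r1", "O2"), -3 / 22)
  expect_identical(g("r1", "AcCoA"), -1 / 11)
  expect_identical(g("r1", "CoQ"), -1 / 11)
  expect_identical(g("r1", "CoA"), 1 / 11)
  expect_identical(g("r1", "CO2"), 2 / 11)
  expect_identical(g("r1", "CoQH2"), 1 / 11)
  expect_identical(g("r1", "Hc"), 0)
  # proton translocation: Hm -> Hc plus 1/33 of acetyl oxidation
  expect_identical(g("r2", "Hc"), 1)
  expect_identical(g("r2", "Hm"), -1)
  expect_identical(g("r2", "O2"), -1 / 22)
  expect_identical(g("r2", "AcCoA"), -1 / 33)
  expect_identical(g("r2", "CoA"), 1 / 33)
  expect_identical(g("r2", "CO2"), 2 / 33)
  expect_identical(g("r2", "CoQ"), -1 / 33)
  expect_identical(g("r2", "CoQH2"), 1 / 33)
  expect_identical(g("r2", "ATPc"), 0)
  expect_identical(g("r2", "Pim"), 0)
})

test_that("the potential/force split is invertible and counts add up", {
  split <- potential_force_split(laws, sm)
  expect_true(split$invertible)
  expect_setequal(split$Yf, c("ATPc", "Hc"))
  expect_equal(length(sm$exchanged), length(laws$broken) + length(split$Yf))
  # relabeled basis is the identity on the potential species
  expect_equal(unname(split$L_relabeled[, split$Yp]),
               diag(length(split$Yp)), tolerance = 1e-12)
  # an alternative split (ATPc potential, ADPc force) is also valid
  alt <- potential_force_split(
    laws, sm, Yp = c("ATPc", "Pim", "Hm", "O2", "H2Om", "AcCoA", "CoA",
                     "CO2", "CoQ", "CoQH2"))
  expect_true(alt$invertible)
  expect_setequal(alt$Yf, c("ADPc", "Hc"))
})

test_that("the nonconservative work rate is representation independent", {
  # cycles normalized on (ADPc, Hc) generate the same F . I as (ATPc, Hc)
  alt <- emergent_cycles(sm, force_species = c("ADPc", "Hc"))
  p <- mito_parameters(); ctrl <- mito_controls(); geom <- mito_geometry()
  withr::with_seed(5, {
    for (i in 1:5) {
      s <- random_state()
      G <- stats::setNames(reaction_gibbs(s, ctrl)$DrG,
                           reaction_gibbs(s, ctrl)$reaction)
      J <- stats::setNames(mito_fluxes(s, p, ctrl, geom)$flux,
                           mito_fluxes(s, p, ctrl, geom)$reaction)
      I <- exchange_currents(J, geom, p)
      F1v <- as.numeric(G[sm$reactions] %*% cyc$C)       # (r1, r2)
      F2v <- as.numeric(G[sm$reactions] %*% alt$C)
      w1 <- F1v[1] * I[["I_ATPc"]] + F1v[2] * I[["I_Hc"]]
      # I_ADPc = -I_ATPc: ADPc appears with opposite stoichiometry
      w2 <- F2v[1] * (-I[["I_ATPc"]]) + F2v[2] * I[["I_Hc"]]
      expect_equal(w1, w2, tolerance = 1e-10)
    }
  })
})

test_that("cycle-weighted forces equal the exchanged-species assembly", {
  # route A: sum_k c_k DrG_k(state); route B: cycle-weighted standard parts
  # + RT log terms of exchanged species only + net charge term. Equality
  # requires exact cancellation of all internal-species log terms.
  tc <- thermo_constants()
  ctrl <- mito_controls(); p <- mito_parameters(); geom <- mito_geometry()
  RT <- tc$R * tc$T
  g0k <- c(ANT = RT * log((tc$frac_ATP4_c * tc$frac_ADP3_m) /
                            (tc$frac_ATP4_m * tc$frac_ADP3_c)),
           F1 = -tc$DrG0_Hyd_m, Ox = tc$DrG0_Ox, CS = tc$DrG0_CS,
           ACO = tc$DrG0_ACO, IDH = tc$DrG0_IDH, KGDH = tc$DrG0_KGDH,
           SL = tc$DrG0_SL, SDH = tc$DrG0_SDH, FH = tc$DrG0_FH,
           MDH = tc$DrG0_MDH)
  zk <- c(ANT = -1, F1 = -3, Ox = 10, CS = 0, ACO = 0, IDH = 0, KGDH = 0,
          SL = 0, SDH = 0, FH = 0, MDH = 0)
  eff <- cyc$effective
  withr::with_seed(9, {
    for (i in 1:100) {
      s <- random_state()
      conc <- c(ATPc = s[["ATPc"]], ADPc = s[["ADPc"]], Pim = ctrl$Pi_m,
                Hc = ctrl$H_c, Hm = ctrl$H_m, O2 = ctrl$O2, H2Om = 1,
                AcCoA = ctrl$AcCoA, CoA = ctrl$CoA, CO2 = ctrl$CO2,
                CoQ = ctrl$CoQ, CoQH2 = ctrl$CoQH2)
      G <- stats::setNames(reaction_gibbs(s, ctrl, tc)$DrG, flux_names())
      for (cycle in c("r1", "r2")) {
        cvec <- cyc$C[, cycle]
        routeA <- sum(cvec * G[sm$reactions])
        coef <- eff[[cycle]]
        routeB <- sum(cvec * g0k[sm$reactions]) +
          sum(cvec * zk[sm$reactions]) * geom$F * s[["DPsi"]] +
          RT * sum(coef * log(conc[eff$species]))
        expect_equal(routeA, routeB, tolerance = 1e-10)
      }
    }
  })
})

test_that("closed-system trajectories conserve every law", {
  # external exchange off: zero the external reaction rates
  p <- mito_parameters(Vmax_SERCA = 0, Vmax_UNI = 0, Vmax_NCX = 0,
                       Vmax_IP3R = 0, V_LEAK = 0, k_Hyd = 0, g_H = 0)
  tr <- simulate_model(seq(0, 500, by = 50), p = p)
  # unbroken + broken laws restricted to dynamic species reduce to the
  # five conserved pools; check them along the trajectory
  cs <- conserved_sums(as.matrix(tr[, state_names()]), p)
  for (col in names(cs)) {
    expect_lt(diff(range(cs[[col]])) / abs(cs[[col]][1]), 1e-9)
  }
})
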