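# Rate laws and rate equations.

p0 <- mito_parameters()
c0 <- mito_controls()
g0 <- mito_geometry()

flux_of <- function(state, rxn, p = p0, ctrl = c0) {
  J <- mito_fluxes(state, p, ctrl, g0)
  J$flux[J$reaction == rxn]
}

test_that("reversible rate laws vanish exactly at their equilibrium conditions", {
  s <- default_initial_state()
  s[["CIT"]] <- 0.1; s[["ISOC"]] <- p0$K_ACO * 0.1
  expect_identical(flux_of(s, "ACO"), 0)

  s <- default_initial_state()
  s[["FUM"]] <- 0.2; s[["MAL"]] <- p0$K_FH * 0.2
  expect_equal(flux_of(s, "FH"), 0, tolerance = 1e-15)

  s <- default_initial_state()
  s[["CaER"]] <- s[["Cac"]]
  expect_identical(flux_of(s, "ERout"), 0)

  # proton leak crosses zero at the Nernst offset of the pH gradient
  s <- default_initial_state()
  s[["DPsi"]] <- 2.303 * g0$R * g0$T * c0$DeltapH / g0$F
  expect_equal(flux_of(s, "Hl"), 0, tolerance = 1e-18)

  # MDH and SL at their mass-action equilibrium ratios
  s <- default_initial_state()
  s[["OAA"]] <- s[["MAL"]] * s[["NAD"]] * p0$K_MDH / s[["NADH"]]
  expect_equal(flux_of(s, "MDH"), 0, tolerance = 1e-12)
  s <- default_initial_state()
  s[["SUC"]] <- p0$K_SL * s[["SCoA"]] * s[["ADPm"]] * c0$Pi_m /
    (s[["ATPm"]] * c0$CoA)
  expect_equal(flux_of(s, "SL"), 0, tolerance = 1e-12)

  # ANT at the voltage-shifted nucleotide equilibrium
  s <- default_initial_state()
  FoRT <- g0$F / (g0$R * g0$T)
  # choose ATPc so that (ATP4c ADP3m)/(ATP4m ADP3c) = e^{F DPsi/RT}
  s[["ATPc"]] <- exp(FoRT * s[["DPsi"]]) *
    (0.05 * s[["ATPm"]] * 0.45 * s[["ADPc"]]) / (0.36 * s[["ADPm"]]) / 0.05
  expect_equal(flux_of(s, "ANT"), 0, tolerance = 1e-12)
})

test_that("prefactor zeros and saturation limits match the closed forms", {
  s <- default_initial_state()
  expect_identical(flux_of(s, "Ox", p = mito_parameters(rho_res = 0)), 0)
  expect_identical(flux_of(s, "F1", p = mito_parameters(rho_f1 = 0)), 0)

  s[["Cac"]] <- 0
  expect_identical(flux_of(s, "UNI"), 0)

  # half-saturation of bulk hydrolysis: k_Hyd / 2 = 0.045 mM/s
  s <- default_initial_state()
  s[["ATPc"]] <- p0$K_M_ATPc
  expect_equal(flux_of(s, "Hyd"), 0.045, tolerance = 1e-12)

  # SERCA at double half-saturation runs at a quarter of its limiting rate
  s <- default_initial_state()
  s[["Cac"]] <- p0$K_Ca; s[["ATPc"]] <- p0$K_ATPc
  expect_equal(flux_of(s, "SERCA"), p0$Vmax_SERCA / 4, tolerance = 1e-12)
})

test_that("KGDH calcium activation saturates to its analytic limit", {
  s <- default_initial_state()
  s[["Cam"]] <- 1e9
  # product denominator: activation removes the whole saturating term
  expect_equal(flux_of(s, "KGDH"), p0$Vmax_KGDH, tolerance = 1e-4)
  # additive variant: the aKG term survives
  pa <- mito_parameters(kgdh_form = "additive")
  expect_equal(flux_of(s, "KGDH", p = pa),
               pa$Vmax_KGDH / (1 + pa$K_M_aKG / s[["aKG"]]),
               tolerance = 1e-4)
})

test_that("frozen direct-evaluation values reproduce (IDH, Ox, F1)", {
  s <- default_initial_state()
  s[["ISOC"]] <- 0.05; s[["NAD"]] <- 0.64; s[["NADH"]] <- 0.16
  s[["ADPm"]] <- 10; s[["Cam"]] <- 0.2
  expect_equal(flux_of(s, "IDH"), 0.0634620922936715, tolerance = 1e-12)

  s <- default_initial_state()
  s[["DPsi"]] <- 150
  s[["NADH"]] <- 0.2 * s[["NAD"]]            # ratio 0.2 enters A_res
  s[["ATPm"]] <- 5; s[["ADPm"]] <- 10        # A_F1 with Pi_m = 20
  expect_equal(flux_of(s, "Ox"), 0.159875777747621, tolerance = 1e-12)
  expect_equal(flux_of(s, "F1"), 0.271246430236578, tolerance = 1e-12)
})

test_that("the uniporter is continuous through its voltage singularity", {
  s <- default_initial_state()
  s[["Cac"]] <- 0.25
  s[["DPsi"]] <- p0$DeltaPsi_star
  j0 <- flux_of(s, "UNI")
  expect_equal(j0, 0.000147877182018232, tolerance = 1e-12)
  for (eps in c(-1e-6, 1e-6)) {
    s[["DPsi"]] <- p0$DeltaPsi_star + eps
    expect_equal(flux_of(s, "UNI"), j0, tolerance = 1e-6)
  }
})

test_that("fluxes agree with an independently transcribed oracle to 1e-12", {
  withr::with_seed(42, {
    for (i in 1:100) {
      s <- random_state()
      a <- mito_fluxes(s, p0, c0, g0)$flux
      b <- oracle_fluxes(s, p0, c0, g0)
      expect_lt(max(abs(a - b) / pmax(abs(b), 1e-300)), 1e-12)
    }
  })
})

test_that("compiled kernel matches the reference R rate laws to 1e-12", {
  withr::with_seed(7, {
    Y <- t(replicate(50, unname(random_state())))
    a <- camito:::flux_matrix(Y, p0, c0, g0)
    m <- build_model(p0, c0, g0)
    b <- t(apply(Y, 1, m$fluxes))
    expect_lt(max(abs(a - b) / pmax(abs(b), 1e-300)), 1e-12)
  })
})

test_that("rate equations conserve the five pools and match the flux assembly", {
  withr::with_seed(11, {
    for (i in 1:20) {
      s <- random_state()
      d <- time_derivatives(s, p0, c0, g0)
      expect_equal(d[["ATPc"]] + d[["ADPc"]], 0, tolerance = 1e-14)
      expect_equal(d[["ATPm"]] + d[["ADPm"]], 0, tolerance = 1e-12)
      expect_equal(d[["NAD"]] + d[["NADH"]], 0, tolerance = 1e-12)
      tca <- c("CIT", "ISOC", "aKG", "SCoA", "SUC", "FUM", "MAL", "OAA")
      expect_equal(sum(d[tca]), 0, tolerance = 1e-10)
      ca <- d[["Cac"]] / g0$f_c + g0$delta * d[["Cam"]] / g0$f_m +
        g0$alpha * d[["CaER"]] / g0$f_ER
      expect_equal(ca, 0, tolerance = 1e-9)

      # membrane-potential equation is the printed linear charge balance
      J <- with(mito_fluxes(s, p0, c0, g0), stats::setNames(flux, reaction))
      expect_equal(d[["DPsi"]],
                   (10 * J[["Ox"]] - 3 * J[["F1"]] - J[["ANT"]] - J[["Hl"]] -
                      J[["NCX"]] - 2 * J[["UNI"]]) / g0$C_m,
                   tolerance = 1e-10)
    }
  })
  # hand-checked linear combination of a fixed flux vector
  J <- stats::setNames(rep(0, 17), c("ERout", "SERCA", "NCX", "UNI", "Hyd",
                                     "Ox", "F1", "CS", "ACO", "IDH", "KGDH",
                                     "SL", "SDH", "FH", "MDH", "ANT", "Hl"))
  J[c("Ox", "F1", "ANT", "Hl", "NCX", "UNI")] <-
    c(0.1, 0.2, 0.05, 0.01, 0.001, 0.002)
  d <- camito:::.derivatives_from_fluxes(J, p0, g0)
  expect_equal(d[["DPsi"]], 184.878587196, tolerance = 1e-9)
})

test_that("domain violations are rejected explicitly", {
  s <- default_initial_state()
  s[["Cac"]] <- -0.1
  expect_error(mito_fluxes(s), "negative")
  s <- default_initial_state()
  s[["NAD"]] <- 0
  expect_error(oxphos_fluxes(s), "NAD")
  expect_error(mito_parameters(not_a_parameter = 1), "unknown")
  expect_error(validate_model_inputs(mito_parameters(Vmax_SERCA = -1)),
               "negative")
})
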