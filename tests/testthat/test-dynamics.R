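# Integration, classification, period measurement, scans.

test_that("a zero vector field leaves the state constant", {
  p <- mito_parameters(Vmax_SERCA = 0, Vmax_UNI = 0, Vmax_NCX = 0,
                       Vmax_IP3R = 0, V_LEAK = 0, k_Hyd = 0, g_H = 0,
                       Vmax_ANT = 0, Vmax_CS = 0, Vmax_IDH = 0,
                       Vmax_KGDH = 0, Vmax_SDH = 0, Vmax_MDH = 0,
                       rho_res = 0, rho_f1 = 0, kf_ACO = 0, kf_FH = 0,
                       kf_SL = 0)
  s0 <- default_initial_state(p)
  tr <- simulate_model(seq(0, 100, by = 10), init = s0, p = p)
  for (v in state_names()) {
    expect_equal(tr[[v]], rep(s0[[v]], nrow(tr)), tolerance = 1e-12)
  }
})

test_that("an injected sinusoid is measured at its true period", {
  tt <- seq(0, 2000, by = 0.5)
  tr <- tibble::tibble(time = tt)
  for (v in state_names()) tr[[v]] <- 1
  tr$Cac <- 0.5 + 0.4 * sin(2 * pi * tt / 120)
  class(tr) <- c("mito_trajectory", class(tr))
  cm <- classify_and_measure(tr, transient = 100)
  expect_equal(cm$regime, "oscillatory")
  expect_equal(cm$period, 120, tolerance = 1e-3)
  expect_lt(cm$cv, 1e-4)
})

test_that("a constant trajectory is classified steady with no period", {
  tr <- tibble::tibble(time = seq(0, 1000, 1))
  for (v in state_names()) tr[[v]] <- 1
  class(tr) <- c("mito_trajectory", class(tr))
  cm <- classify_and_measure(tr, transient = 0)
  expect_equal(cm$regime, "steady")
  expect_true(is.na(cm$period))
})

test_that("the basal steady state sits in the physiological windows", {
  ss <- baseline_steady()
  expect_true(attr(ss, "stable"))
  expect_gt(ss[["DPsi"]], 120); expect_lt(ss[["DPsi"]], 170)
  ratio <- (ss[["ATPc"]] + 0.15 * ss[["ATPm"]]) /
    (ss[["ADPc"]] + 0.15 * ss[["ADPm"]])
  expect_gt(ratio, 1); expect_lt(ratio, 3.5)
  # residual of the vector field at the located fixed point
  d <- time_derivatives(ss)
  expect_lt(max(abs(d[1:14])), 1e-9)
})

test_that("conserved pools drift below 1e-6 relative over 1e4 s", {
  tr <- simulate_model(seq(0, 1e4, by = 100), p = mito_parameters(),
                       ctrl = mito_controls(IP3 = 0.3),
                       rtol = 1e-9, atol = 1e-11)
  cs <- conserved_sums(as.matrix(tr[, state_names()]))
  for (col in names(cs)) {
    expect_lt(diff(range(cs[[col]])) / abs(cs[[col]][1]), 1e-6)
  }
})

test_that("stimulation produces sustained Ca2+/ATP oscillations; basal does not", {
  osc <- cached("osc_ip3_stim", {
    tr0 <- simulate_model(seq(0, 20000, 2000), init = baseline_steady(),
                          ctrl = mito_controls(IP3 = 0.35))
    s1 <- unlist(tr0[nrow(tr0), state_names()])
    simulate_model(seq(0, 14000, 0.25), init = s1,
                   ctrl = mito_controls(IP3 = 0.35))
  })
  cm <- classify_and_measure(osc, transient = 0)
  expect_equal(cm$regime, "oscillatory")
  st <- cm$state_stats
  amp_atp <- with(st[st$variable == "ATPc", ], max - min)
  expect_gt(amp_atp, 0.01)  # ATPc oscillates along with Ca2+
  expect_gt(st$max[st$variable == "Cac"], 0.8)

  # basal stimulation relaxes to the fixed point
  tr <- simulate_model(seq(0, 3000, 10), init = baseline_steady())
  cm0 <- classify_and_measure(tr, transient = 1000)
  expect_equal(cm0$regime, "steady")
})

test_that("the period decreases with stimulation strength", {
  period_at <- function(ip3) {
    res <- cached(paste0("pt_ip3_", ip3), {
      camito:::.analyse_point(mito_parameters(), mito_controls(IP3 = ip3),
                              mito_geometry(), baseline_steady(),
                              measure = 8000, dt = 0.5)
    })
    res$summary$period
  }
  expect_gt(period_at(0.35), period_at(0.55))
})

test_that("period estimates are robust to tolerance and sampling changes", {
  tr0 <- simulate_model(seq(0, 5000, 1000), init = baseline_steady(),
                        ctrl = mito_controls(IP3 = 0.5))
  s1 <- unlist(tr0[nrow(tr0), state_names()])
  per <- sapply(list(c(1e-8, 0.5), c(1e-9, 0.25)), function(cfg) {
    tr <- simulate_model(seq(0, 4000, cfg[2]), init = s1,
                         ctrl = mito_controls(IP3 = 0.5),
                         rtol = cfg[1], atol = cfg[1] * 1e-2)
    classify_and_measure(tr, transient = 0)$period
  })
  expect_lt(abs(diff(per)) / per[1], 0.01)
})

test_that("period averages close the cycle", {
  osc <- cached("osc_ip3_stim", stop("cache miss"))
  cm <- classify_and_measure(osc, transient = 0)
  # time-average of every d[X]/dt over an integer number of periods is
  # negligible against the mean flux scale
  d <- osc[osc$time >= cm$window[1] & osc$time <= cm$window[2], ]
  Jbar <- mean(abs(unlist(d[, flux_names()])))
  for (v in c("ATPc", "NADH", "CIT", "Cac", "DPsi")) {
    dv <- (d[[v]][nrow(d)] - d[[v]][1]) / (cm$window[2] - cm$window[1])
    scale <- if (v %in% c("Cac", "DPsi")) Jbar * 1e3 else Jbar
    expect_lt(abs(dv) / scale, 1e-3)
  }
  # averages of conserved pools equal the totals
  p <- mito_parameters()
  st <- cm$state_stats
  g <- function(v) st$mean[st$variable == v]
  expect_equal(unname(g("ATPc") + g("ADPc")), p$A_tot, tolerance = 1e-6)
  expect_equal(unname(g("NAD") + g("NADH")), p$N_tot, tolerance = 1e-6)
})

test_that("classification is deterministic", {
  a <- simulate_model(seq(0, 500, 0.5), ctrl = mito_controls(IP3 = 0.3))
  b <- simulate_model(seq(0, 500, 0.5), ctrl = mito_controls(IP3 = 0.3))
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("a degenerate one-point scan reproduces the steady-state analysis", {
  sc <- scan_parameter("IP3", 0.1)
  expect_equal(nrow(sc), 1)
  expect_equal(sc$regime, "steady")
  ss <- baseline_steady()
  expect_equal(sc$DPsi_mean, ss[["DPsi"]], tolerance = 1e-6)
  led <- work_ledger(ss)
  expect_equal(sc$eta, led$eta, tolerance = 1e-8)
  expect_equal(sc$Tsigma, led$Tsigma, tolerance = 1e-6)
})

test_that("bisection refines an oscillation-onset bracket", {
  loc <- locate_bifurcation("IP3", 0.20, 0.40, tol = 0.06,
                            init = baseline_steady(),
                            measure = 6000, dt = 0.5)
  expect_lt(loc$upper - loc$lower, 0.061)
  expect_gt(loc$location, 0.20); expect_lt(loc$location, 0.40)
  expect_error(locate_bifurcation("IP3", 0.05, 0.10, tol = 0.05,
                                  init = baseline_steady()),
               "same regime")
})

test_that("scan grids are validated and bifurcations are bracketed", {
  expect_error(scan_parameter("IP3", c(0.3, 0.1, 0.2)), "monotone")
  sc <- cached("scan_onset", {
    scan_parameter("IP3", c(0.2, 0.25, 0.3, 0.35), measure = 8000, dt = 0.5)
  })
  bif <- attr(sc, "bifurcations")
  expect_gt(nrow(bif), 0)
  expect_true(any(bif$to == "oscillatory" | bif$from == "oscillatory"))
})
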