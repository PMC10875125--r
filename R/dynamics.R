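# Integration, regime classification, period measurement, parameter scans.

pack_params <- function(p, ctrl, geom) {
  c(geom$alpha, geom$delta, geom$f_c, geom$f_ER, geom$f_m, geom$C_m,
    geom$gamma, geom$R * geom$T, geom$F,
    ctrl$Pi_c, ctrl$Pi_m, ctrl$Na_c, ctrl$Na_m, ctrl$Mg_m, ctrl$H_c,
    ctrl$H_m, ctrl$O2, ctrl$AcCoA, ctrl$CoA, ctrl$CO2, ctrl$CoQ,
    ctrl$CoQH2, ctrl$IP3, ctrl$DeltapH,
    p$Vmax_SERCA, p$Vmax_UNI, p$Vmax_NCX, p$Vmax_IP3R, p$V_LEAK,
    p$Vmax_ANT, p$Vmax_CS, p$Vmax_IDH, p$Vmax_KGDH, p$Vmax_SDH,
    p$Vmax_MDH, p$rho_res, p$rho_f1, p$kf_ACO, p$kf_FH, p$kf_SL,
    p$k_Hyd, p$g_H,
    p$K_M_AcCoA, p$K_M_OAA_CS, p$K_i_AcCoA, p$K_s_AcCoA, p$K_M_ISOC,
    p$K_M_NAD_IDH, p$K_a_ADP, p$K_a_Cam, p$K_i_NADH, p$k_h_1, p$k_h_2,
    p$K_M_aKG, p$K_M_NAD_KGDH, p$K_D_Mg, p$K_D_Ca, p$K_M_SUC, p$K_i_OAA,
    p$K_i_FUM, p$K_M_MAL, p$K_M_NAD_MDH, p$K_M_OAA_MDH, p$K_M_NADH,
    p$K_M_Na, p$K_M_Ca, p$K_trans, p$K_act, p$L_uni, p$K_Ca, p$K_ATPc,
    p$K_M_ATPc, p$K_a_IP3, p$K_a_Cac, p$K_i_Ca,
    p$K_ACO, p$K_FH, p$K_MDH, p$K_SL, p$K_F1, p$K_res,
    p$n_i, p$n_aKG, p$n_a, p$n_Na, p$b_NCX, p$f_ANT, p$g_Ox,
    p$p1, p$p2, p$p3, p$pa, p$pc1, p$pc2,
    p$r1, p$r2, p$r3, p$ra, p$rc1, p$rc2,
    p$DeltaPsi_star, p$DeltaPsi_B,
    as.numeric(isTRUE(p$ares_sqrt)),
    as.numeric(identical(p$kgdh_form, "additive")),
    as.numeric(isTRUE(p$ox_half)),
    as.numeric(isTRUE(p$serca_coupled)))
}

# fast flux evaluation on a state matrix through the compiled kernel
flux_matrix <- function(Y, p, ctrl, geom) {
  storage.mode(Y) <- "double"
  out <- .Call(camito_flux_matrix, Y, pack_params(p, ctrl, geom))
  colnames(out) <- flux_names()
  out
}

#' Integrate the model
#'
#' Stiff integration (lsoda) of the 18 rate equations through the compiled
#' kernel; the 17 reaction rates are carried along as auxiliary outputs so
#' the returned trajectory contains both the state and the flux vector at
#' every sample time.
#'
#' @param times numeric vector of output times (s), strictly increasing
#' @param init initial state; defaults to [default_initial_state()]
#' @inheritParams validate_model_inputs
#' @param rtol,atol solver tolerances
#' @param engine `"compiled"` (default) or `"r"` (reference implementation)
#' @return a `mito_trajectory` tibble: `time`, the 18 state columns and the
#'   17 flux columns, with solver metadata in attributes.
#' @export
#' @examples
#' tr <- simulate_model(times = seq(0, 10, 0.5))
simulate_model <- function(times, init = NULL, p = mito_parameters(),
                           ctrl = mito_controls(), geom = mito_geometry(),
                           rtol = 1e-8, atol = 1e-10,
                           engine = c("compiled", "r")) {
  engine <- match.arg(engine)
  if (is.null(init)) init <- default_initial_state(p, geom)
  init <- .check_state(init)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (engine == "compiled") {
    out <- deSolve::ode(unname(init), times, func = "camito_derivs",
                        parms = pack_params(p, ctrl, geom),
                        dllname = "camito", initfunc = "camito_init",
                        nout = 17, outnames = flux_names(),
                        method = "lsoda", rtol = rtol, atol = atol,
                        maxsteps = 500000)
  } else {
    m <- build_model(p, ctrl, geom)
    out <- deSolve::ode(unname(init), times, m$deriv, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol,
                        maxsteps = 500000)
  }
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0) {
    last <- out[nrow(out), ]
    stop(sprintf(
      "integration failed at t = %.6g (istate = %d); last state: %s",
      last[1], istate[1],
      paste(sprintf("%s=%.4g", state_names(), last[2:19]), collapse = ", ")),
      call. = FALSE)
  }
  m <- as.data.frame(out)
  if (engine == "r") {
    J <- t(apply(as.matrix(m[, 2:19]), 1, build_model(p, ctrl, geom)$fluxes))
    m <- cbind(m, J)
  }
  names(m) <- c("time", state_names(), flux_names())
  tr <- tibble::as_tibble(m)
  attr(tr, "p") <- p; attr(tr, "ctrl") <- ctrl; attr(tr, "geom") <- geom
  attr(tr, "solver") <- list(method = "lsoda", rtol = rtol, atol = atol,
                             engine = engine)
  class(tr) <- c("mito_trajectory", class(tr))
  tr
}

# reconstruct full 18-state from the 13 free coordinates via conserved totals
.reduced_names <- c("aKG", "ATPc", "ATPm", "CIT", "FUM", "ISOC", "MAL",
                    "NADH", "SCoA", "SUC", "Cac", "Cam", "DPsi")

.expand_state <- function(z, p, geom) {
  full <- c(
    ADPc = p$A_tot - z[["ATPc"]], ADPm = p$Am_tot - z[["ATPm"]],
    aKG = z[["aKG"]], ATPc = z[["ATPc"]], ATPm = z[["ATPm"]],
    CIT = z[["CIT"]], FUM = z[["FUM"]], ISOC = z[["ISOC"]], MAL = z[["MAL"]],
    NAD = p$N_tot - z[["NADH"]], NADH = z[["NADH"]],
    OAA = p$cK_tot - (z[["CIT"]] + z[["ISOC"]] + z[["aKG"]] + z[["SCoA"]] +
                        z[["SUC"]] + z[["FUM"]] + z[["MAL"]]),
    SCoA = z[["SCoA"]], SUC = z[["SUC"]],
    Cac = z[["Cac"]], Cam = z[["Cam"]],
    CaER = (p$c_tot - z[["Cac"]] / geom$f_c - geom$delta * z[["Cam"]] / geom$f_m) *
      geom$f_ER / geom$alpha,
    DPsi = z[["DPsi"]]
  )
  full[state_names()]
}

.reduce_state <- function(s) s[.reduced_names]

#' Locate a stable steady state
#'
#' Damped Newton iteration on the conserved-pool-reduced system (13 free
#' coordinates), falling back to long-time integration when Newton leaves
#' the physical domain or stalls. Stability is assessed from the eigenvalues
#' of the reduced Jacobian.
#'
#' @param guess full 18-component state used as the starting point
#' @inheritParams simulate_model
#' @param tol componentwise residual tolerance on d(state)/dt (mM/s scale)
#' @return named state vector with attributes `converged_by`
#'   (`"newton"` or `"integration"`), `stable` (logical), and
#'   `eigenvalues` (complex, reduced system).
#' @export
find_steady_state <- function(p = mito_parameters(), ctrl = mito_controls(),
                              geom = mito_geometry(), guess = NULL,
                              tol = 1e-10) {
  if (is.null(guess)) guess <- default_initial_state(p, geom)
  guess <- .check_state(guess)

  rhs_full <- function(s) {
    J <- flux_matrix(matrix(s, nrow = 1), p, ctrl, geom)[1, ]
    .derivatives_from_fluxes(J, p, geom)
  }
  rhs_red <- function(z) .reduce_state(rhs_full(.expand_state(z, p, geom)))
  # scale residuals so mM-, uM- and mV-valued equations are comparable
  sc <- c(rep(1, 10), 1e-3, 1e-3, 1e-3 / mito_geometry()$C_m * 1e-3)
  sc <- stats::setNames(rep(1, 13), .reduced_names)
  sc[c("Cac", "Cam")] <- 1e-3   # uM/s -> mM/s scale
  sc["DPsi"] <- 1e-3            # mV/s, comparable magnitude

  num_jac <- function(fn, z) {
    f0 <- fn(z)
    Jm <- matrix(0, length(f0), length(z))
    for (j in seq_along(z)) {
      h <- max(1e-7 * abs(z[j]), 1e-9)
      zp <- z; zp[j] <- z[j] + h
      zm <- z; zm[j] <- z[j] - h
      Jm[, j] <- (fn(zp) - fn(zm)) / (2 * h)
    }
    Jm
  }

  newton_ok <- FALSE
  z <- .reduce_state(guess)
  for (it in 1:60) {
    f <- rhs_red(z)
    if (max(abs(f * sc)) < tol) { newton_ok <- TRUE; break }
    Jm <- tryCatch(num_jac(rhs_red, z), error = function(e) NULL)
    step <- if (is.null(Jm)) NULL else
      tryCatch(solve(Jm, -f), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1; improved <- FALSE
    f0n <- sqrt(sum((f * sc)^2))
    for (k in 1:12) {
      zn <- z + lam * step
      ok <- all(zn[-13] >= 0) &&
        all(.expand_state(zn, p, geom)[1:17] >= 0) &&
        tryCatch(sqrt(sum((rhs_red(zn) * sc)^2)) < f0n, error = function(e) FALSE)
      if (ok) { z <- zn; improved <- TRUE; break }
      lam <- lam / 2
    }
    if (!improved) break
  }
  by <- "newton"
  if (!newton_ok) {
    # fall back to relaxation by integration
    tr <- simulate_model(seq(0, 60000, by = 1000), init = guess,
                         p = p, ctrl = ctrl, geom = geom)
    z <- .reduce_state(unlist(tr[nrow(tr), state_names()]))
    for (it in 1:40) {
      f <- rhs_red(z)
      if (max(abs(f * sc)) < tol) { newton_ok <- TRUE; break }
      Jm <- num_jac(rhs_red, z)
      step <- tryCatch(solve(Jm, -f), error = function(e) NULL)
      if (is.null(step)) break
      zn <- z + step
      if (any(zn[-13] < 0) || any(.expand_state(zn, p, geom)[1:17] < 0)) break
      z <- zn
    }
    by <- if (newton_ok) "integration+newton" else "integration"
  }
  s <- .expand_state(z, p, geom)
  Jm <- num_jac(rhs_red, .reduce_state(s))
  ev <- eigen(Jm, only.values = TRUE)$values
  structure(s, converged_by = by, stable = all(Re(ev) < 1e-9),
            eigenvalues = ev)
}

.derivatives_from_fluxes <- function(J, p, geom) {
  half <- if (isTRUE(p$serca_coupled)) 0.5 else 0
  c(
    ADPc = -geom$delta * J[["ANT"]] + J[["Hyd"]] + half * J[["SERCA"]],
    ADPm = J[["ANT"]] - J[["F1"]] - J[["SL"]],
    aKG = J[["IDH"]] - J[["KGDH"]],
    ATPc = geom$delta * J[["ANT"]] - J[["Hyd"]] - half * J[["SERCA"]],
    ATPm = -J[["ANT"]] + J[["F1"]] + J[["SL"]],
    CIT = J[["CS"]] - J[["ACO"]],
    FUM = J[["SDH"]] - J[["FH"]],
    ISOC = J[["ACO"]] - J[["IDH"]],
    MAL = J[["FH"]] - J[["MDH"]],
    NAD = J[["Ox"]] - J[["IDH"]] - J[["KGDH"]] - J[["MDH"]],
    NADH = -J[["Ox"]] + J[["IDH"]] + J[["KGDH"]] + J[["MDH"]],
    OAA = J[["MDH"]] - J[["CS"]],
    SCoA = J[["KGDH"]] - J[["SL"]],
    SUC = J[["SL"]] - J[["SDH"]],
    Cac = geom$f_c * geom$gamma *
      (-J[["SERCA"]] + J[["ERout"]] + geom$delta * (J[["NCX"]] - J[["UNI"]])),
    Cam = geom$f_m * geom$gamma * (J[["UNI"]] - J[["NCX"]]),
    CaER = geom$f_ER * geom$gamma / geom$alpha * (J[["SERCA"]] - J[["ERout"]]),
    DPsi = (10 * J[["Ox"]] - 3 * J[["F1"]] - J[["ANT"]] - J[["Hl"]] -
              J[["NCX"]] - 2 * J[["UNI"]]) / geom$C_m
  )
}

# one refined peak per excursion above the signal's mid level; immune to
# micro-ripples on spike tops that defeat local-maximum detectors
.find_peaks <- function(t, x, min_prominence) {
  n <- length(x)
  if (n < 3) return(numeric(0))
  lo <- min(x); hi <- max(x)
  if (hi - lo < 2 * min_prominence) return(numeric(0))
  L <- (hi + lo) / 2
  above <- x >= L
  ups <- which(!above[-n] & above[-1]) + 1L
  downs <- which(above[-n] & !above[-1])
  if (!length(ups) || !length(downs)) return(numeric(0))
  peaks <- vapply(ups, function(u) {
    d <- downs[downs >= u][1]
    if (is.na(d)) return(NA_real_)
    i <- u - 1L + which.max(x[u:d])
    if (i <= 1 || i >= n) return(t[i])
    y1 <- x[i - 1]; y2 <- x[i]; y3 <- x[i + 1]
    den <- y1 - 2 * y2 + y3
    if (den >= 0) return(t[i])
    t[i] + 0.5 * (y1 - y3) / den * (t[i + 1] - t[i])
  }, numeric(1))
  peaks[!is.na(peaks)]
}

#' Classify a trajectory and measure its oscillation
#'
#' Discards the transient, then decides between a steady and an oscillatory
#' regime from the relative peak-to-trough amplitude of cytosolic Ca2+.
#' For oscillatory trajectories the period is the mean inter-peak interval
#' (quadratically refined peak times); a coefficient of variation of the
#' intervals below `cv_tol` is required to declare a stable limit cycle,
#' otherwise the trajectory is flagged `"transient"`. Per-variable
#' statistics and period-averaged fluxes are computed by trapezoidal
#' integration over an integer number of periods.
#'
#' @param traj a `mito_trajectory`
#' @param transient model time (s) to discard before analysis
#' @param amp_threshold relative Ca2+ amplitude above which the regime is
#'   declared oscillatory
#' @param cv_tol maximal coefficient of variation of inter-peak intervals
#' @return an `oscillation_summary`: list with `regime`, `period`,
#'   `period_se`, `cv`, `n_periods`, `window`, `state_stats` (tibble of
#'   min/max/mean per variable), `flux_means` (named vector).
#' @export
classify_and_measure <- function(traj, transient = 5000,
                                 amp_threshold = 0.05, cv_tol = 0.02) {
  d <- traj[traj$time >= transient, , drop = FALSE]
  if (nrow(d) < 10) stop("trajectory too short after transient", call. = FALSE)
  tt <- d$time; ca <- d$Cac
  amp <- (max(ca) - min(ca)) / max(mean(ca), 1e-12)

  has_fluxes <- all(flux_names() %in% names(d))
  avg_window <- function(i0, i1) {
    w <- d[i0:i1, , drop = FALSE]
    dt <- diff(w$time)
    trap <- function(v) sum(dt * (v[-1] + v[-length(v)]) / 2) /
      (w$time[nrow(w)] - w$time[1])
    stats <- tibble::tibble(
      variable = state_names(),
      min = vapply(state_names(), function(v) min(w[[v]]), numeric(1)),
      max = vapply(state_names(), function(v) max(w[[v]]), numeric(1)),
      mean = vapply(state_names(), function(v) trap(w[[v]]), numeric(1))
    )
    fm <- if (has_fluxes)
      vapply(flux_names(), function(v) trap(w[[v]]), numeric(1)) else NULL
    list(stats = stats, fm = fm, t0 = w$time[1], t1 = w$time[nrow(w)])
  }

  if (amp <= amp_threshold) {
    aw <- avg_window(max(1, nrow(d) - 50), nrow(d))
    out <- list(regime = "steady", period = NA_real_, period_se = NA_real_,
                cv = NA_real_, n_periods = 0L,
                window = c(aw$t0, aw$t1),
                state_stats = aw$stats, flux_means = aw$fm)
    class(out) <- "oscillation_summary"
    return(out)
  }

  prom <- amp_threshold * mean(ca)
  pk <- .find_peaks(tt, ca, min_prominence = max(prom, 0.25 * (max(ca) - min(ca))))
  if (length(pk) < 3) {
    out <- list(regime = "transient", period = NA_real_, period_se = NA_real_,
                cv = NA_real_, n_periods = length(pk),
                window = range(tt),
                state_stats = avg_window(1, nrow(d))$stats,
                flux_means = avg_window(1, nrow(d))$fm)
    class(out) <- "oscillation_summary"
    return(out)
  }
  ip <- diff(pk)
  period <- mean(ip)
  cv <- stats::sd(ip) / period
  # a period-doubled cycle has two spikes per period: alternating intervals
  # with a large spread, but consecutive-pair sums that are nearly constant
  if ((!is.finite(cv) || cv >= cv_tol) && length(pk) >= 7) {
    for (off in 0:1) {
      first <- 1 + off
      starts <- seq(first, length(pk) - 2, by = 2)
      if (length(starts) < 3) next
      sums <- pk[starts + 2] - pk[starts]
      cv2 <- stats::sd(sums) / mean(sums)
      if (is.finite(cv2) && cv2 < cv_tol) {
        pk <- pk[seq(first, starts[length(starts)] + 2, by = 2)]
        ip <- diff(pk)
        period <- mean(ip)
        cv <- cv2
        break
      }
    }
  }
  regime <- if (is.finite(cv) && cv < cv_tol) "oscillatory" else "transient"

  # integer number of periods: from first to last detected peak
  i0 <- which.min(abs(tt - pk[1])); i1 <- which.min(abs(tt - pk[length(pk)]))
  aw <- avg_window(i0, i1)
  out <- list(regime = regime, period = period,
              period_se = stats::sd(ip) / sqrt(length(ip)), cv = cv,
              n_periods = length(ip),
              window = c(pk[1], pk[length(pk)]),
              state_stats = aw$stats, flux_means = aw$fm)
  class(out) <- "oscillation_summary"
  out
}

#' @export
print.oscillation_summary <- function(x, ...) {
  cat("<oscillation_summary>\n regime:", x$regime, "\n")
  if (x$regime == "oscillatory") {
    cat(sprintf(" period: %.2f s (se %.3f, cv %.4f, %d periods)\n",
                x$period, x$period_se, x$cv, x$n_periods))
  }
  invisible(x)
}

# attractor analysis at one parameter point: steady state via Newton when
# stable, otherwise limit cycle via integration; returns summary + state
.analyse_point <- function(p, ctrl, geom, init, transient = 5000,
                           measure = 6000, dt = 0.25,
                           amp_threshold = 0.05, rtol = 1e-8, atol = 1e-10) {
  ss <- tryCatch(find_steady_state(p, ctrl, geom, guess = init),
                 error = function(e) NULL)
  if (!is.null(ss) && isTRUE(attr(ss, "stable"))) {
    tr <- simulate_model(seq(0, 200, by = 100), init = ss, p = p, ctrl = ctrl,
                         geom = geom, rtol = rtol, atol = atol)
    J <- unlist(tr[nrow(tr), flux_names()])
    stats <- tibble::tibble(variable = state_names(),
                            min = unname(ss), max = unname(ss),
                            mean = unname(ss))
    summary <- structure(
      list(regime = "steady", period = NA_real_, period_se = NA_real_,
           cv = NA_real_, n_periods = 0L, window = c(0, 0),
           state_stats = stats, flux_means = J),
      class = "oscillation_summary")
    return(list(summary = summary, end_state = ss, traj = NULL))
  }
  # unstable or non-convergent: integrate through the transient, then sample;
  # extend the horizon until the attractor is resolved (slow periods near
  # onset need several extensions)
  tr0 <- simulate_model(seq(0, transient, by = transient / 4), init = init,
                        p = p, ctrl = ctrl, geom = geom,
                        rtol = rtol, atol = atol)
  s1 <- unlist(tr0[nrow(tr0), state_names()])
  horizon <- measure
  for (k in 1:4) {
    tr <- simulate_model(seq(0, horizon, by = dt), init = s1, p = p,
                         ctrl = ctrl, geom = geom, rtol = rtol, atol = atol)
    summary <- classify_and_measure(tr, transient = 0,
                                    amp_threshold = amp_threshold)
    done <- summary$regime == "steady" ||
      (summary$regime == "oscillatory" && summary$n_periods >= 8)
    if (done || k == 4) break
    s1 <- unlist(tr[nrow(tr), state_names()])
    horizon <- 2 * horizon
  }
  list(summary = summary, end_state = unlist(tr[nrow(tr), state_names()]),
       traj = tr)
}

#' Scan an attractor along one parameter
#'
#' Continuation scan: each grid point starts from the previous point's
#' attractor. Steady points are located by Newton iteration and accepted
#' when the reduced Jacobian is stable; otherwise the limit cycle is
#' integrated, classified and measured. Each point carries the full
#' thermodynamic work ledger (period-averaged in oscillatory regimes).
#'
#' @param name parameter to scan: `"IP3"` or `"AcCoA"` (controlled species,
#'   uM), or any kinetic constant name from [mito_parameters()]
#' @param grid strictly monotone numeric grid (uM for IP3/AcCoA)
#' @inheritParams simulate_model
#' @param transient,measure,dt classification horizon controls (s)
#' @param amp_threshold oscillation amplitude criterion
#' @return a `mito_scan` tibble: one row per grid point with regime,
#'   period, Ca2+/ATP statistics and the work ledger columns. Bifurcation
#'   brackets (regime changes between adjacent points) are in
#'   `attr(, "bifurcations")`.
#' @export
scan_parameter <- function(name, grid, p = mito_parameters(),
                           ctrl = mito_controls(), geom = mito_geometry(),
                           init = NULL, transient = 5000, measure = 6000,
                           dt = 0.25, amp_threshold = 0.05) {
  stopifnot(length(grid) >= 1, all(grid > 0) || name == "DPsi")
  if (is.unsorted(grid) && is.unsorted(rev(grid))) {
    stop("grid must be monotone", call. = FALSE)
  }
  at <- function(v) {
    if (name %in% c("IP3", names(mito_controls()))) {
      val <- if (name == "AcCoA") v / 1e3 else v   # AcCoA grid given in uM
      list(p = p, ctrl = apply_overrides(unclass(ctrl),
                                         stats::setNames(list(val), name),
                                         "mito_controls"))
    } else {
      list(p = apply_overrides(unclass(p), stats::setNames(list(v), name),
                               "mito_parameters"), ctrl = ctrl)
    }
  }
  state <- if (is.null(init)) default_initial_state(p, geom) else .check_state(init)
  rows <- vector("list", length(grid))
  prev_regime <- "steady"
  for (i in seq_along(grid)) {
    pc <- at(grid[i])
    res <- .analyse_point(pc$p, pc$ctrl, geom, state, transient = transient,
                          measure = measure, dt = dt,
                          amp_threshold = amp_threshold)
    state <- res$end_state
    led <- point_ledger(res, pc$p, pc$ctrl, geom)
    sm <- res$summary
    st <- sm$state_stats
    g <- function(v, w) st[[w]][st$variable == v]
    rows[[i]] <- tibble::tibble(
      param = name, value = grid[i], regime = sm$regime,
      period = sm$period, period_se = sm$period_se,
      Cac_mean = g("Cac", "mean"), Cac_min = g("Cac", "min"),
      Cac_max = g("Cac", "max"),
      Cam_mean = g("Cam", "mean"), ATPc_mean = g("ATPc", "mean"),
      DPsi_mean = g("DPsi", "mean")
    ) |> dplyr::bind_cols(led)
    prev_regime <- sm$regime
  }
  out <- dplyr::bind_rows(rows)
  ch <- which(out$regime[-1] != out$regime[-nrow(out)])
  bif <- if (length(ch)) {
    tibble::tibble(lower = out$value[ch], upper = out$value[ch + 1],
                   from = out$regime[ch], to = out$regime[ch + 1])
  } else {
    tibble::tibble(lower = numeric(0), upper = numeric(0),
                   from = character(0), to = character(0))
  }
  attr(out, "bifurcations") <- bif
  attr(out, "p") <- p; attr(out, "ctrl") <- ctrl; attr(out, "geom") <- geom
  class(out) <- c("mito_scan", class(out))
  out
}

#' Refine a regime-change point by bisection
#'
#' Brackets the onset (or termination) of oscillations between two grid
#' values of a scan parameter and bisects to the requested absolute
#' tolerance, classifying each midpoint from a fresh transient.
#'
#' @inheritParams scan_parameter
#' @param lower,upper bracket: regimes at the two ends must differ
#' @param tol absolute tolerance on the parameter (uM for IP3/AcCoA)
#' @return list with `location`, `lower`, `upper`, `n_evals`.
#' @export
locate_bifurcation <- function(name, lower, upper, p = mito_parameters(),
                               ctrl = mito_controls(), geom = mito_geometry(),
                               init = NULL, tol = 1e-3, ...) {
  cls <- function(v) {
    sc <- scan_parameter(name, v, p, ctrl, geom, init = init, ...)
    sc$regime[1]
  }
  rl <- cls(lower); ru <- cls(upper)
  if (rl == ru) stop("bracket endpoints have the same regime", call. = FALSE)
  n <- 2L
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    rm <- cls(mid); n <- n + 1L
    if (rm == rl) lower <- mid else upper <- mid
  }
  list(location = (lower + upper) / 2, lower = lower, upper = upper,
       n_evals = n)
}
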