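test_that("waveform templates match their DUS extrema exactly", {
  w <- build_waveform("triphasic", psv = 88.30, mdv = -14.90, period = 1)
  expect_equal(max(w$values), 88.30)
  expect_equal(min(w$values), -14.90)
  expect_equal(w$period, 1)
  m <- build_waveform("monophasic", psv = 1, mdv = 0)
  expect_gte(min(m$values), 0)
  expect_equal(max(m$values), 1)
  expect_error(build_waveform("monophasic", psv = 50, mdv = -5), "mdv")
  expect_error(build_waveform("triphasic", psv = 50, mdv = 5), "mdv")
  # every triphasic DUS row has net forward flow
  dus <- fp_dus_velocities()
  tri <- dus[dus$phase_type == "triphasic", ]
  for (i in seq_len(nrow(tri))) {
    wi <- build_waveform("triphasic", psv = tri$psv_cm_s[i], mdv = tri$mdv_cm_s[i])
    expect_gt(vesselwarp:::waveform_mean(wi), 0)
  }
})

test_that("velocity-to-flow conversion keeps units honest", {
  tt <- seq(0, 1, length.out = 101)[-101]
  w <- waveform(tt, rep(10, 100), 1, kind = "velocity")  # 10 cm/s
  Q <- waveform_to_flow(w, 10)                           # 10 mm^2 inlet
  expect_equal(unique(Q$values), 1000)                   # 100 mm/s * 10 mm^2
  expect_equal(attr(Q, "mean_flow_ml_min"), 60)
  Q2 <- waveform_to_flow(w, 20)
  expect_equal(Q2$values, 2 * Q$values)
  expect_error(waveform_to_flow(w, 0), "inlet_area")
})

test_that("published post-angioplasty inflows average 86.73 ml/min for P1-P4", {
  f <- fp_inlet_flows()
  m <- mean(f$flow_ml_min[f$time_point == "post_pta" &
                            f$patient %in% c("P1", "P2", "P3", "P4")])
  expect_equal(round(m, 2), 86.73)
})

test_that("parabolic inlet profiles conserve flux", {
  # ideal disk cap (128-gon fan): centerline peak is exactly twice the mean
  th <- seq(0, 2 * pi, length.out = 129)[-129]
  disk <- tri_mesh(rbind(c(0, 0, 0), cbind(2 * cos(th), 2 * sin(th), 0)),
                   cbind(1L, 1L + seq_along(th), 1L + c(seq_along(th)[-1], 1L)),
                   rep("inlet", length(th)))
  ppd <- parabolic_profile(10, disk)
  expect_lt(abs(max(ppd$speed) / 20 - 1), 0.005)
  # extracted mesh cap: peak within 5 %, flux conserved to 0.5 %
  mc <- cyl12_clipped()
  pp <- parabolic_profile(10, mc, cap = "inlet")
  expect_lt(abs(max(pp$speed) / 20 - 1), 0.05)
  a <- sum(face_areas(mc)[mc$tags == "inlet"])
  expect_lt(abs(pp$flux_cm_s_mm2 / (10 * a) - 1), 0.005)
  # squashed cap (2:1): exact flux conservation after rescaling
  sq <- mc
  sq$vertices[, 2] <- sq$vertices[, 2] / 2
  pp2 <- parabolic_profile(10, sq, cap = "inlet")
  a2 <- sum(face_areas(sq)[sq$tags == "inlet"])
  expect_lt(abs(pp2$flux_cm_s_mm2 / (10 * a2) - 1), 1e-6)
  # two disjoint caps are rejected
  two <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                        c(5, 5, 0), c(6, 5, 0), c(5, 6, 0)),
                  rbind(c(1, 2, 3), c(4, 5, 6)),
                  rep("inlet", 2))
  expect_error(parabolic_profile(10, two), "component")
})

test_that("Windkessel integration matches closed forms", {
  tt <- seq(0, 1, length.out = 501)[-501]
  rc <- windkessel_rc(2e-5, 1e5)
  # constant flow: steady state P = Q R
  Qc <- waveform(tt, rep(60, 500), 1, kind = "flow")
  pt <- windkessel_pressure(Qc, rc, P0 = 80, tol_mmHg = 1e-4, max_cycles = 200)
  expect_equal(pt$p_sys, MPa_to_mmHg(60 * rc$R), tolerance = 1e-3)
  # zero flow: exponential decay with time constant R C (the returned
  # trace is the second cycle, starting one period into the decay)
  Q0 <- waveform(tt, rep(0, 500), 1, kind = "flow")
  one <- windkessel_pressure(Q0, rc, P0 = 80, tol_mmHg = 1e9)
  tau <- rc$R * rc$C
  expect_equal(one$P_mmHg[1], 80 * exp(-1 / tau), tolerance = 1e-3)
  expect_equal(one$P_mmHg[length(one$P_mmHg)], 80 * exp(-2 / tau),
               tolerance = 1e-3)
  # sinusoidal forcing: amplitude R Q1 / sqrt(1 + (w R C)^2), mean Q0 R
  om <- 2 * pi
  Qs <- waveform(tt, 50 + 20 * sin(om * tt), 1, kind = "flow")
  ps <- windkessel_pressure(Qs, rc, tol_mmHg = 1e-3, max_cycles = 200)
  amp <- (ps$p_sys - ps$p_dia) / 2
  amp_cf <- MPa_to_mmHg(rc$R * 20 / sqrt(1 + (om * rc$R * rc$C)^2))
  expect_lt(abs(amp / amp_cf - 1), 0.005)
  expect_lt(abs(mean(ps$P_mmHg) / MPa_to_mmHg(50 * rc$R) - 1), 0.005)
})

test_that("Windkessel calibration inverts the forward model", {
  tt <- seq(0, 1, length.out = 501)[-501]
  om <- 2 * pi
  # forward with known parameters, then recover them
  rc_true <- windkessel_rc(1.4e-5, 1.1e5)
  Qs <- waveform(tt, 520 + 260 * sin(om * tt), 1, kind = "flow")
  target <- windkessel_pressure(Qs, rc_true, tol_mmHg = 1e-5, max_cycles = 500)
  rc_fit <- calibrate_windkessel(Qs, p_sys = target$p_sys, p_dia = target$p_dia,
                                 tol_mmHg = 1e-3)
  expect_lt(abs(rc_fit$R / rc_true$R - 1), 0.001)
  expect_lt(abs(rc_fit$C / rc_true$C - 1), 0.001)

  # 120/80 round trip within 0.1 mmHg
  rc <- calibrate_windkessel(Qs, 120, 80)
  back <- windkessel_pressure(Qs, rc, tol_mmHg = 1e-3, max_cycles = 200)
  expect_lt(abs(back$p_sys - 120), 0.1)
  expect_lt(abs(back$p_dia - 80), 0.1)

  # doubling the flow halves R and doubles C (same pressures)
  Q2 <- waveform(tt, 2 * (520 + 260 * sin(om * tt)), 1, kind = "flow")
  rc2 <- calibrate_windkessel(Q2, 120, 80, tol_mmHg = 1e-3)
  rc1 <- calibrate_windkessel(Qs, 120, 80, tol_mmHg = 1e-3)
  expect_lt(abs(rc2$R / (rc1$R / 2) - 1), 0.005)
  expect_lt(abs(rc2$C / (2 * rc1$C) - 1), 0.005)

  expect_error(calibrate_windkessel(Qs, 80, 120), "infeasible")
  Qflat <- waveform(tt, rep(500, 500), 1, kind = "flow")
  expect_error(calibrate_windkessel(Qflat, 120, 80), "unidentifiable")
})

test_that("Poiseuille wall shear stress follows the closed form", {
  expect_equal(signif(poiseuille_wss(100, 2, 3.5e-3), 3), 0.0557)
  expect_equal(poiseuille_wss(0, 2), 0)
  expect_equal(poiseuille_wss(200, 2), 2 * poiseuille_wss(100, 2))
  expect_equal(poiseuille_wss(100, 1), 8 * poiseuille_wss(100, 2))
  expect_error(poiseuille_wss(100, 0), "radius")
})

test_that("unit conversions are exact inverses", {
  x <- c(0.123, 80, 120, 1e4)
  expect_equal(MPa_to_mmHg(mmHg_to_MPa(x)), x, tolerance = 1e-12)
  expect_equal(Pa_to_mmHg(mmHg_to_Pa(x)), x, tolerance = 1e-12)
  expect_equal(mm3_s_to_ml_min(ml_min_to_mm3_s(x)), x, tolerance = 1e-12)
  expect_equal(mm_s_to_cm_s(cm_s_to_mm_s(x)), x, tolerance = 1e-12)
  expect_equal(MPa_to_Pa(Pa_to_MPa(x)), x, tolerance = 1e-12)
})
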