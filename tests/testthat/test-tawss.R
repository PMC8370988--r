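# tiny two-face mesh for operator-level TAWSS checks
unit_patch <- function(tags = c("wall", "wall")) {
  tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
           rbind(c(1, 2, 3), c(1, 3, 4)), tags)
}

test_that("TAWSS reproduces closed-form time integrals", {
  m <- unit_patch()
  tt <- seq(0, 1, length.out = 2001)[-2001]
  # constant 1 Pa
  s1 <- wss_series(m, tt, matrix(1, 2, length(tt)), period = 1)
  expect_equal(compute_tawss(s1), c(1, 1), tolerance = 1e-9)
  # square wave 0/2 Pa averages to 1 Pa
  sq <- ifelse(tt < 0.5, 0, 2)
  s2 <- wss_series(m, tt, rbind(sq, sq), period = 1)
  expect_equal(compute_tawss(s2), c(1, 1), tolerance = 1e-3)
  # |sin|: integral 2/pi, within 0.1 % at 500 samples
  t5 <- seq(0, 1, length.out = 501)[-501]
  s3 <- wss_series(m, t5, rbind(abs(sin(2 * pi * t5)), abs(sin(2 * pi * t5))),
                   period = 1)
  expect_lt(max(abs(compute_tawss(s3) / (2 / pi) - 1)), 1e-3)
  expect_error(compute_tawss(wss_series(m, 0, matrix(1, 2, 1), period = 1)),
               ">= 2 time samples")
})

test_that("TAWSS is linear and monotone in the input field", {
  m <- unit_patch()
  tt <- seq(0, 1, length.out = 101)[-101]
  set.seed(5)
  w1 <- matrix(runif(2 * 100), 2)
  w2 <- matrix(runif(2 * 100), 2)
  t1 <- compute_tawss(wss_series(m, tt, w1, period = 1))
  t2 <- compute_tawss(wss_series(m, tt, w2, period = 1))
  t12 <- compute_tawss(wss_series(m, tt, w1 + w2, period = 1))
  expect_equal(t12, t1 + t2, tolerance = 1e-12)
  expect_true(all(compute_tawss(wss_series(m, tt, w1 + 0.5, period = 1)) > t1))
})

test_that("adverse-area classification uses strict thresholds and exact partition", {
  m <- cyl_clipped()
  nf <- nrow(m$faces)
  tawss <- rep(1, nf)
  rep1 <- adverse_areas(tawss, m)
  expect_equal(rep1$low_cm2, 0)
  expect_equal(rep1$high_cm2, 0)
  expect_equal(rep1$normal_cm2, rep1$wall_cm2, tolerance = 1e-12)
  # a face exactly at the 0.5 Pa threshold is normal (strict <)
  tawss2 <- rep(0.5, nf)
  rep2 <- adverse_areas(tawss2, m)
  expect_equal(rep2$low_cm2, 0)
  # partition is conserved exactly
  set.seed(9)
  tawss3 <- runif(nf, 0, 10)
  rep3 <- adverse_areas(tawss3, m)
  expect_equal(rep3$low_cm2 + rep3$high_cm2 + rep3$normal_cm2, rep3$wall_cm2,
               tolerance = 1e-12)
  expect_error(adverse_areas(tawss3[-1], m), "per mesh face")
  tawss4 <- tawss3; tawss4[which(m$tags == "wall")[1]] <- NA
  expect_error(adverse_areas(tawss4, m), "missing")
})

test_that("attenuated false-lumen surfaces fall under the low-TAWSS threshold", {
  tr <- flap_truth()
  m <- flap_mesh()
  mc <- clip_and_extend(m, tr$centerline, 2, 18, ext_len = 0)
  w <- build_waveform("triphasic", psv = 88.3, mdv = -14.9)
  Q <- waveform_to_flow(w, pi * 4)
  ser <- poiseuille_field(mc, tr$centerline, Q, attenuation = 0.05)
  tw <- compute_tawss(ser)
  rep <- adverse_areas(tw, mc)
  # main-lumen TAWSS sits between the thresholds, so every attenuated
  # false-lumen face drops below 0.5 Pa
  main <- mc$tags == "wall"
  expect_gt(min(tw[main]), 0.5)
  expect_equal(rep$false_lumen_low_coverage, 1)
  expect_gte(rep$low_in_false_lumen_cm2, rep$false_lumen_cm2 - 1e-9)
})

test_that("Poiseuille field reflects local radius and flow scaling", {
  tr <- cyl_truth()
  mc <- cyl_clipped()
  tt <- seq(0, 1, length.out = 101)[-101]
  Qc <- waveform(tt, rep(100, 100), 1, kind = "flow")
  ser <- poiseuille_field(mc, tr$centerline, Qc)
  tw <- compute_tawss(ser)
  wall <- mc$tags == "wall"
  expect_lt(diff(range(tw[wall])) / mean(tw[wall]), 0.05)
  expect_lt(abs(mean(tw[wall]) / poiseuille_wss(100, 2) - 1), 0.05)

  # halving the radius multiplies local WSS by ~8
  sten <- make_phantom(phantom_spec("straight", length = 24, radius = 2,
                                    stenosis = list(position = 0.5, severity = 0.5,
                                                    width_mm = 16)),
                       voxel_spacing = 0.15)
  ms <- clip_and_extend(label_to_surface(sten$label_volume), sten$centerline,
                        2, 22, ext_len = 0)
  ser2 <- poiseuille_field(ms, sten$centerline, Qc, bin_mm = 1)
  tw2 <- compute_tawss(ser2)
  ctr <- vesselwarp:::face_centroids(ms)
  at <- function(z) mean(tw2[ms$tags == "wall" & abs(ctr[, 3] - z) < 0.5])
  expect_lt(abs(at(12) / at(3) / 8 - 1), 0.15)
})

test_that("group summaries reproduce published area statistics and textbook t-tests", {
  g <- fp_lumen_geometry()
  pre <- g$total_area_cm2[g$time_point == "pre_pta"]
  gs <- group_summary(pre, rep("pre", length(pre)))
  expect_equal(sprintf("%.2f", gs$summary$mean), "7.00")
  expect_equal(sprintf("%.2f", gs$summary$sd), "2.77")

  # hand-computed pooled t for {1,2,3} vs {4,5,6}: sp^2 = 1, so
  # t = -3 / sqrt(2/3), df = 4
  gs2 <- group_summary(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(gs2$tests$t, -3 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(gs2$tests$df, 4)
  expect_equal(gs2$tests$p, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-9)
  expect_equal(round(gs2$tests$p, 3), 0.021)
  expect_true(gs2$tests$significant)

  # identical groups compare equal
  gs3 <- group_summary(c(1, 2, 1, 2), rep(c("a", "b"), each = 2))
  expect_equal(gs3$tests$t, 0)
  expect_equal(gs3$tests$p, 1)
  expect_error(group_summary(c(1, 2, 3), c("a", "a", "b")), "n >= 2")

  # cross-check against the stats implementation on random data
  set.seed(33)
  for (i in 1:50) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), mean = runif(1))
    ours <- group_summary(c(x, y), c(rep("x", length(x)), rep("y", length(y))))
    ref <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(ours$tests$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$tests$p, ref$p.value, tolerance = 1e-9)
  }
})
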