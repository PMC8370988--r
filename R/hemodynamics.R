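#' Inlet velocity / flow waveform
#'
#' Periodic waveform over one cardiac cycle, either in velocity units
#' (cm/s, spatial mean over the inlet) or flow units (mm^3/s).
#'
#' @param t sample times in s, in `[0, T)`, strictly increasing.
#' @param values velocities (cm/s) or flows (mm^3/s).
#' @param period cycle period T in s.
#' @param kind `"velocity"` or `"flow"`.
#' @param phase_type `"monophasic"` or `"triphasic"`.
#' @param psv,mdv waveform extrema (same units as `values`).
#' @return object of class `waveform`.
#' @export
waveform <- function(t, values, period, kind = c("velocity", "flow"),
                     phase_type = c("triphasic", "monophasic"),
                     psv = max(values), mdv = min(values)) {
  kind <- match.arg(kind); phase_type <- match.arg(phase_type)
  if (any(t < 0 | t >= period)) stop("sample times must lie in [0, T)")
  if (is.unsorted(t, strictly = TRUE)) stop("sample times must be strictly increasing")
  structure(list(t = t, values = values, period = period, kind = kind,
                 phase_type = phase_type, psv = psv, mdv = mdv),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %s %s, T = %.2f s, range [%.2f, %.2f] %s\n",
              x$phase_type, x$kind, x$period, min(x$values), max(x$values),
              if (x$kind == "velocity") "cm/s" else "mm^3/s"))
  invisible(x)
}

# periodic linear interpolation of a waveform at arbitrary times
waveform_at <- function(w, t_query) {
  tq <- t_query %% w$period
  tt <- c(w$t, w$period)
  vv <- c(w$values, w$values[1])
  approx(tt, vv, xout = tq)$y
}

# time average over one period (trapezoid on the periodic closure)
waveform_mean <- function(w) {
  tt <- c(w$t, w$period)
  vv <- c(w$values, w$values[1])
  trapz_xy(tt, vv) / w$period
}

#' Build a template inlet velocity waveform from DUS extrema
#'
#' Peripheral-artery velocity waveforms are parameterized by their
#' duplex-ultrasound extrema: peak systolic velocity (PSV) and minimum
#' diastolic velocity (MDV).  The triphasic template is a piecewise
#' sinusoid: a forward systolic lobe reaching PSV, a reverse
#' early-diastolic lobe reaching MDV (< 0), a smaller forward
#' late-diastolic lobe, then a zero-flow rest phase.  The monophasic
#' template (used when the inlet sits downstream of a flow-limiting
#' lesion) is a single forward lobe riding on a non-negative diastolic
#' plateau.  Extrema are matched exactly by construction.
#'
#' @param phase_type `"triphasic"` or `"monophasic"`.
#' @param psv peak systolic velocity, cm/s (> 0).
#' @param mdv minimum diastolic velocity, cm/s (< 0 for triphasic,
#'   >= 0 for monophasic; default 0).
#' @param period cardiac period in s (default 1; the period is a
#'   modeling choice, not a measured quantity).
#' @param n_samples samples per cycle.
#' @param phase_fractions list with `systole`, `reverse`, `late`
#'   fractions of the period (defaults 0.30 / 0.20 / 0.25) and
#'   `late_amplitude` as a fraction of PSV (default 0.2).
#' @return a velocity [waveform].
#' @export
#' @examples
#' w <- build_waveform("triphasic", psv = 88.30, mdv = -14.90)
#' c(max(w$values), min(w$values))
build_waveform <- function(phase_type = c("triphasic", "monophasic"),
                           psv, mdv = 0, period = 1, n_samples = 500,
                           phase_fractions = list()) {
  phase_type <- match.arg(phase_type)
  if (psv <= 0) stop("psv must be > 0")
  pf <- modifyList(list(systole = 0.30, reverse = 0.20, late = 0.25,
                        late_amplitude = 0.2), phase_fractions)
  t <- seq(0, period, length.out = n_samples + 1)[seq_len(n_samples)]
  if (phase_type == "triphasic") {
    if (mdv >= 0) stop("triphasic waveform requires mdv < 0")
    t1 <- pf$systole * period
    t2 <- t1 + pf$reverse * period
    t3 <- t2 + pf$late * period
    v <- numeric(n_samples)
    i1 <- t < t1
    v[i1] <- psv * sin(pi * t[i1] / t1)
    i2 <- t >= t1 & t < t2
    v[i2] <- mdv * sin(pi * (t[i2] - t1) / (t2 - t1))
    i3 <- t >= t2 & t < t3
    v[i3] <- pf$late_amplitude * psv * sin(pi * (t[i3] - t2) / (t3 - t2))
    # exact extrema: the sampled grid may straddle the lobe peaks
    v[which.max(v)] <- psv
    v[which.min(v)] <- mdv
  } else {
    if (mdv < 0) stop("monophasic waveform requires mdv >= 0")
    t1 <- pf$systole * period
    v <- rep(mdv, n_samples)
    i1 <- t < t1
    v[i1] <- mdv + (psv - mdv) * sin(pi * t[i1] / t1)
    v[which.max(v)] <- psv
  }
  waveform(t, v, period, kind = "velocity", phase_type = phase_type,
           psv = psv, mdv = if (phase_type == "triphasic") mdv else min(v))
}

#' Convert a velocity waveform to a volumetric flow waveform
#'
#' `Q(t) = v(t) * A` with v the spatial-mean inlet velocity (cm/s,
#' converted to mm/s) and A the inlet area (mm^2), giving Q in mm^3/s.
#' The time-averaged flow in ml/min is attached as attribute
#' `mean_flow_ml_min`.
#'
#' @param w a velocity [waveform].
#' @param inlet_area inlet cross-section area in mm^2 (> 0).
#' @return a flow [waveform] (mm^3/s).
#' @export
waveform_to_flow <- function(w, inlet_area) {
  if (inlet_area <= 0) stop("inlet_area must be > 0")
  if (w$kind != "velocity") stop("expected a velocity waveform")
  q <- cm_s_to_mm_s(w$values) * inlet_area
  out <- waveform(w$t, q, w$period, kind = "flow", phase_type = w$phase_type,
                  psv = max(q), mdv = min(q))
  attr(out, "mean_flow_ml_min") <- mm3_s_to_ml_min(waveform_mean(out))
  out
}

#' Parabolic inlet velocity profile on a mesh cap
#'
#' Assigns each cap vertex the radial parabolic law
#' `v(r) = 2 v_mean (1 - (r / R_eff)^2)` about the cap centroid, with
#' `R_eff` the maximum centroid distance, then rescales so the
#' face-integrated flux equals `v_mean * area` exactly (the rescale is
#' a no-op for a circular cap up to discretization).
#'
#' @param v_mean spatial-mean inlet velocity (cm/s).
#' @param mesh a clipped [tri_mesh].
#' @param cap tag of the cap to load (default `"inlet"`).
#' @return list with `vertex_ids`, `speed` (cm/s per cap vertex),
#'   `direction` (unit inflow vector), `flux_cm_s_mm2`.
#' @export
parabolic_profile <- function(v_mean, mesh, cap = "inlet") {
  sel <- which(mesh$tags == cap)
  if (length(sel) == 0) stop("mesh has no '", cap, "' faces")
  f <- mesh$faces[sel, , drop = FALSE]
  # connectivity check: a single cap must be one vertex-connected patch
  comp <- face_components(f)
  if (max(comp) > 1)
    stop("cap '", cap, "' has ", max(comp),
         " components; parabolic profile needs a single planar cap")
  vid <- sort(unique(as.vector(f)))
  pts <- mesh$vertices[vid, , drop = FALSE]
  ctr <- colMeans(pts)
  r <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  R_eff <- max(r)
  law <- function(p) {
    rr <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    2 * v_mean * pmax(0, 1 - (rr / R_eff)^2)
  }
  speed <- law(pts)
  # face-integrated flux by edge-midpoint quadrature (exact for the
  # quadratic radial law, unlike vertex averaging on fan caps)
  a <- face_areas(tri_mesh(mesh$vertices, f, rep("inlet", nrow(f))))
  V <- mesh$vertices
  m12 <- (V[f[, 1], , drop = FALSE] + V[f[, 2], , drop = FALSE]) / 2
  m23 <- (V[f[, 2], , drop = FALSE] + V[f[, 3], , drop = FALSE]) / 2
  m31 <- (V[f[, 3], , drop = FALSE] + V[f[, 1], , drop = FALSE]) / 2
  fl <- sum(a * (law(m12) + law(m23) + law(m31)) / 3)
  target <- v_mean * sum(a)
  scale <- if (abs(fl) > 1e-12) target / fl else 1
  n_out <- colMeans(face_normals(mesh)[sel, , drop = FALSE])
  list(vertex_ids = vid, speed = speed * scale,
       direction = -unitv(n_out), flux_cm_s_mm2 = fl * scale)
}

# connected components of a face set (shared-vertex connectivity)
face_components <- function(faces) {
  nf <- nrow(faces)
  parent <- seq_len(nf)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  by_vert <- split(rep(seq_len(nf), 3), as.vector(faces))
  for (grp in by_vert) {
    if (length(grp) < 2) next
    r0 <- find(grp[1])
    for (g in grp[-1]) parent[find(g)] <- r0
  }
  roots <- vapply(seq_len(nf), find, integer(1))
  match(roots, unique(roots))
}

#' Two-element Windkessel outlet model
#'
#' @param R peripheral resistance in MPa s/mm^3 (> 0).
#' @param C compliance in mm^3/MPa (> 0).
#' @return object of class `windkessel_rc`.
#' @export
windkessel_rc <- function(R, C) {
  if (R <= 0 || C <= 0) stop("Windkessel R and C must be > 0")
  structure(list(R = R, C = C), class = "windkessel_rc")
}

#' @export
print.windkessel_rc <- function(x, ...) {
  cat(sprintf("<windkessel_rc> R = %.3g MPa s/mm^3, C = %.3g mm^3/MPa (tau = %.2f s)\n",
              x$R, x$C, x$R * x$C))
  invisible(x)
}

#' Integrate the two-element Windkessel pressure
#'
#' Solves `C dP/dt = Q(t) - P/R` from an initial pressure `P0`
#' (default 80 mmHg, the initial pressure applied to the whole
#' domain), cycle by cycle with an exponential midpoint integrator
#' (exact for piecewise-constant forcing), until the cycle-to-cycle
#' maximum pressure difference drops below `tol_mmHg`.  The last cycle
#' is returned, mirroring transient CFD practice of discarding
#' start-up cycles.
#'
#' @param Q a flow [waveform] in mm^3/s.
#' @param rc a [windkessel_rc].
#' @param P0 initial pressure in mmHg.
#' @param dt time step in s (default 2e-3).
#' @param tol_mmHg cycle convergence tolerance (default 0.1).
#' @param max_cycles cycle cap (default 20).
#' @return object of class `pressure_trace`: `t` (s over one cycle),
#'   `P_mmHg`, `p_sys`, `p_dia`, `cycles` run.
#' @export
windkessel_pressure <- function(Q, rc, P0 = 80, dt = 2e-3, tol_mmHg = 0.1,
                                max_cycles = 20) {
  stopifnot(inherits(rc, "windkessel_rc"))
  if (Q$kind != "flow") stop("expected a flow waveform (mm^3/s)")
  T_ <- Q$period
  nt <- max(2L, round(T_ / dt))
  tgrid <- seq(0, T_, length.out = nt + 1)
  q_mid <- waveform_at(Q, (tgrid[-1] + tgrid[-(nt + 1)]) / 2)
  h <- T_ / nt
  tau <- rc$R * rc$C
  decay <- exp(-h / tau)
  P <- mmHg_to_MPa(P0)
  prev <- NULL
  for (cyc in seq_len(max_cycles)) {
    trace <- numeric(nt + 1)
    trace[1] <- P
    for (i in seq_len(nt)) {
      Pinf <- q_mid[i] * rc$R
      P <- Pinf + (P - Pinf) * decay
      trace[i + 1] <- P
    }
    if (!is.null(prev) && max(abs(trace - prev)) < mmHg_to_MPa(tol_mmHg)) {
      prev <- trace
      break
    }
    if (cyc == max_cycles)
      stop(sprintf("Windkessel pressure did not reach a periodic state in %d cycles", max_cycles))
    prev <- trace
  }
  Pm <- MPa_to_mmHg(prev)
  structure(list(t = tgrid, P_mmHg = Pm, p_sys = max(Pm), p_dia = min(Pm),
                 cycles = cyc), class = "pressure_trace")
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf("<pressure_trace> %.1f/%.1f mmHg after %d cycles\n",
              x$p_sys, x$p_dia, x$cycles))
  invisible(x)
}

#' Calibrate Windkessel parameters against an idealized pressure profile
#'
#' Finds (R, C) such that the periodic Windkessel pressure driven by
#' the inlet flow has the prescribed systolic and diastolic extrema
#' (120/80 mmHg idealized profile by default).  A damped Newton
#' iteration in log-parameters with finite-difference Jacobian solves
#' the two-equation system; residuals of the fit are reported.
#'
#' @param Q a flow [waveform] (positive time average, pulsatile).
#' @param p_sys,p_dia target extrema in mmHg.
#' @param tol_mmHg convergence tolerance on the extrema (default 0.01).
#' @param max_iter Newton iteration cap.
#' @return a [windkessel_rc] with attribute `residual_mmHg`.
#' @export
calibrate_windkessel <- function(Q, p_sys = 120, p_dia = 80,
                                 tol_mmHg = 0.01, max_iter = 50) {
  if (p_sys <= p_dia) stop("infeasible targets: p_sys must exceed p_dia")
  qm <- waveform_mean(Q)
  if (qm <= 0) stop("flow waveform must have a positive time average")
  if ((max(Q$values) - min(Q$values)) < 1e-9 * max(abs(Q$values), 1))
    stop("constant flow: the compliance C is unidentifiable from pressure extrema")

  fwd <- function(x) {
    rc <- windkessel_rc(exp(x[1]), exp(x[2]))
    pt <- windkessel_pressure(Q, rc, P0 = p_dia, tol_mmHg = tol_mmHg / 10,
                              max_cycles = 100)
    c(pt$p_sys - p_sys, pt$p_dia - p_dia)
  }
  R0 <- mmHg_to_MPa((p_sys + p_dia) / 2) / qm
  x <- log(c(R0, 1.5 / R0))
  f <- fwd(x)
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < tol_mmHg) break
    J <- matrix(0, 2, 2)
    hstep <- 1e-4
    for (j in 1:2) {
      xp <- x; xp[j] <- xp[j] + hstep
      J[, j] <- (fwd(xp) - f) / hstep
    }
    step <- tryCatch(solve(J, -f), error = function(e) -f * 0.1)
    lam <- 1
    repeat {
      xn <- x + lam * step
      fn <- tryCatch(fwd(xn), error = function(e) rep(Inf, 2))
      if (sum(fn^2) < sum(f^2) || lam < 1e-4) break
      lam <- lam / 2
    }
    x <- xn; f <- fn
  }
  if (max(abs(f)) > 10 * tol_mmHg)
    warning(sprintf("Windkessel calibration residual %.3g mmHg above tolerance", max(abs(f))))
  out <- windkessel_rc(exp(x[1]), exp(x[2]))
  attr(out, "residual_mmHg") <- max(abs(f))
  out
}

#' Poiseuille wall shear stress
#'
#' Fully developed laminar flow in a circular tube:
#' `tau = 4 mu Q / (pi r^3)`.  With Q in mm^3/s, r in mm and mu in
#' Pa s, the result is in Pa directly.  Serves as the analytic
#' desk-scale oracle for wall shear stress where a full 3D solver is
#' out of scope.
#'
#' @param Q flow in mm^3/s.
#' @param radius lumen radius in mm (> 0).
#' @param mu dynamic viscosity in Pa s (default 3.5e-3, blood).
#' @return wall shear stress in Pa.
#' @export
#' @examples
#' poiseuille_wss(100, 2) # 0.0557 Pa
poiseuille_wss <- function(Q, radius, mu = 3.5e-3) {
  if (any(radius <= 0)) stop("radius must be > 0")
  4 * mu * Q / (pi * radius^3)
}
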