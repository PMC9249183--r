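# Default verification grid: stenosed, healthy and dilated stations at
# realistic plug radii and drives.
oracle_grid <- function() {
  expand.grid(H = c(0.7, 0.85, 1.0, 1.1),
              r0 = c(0, 0.1, 0.2, 0.3),
              drive = c(0.5, 1, 2))
}

#' Station flux by adaptive quadrature
#'
#' Brute-force evaluation of `Q = 2 * int_0^r0 u_p r dr + 2 * int_r0^H u r dr`
#' from the velocity profile itself, used to guard the closed-form
#' conductance. The plug integral is `u_p * r0^2`; the sheared annulus is
#' integrated adaptively.
#'
#' @param H Station wall radius.
#' @param r0 Plug-core radius, `r0 <= H`.
#' @param drive Net axial drive `M + f + P`.
#' @param rel_tol Relative tolerance passed to the adaptive integrator.
#' @return The flux `Q`; agrees with `conductance(H, r0) * drive`.
#' @export
flux_by_quadrature <- function(H, r0, drive, rel_tol = 1e-10) {
  if (r0 > H) plug_overflow_error(r0, H)
  plug_part <- plug_velocity(H, r0, drive) * r0^2
  if (r0 >= H) return(plug_part)
  ann <- stats::integrate(function(r) axial_velocity(r, H, r0, drive) * r,
                          lower = r0, upper = H,
                          rel.tol = rel_tol, abs.tol = 1e-14,
                          subdivisions = 500L)
  if (ann$message != "OK")
    stop("flux quadrature did not converge: ", ann$message)
  plug_part + 2 * ann$value
}

# Richardson-extrapolated one-sided derivative of u at the wall, using the
# second-order formula (4 u(H-h) - u(H-2h)) / (2h) (u(H) = 0 by no-slip).
wall_slope_fd <- function(H, r0, drive, step) {
  fd <- function(h) (4 * axial_velocity(H - h, H, r0, drive) -
                       axial_velocity(H - 2 * h, H, r0, drive)) / (2 * h)
  (4 * fd(step / 2) - fd(step)) / 3
}

#' Wall shear stress by finite differences
#'
#' Independent check of the closed-form wall shear stress: reconstructs the
#' drive from the flux via the chosen mode's inversion, then measures
#' `-du/dr` at `r = H` by a Richardson-extrapolated one-sided finite
#' difference of the velocity profile. In `"derived"` mode this matches
#' [wall_shear_stress()] directly; in `"paper"` mode the printed formula
#' contains an additive body-force term that is not a velocity gradient, so
#' only the difference structure is meaningful there.
#'
#' @inheritParams pressure_gradient
#' @param step Finite-difference step; must be small relative to `H - r0`.
#' @return The finite-difference wall shear stress.
#' @export
wss_by_finite_difference <- function(Q, H, r0, force = force_field(),
                                     mode = c("paper", "derived"),
                                     step = 1e-3) {
  mode <- match.arg(mode)
  if (2 * step >= (H - r0))
    stop("finite-difference step too large relative to the sheared annulus")
  P <- pressure_gradient(Q, H, r0, force, mode)
  drive <- force$M + force$f + P
  wall_slope_fd(H, r0, drive, step)
}

#' Residual of the Casson constitutive law
#'
#' With the momentum balance giving `tau(r) = drive * r / 2` and the yield
#' stress `tau0 = drive * r0 / 2`, the Casson law requires
#' `sqrt(tau) = sqrt(tau0) + sqrt(-du/dr)` throughout the sheared annulus.
#' The velocity slope is measured by Richardson-extrapolated central
#' differences of [axial_velocity()], so the check is independent of the
#' analytic slope.
#'
#' @param H Station wall radius.
#' @param r0 Plug-core radius.
#' @param drive Net axial drive (must be positive for the law to apply).
#' @param r_grid Radii in `(r0, H]` at which to evaluate the residual;
#'   defaults to ten points spanning the annulus.
#' @return Maximum absolute residual over the grid.
#' @export
casson_residual <- function(H, r0, drive, r_grid = NULL) {
  stopifnot(drive > 0, r0 < H)
  if (is.null(r_grid))
    r_grid <- r0 + (H - r0) * seq(0.1, 0.99, length.out = 10)
  if (any(r_grid <= r0) || any(r_grid > H))
    stop("residual grid must lie in (r0, H]")
  tau0 <- drive * r0 / 2
  res <- vapply(r_grid, function(r) {
    h <- min(1e-3, (H - r) / 2, (r - r0) / 2)
    if (h <= 0) h <- 1e-6
    cd <- function(hh) (axial_velocity(r + hh, H, r0, drive) -
                          axial_velocity(r - hh, H, r0, drive)) / (2 * hh)
    slope <- (4 * cd(h / 2) - cd(h)) / 3
    tau <- drive * r / 2
    sqrt(tau) - sqrt(tau0) - sqrt(pmax(-slope, 0))
  }, numeric(1))
  max(abs(res))
}

oracle_row <- function(name, abs_err, rel_err, grid, tol, use_rel = TRUE) {
  data.frame(name = name,
             max_abs_error = abs_err, max_rel_error = rel_err,
             grid = grid, tolerance = tol,
             passed = (if (use_rel) rel_err else abs_err) <= tol,
             stringsAsFactors = FALSE)
}

#' Run the full oracle suite
#'
#' Verifies every closed form against brute force and the degenerate limits:
#' flux versus adaptive quadrature, the Casson constitutive residual, the
#' finite-difference wall shear stress, no-slip and plug-flatness, the
#' Newtonian collapse, and the unit normalizations of an unlesioned vessel.
#'
#' @return A data frame (one row per verifier) with columns `name`,
#'   `max_abs_error`, `max_rel_error`, `grid`, `tolerance`, `passed`.
#' @examples
#' \donttest{
#' rep <- limit_suite()
#' all(rep$passed)
#' }
#' @export
limit_suite <- function() {
  grid <- oracle_grid()
  out <- list()

  # Flux: closed form vs quadrature
  rel <- mapply(function(H, r0, D) {
    q_ref <- flux_by_quadrature(H, r0, D)
    abs(q_ref - conductance(H, r0) * D) / max(abs(q_ref), 1e-300)
  }, grid$H, grid$r0, grid$drive)
  out$flux <- oracle_row("flux_closed_form_vs_quadrature",
                         max(rel * 1), max(rel),
                         "H x r0 x drive default grid", 1e-8)

  # Constitutive residual
  res <- mapply(function(H, r0, D) casson_residual(H, r0, D),
                grid$H, grid$r0, grid$drive)
  out$casson <- oracle_row("casson_constitutive_residual",
                           max(res), max(res),
                           "H x r0 x drive default grid", 1e-8, use_rel = FALSE)

  # Wall shear stress: derived closed form vs finite difference
  frc <- force_field(M = 0.7, F_grav = 0.3, phi = pi / 6)
  sub <- grid[grid$r0 < grid$H - 0.05, ]
  rel_w <- mapply(function(H, r0, D) {
    Q <- conductance(H, r0) * D
    fd <- wss_by_finite_difference(Q, H, r0, frc, "derived")
    cf <- wall_shear_stress(Q, H, r0, frc, "derived")
    abs(fd - cf) / max(abs(cf), 1e-300)
  }, sub$H, sub$r0, sub$drive)
  out$wss <- oracle_row("wss_closed_form_vs_finite_difference",
                        max(rel_w), max(rel_w),
                        "H x r0 x drive default grid", 1e-6)

  # No-slip and plug flatness
  noslip <- max(abs(mapply(function(H, r0, D) axial_velocity(H, H, r0, D),
                           grid$H, grid$r0, grid$drive)))
  out$noslip <- oracle_row("no_slip_at_wall", noslip, noslip,
                           "H x r0 x drive default grid", 1e-14,
                           use_rel = FALSE)
  flat <- max(abs(mapply(function(H, r0, D) {
    axial_velocity(r0, H, r0, D) - plug_velocity(H, r0, D)
  }, grid$H, grid$r0, grid$drive)))
  out$plug <- oracle_row("plug_velocity_continuity", flat, flat,
                         "H x r0 x drive default grid", 1e-14,
                         use_rel = FALSE)

  # Newtonian collapse: r0 = 0 recovers Poiseuille profile, g = H^4/8,
  # tau_w = 4 Q / H^3 (derived mode, unforced)
  newt <- max(vapply(c(0.7, 0.85, 1.0, 1.1), function(H) {
    r <- seq(0, H, length.out = 11)
    e1 <- max(abs(axial_velocity(r, H, 0, 1) - (H^2 - r^2) / 4))
    e2 <- abs(conductance(H, 0) - H^4 / 8)
    Q <- conductance(H, 0)
    e3 <- abs(wall_shear_stress(Q, H, 0, force_field(0, 0, 0), "derived") -
                4 * Q / H^3)
    max(e1, e2, e3)
  }, numeric(1)))
  out$newtonian <- oracle_row("newtonian_collapse", newt, newt,
                              "H in {0.7, 0.85, 1.0, 1.1}", 1e-12,
                              use_rel = FALSE)

  # Healthy vessel: unit normalizations in both modes
  geom0 <- vessel_geometry(list(
    abnormal_segment(0, 0.2, 0.2, "stenosis"),
    abnormal_segment(0, 0.2, 0.6, "dilatation")
  ))
  norm_err <- max(vapply(c("paper", "derived"), function(m) {
    lb <- normalized_impedance(0.1, geom0, 0.2, frc, m)
    tw <- normalized_wss(0.1, geom0, 0.2, frc, m, station = 0.3)
    max(abs(lb - 1), abs(tw - 1))
  }, numeric(1)))
  out$norm <- oracle_row("healthy_vessel_unit_normalization",
                         norm_err, norm_err, "both modes", 1e-12,
                         use_rel = FALSE)

  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
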