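#' Constant axial body-force field
#'
#' The net dimensionless axial drive on the fluid is `M + f + P`: a
#' magnetization constant `M`, a gravity/inclination term `f = F * sin(phi)`,
#' and the pressure gradient `P`. `M` and `F` are taken as given
#' dimensionless constants; `phi` is the inclination of the tube axis to the
#' horizontal, in radians.
#'
#' @param M Magnetization constant (dimensionless), default 2.
#' @param F_grav Gravity constant (dimensionless), default 0.3.
#' @param phi Inclination angle in radians, default `pi/6`.
#' @return An object of class `force_field` with fields `M`, `F`, `phi` and
#'   the derived `f = F * sin(phi)`.
#' @examples
#' force_field(M = 2, F_grav = 0.3, phi = pi / 6)
#' force_field(M = 0, F_grav = 0, phi = 0)  # unforced horizontal tube
#' @export
force_field <- function(M = 2, F_grav = 0.3, phi = pi / 6) {
  stopifnot(is.numeric(M), is.numeric(F_grav), is.numeric(phi),
            is.finite(M), is.finite(F_grav), is.finite(phi))
  structure(list(M = as.numeric(M), F = as.numeric(F_grav),
                 phi = as.numeric(phi),
                 f = as.numeric(F_grav) * sin(as.numeric(phi))),
            class = "force_field")
}

#' @export
print.force_field <- function(x, ...) {
  cat(sprintf("Body forces: M = %g, F = %g, phi = %g rad (f = F sin phi = %g)\n",
              x$M, x$F, x$phi, x$f))
  invisible(x)
}

plug_overflow_error <- function(r0, H, where = NULL) {
  msg <- sprintf("plug core (r0 = %g) is wider than the lumen (H = %g)%s",
                 r0, H, if (is.null(where)) "" else sprintf(" at z = %g", where))
  stop(errorCondition(msg, class = c("stenoflow_plug_overflow", "error")))
}

#' Station conductance of the Casson flow
#'
#' At a station of radius `H` the flux is `Q = g(H, r0) * (M + f + P)` with
#' the Buckingham-Reiner-type conductance
#' `g = H^3 r0 / 6 + H^4 / 8 - r0^4 / 168 - (2/7) sqrt(r0) H^(7/2)`.
#' For `r0 = 0` this collapses to the Newtonian Poiseuille value `H^4 / 8`.
#'
#' @param H Station wall radius (dimensionless), `H > 0`. Vectorized.
#' @param r0 Plug-core radius, `0 <= r0 <= H`.
#' @return The conductance `g`, positive for `r0 < H`, zero at `r0 = H`.
#' @examples
#' conductance(1, 0)    # 1/8, Newtonian tube
#' conductance(0.8, 0)  # 0.8^4 / 8
#' @export
conductance <- function(H, r0) {
  stopifnot(is.numeric(H), is.numeric(r0))
  if (any(r0 < 0)) stop("plug radius r0 must be non-negative")
  if (any(r0 > H + 1e-15)) plug_overflow_error(max(r0), min(H))
  H^3 * r0 / 6 + H^4 / 8 - r0^4 / 168 - (2 / 7) * sqrt(r0) * H^(7 / 2)
}

#' Axial velocity profile with plug core
#'
#' Outside the plug (`r0 <= r <= H`) the Casson solution is
#' `u = (D/2) * ((H^2 - r^2)/2 - (4/3) sqrt(r0) (H^(3/2) - r^(3/2)) + r0 (H - r))`
#' with `D = M + f + P` the net drive and viscosity 1 in dimensionless form;
#' inside the plug (`r < r0`) the fluid moves rigidly at the plug velocity.
#' The profile satisfies no-slip `u(H) = 0` and a shear-free plug boundary
#' `du/dr = 0` at `r = r0`.
#'
#' @param r Radial coordinate(s) in `[0, H]`. Vectorized.
#' @param H Station wall radius.
#' @param r0 Plug-core radius, `r0 <= H`.
#' @param drive Net axial drive `D = M + f + P`.
#' @return Velocity at each `r`.
#' @examples
#' axial_velocity(0, 1, 0, 1)  # Poiseuille centerline: 1/4
#' axial_velocity(1, 1, 0.2, 1)  # no-slip wall: 0
#' @export
axial_velocity <- function(r, H, r0, drive) {
  stopifnot(is.numeric(r), length(H) == 1L, length(r0) == 1L,
            length(drive) == 1L)
  if (any(r < 0) || any(r > H + 1e-15))
    stop(sprintf("radial coordinate outside [0, %g]", H))
  if (r0 > H + 1e-15) plug_overflow_error(r0, H)
  rr <- pmax(r, r0)  # plug region rides at u(r0)
  (drive / 2) * ((H^2 - rr^2) / 2 -
                   (4 / 3) * sqrt(r0) * (H^(3 / 2) - rr^(3 / 2)) +
                   r0 * (H - rr))
}

#' Plug (core) velocity
#'
#' Closed form of [axial_velocity()] at `r = r0`:
#' `u_p = (D/2) * (H^2/2 + H r0 - (4/3) sqrt(r0) H^(3/2) - r0^2/6)`.
#' At `r0 = 0` this is the Poiseuille centerline speed `D H^2 / 4`; at
#' `r0 = H` the bracket vanishes and the whole cross-section is unyielded
#' and motionless.
#'
#' @inheritParams axial_velocity
#' @return The plug velocity `u_p`.
#' @export
plug_velocity <- function(H, r0, drive) {
  if (any(r0 > H + 1e-15)) plug_overflow_error(max(r0), min(H))
  (drive / 2) * (H^2 / 2 + H * r0 - (4 / 3) * sqrt(r0) * H^(3 / 2) - r0^2 / 6)
}

#' Pressure gradient sustaining a prescribed flux
#'
#' Inverts the flux relation at a station. Two conventions are provided:
#' `"paper"` reproduces the published parameter studies,
#' `P = -Q/g(H, r0) + (M + f)`; `"derived"` is the sign-consistent inversion
#' of `Q = g * (M + f + P)`, namely `P = Q/g - (M + f)`. With no body
#' forces the two differ only by sign.
#'
#' @param Q Dimensionless volumetric flux.
#' @param H Station wall radius. Vectorized.
#' @param r0 Plug-core radius.
#' @param force A [force_field()].
#' @param mode `"paper"` (default) or `"derived"`.
#' @return The pressure gradient `P` at the station.
#' @export
pressure_gradient <- function(Q, H, r0, force = force_field(),
                              mode = c("paper", "derived")) {
  mode <- match.arg(mode)
  stopifnot(inherits(force, "force_field"))
  g <- conductance(H, r0)
  if (any(abs(g) < 1e-13))
    stop("degenerate station: conductance is zero (r0 = H)")
  mf <- force$M + force$f
  if (mode == "paper") -Q / g + mf else Q / g - mf
}

#' Wall shear stress at a station
#'
#' In `"derived"` mode this is the physical viscous traction
#' `tau_w = -du/dr` at `r = H` with the drive eliminated through the flux
#' relation: `tau_w = Q (sqrt(H) - sqrt(r0))^2 / (2 g(H, r0))`, which
#' collapses to the Newtonian `4 Q / H^3` at `r0 = 0`. In `"paper"` mode the
#' published form is used, which adds the body-force term:
#' `tau_w = Q (sqrt(H) - sqrt(r0))^2 / (2 g) + (M + f)`.
#'
#' @inheritParams pressure_gradient
#' @return The wall shear stress.
#' @export
wall_shear_stress <- function(Q, H, r0, force = force_field(),
                              mode = c("paper", "derived")) {
  mode <- match.arg(mode)
  stopifnot(inherits(force, "force_field"))
  g <- conductance(H, r0)
  if (any(abs(g) < 1e-13))
    stop("degenerate station: conductance is zero (r0 = H)")
  core <- Q * (sqrt(H) - sqrt(r0))^2 / (2 * g)
  if (mode == "paper") core + force$M + force$f else core
}

#' Plug radius from the yield stress
#'
#' The force balance over the plug core gives `P r0 / 2 = tau0`, hence
#' `r0 = 2 tau0 / |P|`. This converter is provided for dimensional
#' convenience; the dimensionless pipeline treats `r0` as a free input.
#'
#' @param tau0 Yield stress, `>= 0`.
#' @param P Pressure gradient; must be non-zero when `tau0 > 0`.
#' @param lumen_radius Smallest lumen radius the plug must fit inside
#'   (default 1); exceeding it raises a plug-overflow error.
#' @return The plug-core radius `r0`.
#' @examples
#' plug_radius_from_yield(0.1, 1)  # 0.2
#' @export
plug_radius_from_yield <- function(tau0, P, lumen_radius = 1) {
  stopifnot(is.numeric(tau0), is.numeric(P), tau0 >= 0)
  if (tau0 == 0) return(0)
  if (P == 0)
    stop("no flow: zero pressure gradient cannot overcome a positive yield stress")
  r0 <- 2 * tau0 / abs(P)
  if (r0 >= lumen_radius) plug_overflow_error(r0, lumen_radius)
  r0
}
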