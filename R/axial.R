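# Composite Simpson rule on [a, b] with n (even) subintervals, given a
# vectorized integrand.
simpson <- function(f, a, b, n) {
  if (n %% 2L) n <- n + 1L
  x <- seq(a, b, length.out = n + 1L)
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  sum(w * f(x)) * (b - a) / (3 * n)
}

# Panel-aligned composite Simpson: breakpoints at segment bounds so that the
# derivative kinks of H(z) at alpha_i, beta_i never fall inside a panel.
# 'nodes' is the total node budget, allocated proportionally to panel length.
simpson_panels <- function(f, breaks, nodes) {
  breaks <- sort(unique(breaks))
  lens <- diff(breaks)
  total <- sum(lens)
  val <- 0
  for (i in seq_along(lens)) {
    ni <- max(2L, 2L * ceiling((nodes - 1L) * lens[i] / total / 2))
    val <- val + simpson(f, breaks[i], breaks[i + 1L], ni)
  }
  val
}

quad_breaks <- function(geometry) {
  b <- segment_bounds(geometry)
  L <- geometry$domain_length
  pts <- c(0, L)
  if (nrow(b)) pts <- c(pts, b$alpha[b$alpha < L], b$beta[b$beta < L])
  sort(unique(pts))
}

check_plug_fits <- function(geometry, r0) {
  deltas <- vapply(geometry$segments, `[[`, numeric(1), "delta")
  Hmin <- geometry$reference_radius - if (length(deltas)) max(c(deltas, 0)) else 0
  if (r0 >= Hmin) {
    z_worst <- if (length(deltas) && max(deltas) > 0)
      segment_midpoint(geometry, which.max(deltas)) else 0
    plug_overflow_error(r0, Hmin, where = z_worst)
  }
  invisible(Hmin)
}

#' Pressure drop along the vessel
#'
#' Integrates the station pressure gradient over the whole domain,
#' `delta_p = integral of P(z) dz` on `[0, domain_length]`, by composite
#' Simpson quadrature with panels aligned to the segment boundaries (where
#' the wall profile has derivative kinks). The integrand is the closed-form
#' [pressure_gradient()] in the chosen mode.
#'
#' @param Q Dimensionless flux.
#' @param geometry A [vessel_geometry()].
#' @param r0 Plug-core radius; must be smaller than the narrowest lumen.
#' @param force A [force_field()].
#' @param mode `"paper"` or `"derived"`; see [pressure_gradient()].
#' @param quadrature_points Total quadrature node budget (default 2001).
#' @return The signed pressure drop `delta_p`.
#' @export
pressure_drop <- function(Q, geometry, r0, force = force_field(),
                          mode = c("paper", "derived"),
                          quadrature_points = 2001L) {
  mode <- match.arg(mode)
  stopifnot(inherits(geometry, "vessel_geometry"))
  check_plug_fits(geometry, r0)
  integrand <- function(z)
    pressure_gradient(Q, wall_radius(z, geometry), r0, force, mode)
  simpson_panels(integrand, quad_breaks(geometry), quadrature_points)
}

#' Flow impedance (resistance)
#'
#' `lambda = delta_p / Q`, the pressure drop per unit flux.
#'
#' @inheritParams pressure_drop
#' @return The impedance `lambda`.
#' @export
impedance <- function(Q, geometry, r0, force = force_field(),
                      mode = c("paper", "derived"),
                      quadrature_points = 2001L) {
  if (Q == 0) stop("impedance is undefined at zero flux")
  pressure_drop(Q, geometry, r0, force, mode, quadrature_points) / Q
}

#' Impedance of the healthy (uniform) tube
#'
#' The no-lesion reference: the same integral with `H == 1` over the same
#' domain length, so the normalized ratio compares like with like. The
#' integrand is constant, hence the quadrature is exact.
#'
#' @inheritParams pressure_drop
#' @param domain_length Axial extent of the reference tube (use the same
#'   value as the lesioned geometry being normalized).
#' @return The reference impedance `lambda_n`.
#' @export
reference_impedance <- function(Q, r0, force = force_field(),
                                mode = c("paper", "derived"),
                                domain_length = 1) {
  mode <- match.arg(mode)
  if (Q == 0) stop("impedance is undefined at zero flux")
  if (r0 >= 1) plug_overflow_error(r0, 1)
  pressure_gradient(Q, 1, r0, force, mode) * domain_length / Q
}

#' Normalized flow impedance
#'
#' `lambda_bar = lambda / lambda_n`: the impedance of the lesioned vessel
#' relative to a healthy tube of the same length. Equals 1 exactly when all
#' lesion heights are zero.
#'
#' @inheritParams pressure_drop
#' @return The normalized impedance `lambda_bar`.
#' @export
normalized_impedance <- function(Q, geometry, r0, force = force_field(),
                                 mode = c("paper", "derived"),
                                 quadrature_points = 2001L) {
  mode <- match.arg(mode)
  lam <- impedance(Q, geometry, r0, force, mode, quadrature_points)
  lam_n <- reference_impedance(Q, r0, force, mode, geometry$domain_length)
  if (lam_n == 0) stop("reference impedance is zero; cannot normalize")
  lam / lam_n
}

#' Wall shear stress of the healthy tube
#'
#' [wall_shear_stress()] evaluated at `H = 1`; independent of the geometry.
#'
#' @inheritParams pressure_gradient
#' @return The reference wall shear stress `tau_wn`.
#' @export
reference_wss <- function(Q, r0, force = force_field(),
                          mode = c("paper", "derived")) {
  mode <- match.arg(mode)
  if (r0 >= 1) plug_overflow_error(r0, 1)
  wall_shear_stress(Q, 1, r0, force, mode)
}

#' Normalized wall shear stress at a station
#'
#' `tau_bar_w = tau_w(z*) / tau_wn`. The default station `"throat"` is the
#' midpoint of the first non-zero lesion, where the lumen deviation is
#' maximal; any axial coordinate inside the domain may be given instead.
#'
#' @inheritParams pressure_drop
#' @param station Either `"throat"` or a numeric axial coordinate.
#' @return The normalized wall shear stress `tau_bar_w`.
#' @export
normalized_wss <- function(Q, geometry, r0, force = force_field(),
                           mode = c("paper", "derived"), station = "throat") {
  mode <- match.arg(mode)
  stopifnot(inherits(geometry, "vessel_geometry"))
  z_star <- if (identical(station, "throat")) throat_station(geometry)
            else as.numeric(station)
  H_star <- wall_radius(z_star, geometry)
  if (r0 >= H_star) plug_overflow_error(r0, H_star, where = z_star)
  tau <- wall_shear_stress(Q, H_star, r0, force, mode)
  tau_n <- reference_wss(Q, r0, force, mode)
  if (tau_n == 0) stop("reference wall shear stress is zero; cannot normalize")
  tau / tau_n
}

#' Full axial solution for one parameter set
#'
#' Convenience wrapper assembling the pressure drop, impedance, wall-shear
#' profile and all normalized quantities into one object.
#'
#' @inheritParams pressure_drop
#' @param station Station for the normalized wall shear stress
#'   (`"throat"` or numeric).
#' @param profile_points Number of axial stations in the emitted
#'   wall-shear profile table.
#' @return An object of class `axial_solution`: a list with `delta_p`,
#'   `lambda`, `lambda_n`, `lambda_bar`, `tau_wn`, `tau_bar_w`,
#'   `station` (the resolved z), and `profile`, a data frame with columns
#'   `z`, `H`, `P`, `tau_w`.
#' @examples
#' geom <- vessel_geometry(list(abnormal_segment(0.1, 0.2, 0.2, "stenosis")))
#' sol <- axial_solution(0.1, geom, 0.2)
#' sol$lambda_bar
#' @export
axial_solution <- function(Q, geometry, r0, force = force_field(),
                           mode = c("paper", "derived"), station = "throat",
                           quadrature_points = 2001L, profile_points = 201L) {
  mode <- match.arg(mode)
  dp <- pressure_drop(Q, geometry, r0, force, mode, quadrature_points)
  lam <- dp / Q
  lam_n <- reference_impedance(Q, r0, force, mode, geometry$domain_length)
  z <- seq(0, geometry$domain_length, length.out = profile_points)
  H <- wall_profile(z, geometry)
  prof <- data.frame(
    z = z, H = H,
    P = pressure_gradient(Q, H, r0, force, mode),
    tau_w = wall_shear_stress(Q, H, r0, force, mode)
  )
  z_star <- if (identical(station, "throat")) throat_station(geometry)
            else as.numeric(station)
  structure(list(
    delta_p = dp, abs_delta_p = abs(dp),
    lambda = lam, lambda_n = lam_n, lambda_bar = lam / lam_n,
    tau_wn = reference_wss(Q, r0, force, mode),
    tau_bar_w = normalized_wss(Q, geometry, r0, force, mode, z_star),
    station = z_star, mode = mode, profile = prof
  ), class = "axial_solution")
}

#' @export
print.axial_solution <- function(x, ...) {
  cat(sprintf("Axial Casson solution (%s mode)\n", x$mode))
  cat(sprintf("  delta_p    = %.6g\n", x$delta_p))
  cat(sprintf("  lambda     = %.6g   lambda_n = %.6g   lambda_bar = %.6g\n",
              x$lambda, x$lambda_n, x$lambda_bar))
  cat(sprintf("  tau_wn     = %.6g   tau_bar_w(z = %.3g) = %.6g\n",
              x$tau_wn, x$station, x$tau_bar_w))
  invisible(x)
}
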