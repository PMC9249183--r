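sweep_params <- c("delta1", "delta2", "M", "phi", "r0")

#' Default sweep grid for a parameter
#'
#' Uniform grids bracketing the anchor values of the parameter studies:
#' lesion heights over `[0, 0.2]`, plug radius over `[0.01, 0.4]`,
#' magnetization over `[0, 4]`, inclination over `[0, pi/2]`.
#'
#' @param param One of `"delta1"`, `"delta2"`, `"M"`, `"phi"`, `"r0"`.
#' @param n Number of grid points (default 21).
#' @return A sorted numeric vector.
#' @export
default_sweep_grid <- function(param, n = 21L) {
  param <- match.arg(param, sweep_params)
  switch(param,
         delta1 = , delta2 = seq(0, 0.2, length.out = n),
         r0 = seq(0.01, 0.4, length.out = n),
         M = seq(0, 4, length.out = n),
         phi = seq(0, pi / 2, length.out = n))
}

#' Specify a parameter sweep
#'
#' One parameter is swept along a grid; optionally a second "family"
#' parameter takes a few values, one response curve per value (as in the
#' multi-curve parameter-study figures).
#'
#' @param swept Name of the swept parameter: `"delta1"` (stenosis height),
#'   `"delta2"` (dilatation height), `"M"`, `"phi"` or `"r0"`.
#' @param grid Sorted numeric grid for the swept parameter; defaults to
#'   [default_sweep_grid()].
#' @param family Optional name of the second varied parameter.
#' @param family_values Values of the family parameter (one curve each).
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(swept, grid = default_sweep_grid(swept),
                       family = NULL, family_values = NULL) {
  swept <- match.arg(swept, sweep_params)
  if (!length(grid)) stop("sweep grid must be non-empty")
  if (is.unsorted(grid, strictly = TRUE))
    stop("sweep grid must be strictly increasing")
  if (!is.null(family)) {
    family <- match.arg(family, sweep_params)
    if (identical(family, swept))
      stop("swept and family parameters must be distinct")
    if (!length(family_values)) stop("family_values must be non-empty")
    if (is.unsorted(family_values, strictly = TRUE))
      stop("family_values must be strictly increasing")
  }
  structure(list(swept = swept, grid = as.numeric(grid), family = family,
                 family_values = as.numeric(family_values)),
            class = "sweep_spec")
}

set_sweep_param <- function(config, param, value) {
  switch(param,
    delta1 = {
      if (!identical(config$geometry$segments[[1]]$kind, "stenosis"))
        stop("sweeping delta1 requires segment 1 to be the stenosis")
      config$geometry$segments[[1]]$height <- value
    },
    delta2 = {
      if (length(config$geometry$segments) < 2 ||
          !identical(config$geometry$segments[[2]]$kind, "dilatation"))
        stop("sweeping delta2 requires segment 2 to be the dilatation")
      config$geometry$segments[[2]]$height <- value
    },
    M = config$forces$M <- value,
    phi = config$forces$phi <- value,
    r0 = config$casson$plug_radius <- value
  )
  config
}

# Station at which WSS and velocity are reported: pinned to the lesion being
# varied so that the response actually reflects the sweep; otherwise the
# first non-zero lesion.
sweep_station <- function(spec, geometry) {
  lesion <- intersect(c(spec$swept, spec$family), c("delta1", "delta2"))
  if (length(lesion)) {
    idx <- if (lesion[1] == "delta1") 1L else 2L
    return(segment_midpoint(geometry, idx))
  }
  deltas <- vapply(geometry$segments, `[[`, numeric(1), "delta")
  idx <- which(deltas != 0)[1]
  if (is.na(idx)) idx <- 1L
  segment_midpoint(geometry, idx)
}

#' Run a parameter sweep
#'
#' Evaluates the normalized impedance, the normalized wall shear stress at
#' the varied lesion's throat, and the axial velocity (plug/centerline and
#' at a fixed probe radius, default 0.2) at that station, for every
#' combination of swept and family values. The computation is closed-form
#' plus fixed quadrature: identical inputs give identical tables.
#'
#' @param spec A [sweep_spec()].
#' @param config Base configuration; see [default_config()]. Parameters not
#'   swept keep their configured values, so set the height of a lesion to 0
#'   in the config to study the other lesion in isolation.
#' @return A data frame with columns `swept_name`, `swept_value`,
#'   `family_name`, `family_value`, `lambda_bar`, `tau_bar_w`, `u_center`,
#'   `u_at_r`.
#' @export
run_sweep <- function(spec, config = default_config()) {
  stopifnot(inherits(spec, "sweep_spec"))
  fam_vals <- if (is.null(spec$family)) NA_real_ else spec$family_values
  rows <- vector("list", length(spec$grid) * length(fam_vals))
  k <- 0L
  for (fv in fam_vals) {
    for (sv in spec$grid) {
      cfg <- set_sweep_param(config, spec$swept, sv)
      if (!is.null(spec$family)) cfg <- set_sweep_param(cfg, spec$family, fv)
      geom <- config_geometry(cfg)
      frc <- config_forces(cfg)
      r0 <- config_plug_radius(cfg)
      Q <- parse_numeric(cfg$flux, "flux")
      mode <- cfg$mode
      z_star <- sweep_station(spec, geom)
      H_star <- wall_radius(z_star, geom)
      res <- tryCatch({
        lb <- normalized_impedance(Q, geom, r0, frc, mode,
                                   as.integer(cfg$quadrature_points))
        tw <- normalized_wss(Q, geom, r0, frc, mode, station = z_star)
        P <- pressure_gradient(Q, H_star, r0, frc, mode)
        drive <- frc$M + frc$f + P
        probe <- parse_numeric(cfg$radial_probe, "radial_probe")
        data.frame(swept_name = spec$swept, swept_value = sv,
                   family_name = if (is.null(spec$family)) NA_character_
                                 else spec$family,
                   family_value = fv,
                   lambda_bar = lb, tau_bar_w = tw,
                   u_center = axial_velocity(0, H_star, r0, drive),
                   u_at_r = axial_velocity(min(probe, H_star), H_star, r0,
                                           drive),
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        stop(sprintf("sweep failed at %s = %g%s: %s", spec$swept, sv,
                     if (is.null(spec$family)) ""
                     else sprintf(", %s = %g", spec$family, fv),
                     conditionMessage(e)), call. = FALSE)
      })
      k <- k + 1L
      rows[[k]] <- res
    }
  }
  do.call(rbind, rows)
}

#' Shipped trend expectations
#'
#' The qualitative directions the parameter studies report: normalized
#' impedance and throat wall shear stress rise with stenosis height and
#' fall with dilatation height; velocity falls with stenosis height and
#' plug radius and rises with dilatation height, magnetization and
#' inclination. The concluding summary of the study that introduced this
#' model reverses the stenosis-height direction for impedance and wall
#' shear stress; the direction encoded here is the one its abstract and
#' figure descriptions state, and the discrepancy is noted in the `source`
#' strings rather than reconciled silently.
#'
#' @return A data frame with columns `response`, `swept`, `direction`,
#'   `source`.
#' @export
default_trend_expectations <- function() {
  data.frame(
    response = c("lambda_bar", "lambda_bar", "tau_bar_w", "tau_bar_w",
                 "u_center", "u_center", "u_center", "u_center", "u_center"),
    swept = c("delta1", "delta2", "delta1", "delta2",
              "delta1", "delta2", "M", "phi", "r0"),
    direction = c("increasing", "decreasing", "increasing", "decreasing",
                  "decreasing", "increasing", "increasing", "increasing",
                  "decreasing"),
    source = c(
      "abstract/fig02 trend: impedance rises with stenosis height (concluding summary states the reverse)",
      "abstract/fig03 trend: impedance falls with dilatation height",
      "abstract/fig10 trend: wall shear stress rises with stenosis height (concluding summary states the reverse)",
      "abstract/fig11 trend: wall shear stress falls with dilatation height",
      "fig18 trend: velocity falls with stenosis height",
      "fig19 trend: velocity rises with dilatation height",
      "fig20-21 trend: velocity rises with magnetization",
      "fig22-23 trend: velocity rises with inclination",
      "fig24-25 trend: velocity falls with plug radius"),
    stringsAsFactors = FALSE
  )
}

#' Check sweep tables against expected trend directions
#'
#' For each expectation, the rows of the table(s) sweeping the named
#' parameter are grouped by family value and the successive finite
#' differences of the response are sign-tested (strict monotonicity).
#'
#' @param tables A sweep result table from [run_sweep()], or a list of them.
#' @param expectations A data frame like [default_trend_expectations()].
#' @return A data frame with one row per expectation: `response`, `swept`,
#'   `direction`, `status` (`"PASS"`, `"FAIL"` or `"NOT-EVALUABLE"`),
#'   `worst_violation` (largest wrong-signed finite difference, 0 if none)
#'   and `source`.
#' @export
monotonicity_report <- function(tables,
                                expectations = default_trend_expectations()) {
  if (is.data.frame(tables)) tables <- list(tables)
  tab <- do.call(rbind, tables)
  needed <- c("swept_name", "swept_value", "family_value")
  if (!all(needed %in% names(tab)))
    stop("tables must come from run_sweep()")
  out <- expectations
  out$status <- NA_character_
  out$worst_violation <- NA_real_
  for (i in seq_len(nrow(expectations))) {
    e <- expectations[i, ]
    if (!e$response %in% names(tab)) {
      out$status[i] <- "NOT-EVALUABLE"
      next
    }
    rows <- tab[tab$swept_name == e$swept, , drop = FALSE]
    if (!nrow(rows)) {
      out$status[i] <- "NOT-EVALUABLE"
      next
    }
    worst <- -Inf
    for (fv in unique(rows$family_value)) {
      grp <- rows[is.na(rows$family_value) == is.na(fv) &
                    (is.na(fv) | rows$family_value == fv), , drop = FALSE]
      grp <- grp[order(grp$swept_value), , drop = FALSE]
      if (nrow(grp) < 2) next
      d <- diff(grp[[e$response]])
      viol <- if (e$direction == "increasing") -d else d
      worst <- max(worst, max(viol))
    }
    if (!is.finite(worst)) {
      out$status[i] <- "NOT-EVALUABLE"
    } else {
      # strict monotonicity: any non-negative wrong-signed difference fails
      out$status[i] <- if (worst >= 0) "FAIL" else "PASS"
      out$worst_violation[i] <- max(worst, 0)
    }
  }
  out[, c("response", "swept", "direction", "status", "worst_violation",
          "source")]
}
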