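#' Define one abnormal wall segment (stenosis or dilatation)
#'
#' A lesion is a cosine-shaped bump in the dimensionless wall radius: a
#' stenosis narrows the lumen (positive signed height), a post-stenotic
#' dilatation widens it (negative signed height). Heights are given as a
#' positive magnitude together with an explicit `kind`, so the sign convention
#' is applied internally and cannot be mistyped.
#'
#' @param height Lesion height as a fraction of the reference radius;
#'   must satisfy `0 <= height < 1` so the wall radius stays positive.
#' @param length Dimensionless axial extent of the lesion; must be positive.
#' @param gap Dimensionless distance from the end of the previous segment (or
#'   the tube inlet for the first segment) to the start of this one; `>= 0`.
#' @param kind Either `"stenosis"` (lumen narrows) or `"dilatation"`
#'   (lumen widens).
#' @return An object of class `abnormal_segment` with fields `delta` (signed
#'   height), `length` and `gap`.
#' @examples
#' abnormal_segment(0.1, 0.2, 0.2, "stenosis")
#' abnormal_segment(0.1, 0.2, 0.6, "dilatation")
#' @export
abnormal_segment <- function(height, length, gap,
                             kind = c("stenosis", "dilatation")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(height), length(height) == 1L, is.finite(height))
  if (height < 0)
    stop("'height' is a magnitude; use kind = \"dilatation\" for a widening")
  if (height >= 1)
    stop("lesion height must be < 1 (wall radius must stay positive)")
  if (!is.numeric(length) || length <= 0)
    stop("segment 'length' must be positive")
  if (!is.numeric(gap) || gap < 0)
    stop("segment 'gap' must be non-negative")
  structure(
    list(delta = if (kind == "stenosis") height else -height,
         length = as.numeric(length), gap = as.numeric(gap), kind = kind),
    class = "abnormal_segment"
  )
}

#' Assemble a vessel geometry from ordered abnormal segments
#'
#' The wall radius equals the reference radius everywhere outside the
#' segments; inside segment i it is
#' `H(z) = R0 - (delta_i/2) * (1 + cos(2*pi*(z - alpha_i - L_i/2)/L_i))`,
#' a cosine bump that vanishes continuously at both segment ends and attains
#' its full height `R0 - delta_i` at the segment midpoint (the throat of a
#' stenosis).
#'
#' @param segments List of [abnormal_segment()] objects, in axial order.
#' @param reference_radius Radius of the healthy tube; fixed at 1 in
#'   dimensionless work.
#' @param domain_length Total axial extent over which the pressure drop is
#'   integrated. `"auto"` (default) takes `max(1, beta_last)` so that no
#'   lesion is ever truncated mid-bump; a numeric value is honoured as long
#'   as it covers the last segment.
#' @return An object of class `vessel_geometry`.
#' @seealso [wall_radius()], [segment_bounds()], [validate_mild_stenosis()]
#' @examples
#' geom <- vessel_geometry(list(
#'   abnormal_segment(0.1, 0.2, 0.2, "stenosis"),
#'   abnormal_segment(0.1, 0.2, 0.6, "dilatation")
#' ))
#' segment_bounds(geom)
#' @export
vessel_geometry <- function(segments = list(), reference_radius = 1,
                            domain_length = "auto") {
  if (inherits(segments, "abnormal_segment")) segments <- list(segments)
  ok <- vapply(segments, inherits, logical(1), "abnormal_segment")
  if (!all(ok))
    stop("'segments' must be a list of abnormal_segment objects (bad index ",
         paste(which(!ok), collapse = ", "), ")")
  if (!is.numeric(reference_radius) || reference_radius <= 0)
    stop("'reference_radius' must be positive")

  geom <- structure(
    list(segments = segments, reference_radius = as.numeric(reference_radius),
         domain_length = NA_real_),
    class = "vessel_geometry"
  )
  b <- segment_bounds(geom)
  beta_last <- if (nrow(b)) b$beta[nrow(b)] else 0
  if (identical(domain_length, "auto")) {
    geom$domain_length <- max(1, beta_last)
  } else {
    if (!is.numeric(domain_length) || domain_length <= 0)
      stop("'domain_length' must be \"auto\" or a positive number")
    if (domain_length < beta_last)
      stop(sprintf("domain_length (%g) ends before the last segment (beta = %g)",
                   domain_length, beta_last))
    geom$domain_length <- as.numeric(domain_length)
  }
  geom
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf("Vessel geometry: %d abnormal segment(s), R0 = %g, domain [0, %g]\n",
              length(x$segments), x$reference_radius, x$domain_length))
  if (length(x$segments)) {
    b <- segment_bounds(x)
    for (i in seq_along(x$segments)) {
      s <- x$segments[[i]]
      cat(sprintf("  %d: %-10s delta = %+g  over [%g, %g]\n",
                  i, s$kind, s$delta, b$alpha[i], b$beta[i]))
    }
  }
  invisible(x)
}

#' Axial bounds of each abnormal segment
#'
#' Segment i starts at `alpha_i = -L_i + sum_{j<=i}(L_j + d_j)` and ends at
#' `beta_i = sum_{j<=i}(L_j + d_j)`, i.e. the gaps and lengths accumulate
#' along the axis; consecutive bounds never overlap because gaps are
#' non-negative and lengths positive.
#'
#' @param geometry A [vessel_geometry()].
#' @return A data frame with one row per segment and columns `alpha`, `beta`.
#' @export
segment_bounds <- function(geometry) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  segs <- geometry$segments
  if (!length(segs))
    return(data.frame(alpha = numeric(0), beta = numeric(0)))
  len <- vapply(segs, `[[`, numeric(1), "length")
  gap <- vapply(segs, `[[`, numeric(1), "gap")
  beta <- cumsum(len + gap)
  alpha <- beta - len
  bad <- which(diff(c(0, alpha)) < 0 | beta <= alpha)
  if (length(bad))
    stop("overlapping or negative-extent segment at index ",
         paste(bad, collapse = ", "))
  data.frame(alpha = alpha, beta = beta)
}

#' Dimensionless wall radius H(z)
#'
#' @param z Axial coordinate(s) in `[0, domain_length]`.
#' @param geometry A [vessel_geometry()].
#' @return Numeric vector of wall radii, one per element of `z`. Ties at a
#'   shared segment boundary are resolved by the segment starting there; the
#'   value is identical by continuity.
#' @examples
#' geom <- vessel_geometry(list(abnormal_segment(0.2, 0.2, 0.2, "stenosis")))
#' wall_radius(0.3, geom)  # throat: 1 - 0.2 = 0.8
#' @export
wall_radius <- function(z, geometry) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  if (any(!is.finite(z)) || any(z < 0) || any(z > geometry$domain_length))
    stop(sprintf("z outside the domain [0, %g]", geometry$domain_length))
  R0 <- geometry$reference_radius
  H <- rep(R0, length(z))
  if (!length(geometry$segments)) return(H)
  b <- segment_bounds(geometry)
  for (i in seq_along(geometry$segments)) {
    s <- geometry$segments[[i]]
    in_i <- z >= b$alpha[i] & z <= b$beta[i]
    if (any(in_i)) {
      arg <- 2 * pi * (z[in_i] - b$alpha[i] - s$length / 2) / s$length
      H[in_i] <- R0 - (s$delta / 2) * (1 + cos(arg))
    }
  }
  if (any(H <= 0))
    stop("wall radius is non-positive; lesion height too large")
  H
}

#' Wall profile over an axial grid
#'
#' Vectorized [wall_radius()] for quadrature and plotting.
#'
#' @param z_grid Strictly increasing numeric vector within the domain.
#' @param geometry A [vessel_geometry()].
#' @return Numeric vector of the same length as `z_grid`.
#' @export
wall_profile <- function(z_grid, geometry) {
  if (length(z_grid) > 1 && any(diff(z_grid) <= 0))
    stop("'z_grid' must be strictly increasing")
  wall_radius(z_grid, geometry)
}

#' Check the mild-stenosis regime
#'
#' The locally-Poiseuille closed form assumes every lesion is shallow
#' relative to both its own length and the vessel radius. "Much smaller
#' than" is operationalized as a ratio threshold: a segment is flagged when
#' `|delta|/L > tolerance` or `|delta|/min(R0, R_out) > tolerance`. The
#' outlet radius equals the reference radius in this geometry (lesions close
#' up at their ends), so the second ratio reduces to `|delta|/R0`. This is
#' an advisory report by default; `strict = TRUE` promotes flags to errors.
#'
#' @param geometry A [vessel_geometry()].
#' @param tolerance Largest ratio still considered "much smaller than";
#'   default 0.3.
#' @param strict Error instead of flagging? Default `FALSE`.
#' @return A data frame with one row per segment: `ratio_length`,
#'   `ratio_radius`, `flagged`; plus attribute `"pass"` (no segment flagged).
#' @export
validate_mild_stenosis <- function(geometry, tolerance = 0.3, strict = FALSE) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  segs <- geometry$segments
  R0 <- geometry$reference_radius
  rep_df <- data.frame(
    segment = seq_along(segs),
    ratio_length = vapply(segs, function(s) abs(s$delta) / s$length, numeric(1)),
    ratio_radius = vapply(segs, function(s) abs(s$delta) / R0, numeric(1))
  )
  rep_df$flagged <- rep_df$ratio_length > tolerance |
    rep_df$ratio_radius > tolerance
  attr(rep_df, "pass") <- !any(rep_df$flagged)
  attr(rep_df, "tolerance") <- tolerance
  if (strict && any(rep_df$flagged))
    stop("mild-stenosis assumption violated at segment ",
         paste(rep_df$segment[rep_df$flagged], collapse = ", "))
  rep_df
}

#' Axial station of the throat
#'
#' The throat is the midpoint of the first segment with non-zero height,
#' where the deviation of the lumen from the healthy radius is maximal.
#'
#' @param geometry A [vessel_geometry()].
#' @return The axial coordinate of the throat.
#' @export
throat_station <- function(geometry) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  deltas <- vapply(geometry$segments, `[[`, numeric(1), "delta")
  i <- which(deltas != 0)[1]
  if (is.na(i))
    stop("geometry has no abnormal segment; cannot resolve the throat")
  b <- segment_bounds(geometry)
  (b$alpha[i] + b$beta[i]) / 2
}

# Midpoint of a specific segment, used by the sweep engine to pin the
# evaluation station to the lesion actually being varied.
segment_midpoint <- function(geometry, index) {
  b <- segment_bounds(geometry)
  if (index < 1 || index > nrow(b))
    stop("segment index out of range")
  (b$alpha[index] + b$beta[index]) / 2
}
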