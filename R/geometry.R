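#' Spherical geometry for raycast telemetry
#'
#' Array elements and raycast hits live on a sphere centred at the headset
#' origin. Orientations are expressed as a pair of signed angles in degrees
#' relative to the calibrated forward axis:
#'
#' * `lateral` — azimuth, positive towards the player's right, in
#'   \[-180, 180\].
#' * `vertical` — elevation, positive up, in \[-90, 90\].
#'
#' The calibrated frame is right-handed with forward = +z, up = +y,
#' right = +x. In clinical write-ups of headset telemetry the horizontal
#' angle is often labelled "latitude" and the vertical angle "longitude";
#' the mapping used throughout this package is lateral = "latitude",
#' vertical = "longitude" (see [metric_names()]).
#'
#' @name geometry
#' @keywords internal
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Convert a Cartesian direction to lateral/vertical angles
#'
#' @param direction Numeric 3-vector `c(x, y, z)` (or an n x 3 matrix of
#'   directions) in the calibrated frame; need not be unit length.
#'
#' @return A tibble with columns `lateral` and `vertical` (degrees), one row
#'   per input direction.
#' @examples
#' cartesian_to_angles(c(0, 0, 1)) # straight ahead -> (0, 0)
#' cartesian_to_angles(c(1, 0, 0)) # pure right -> (90, 0)
#' @export
cartesian_to_angles <- function(direction) {
  m <- if (is.matrix(direction)) direction else matrix(direction, ncol = 3, byrow = TRUE)
  if (ncol(m) != 3) {
    stop("`direction` must be a 3-vector or an n x 3 matrix", call. = FALSE)
  }
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm < 1e-12)) {
    stop("zero-norm direction has no defined orientation", call. = FALSE)
  }
  m <- m / nrm
  tibble::tibble(
    lateral = rad2deg(atan2(m[, 1], m[, 3])),
    vertical = rad2deg(asin(pmin(1, pmax(-1, m[, 2]))))
  )
}

#' Convert lateral/vertical angles to a Cartesian point on a sphere
#'
#' Inverse of [cartesian_to_angles()] up to the radius.
#'
#' @param lateral,vertical Angles in degrees (vectorised).
#' @param radius Sphere radius in metres (default 2, the near surface).
#'
#' @return An n x 3 matrix of points, each with norm `radius`.
#' @export
angles_to_cartesian <- function(lateral, vertical, radius = 2) {
  stopifnot(radius > 0)
  la <- deg2rad(lateral)
  ve <- deg2rad(vertical)
  cbind(
    x = radius * cos(ve) * sin(la),
    y = radius * sin(ve),
    z = radius * cos(ve) * cos(la)
  )
}

#' Angular eccentricity of a position
#'
#' Great-circle angle (degrees) between the direction `(lateral, vertical)`
#' and the calibrated forward axis. Zero iff the position is straight ahead.
#'
#' @inheritParams angles_to_cartesian
#' @return Numeric vector of eccentricities in degrees, in \[0, 180\].
#' @export
angular_eccentricity <- function(lateral, vertical) {
  cosd <- cos(deg2rad(vertical)) * cos(deg2rad(lateral))
  rad2deg(acos(pmin(1, pmax(-1, cosd))))
}

#' Build a concentric-ring spherical search grid
#'
#' Positions are grouped into concentric rings at the given eccentricities;
#' within each ring the polar angle runs uniformly from 0 (player's right)
#' counter-clockwise in steps of `within_ring_spacing`.
#'
#' @param ring_eccentricities Ring eccentricities in degrees, each in (0, 90).
#' @param within_ring_spacing Polar-angle spacing within each ring, degrees;
#'   must divide 360.
#'
#' @return A tibble with columns `ring` (eccentricity, degrees), `polar`
#'   (degrees), `lateral`, `vertical` (degrees), `ecc` (recomputed
#'   eccentricity; equals `ring` up to floating point).
#' @examples
#' g <- build_spherical_grid(c(12.5, 25, 37.5, 50), 15)
#' nrow(g) # 4 rings x 24 positions
#' @export
build_spherical_grid <- function(ring_eccentricities, within_ring_spacing = 15) {
  if (within_ring_spacing <= 0 || abs(360 / within_ring_spacing - round(360 / within_ring_spacing)) > 1e-9) {
    stop("`within_ring_spacing` must be positive and divide 360", call. = FALSE)
  }
  if (any(ring_eccentricities <= 0 | ring_eccentricities >= 90)) {
    stop("ring eccentricities must lie in (0, 90) degrees", call. = FALSE)
  }
  polar <- seq(0, 360 - within_ring_spacing, by = within_ring_spacing)
  grid <- tidyr::expand_grid(ring = ring_eccentricities, polar = polar)
  # point at angular distance `ring` from forward, at polar angle `polar`
  # (0 = right, 90 = up) around the forward axis
  ecc_r <- deg2rad(grid$ring)
  pol_r <- deg2rad(grid$polar)
  v <- cbind(
    sin(ecc_r) * cos(pol_r),
    sin(ecc_r) * sin(pol_r),
    cos(ecc_r)
  )
  ang <- cartesian_to_angles(v)
  tibble::tibble(
    ring = grid$ring,
    polar = grid$polar,
    lateral = ang$lateral,
    vertical = ang$vertical,
    ecc = angular_eccentricity(ang$lateral, ang$vertical)
  )
}

#' Assign an array position to a spatial quadrant
#'
#' Dominant-axis rule: `|lateral| > |vertical|` gives left/right by the sign
#' of `lateral`; `|vertical| > |lateral|` gives up/down by the sign of
#' `vertical`. Exact ties (including the origin) are assigned `"axis"` and
#' excluded from quadrant contrasts — except that positions lying exactly on
#' one axis (the other coordinate zero) are unambiguous and keep the
#' quadrant of their nonzero coordinate.
#'
#' @inheritParams angles_to_cartesian
#' @return Character vector in `c("left", "right", "up", "down", "axis")`.
#' @examples
#' assign_quadrant(25, 0) # "right"
#' assign_quadrant(20, 20) # "axis" (tie, excluded)
#' @export
assign_quadrant <- function(lateral, vertical) {
  al <- abs(lateral)
  av <- abs(vertical)
  out <- rep("axis", length(al))
  horiz <- al > av
  vert <- av > al
  out[horiz & lateral > 0] <- "right"
  out[horiz & lateral < 0] <- "left"
  out[vert & vertical > 0] <- "up"
  out[vert & vertical < 0] <- "down"
  out
}
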