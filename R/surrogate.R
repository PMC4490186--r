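#' Empirical pulse wave velocity of a vessel
#'
#' Empirical relation `c(R) = 13.3 / (2R)^0.3` evaluated literally on the
#' local vessel radius `R` in cm. As printed, the relation yields a velocity
#' whose magnitude corresponds to m/s (the underlying empirical fit was made
#' with diameter in mm and velocity in m/s); `units = "cgs"` multiplies by
#' 100 to obtain cm/s for use in CGS circuit formulas. The model internals
#' use the CGS convention; the literal value is the default so the relation
#' reads exactly as published.
#'
#' @param radius vessel radius, cm (> 0); vectorized
#' @param units `"literal"` (as printed) or `"cgs"` (cm/s)
#' @return pulse wave velocity
#' @export
pulse_wave_velocity <- function(radius, units = c("literal", "cgs")) {
  units <- match.arg(units)
  if (any(radius <= 0)) stop("radius must be > 0")
  c_lit <- 13.3 / (2 * radius)^0.3
  if (units == "cgs") 100 * c_lit else c_lit
}

#' Elastic wall modulus from pulse wave velocity
#'
#' `E = E* 3 rho R c^2 / (2 zeta)` for an incompressible linearly elastic
#' membrane of thickness `zeta` (by default 10 % of the local radius) with
#' scaling factor `E* = 2`. With the default thickness rule the radius
#' cancels and the modulus reduces to `E = 30 rho c^2`.
#'
#' @param radius vessel radius, cm
#' @param c pulse wave velocity (same unit system as desired for `E`)
#' @param rho blood density, g cm^-3
#' @param e_star dimensionless scaling factor
#' @param zeta wall thickness, cm (default `0.1 * radius`)
#' @return elastic modulus (rho c^2 units)
#' @export
wall_modulus <- function(radius, c, rho = 1.06, e_star = 2,
                         zeta = 0.1 * radius) {
  if (any(radius <= 0) || any(c <= 0) || any(rho <= 0) || any(zeta <= 0) ||
      any(e_star <= 0)) stop("all wall-property inputs must be > 0")
  e_star * 3 * rho * radius * c^2 / (2 * zeta)
}

#' Characteristic outlet resistance
#'
#' Matches the proximal Windkessel resistance of an outlet to its
#' characteristic impedance, `R1 = rho c / A`.
#'
#' @param area outlet area, cm^2 (> 0)
#' @param c pulse wave velocity, cm s^-1
#' @param rho blood density, g cm^-3
#' @return resistance, dyn s cm^-5
#' @export
characteristic_resistance <- function(area, c, rho = 1.06) {
  if (any(area <= 0)) stop("area must be > 0")
  rho * c / area
}

#' Rotated gravity vector
#'
#' Literal evaluation of the tilt rotation: the initial gravity vector
#' `g0 = [0, 0, -g]` (supine: the z-axis runs back-to-chest) rotated by
#' `theta` around the y-axis, giving `[g sin(theta), 0, -g cos(theta)]`.
#' The x-axis runs feet-to-head; the tilt protocol chooses the rotation
#' sense so that the upright posture places the carotids above the heart
#' (see [tilt_protocol()]).
#'
#' @param theta rotation angle, radians
#' @param g gravity magnitude, cm s^-2
#' @return length-3 gravity vector, cm s^-2
#' @export
gravity_vector <- function(theta, g = 9.810e2) {
  c(g * sin(theta), 0, -g * cos(theta))
}

#' Hydrostatic pressure source across a segment
#'
#' The gravity body force is realized in 0D as a pressure source in series
#' with each vessel segment: `rho * (g . delta_r)`, where `delta_r` is the
#' downstream-minus-upstream position difference of the segment in body
#' coordinates. Zero when gravity is perpendicular to the segment. With this
#' sign the static (no-flow) pressure difference between segment ends equals
#' the hydrostatic head exactly.
#'
#' @param delta_r position difference vector (length 2 `c(dx, dz)` or
#'   length 3 `c(dx, dy, dz)`), cm
#' @param g_vec gravity vector from [gravity_vector()] (length 3) or its
#'   `c(g_x, g_z)` components
#' @param rho blood density, g cm^-3
#' @return pressure source, dyn cm^-2
#' @export
hydrostatic_source <- function(delta_r, g_vec, rho = 1.06) {
  if (length(delta_r) == 2L) delta_r <- c(delta_r[1], 0, delta_r[2])
  if (length(g_vec) == 2L) g_vec <- c(g_vec[1], 0, g_vec[2])
  rho * sum(g_vec * delta_r)
}

#' Default surrogate geometry of the large arteries
#'
#' The compartmental surrogate replaces the image-based arterial domain with
#' ten R-L-C segments: ascending aorta to an arch node, then left/right
#' subclavian, left/right common carotids splitting into internal/external
#' carotids, and the descending aorta. Radii and lengths are nominal adult
#' values; terminal (outlet) radii default to the values obtained by
#' inverting the characteristic-impedance rule against the published
#' proximal Windkessel resistances (see [outlet_radius_from_r1()]), which is
#' also how the default outlet areas are set.
#'
#' Elevations are body-frame x-coordinates (feet-to-head axis, cm, aortic
#' root at 0) of each segment's endpoints; in the upright posture the
#' carotid outlets sit 25 cm above the root, the subclavians 5 cm above and
#' the descending-aorta outlet 15 cm below. The z-extent is zero by default
#' so the supine posture carries no hydrostatic offsets. All values are
#' configuration, not constants.
#'
#' @return data.frame with one row per segment: `segment`, `from`, `to`,
#'   `radius` (cm), `length` (cm), `x_start`, `x_end`, `z_start`, `z_end`
#'   (cm), `outlet` (name of the Windkessel outlet fed by the segment, or NA)
#' @export
default_vessel_geometry <- function() {
  seg <- function(segment, from, to, radius, length, x0, x1, outlet = NA) {
    data.frame(segment = segment, from = from, to = to, radius = radius,
               length = length, x_start = x0, x_end = x1,
               z_start = 0, z_end = 0, outlet = outlet,
               stringsAsFactors = FALSE)
  }
  r_out <- vapply(windkessel_defaults()$r1, outlet_radius_from_r1, numeric(1))
  names(r_out) <- windkessel_defaults()$outlet
  rbind(
    seg("asc_aorta",  "root",  "arch",   1.45, 5,  0,   3),
    seg("subclavian_r", "arch", "sub_r", r_out[["subclavian_r"]], 8, 3, 5,
        "subclavian_r"),
    seg("subclavian_l", "arch", "sub_l", r_out[["subclavian_l"]], 8, 3, 5,
        "subclavian_l"),
    seg("common_carotid_r", "arch", "car_r", 0.35, 12, 3, 15),
    seg("common_carotid_l", "arch", "car_l", 0.35, 12, 3, 15),
    seg("internal_carotid_r", "car_r", "icar_r",
        r_out[["internal_carotid_r"]], 10, 15, 25, "internal_carotid_r"),
    seg("external_carotid_r", "car_r", "ecar_r",
        r_out[["external_carotid_r"]], 10, 15, 25, "external_carotid_r"),
    seg("internal_carotid_l", "car_l", "icar_l",
        r_out[["internal_carotid_l"]], 10, 15, 25, "internal_carotid_l"),
    seg("external_carotid_l", "car_l", "ecar_l",
        r_out[["external_carotid_l"]], 10, 15, 25, "external_carotid_l"),
    seg("desc_aorta", "arch", "dao", r_out[["desc_aorta"]], 25, 3, -15,
        "desc_aorta")
  )
}

#' Invert the characteristic-impedance rule for the outlet radius
#'
#' Solves `pi R^2 = rho c(R) / R1` for the outlet radius, where `c(R)` is
#' the empirical pulse wave velocity in cm/s: the radius whose circular area
#' and wave speed reproduce a given proximal Windkessel resistance.
#'
#' @param r1 proximal (characteristic) resistance, dyn s cm^-5
#' @param rho blood density, g cm^-3
#' @return radius, cm
#' @export
outlet_radius_from_r1 <- function(r1, rho = 1.06) {
  f <- function(r) pi * r^2 - rho * pulse_wave_velocity(r, "cgs") / r1
  stats::uniroot(f, c(1e-3, 10), tol = 1e-10)$root
}

#' Derived circuit parameters of the surrogate segments
#'
#' Per-segment Poiseuille resistance `8 mu l / (pi R^4)`, inertance
#' `rho l / A` and compliance from the Bramwell-Hill relation
#' `C = l A / (rho c^2)` with the empirical pulse wave velocity (CGS). The
#' wall modulus implied by the same wave speed is reported alongside.
#'
#' @param geometry data.frame as returned by [default_vessel_geometry()]
#' @param rho blood density, g cm^-3
#' @param mu dynamic viscosity, P (g cm^-1 s^-1)
#' @return the geometry with columns `area`, `c_cgs`, `r_seg`, `l_seg`,
#'   `c_seg`, `e_wall` appended
#' @export
segment_parameters <- function(geometry, rho = 1.06, mu = 0.04) {
  stopifnot(all(geometry$radius > 0), all(geometry$length > 0))
  a <- pi * geometry$radius^2
  cc <- pulse_wave_velocity(geometry$radius, "cgs")
  geometry$area <- a
  geometry$c_cgs <- cc
  geometry$r_seg <- 8 * mu * geometry$length / (pi * geometry$radius^4)
  geometry$l_seg <- rho * geometry$length / a
  geometry$c_seg <- geometry$length * a / (rho * cc^2)
  geometry$e_wall <- wall_modulus(geometry$radius, cc, rho)
  geometry
}
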