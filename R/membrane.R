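#' Membrane specification
#'
#' Physical parameters of the circular speaker membrane that carries the
#' mirror. The membrane is characterised by its radius `a`, mass `m`, surface
#' density `sigma = m / (pi a^2)`, tension `T` and fundamental-mode (0,1)
#' resonance `f01 = (c01 / (2 pi a)) sqrt(T / sigma)`, where `c01` is the
#' first zero of the Bessel function J0. Any consistent subset of
#' `{sigma, tension, f01}` may be given; missing members are derived.
#'
#' @param a Membrane radius in metres.
#' @param m Membrane mass in kilograms.
#' @param tension Membrane tension in N/m, or `NULL` to derive from `f01`.
#' @param f01 Fundamental-mode resonance in Hz, or `NULL` to derive from
#'   `tension`.
#' @param q_factor Modal quality factor used by the vibration simulator
#'   (dimensionless); it has no effect on the static tension/resonance
#'   relations.
#'
#' @return An object of class `membrane_spec`: a list with elements `a`, `m`,
#'   `area`, `sigma`, `tension`, `f01`, `c01`, `q_factor`.
#' @examples
#' spec <- membrane_spec(a = 0.04, m = 0.002, f01 = 187)
#' spec$tension # ~152 N/m
#' @export
membrane_spec <- function(a = 0.04, m = 0.002, tension = NULL, f01 = NULL,
                          q_factor = 50) {
  stopifnot(is.numeric(a), length(a) == 1, is.numeric(m), length(m) == 1)
  if (a <= 0) stop("membrane radius `a` must be > 0", call. = FALSE)
  if (m <= 0) stop("membrane mass `m` must be > 0", call. = FALSE)
  if (q_factor <= 0) stop("`q_factor` must be > 0", call. = FALSE)
  area <- membrane_area(a)
  sigma <- surface_density(m, area)
  if (is.null(tension) && is.null(f01)) {
    f01 <- 187 # bench default: measured fundamental of the reference build
  }
  spec <- structure(
    list(a = a, m = m, area = area, sigma = sigma,
         tension = tension, f01 = f01,
         c01 = bessel_j0_first_zero(), q_factor = q_factor),
    class = "membrane_spec"
  )
  if (is.null(spec$tension)) {
    spec$tension <- tension_from_resonance(spec$f01, spec)
  } else if (is.null(spec$f01)) {
    spec$f01 <- fundamental_frequency(spec)
  } else {
    f_chk <- fundamental_frequency(spec)
    if (abs(f_chk - spec$f01) > 1e-6 * spec$f01) {
      stop("inconsistent `tension` and `f01`: tension implies f01 = ",
           signif(f_chk, 6), " Hz", call. = FALSE)
    }
  }
  spec
}

#' @export
print.membrane_spec <- function(x, ...) {
  cat("<membrane_spec>\n",
      sprintf("  a = %g m, m = %g kg, A = %.3g m^2\n", x$a, x$m, x$area),
      sprintf("  sigma = %.3g kg/m^2, T = %.4g N/m, f01 = %.4g Hz (Q = %g)\n",
              x$sigma, x$tension, x$f01, x$q_factor))
  invisible(x)
}

#' Area of a circular membrane
#'
#' @param a Radius in metres (> 0).
#' @return Area `pi * a^2` in square metres.
#' @examples
#' membrane_area(0.04) # 5.03e-3 m^2
#' @export
membrane_area <- function(a) {
  stopifnot(is.numeric(a))
  if (any(a <= 0)) stop("radius must be > 0", call. = FALSE)
  pi * a^2
}

#' Surface density of a membrane
#'
#' Mass per unit area, `sigma = m / A`, determined gravimetrically.
#'
#' @param m Mass in kg (> 0).
#' @param A Area in m^2 (> 0).
#' @return Surface density in kg/m^2.
#' @examples
#' surface_density(0.002, membrane_area(0.04)) # 0.398 kg/m^2
#' @export
surface_density <- function(m, A) {
  stopifnot(is.numeric(m), is.numeric(A))
  if (any(m <= 0) || any(A <= 0)) {
    stop("mass and area must be > 0", call. = FALSE)
  }
  m / A
}

#' First zero of the Bessel function J0
#'
#' Computed by bracketed root finding of `besselJ(x, 0)` on (2, 3), not
#' looked up, so the value carries full double precision (2.404825...).
#'
#' @return The smallest positive root of J0, approximately 2.4048.
#' @export
bessel_j0_first_zero <- function() {
  stats::uniroot(function(x) besselJ(x, 0), c(2, 3), tol = 1e-14)$root
}

#' Membrane tension from the fundamental resonance
#'
#' Inverts the circular-membrane mode (0,1) relation
#' `f01 = (c01 / (2 pi a)) sqrt(T / sigma)` to
#' `T = sigma * (2 pi a f01 / c01)^2`.
#'
#' @param f01 Measured fundamental resonance in Hz (> 0).
#' @param spec A [membrane_spec()] (its `sigma`, `a`, `c01` are used).
#' @return Tension in N/m.
#' @examples
#' sp <- membrane_spec(a = 0.04, m = 0.002, f01 = 187)
#' tension_from_resonance(187, sp) # ~152 N/m
#' @export
tension_from_resonance <- function(f01, spec) {
  stopifnot(inherits(spec, "membrane_spec") || is.list(spec))
  if (f01 <= 0) stop("`f01` must be > 0", call. = FALSE)
  spec$sigma * (2 * pi * spec$a * f01 / spec$c01)^2
}

#' Fundamental-mode resonance of a circular membrane
#'
#' Mode (0,1): `f01 = (c01 / (2 pi a)) sqrt(T / sigma)`.
#'
#' @param spec A [membrane_spec()] with `tension`, `sigma`, `a` set.
#' @return Resonance frequency in Hz.
#' @export
fundamental_frequency <- function(spec) {
  if (spec$tension <= 0 || spec$sigma <= 0 || spec$a <= 0) {
    stop("tension, sigma and a must all be > 0", call. = FALSE)
  }
  (spec$c01 / (2 * pi * spec$a)) * sqrt(spec$tension / spec$sigma)
}

#' Optical geometry of the mirror-laser-screen system
#'
#' @param incidence_angle Angle of the membrane/mirror assembly relative to
#'   the screen normal, degrees in (0, 90).
#' @param screen_width,screen_height Screen size in metres.
#' @param mirror_diameter Mirror diameter in metres (metadata).
#' @param laser_wavelength_nm Laser wavelength in nm (metadata).
#' @param mirror_to_screen Optical path length from mirror to screen in
#'   metres; sets the lever arm converting mirror tilt to spot displacement.
#' @param rest_spot Resting laser-spot position on the screen, metres,
#'   relative to the screen centre.
#'
#' @return An object of class `optical_geometry`.
#' @export
optical_geometry <- function(incidence_angle = 30,
                             screen_width = 0.40, screen_height = 0.60,
                             mirror_diameter = 0.025,
                             laser_wavelength_nm = 650,
                             mirror_to_screen = 0.50,
                             rest_spot = c(0, 0)) {
  if (screen_width <= 0 || screen_height <= 0) {
    stop("screen dimensions must be > 0", call. = FALSE)
  }
  if (incidence_angle <= 0 || incidence_angle >= 90) {
    stop("`incidence_angle` must lie in (0, 90) degrees", call. = FALSE)
  }
  if (mirror_to_screen <= 0) stop("`mirror_to_screen` must be > 0", call. = FALSE)
  stopifnot(length(rest_spot) == 2, is.numeric(rest_spot))
  structure(
    list(incidence_angle = incidence_angle,
         screen_width = screen_width, screen_height = screen_height,
         mirror_diameter = mirror_diameter,
         laser_wavelength_nm = laser_wavelength_nm,
         mirror_to_screen = mirror_to_screen,
         rest_spot = as.numeric(rest_spot)),
    class = "optical_geometry"
  )
}
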