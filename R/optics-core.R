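# Optical-system parameters and paraxial Green's functions.
#
# All quantities are SI (metres, cycles per metre) at the R level; the
# command-line interface and file writers convert to mm / cycles-per-mm.

#' Gaussian-apodized paraxial imaging system
#'
#' Immutable description of a single-lens paraxial imaging system whose
#' limiting iris is apodized so that the amplitude point-spread function is
#' Gaussian. The Gaussian-equivalent numerical aperture is
#' `NA0 = sigma_l / o`, where `sigma_l` is the apodized pupil width and `o`
#' the object distance of the focused plane. The focused Airy width is
#' `sigma0 = lambda / (2 sqrt(pi) NA0)`, the sole resolution limit at focus.
#'
#' @param wavelength Illumination wavelength \eqn{\lambda} in metres
#'   (monochromatic, e.g. `500e-9` for green light).
#' @param object_distance Distance `o` (m) from the lens to the plane that is
#'   conjugate to the detector.
#' @param pupil_width Width `sigma_l` (m) of the Gaussian-apodized limiting
#'   iris. Give either this or `na0`.
#' @param na0 Gaussian-equivalent numerical aperture `sigma_l / o`
#'   (dimensionless). Give either this or `pupil_width`.
#' @param magnification Native (in-focus) transverse magnification `M0`.
#'
#' @return An object of class `"imaging_system"` with fields `wavelength`,
#'   `object_distance`, `pupil_width`, `magnification` and derived `na0`,
#'   `k` (wavenumber \eqn{2\pi/\lambda}) and `sigma0`.
#'
#' @examples
#' sys <- imaging_system(500e-9, 0.1, na0 = 0.05)
#' sys$sigma0  # ~2.82 um focused spot width
#' @export
imaging_system <- function(wavelength, object_distance, pupil_width = NULL,
                           na0 = NULL, magnification = 1) {
  stopifnot(is.numeric(wavelength), length(wavelength) == 1L, wavelength > 0,
            is.numeric(object_distance), length(object_distance) == 1L,
            object_distance > 0, is.numeric(magnification),
            magnification != 0)
  if (is.null(pupil_width) == is.null(na0))
    stop("give exactly one of 'pupil_width' and 'na0'")
  if (is.null(pupil_width)) pupil_width <- na0 * object_distance
  if (pupil_width <= 0) stop("'pupil_width' must be positive")
  na0 <- pupil_width / object_distance
  if (na0 >= 0.2)
    warning(sprintf("NA0 = %.3g is outside the paraxial regime (< 0.2); ",
                    na0), "results are extrapolations", call. = FALSE)
  sys <- list(wavelength = wavelength,
              object_distance = object_distance,
              pupil_width = pupil_width,
              magnification = magnification,
              na0 = na0,
              k = 2 * pi / wavelength,
              sigma0 = wavelength / (2 * sqrt(pi) * na0))
  class(sys) <- "imaging_system"
  sys
}

#' @export
print.imaging_system <- function(x, ...) {
  cat("Gaussian-apodized paraxial imaging system\n")
  cat(sprintf("  lambda  = %.4g nm\n", x$wavelength * 1e9))
  cat(sprintf("  o       = %.4g mm\n", x$object_distance * 1e3))
  cat(sprintf("  sigma_l = %.4g mm   (NA0 = %.4g)\n",
              x$pupil_width * 1e3, x$na0))
  cat(sprintf("  M0      = %.4g\n", x$magnification))
  cat(sprintf("  sigma0  = %.4g um  (focused Airy width)\n", x$sigma0 * 1e6))
  invisible(x)
}

#' Defocus state of an imaging system
#'
#' Couples an [imaging_system()] with a signed axial defocus `delta`:
#' positive when the sample sits *beyond* the focused plane (away from the
#' lens), negative when it sits between the focused plane and the lens. The
#' sample is at distance `o + delta` from the lens, which must be positive.
#'
#' @param system An [imaging_system()].
#' @param delta Signed axial defocus (m).
#' @return Object of class `"defocus_state"` wrapping `system` and `delta`.
#' @examples
#' st <- defocus_state(imaging_system(500e-9, 0.1, na0 = 0.05), 1e-3)
#' magnification(st)
#' @export
defocus_state <- function(system, delta) {
  stopifnot(inherits(system, "imaging_system"),
            is.numeric(delta), length(delta) == 1L, is.finite(delta))
  if (system$object_distance + delta <= 0)
    stop("invalid defocus: o + delta must be positive ",
         "(object at or behind the lens plane)")
  st <- list(system = system, delta = delta)
  class(st) <- "defocus_state"
  st
}

#' @export
print.defocus_state <- function(x, ...) {
  print(x$system)
  cat(sprintf("  delta   = %.4g mm  (M = %.4g, NA = %.4g)\n",
              x$delta * 1e3, magnification(x), effective_na(x)))
  invisible(x)
}

#' Effective numerical aperture of a defocused sample
#'
#' `NA(delta) = sigma_l / (o + delta)`: the aperture actually subtended by
#' the pupil as seen from the (defocused) sample plane.
#'
#' @param state A [defocus_state()].
#' @return Dimensionless effective NA.
#' @export
effective_na <- function(state) {
  stopifnot(inherits(state, "defocus_state"))
  state$system$pupil_width / (state$system$object_distance + state$delta)
}

#' Magnification of a defocused sample plane
#'
#' `M(delta) = M0 / (1 + delta / o)`. The *incoherent* image of a defocused
#' plane scales with `M(delta)`; coherent images keep the native `M0`.
#'
#' @param state A [defocus_state()].
#' @return Signed magnification.
#' @examples
#' sys <- imaging_system(500e-9, 0.1, na0 = 0.05)
#' magnification(defocus_state(sys, 0.1))   # 0.5
#' @export
magnification <- function(state) {
  stopifnot(inherits(state, "defocus_state"))
  state$system$magnification / (1 + state$delta / state$system$object_distance)
}

#' Width components of the defocused incoherent PSF
#'
#' The incoherent point-spread function of the Gaussian-apodized system is a
#' Gaussian whose variance splits into a diffraction (Airy) part and a
#' geometric circle-of-confusion part,
#' \deqn{\sigma_{inc}^2(\delta) = \sigma_0^2(\delta) + \sigma_{CoC}^2(\delta),}
#' with \eqn{\sigma_0(\delta) = \lambda / (2\sqrt{\pi} NA(\delta))} and
#' \eqn{\sigma_{CoC}(\delta) = \delta NA(\delta) / (2\sqrt{\pi})}, both using
#' the effective aperture `NA(delta)`. At focus the CoC vanishes and only
#' diffraction limits resolution; away from focus the CoC rapidly dominates.
#'
#' @param state A [defocus_state()].
#' @return Named numeric vector `c(sigma0=, sigma_coc=, sigma_inc=)` in
#'   metres.
#' @seealso [psf_sigma()] for the width of the exactly composed kernel.
#' @examples
#' st <- defocus_state(imaging_system(500e-9, 0.1, na0 = 0.05), 1e-3)
#' sigma_components(st)
#' @export
sigma_components <- function(state) {
  stopifnot(inherits(state, "defocus_state"))
  na_d <- effective_na(state)
  s0 <- state$system$wavelength / (2 * sqrt(pi) * na_d)
  scoc <- state$delta * na_d / (2 * sqrt(pi))
  c(sigma0 = s0, sigma_coc = scoc, sigma_inc = sqrt(s0^2 + scoc^2))
}

#' Width of the composed incoherent kernel
#'
#' Width of the Gaussian `|P_delta|^2` obtained by actually composing the
#' vacuum Fresnel propagator with the focused-system response. The exact
#' composition gives
#' \eqn{\sigma^2 = \sigma_0^2(\delta) + \delta^2 NA_0^2/(4\pi)}
#' (circle of confusion scaled by the *native* aperture), which differs from
#' the modelled [sigma_components()] value by O(`delta/o`). The oracle and
#' the closed-form image paths agree with this width to machine precision.
#'
#' @param state A [defocus_state()].
#' @param model `"exact"` (default) for the composed-kernel width,
#'   `"gaussian"` for the modelled `sigma_inc` of [sigma_components()].
#' @return PSF width (m).
#' @export
psf_sigma <- function(state, model = c("exact", "gaussian")) {
  model <- match.arg(model)
  if (model == "gaussian") return(unname(sigma_components(state)["sigma_inc"]))
  if (state$delta == 0) return(state$system$sigma0)
  q <- green_quadratic(state)
  sqrt(-1 / (4 * Re(q$alpha)))
}

#' Signed defocus phase-chirp scale
#'
#' `z^2(delta) = 2 pi lambda delta` (signed, m^2): the quadratic-in-order
#' phase scale that rearranges the harmonic content of a coherent image. The
#' phase applied to harmonic `n` of fundamental `nu` is
#' `z^2 n^2 nu^2 / 2 = pi lambda delta n^2 nu^2`.
#'
#' @param state A [defocus_state()].
#' @return Signed area (m^2), odd in `delta`.
#' @export
z_squared <- function(state) {
  stopifnot(inherits(state, "defocus_state"))
  2 * pi * state$system$wavelength * state$delta
}

#' Vacuum (Fresnel) propagation kernel
#'
#' Paraxial free-space Green's function over the signed axial distance
#' `delta`:
#' \deqn{D_\delta(u) = \frac{e^{ik\delta}}{i\,2\pi\delta/k}
#'   \exp\!\left(\frac{ik u^2}{2\delta}\right)}, a pure chirp whose modulus
#' is independent of `u`. The global amplitude convention is not physical
#' (all image comparisons are scale-fitted); what matters is the chirp.
#'
#' @param state A [defocus_state()] with `delta != 0`.
#' @param xs Sample-plane coordinate(s) (m).
#' @param x0 Focused-plane coordinate(s) (m).
#' @return Complex amplitude(s), recycled over `xs - x0`.
#' @export
vacuum_green <- function(state, xs, x0) {
  stopifnot(inherits(state, "defocus_state"))
  if (state$delta == 0)
    stop("delta = 0: free-space propagation degenerates to the identity ",
         "kernel; use the focused response directly")
  k <- state$system$k
  d <- state$delta
  u <- xs - x0
  exp(1i * k * d) / (1i * 2 * pi * d / k) * exp(1i * k * u^2 / (2 * d))
}

#' Focused coherent response (complex Green's function at focus)
#'
#' Complex amplitude response of the focused Gaussian-apodized system,
#' \deqn{P_0(x_s, x) = \exp\!\left(-\frac{(x_s - x/M_0)^2}{4\sigma_0^2}\right)
#'   \exp\!\left(\frac{i\pi}{\lambda o}\Big(x_s^2 - \frac{x^2}{M_0^2}\Big)\right).}
#' Its squared modulus is the focused incoherent PSF.
#'
#' @param system An [imaging_system()].
#' @param xs Sample/focused-plane coordinate(s) (m).
#' @param x Detector coordinate(s) (m).
#' @return Complex amplitude(s).
#' @export
focused_green <- function(system, xs, x) {
  stopifnot(inherits(system, "imaging_system"))
  X <- x / system$magnification
  exp(-(xs - X)^2 / (4 * system$sigma0^2)) *
    exp(1i * pi / (system$wavelength * system$object_distance) *
          (xs^2 - X^2))
}

# Quadratic-exponent representation of the composed defocused kernel:
#   P_delta(xs, x) = pref * exp(alpha*xs^2 + mu*X*xs + tau*X^2),  X = x/M0.
# Obtained by carrying out the focused-plane integral of the Fresnel chirp
# against the focused Gaussian response in closed form (single complex
# Gaussian integral; Re(alpha) < 0 always). delta = 0 returns the focused
# response itself (identity kernel limit).
green_quadratic <- function(state) {
  sys <- state$system
  a <- 1 / (4 * sys$sigma0^2)
  b <- pi / (sys$wavelength * sys$object_distance)
  if (state$delta == 0)
    return(list(alpha = -a + 1i * b, mu = 2 * a, tau = -a - 1i * b,
                pref = 1 + 0i))
  cc <- sys$k / (2 * state$delta)
  Q <- -a + 1i * (b + cc)
  list(alpha = 1i * cc + cc^2 / Q,
       mu = 2i * a * cc / Q,
       tau = -a - 1i * b - a^2 / Q,
       pref = exp(1i * sys$k * state$delta) /
         (1i * sys$wavelength * state$delta) * sqrt(-pi / Q))
}

#' Defocused coherent kernel (closed form)
#'
#' The composed Green's function of the defocused system: free-space
#' propagation of the field from the sample plane to the plane in focus,
#' convolved with the focused-system response. For the Gaussian-apodized
#' system the focused-plane integral is a Gaussian integral with a complex
#' quadratic exponent and is evaluated in closed form; `defocused_green()`
#' agrees with adaptive quadrature of that integral to better than 1e-8
#' relative. At `delta = 0` it reduces exactly to [focused_green()].
#'
#' The squared modulus depends on its arguments only through
#' `xs - x / M(delta)` and is a Gaussian of width [psf_sigma()].
#'
#' @param state A [defocus_state()].
#' @param xs Sample-plane coordinate(s) (m).
#' @param x Detector coordinate(s) (m).
#' @return Complex amplitude(s).
#' @export
defocused_green <- function(state, xs, x) {
  stopifnot(inherits(state, "defocus_state"))
  q <- green_quadratic(state)
  X <- x / state$system$magnification
  q$pref * exp(q$alpha * xs^2 + q$mu * X * xs + q$tau * X^2)
}

#' Convert between SI and interface units
#'
#' Helpers for the package's boundary convention: metres and cycles/metre
#' internally, millimetres and cycles/millimetre at external interfaces.
#'
#' @param x Numeric vector.
#' @return Converted numeric vector.
#' @name units
NULL

#' @rdname units
#' @export
mm_to_m <- function(x) x * 1e-3

#' @rdname units
#' @export
m_to_mm <- function(x) x * 1e3

#' @rdname units
#' @export
cycles_per_mm <- function(x) x * 1e3  # -> cycles per metre

#' @rdname units
#' @export
cycles_per_m_to_mm <- function(x) x * 1e-3
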