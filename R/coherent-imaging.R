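# Coherent imaging of periodic objects: defocus transformation of Fourier
# coefficients, closed-form sinusoid images, MTF proxies, self-imaging
# planes, and the NA-independent coherent depth of field.
#
# Key physics: under spatially coherent plane-wave illumination the image
# responds to the *field* transmittance. Defocus applies a pure phase chirp
# exp(-i z^2 n^2 nu^2 / 2), z^2 = 2 pi lambda delta, to each field
# harmonic; only the *focused* pupil attenuates amplitudes. Squaring the
# field doubles the harmonic content (up to order 2N) and makes the image
# coefficients oscillate with defocus instead of blurring.

#' Coherent transfer function of the focused system
#'
#' The pupil spectrum `phi0(nu)`: Fourier transform of the focused coherent
#' response with its weak detector-coordinate dependence dropped. For the
#' Gaussian-apodized system this is evaluated analytically,
#' \deqn{\phi_0(\nu) = \sqrt{\pi/(a - ib)}\; e^{-\pi^2\nu^2/(a - ib)},
#'   \quad a = 1/(4\sigma_0^2),\; b = \pi/(\lambda o),}
#' a Gaussian attenuation `|phi0(nu)/phi0(0)| ~ exp(-4 pi^2 sigma0^2 nu^2)`
#' with a weak quadratic phase. `ideal_pupil()` is the infinite-aperture
#' limit `phi0 == 1`.
#'
#' @param system An [imaging_system()].
#' @return Object of class `"pupil_spectrum"`: a list with the complex
#'   transfer function `phi(nu)` (vectorized over cycles/m), its phase
#'   `phase(nu)`, and `kind` (`"gaussian"` or `"ideal"`).
#' @examples
#' pu <- gaussian_pupil_spectrum(imaging_system(500e-9, 0.1, na0 = 0.05))
#' Mod(pu$phi(10e3) / pu$phi(0))
#' @export
gaussian_pupil_spectrum <- function(system) {
  stopifnot(inherits(system, "imaging_system"))
  a <- 1 / (4 * system$sigma0^2)
  b <- pi / (system$wavelength * system$object_distance)
  phi <- function(nu) sqrt(pi / (a - 1i * b)) * exp(-pi^2 * nu^2 / (a - 1i * b))
  p <- list(phi = phi, phase = function(nu) Arg(phi(nu)),
            kind = "gaussian", system = system)
  class(p) <- "pupil_spectrum"
  p
}

#' @rdname gaussian_pupil_spectrum
#' @export
ideal_pupil <- function() {
  p <- list(phi = function(nu) rep(1 + 0i, length(nu)),
            phase = function(nu) rep(0, length(nu)),
            kind = "ideal", system = NULL)
  class(p) <- "pupil_spectrum"
  p
}

#' @export
print.pupil_spectrum <- function(x, ...) {
  cat(sprintf("pupil_spectrum: %s\n", x$kind))
  invisible(x)
}

#' Defocus-transformed Fourier coefficients of a coherent image
#'
#' The central transformation: for a field object of order `N` the coherent
#' image intensity is again a Fourier series, but of order `2N`, with
#' coefficients given by the autocorrelation of the chirped, pupil-filtered
#' field coefficients
#' \deqn{a'_n(\delta) = \sum_m t_m \overline{t_{m-n}},\qquad
#'   t_m = a_m\,\phi_0(m\nu)\, e^{-i\pi\lambda\delta m^2\nu^2}.}
#' The amplitudes `|t_m|` involve only the *focused* pupil — no circle of
#' confusion — so any harmonic below the focused cut-off survives arbitrary
#' defocus; the chirp phase rearranges, rather than attenuates, the
#' content. The coefficients are Hermitian (real intensity) and the
#' reconstruction equals the squared modulus of the chirped field series
#' pointwise.
#'
#' @param obj A [fourier_object()] (field transmittance).
#' @param state A [defocus_state()].
#' @param pupil A `"pupil_spectrum"` ([ideal_pupil()] or
#'   [gaussian_pupil_spectrum()]).
#' @return Object of class `"coherent_coeffs"`: list with `delta`, `nu`,
#'   integer orders `n` (-2N..2N) and complex coefficients `a`.
#' @examples
#' cc <- coherent_coeffs(make_sinusoid(20e3),
#'   defocus_state(imaging_system(500e-9, 0.1, na0 = 0.05), 2.5e-3),
#'   ideal_pupil())
#' abs(cc$a[cc$n == 1])  # fundamental suppressed at the quarter-Talbot plane
#' @export
coherent_coeffs <- function(obj, state, pupil) {
  stopifnot(inherits(obj, "fourier_object"),
            inherits(state, "defocus_state"),
            inherits(pupil, "pupil_spectrum"))
  nu <- obj$nu
  theta <- pi * state$system$wavelength * state$delta * nu^2
  m_all <- seq.int(-obj$N, obj$N)
  t_m <- fo_coef(obj, m_all) * pupil$phi(m_all * nu) *
    exp(-1i * theta * m_all^2)
  n_out <- seq.int(-2L * obj$N, 2L * obj$N)
  a_out <- vapply(n_out, function(n) {
    sh <- m_all - n
    keep <- sh >= -obj$N & sh <= obj$N
    sum(t_m[keep] * Conj(t_m[match(sh[keep], m_all)]))
  }, complex(1))
  cc <- list(delta = state$delta, nu = nu, n = n_out, a = a_out)
  class(cc) <- "coherent_coeffs"
  cc
}

#' @export
print.coherent_coeffs <- function(x, ...) {
  cat(sprintf("coherent_coeffs: nu = %.4g cycles/mm, delta = %.4g mm\n",
              x$nu * 1e-3, x$delta * 1e3))
  print(data.frame(n = x$n, re = Re(x$a), im = Im(x$a)), row.names = FALSE)
  invisible(x)
}

#' Reconstruct an intensity profile from coherent coefficients
#'
#' Evaluates `sum_n a'_n exp(i 2 pi n nu x / M0)` on a detector grid.
#' Coherent image coordinates are referred to the *native* magnification.
#'
#' @param coeffs A [coherent_coeffs()] result.
#' @param grid Detector coordinates (m).
#' @param m0 Native magnification `M0`.
#' @return An [image_profile()].
#' @export
reconstruct_intensity <- function(coeffs, grid, m0 = 1) {
  stopifnot(inherits(coeffs, "coherent_coeffs"))
  ph <- exp(2i * pi * coeffs$nu * outer(grid / m0, as.numeric(coeffs$n)))
  vals <- as.vector(ph %*% coeffs$a)
  image_profile(grid, Re(vals), delta = coeffs$delta, nu = coeffs$nu,
                magnification_ref = "M0", mode = "coherent")
}

#' Coherent sinusoid image, infinite-aperture limit (closed form)
#'
#' When the fundamental is far below the focused cut-off the pupil can be
#' taken as ideal and the coherent image of the sinusoid reduces to
#' \deqn{I(x) = \tfrac32 - 2\cos(\pi\lambda\delta\nu^2)\cos(2\pi\nu x)
#'   + \tfrac12\cos(4\pi\nu x).}
#' At `delta = 0` this is `4 sin^4(pi nu x)`: perfect imaging of the squared
#' object (global scale is conventional). The image *revives* exactly with
#' axial period `2/(lambda nu^2)`, is shifted by half a period at odd
#' multiples of `1/(lambda nu^2)`, and loses its fundamental entirely at
#' `delta = (m + 1/2)/(lambda nu^2)` — all independent of the aperture.
#'
#' @param delta Defocus (m).
#' @param nu Fundamental frequency (cycles/m, > 0).
#' @param wavelength Wavelength (m).
#' @param grid Detector coordinates (m), referred to `M0 = 1`.
#' @return An [image_profile()].
#' @export
image_sinusoid_ideal <- function(delta, nu, wavelength, grid) {
  stopifnot(nu > 0, wavelength > 0)
  th <- pi * wavelength * delta * nu^2
  I <- 1.5 - 2 * cos(th) * cos(2 * pi * nu * grid) +
    0.5 * cos(4 * pi * nu * grid)
  image_profile(grid, I, delta = delta, nu = nu,
                magnification_ref = "M0", mode = "coherent")
}

#' Coherent sinusoid image for a generic pupil (closed form)
#'
#' Fourier-series closed form of the coherent sinusoid image for an
#' arbitrary focused pupil spectrum `phi0`, derived by expanding the squared
#' modulus of the chirped field series. With `r = |phi0(nu)/phi0(0)|`,
#' `psi = Arg phi0(nu) - 0` and `psi0 = Arg phi0(0)`:
#' \deqn{I = 1 + \tfrac{r^2}{2}
#'  - 2 r \cos(\pi\lambda\delta\nu^2 + \psi_0)\cos(2\pi\nu x + \psi)
#'  + \tfrac{r^2}{2}\cos(4\pi\nu x + 2\psi).}
#' Reduces exactly to [image_sinusoid_ideal()] for the ideal pupil. The
#' second-harmonic amplitude `r^2/2` is independent of defocus.
#'
#' @param pupil A `"pupil_spectrum"`.
#' @param delta Defocus (m).
#' @param nu Fundamental frequency (cycles/m).
#' @param wavelength Wavelength (m).
#' @param grid Detector coordinates (m), referred to `M0 = 1`.
#' @return An [image_profile()].
#' @export
image_sinusoid_generic <- function(pupil, delta, nu, wavelength, grid) {
  stopifnot(inherits(pupil, "pupil_spectrum"), nu > 0, wavelength > 0)
  phi_nu <- pupil$phi(nu)
  phi_0 <- pupil$phi(0)
  r <- Mod(phi_nu / phi_0)
  psi <- Arg(phi_nu) - Arg(phi_0)
  psi0 <- Arg(phi_0)
  th <- pi * wavelength * delta * nu^2
  u <- 2 * pi * nu * grid
  I <- 1 + r^2 / 2 - 2 * r * cos(th + psi0) * cos(u + psi) +
    (r^2 / 2) * cos(2 * u + 2 * psi)
  image_profile(grid, I, delta = delta, nu = nu,
                magnification_ref = "M0", mode = "coherent")
}

# Exponent parameters of the exact Gaussian coherent image:
# the field reaching detector coordinate x (X = x/M0) from harmonic m is
#   G_m(X) = C * exp(Lambda X^2 + m g X + m^2 h),
# obtained by two nested complex Gaussian integrals (focused-plane, then
# sample-plane) carried out in closed form. Re(h) is *independent of
# defocus* (focused-pupil attenuation only), Im(h) = -pi lambda nu^2
# (delta + delta0) carries the Talbot chirp, Re(Lambda) the finite field of
# view, Im(g)/2pi the slightly renormalized fundamental, |Re(g)|/2pi the
# slow hyperbolic envelope rate.
coherent_exponents <- function(state, nu) {
  q <- green_quadratic(state)
  list(h = pi^2 * nu^2 / q$alpha,
       g = -1i * pi * nu * q$mu / q$alpha,
       Lambda = q$tau - q$mu^2 / (4 * q$alpha))
}

#' Parameters of the full Gaussian coherent image
#'
#' Reparametrization of the exact closed form of the coherent sinusoid
#' image in the Gaussian-apodized system, separating frequency filtering
#' from spatial modulation: `c0 = c1 = exp(Re h)` (defocus-independent
#' attenuation of the fundamental and, squared, of the second harmonic),
#' renormalized fundamental `nu_prime = Im(g)/2pi`, hyperbolic
#' field-of-view modulation rate `nu_dprime = |Re(g)|/2pi` (much smaller
#' than `nu` in imaging conditions), axial phase offset
#' `delta0 = -Im(h)/(pi lambda nu^2) - delta` (vanishing for
#' `sigma_l >> sigma0`), and the Gaussian envelope variance
#' `env_sigma2 = -1/(4 Re Lambda) = sigma0^2 + (sigma_l/(2 sqrt(pi)))^2`
#' in object-plane units.
#'
#' @param state A [defocus_state()].
#' @param nu Fundamental frequency (cycles/m, > 0).
#' @return List with `c0`, `c1`, `nu_prime`, `nu_dprime`, `delta0`,
#'   `env_sigma2` and the raw complex exponents `h`, `g`, `Lambda`.
#' @export
gaussian_coherent_params <- function(state, nu) {
  stopifnot(inherits(state, "defocus_state"), nu > 0)
  ex <- coherent_exponents(state, nu)
  lam <- state$system$wavelength
  list(c0 = exp(Re(ex$h)), c1 = exp(Re(ex$h)),
       nu_prime = Im(ex$g) / (2 * pi),
       nu_dprime = abs(Re(ex$g)) / (2 * pi),
       delta0 = -Im(ex$h) / (pi * lam * nu^2) - state$delta,
       env_sigma2 = -1 / (4 * Re(ex$Lambda)),
       h = ex$h, g = ex$g, Lambda = ex$Lambda)
}

#' Exact coherent image of a periodic object in the Gaussian system
#'
#' Evaluates the coherent image intensity
#' `|exp(Lambda X^2) sum_m a_m exp(m g X + m^2 h)|^2` (global scale
#' dropped), the exact closed form of the diffraction integral for a
#' truncated Fourier-series field in the Gaussian-apodized system — finite
#' field of view, pupil phases and all. Validated against brute-force
#' quadrature by [simulate_image()].
#'
#' @param obj A [fourier_object()] (field transmittance).
#' @param state A [defocus_state()].
#' @param grid Detector coordinates (m).
#' @return An [image_profile()] (M0-referred).
#' @export
coherent_image_gaussian <- function(obj, state, grid) {
  stopifnot(inherits(obj, "fourier_object"),
            inherits(state, "defocus_state"))
  ex <- coherent_exponents(state, obj$nu)
  X <- grid / state$system$magnification
  E <- 0 + 0i
  for (i in seq_along(obj$n)) {
    m <- as.numeric(obj$n[i])
    E <- E + obj$a[i] * exp(m * ex$g * X + m^2 * ex$h)
  }
  I <- Mod(exp(ex$Lambda * X^2) * E)^2
  image_profile(grid, I, delta = state$delta, nu = obj$nu,
                magnification_ref = "M0", mode = "coherent")
}

#' Full Gaussian coherent image of the sinusoid (closed form)
#'
#' The complete coherent image of the sinusoidal object in the
#' Gaussian-apodized system, including the Gaussian field-of-view envelope
#' and the hyperbolic edge modulation:
#' \deqn{I \propto e^{2\,\mathrm{Re}\Lambda X^2}\Big[
#'   1 + \tfrac{c_0^2}{2}\cosh(4\pi\nu'' X) + \tfrac{c_0^2}{2}\cos(4\pi\nu' X)
#'   - 2 c_1 \cos(\pi\lambda\nu^2(\delta+\delta_0))\cosh(2\pi\nu'' X)\cos(2\pi\nu' X)
#'   + 2 c_1 \sin(\pi\lambda\nu^2(\delta+\delta_0))\sinh(\pm 2\pi\nu'' X)\sin(2\pi\nu' X)
#'   \Big]}
#' with parameters from [gaussian_coherent_params()] (evaluated via the
#' exact complex exponents, so no sign or constant ambiguity). In the
#' centre of the field of view and for `sigma_l >> sigma0` it reduces to
#' [image_sinusoid_central()]; the image is no longer periodic but has a
#' finite field of view set by the lens.
#'
#' @param state A [defocus_state()].
#' @param nu Fundamental frequency (cycles/m, > 0).
#' @param grid Detector coordinates (m).
#' @param envelope Keep the Gaussian field-of-view envelope (default). With
#'   `FALSE` the envelope factor is divided out, exposing the proper
#'   Fourier expansion that the image reduces to in the middle of the FoV.
#' @return An [image_profile()] (M0-referred), normalized so the DC term of
#'   the central-FoV expansion is 1.
#' @export
image_sinusoid_gaussian <- function(state, nu, grid, envelope = TRUE) {
  stopifnot(inherits(state, "defocus_state"), nu > 0)
  p <- coherent_image_gaussian(make_sinusoid(nu), state, grid)
  I <- p$intensity * 4  # Eq.-(22)-style scale: DC of the expansion is 1
  if (!envelope) {
    ex <- coherent_exponents(state, nu)
    X <- grid / state$system$magnification
    I <- I / exp(2 * Re(ex$Lambda) * X^2)
  }
  image_profile(p$x, I, delta = p$delta, nu = p$nu,
                magnification_ref = "M0", mode = "coherent")
}

#' Central-field-of-view coherent sinusoid image (closed form)
#'
#' The coherent sinusoid image in imaging conditions
#' (`sigma_l >> sigma0`) and near the centre of the field of view:
#' \deqn{I = 1 + \tfrac12 e^{-8\pi^2\sigma_0^2\nu^2}(1 + \cos 4\pi\nu x/M_0)
#'   - 2 e^{-4\pi^2\sigma_0^2\nu^2}\cos(\pi\lambda\nu^2\delta)
#'     \cos(2\pi\nu x/M_0).}
#' Coordinates scale with the *native* `M0`, not `M(delta)`. As
#' `sigma0 -> 0` this reproduces the infinite-aperture form exactly.
#'
#' @param state A [defocus_state()].
#' @param nu Fundamental frequency (cycles/m, > 0).
#' @param grid Detector coordinates (m).
#' @return An [image_profile()].
#' @export
image_sinusoid_central <- function(state, nu, grid) {
  stopifnot(inherits(state, "defocus_state"), nu > 0)
  s0 <- state$system$sigma0
  lam <- state$system$wavelength
  m0 <- state$system$magnification
  g2 <- exp(-4 * pi^2 * s0^2 * nu^2)
  th <- pi * lam * nu^2 * state$delta
  u <- 2 * pi * nu * grid / m0
  I <- 1 + 0.5 * g2^2 * (1 + cos(2 * u)) - 2 * g2 * cos(th) * cos(u)
  image_profile(grid, I, delta = state$delta, nu = nu,
                magnification_ref = "M0", mode = "coherent")
}

#' Incoherent MTF and its two coherent proxies
#'
#' The three functions used to compare the modalities at `(delta, nu)`:
#' \deqn{MTF_{inc} = e^{-2\pi^2(\sigma_0^2(\delta)+\sigma_{CoC}^2(\delta))\nu^2},\quad
#'   MTF_{coh}^{(1)} = -e^{-4\pi^2\sigma_0^2\nu^2}\cos(\pi\lambda\nu^2\delta),\quad
#'   MTF_{coh}^{(2)} = e^{-8\pi^2\sigma_0^2\nu^2}.}
#' The proxies are the fundamental and second-harmonic coefficients of the
#' coherent sinusoid image; unlike a proper MTF the first oscillates with
#' defocus and can be negative, and the second is defocus-independent. Both
#' involve only the *focused* Airy width, so their zero structure is
#' NA-independent.
#'
#' @param state A [defocus_state()].
#' @param nu Spatial frequency (cycles/m, >= 0); vectorized.
#' @return Data frame with columns `nu`, `mtf_inc`, `mtf_coh1`, `mtf_coh2`.
#' @examples
#' st <- defocus_state(imaging_system(500e-9, 0.1, na0 = 0.05), 0)
#' mtf_proxies(st, 10e3)  # (0.969, -0.969, 0.939)
#' @export
mtf_proxies <- function(state, nu) {
  stopifnot(inherits(state, "defocus_state"), all(nu >= 0))
  s0 <- state$system$sigma0  # focused Airy width
  lam <- state$system$wavelength
  data.frame(nu = nu,
             mtf_inc = mtf(state, nu),
             mtf_coh1 = -exp(-4 * pi^2 * s0^2 * nu^2) *
               cos(pi * lam * nu^2 * state$delta),
             mtf_coh2 = exp(-8 * pi^2 * s0^2 * nu^2))
}

#' Zeros of the fundamental coherent MTF proxy in frequency
#'
#' Locates the zero crossings of `mtf_coh1(delta, nu)` as a function of
#' `nu` at fixed defocus by bisection on the sign changes of
#' `cos(pi lambda nu^2 delta)`. The crossings sit at
#' `nu = sqrt((m + 1/2) / (lambda |delta|))`, independent of the aperture.
#'
#' @param state A [defocus_state()] with `delta != 0`.
#' @param nu_max Upper end of the search range (cycles/m).
#' @return Numeric vector of zero positions (cycles/m).
#' @export
mtf_coh1_zeros <- function(state, nu_max) {
  stopifnot(inherits(state, "defocus_state"), state$delta != 0, nu_max > 0)
  f <- function(nu) mtf_proxies(state, nu)$mtf_coh1
  lamd <- state$system$wavelength * abs(state$delta)
  # crossings where pi lam |delta| nu^2 = (m + 1/2) pi
  m_max <- floor(lamd * nu_max^2 - 0.5)
  if (m_max < 0) return(numeric(0))
  vapply(0:m_max, function(m) {
    lo <- sqrt(max(m, 1e-12) / lamd)
    hi <- sqrt((m + 1) / lamd)
    stats::uniroot(f, c(lo, hi), tol = 1e-12 * hi)$root
  }, numeric(1))
}

#' Self-imaging (Talbot-like) planes of a periodic object
#'
#' Enumerates the special defocus planes of the coherent image of a
#' sinusoid of fundamental `nu` within a defocus range, in units of the
#' axial revival scale `1/(lambda nu^2)`:
#' * `perfect` — even multiples: the image repeats exactly;
#' * `shifted` — odd multiples: identical image shifted by half a period;
#' * `suppressed` — half-integer multiples: the fundamental vanishes from
#'   the harmonic content.
#'
#' @param nu Fundamental frequency (cycles/m, > 0).
#' @param wavelength Wavelength (m).
#' @param delta_range Length-2 numeric range of defocus (m).
#' @return Data frame with columns `delta` (m) and `kind` (factor
#'   `perfect`/`shifted`/`suppressed`), ordered by `delta`.
#' @examples
#' special_planes(20e3, 500e-9, c(-7e-3, 7e-3))
#' @export
special_planes <- function(nu, wavelength, delta_range) {
  stopifnot(nu > 0, wavelength > 0, length(delta_range) == 2L)
  lo <- min(delta_range); hi <- max(delta_range)
  unit <- 1 / (wavelength * nu^2)
  grab <- function(offset, step, kind) {
    ms <- seq(ceiling((lo / unit - offset) / step),
              floor((hi / unit - offset) / step))
    if (!length(ms)) return(NULL)
    data.frame(delta = (offset + ms * step) * unit, kind = kind)
  }
  out <- rbind(grab(0, 2, "perfect"), grab(1, 2, "shifted"),
               grab(0.5, 1, "suppressed"))
  out <- out[order(out$delta), , drop = FALSE]
  rownames(out) <- NULL
  out$kind <- factor(out$kind, levels = c("perfect", "shifted", "suppressed"))
  out
}

#' Coherent depth of field at a tolerance
#'
#' The harmonic content of a defocused coherent image changes only through
#' the factor `cos(pi lambda nu^2 delta)`; bounding the distortion by `c`
#' gives the closed-form, NA-independent bound
#' \deqn{\delta_{max} = \frac{\arccos(1-c)}{\pi\lambda\nu^2},}
#' i.e. tolerable frequency `nu ~ 1/sqrt(lambda delta)` — a square-root law
#' in defocus independent of every system parameter except the wavelength,
#' in contrast with the incoherent `1/(NA delta)`.
#'
#' @param nu Spatial frequency (cycles/m, > 0).
#' @param wavelength Wavelength (m).
#' @param c Tolerance in (0, 1).
#' @return A [dof_result()] (`modality = "coherent"`).
#' @examples
#' dof_coherent(10e3, 500e-9, 0.2)  # ~4.1 mm
#' @export
dof_coherent <- function(nu, wavelength, c) {
  stopifnot(nu > 0, wavelength > 0, c > 0, c < 1)
  dof_result(nu, c, acos(1 - c) / (pi * wavelength * nu^2), "coherent")
}

#' Write coherent coefficient tables as CSV
#'
#' Columns `n`, `delta_mm`, `re`, `im`, `modulus` for one or more
#' [coherent_coeffs()] results.
#'
#' @param coeffs_list A [coherent_coeffs()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coeffs_csv <- function(coeffs_list, path) {
  if (inherits(coeffs_list, "coherent_coeffs")) coeffs_list <- list(coeffs_list)
  rows <- do.call(rbind, lapply(coeffs_list, function(cc) {
    data.frame(n = cc$n, delta_mm = cc$delta * 1e3,
               re = Re(cc$a), im = Im(cc$a), modulus = Mod(cc$a))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
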