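# Brute-force evaluation of the raw imaging integrals, used as ground
# truth for every closed form: the coherent image is the squared modulus of
# the field integral of A(xs) against the composed defocused kernel, the
# incoherent image the intensity integral of |A|^2 against the kernel's
# squared modulus. The focused-plane integral inside the kernel is done in
# closed form (optics core), so a single numerical (trapezoid) integral
# over the sample plane remains.

#' Sampled complex transmittance profile
#'
#' Samples a field on a uniform grid for the brute-force imaging integral,
#' choosing (or checking) the sampling step against the two accuracy
#' constraints of the quadrature:
#' * fringe: `dx <= 1/(16 nu_max)` to resolve the finest field fringe;
#' * chirp: `dx <= lambda |delta| / (8 W)` so the Fresnel chirp advances
#'   by less than ~pi/4 per step at the window edge (`W` = window
#'   half-width);
#' plus a kernel-width bound `dx <= sigma_psf / 6` so the Gaussian envelope
#' itself is resolved.
#'
#' @param obj A [fourier_object()], or a function `A(xs)` returning complex
#'   field values (then `nu_max` must be given).
#' @param state A [defocus_state()] (fixes the chirp and kernel bounds).
#' @param window Window half-width `W` (m). Default
#'   `5 * sigma_inc(delta) + 5 / nu`.
#' @param dx Sampling step (m). Default: largest step satisfying all
#'   constraints. A user-supplied step violating a constraint is an error
#'   naming the violated constraint.
#' @param nu_max Highest spatial frequency contained in the field
#'   (cycles/m); taken as `N * nu` for a [fourier_object()].
#' @return Object of class `"sampled_field"`: list with `grid`, `values`,
#'   `window`, `dx`, `nu_max`.
#' @export
sampled_field <- function(obj, state, window = NULL, dx = NULL,
                          nu_max = NULL) {
  stopifnot(inherits(state, "defocus_state"))
  if (inherits(obj, "fourier_object")) {
    if (is.null(nu_max)) nu_max <- max(1L, obj$N) * obj$nu
    if (is.null(window))
      window <- 5 * unname(sigma_components(state)["sigma_inc"]) + 5 / obj$nu
    fun <- function(xs) evaluate_field(obj, xs)
  } else {
    if (!is.function(obj)) stop("'obj' must be a fourier_object or function")
    if (is.null(nu_max) || is.null(window))
      stop("'nu_max' and 'window' are required for a function field")
    fun <- obj
  }
  lam <- state$system$wavelength
  bound_fringe <- 1 / (16 * nu_max)
  bound_chirp <- if (state$delta != 0) lam * abs(state$delta) / (8 * window)
                 else Inf
  bound_kernel <- psf_sigma(state) / 6
  if (is.null(dx)) {
    dx <- min(bound_fringe, bound_chirp, bound_kernel)
  } else {
    if (dx > bound_fringe)
      stop(sprintf("sampling violation (Nyquist/fringe): dx = %.3g > 1/(16 nu_max) = %.3g",
                   dx, bound_fringe))
    if (dx > bound_chirp)
      stop(sprintf("sampling violation (Fresnel chirp): dx = %.3g > lambda|delta|/(8W) = %.3g",
                   dx, bound_chirp))
  }
  grid <- seq(-window, window, by = dx)
  sf <- list(grid = grid, values = as.complex(fun(grid)),
             window = window, dx = dx, nu_max = nu_max)
  class(sf) <- "sampled_field"
  sf
}

#' @export
print.sampled_field <- function(x, ...) {
  cat(sprintf("sampled_field: %d samples, W = %.4g mm, dx = %.4g um, nu_max = %.4g cycles/mm\n",
              length(x$grid), x$window * 1e3, x$dx * 1e6, x$nu_max * 1e-3))
  invisible(x)
}

#' Brute-force image simulation (quadrature oracle)
#'
#' Evaluates the raw image-formation integrals by composite trapezoid
#' quadrature over the sample plane:
#' * coherent: `I(x) = |integral A(xs) P_delta(xs, x) dxs|^2` — the
#'   two-point-interference, phase-sensitive pathway;
#' * incoherent: `I(x) = integral |A(xs)|^2 |P_delta(xs, x)|^2 dxs` — the
#'   linear convolution with the intensity PSF.
#'
#' The defocused kernel `P_delta` is the closed-form Fresnel composition of
#' [defocused_green()]; at `delta = 0` the identity kernel (focused
#' response) is used directly, never the chirp limit.
#'
#' @param state A [defocus_state()].
#' @param field A [sampled_field()].
#' @param mode `"coherent"` or `"incoherent"`.
#' @param x Detector grid (m). Default: 2048 points covering the geometric
#'   image of the sampled window (native M0 for coherent, M(delta) for
#'   incoherent).
#' @return An [image_profile()] (global scale conventional).
#' @export
simulate_image <- function(state, field, mode = c("coherent", "incoherent"),
                           x = NULL) {
  stopifnot(inherits(state, "defocus_state"),
            inherits(field, "sampled_field"))
  mode <- match.arg(mode)
  mref <- if (mode == "coherent") state$system$magnification
          else magnification(state)
  if (is.null(x))
    x <- seq(-0.6 * field$window * abs(mref), 0.6 * field$window * abs(mref),
             length.out = 2048)
  q <- green_quadratic(state)
  xs <- field$grid
  w <- rep(field$dx, length(xs))
  w[c(1L, length(xs))] <- field$dx / 2  # trapezoid ends
  X <- x / state$system$magnification
  # exponents are combined per (xs, x) pair before exponentiating: the
  # individual factors over/underflow although |P_delta| itself is bounded
  if (mode == "coherent") {
    v <- field$values * w
    qa <- q$alpha * xs^2
    E <- vapply(X, function(Xi)
      sum(v * exp(qa + q$mu * Xi * xs + q$tau * Xi^2)), complex(1))
    I <- Mod(E)^2   # |pref|^2 is a constant scale, dropped
  } else {
    a2 <- Mod(field$values)^2 * w
    qa <- 2 * Re(q$alpha) * xs^2
    I <- vapply(X, function(Xi)
      sum(a2 * exp(qa + 2 * Re(q$mu) * Xi * xs + 2 * Re(q$tau) * Xi^2)),
      numeric(1))
  }
  image_profile(x, I, delta = state$delta, nu = NA_real_,
                magnification_ref = if (mode == "coherent") "M0" else "M(delta)",
                mode = mode)
}

#' Extract harmonic coefficients from a sampled profile
#'
#' Linear least-squares fit of
#' `sum_n alpha_n cos(2 pi n nu x / M) + beta_n sin(2 pi n nu x / M)`
#' over an integer number of periods centred in the profile window. Returns
#' the complex series coefficients `a_n = (alpha_n - i beta_n)/2` (`a_0 =
#' alpha_0`) matching the convention `I = sum a_n exp(i 2 pi n nu x / M)`.
#'
#' @param profile An [image_profile()] (or anything with `x` and
#'   `intensity`).
#' @param nu Fundamental object frequency (cycles/m).
#' @param M Magnification referring detector to object coordinates.
#' @param n_max Highest harmonic order to fit.
#' @return Data frame with columns `n`, `a_cos`, `a_sin`, `a` (complex),
#'   `modulus`.
#' @export
extract_harmonics <- function(profile, nu, M, n_max) {
  stopifnot(nu > 0, n_max >= 0)
  u <- profile$x / M
  span <- diff(range(u))
  n_per <- floor(span * nu + 1e-9)
  if (n_per < 3)
    stop(sprintf("window too small: %.3g periods of the fundamental (need >= 3)",
                 span * nu))
  half <- n_per / (2 * nu)
  mid <- mean(range(u))
  keep <- u >= mid - half & u <= mid + half
  u <- u[keep]
  y <- profile$intensity[keep]
  cols <- list(rep(1, length(u)))
  for (n in seq_len(n_max)) {
    cols[[2 * n]] <- cos(2 * pi * n * nu * u)
    cols[[2 * n + 1]] <- sin(2 * pi * n * nu * u)
  }
  Xm <- do.call(cbind, cols)
  qr_x <- qr(Xm)
  if (qr_x$rank < ncol(Xm))
    stop("rank-deficient harmonic fit: window too small for the requested orders")
  beta <- qr.coef(qr_x, y)
  n <- 0:n_max
  a_cos <- c(beta[1], beta[seq(2, by = 2, length.out = n_max)])
  a_sin <- c(0, beta[seq(3, by = 2, length.out = n_max)])
  a <- complex(real = a_cos / c(1, rep(2, n_max)),
               imaginary = -a_sin / c(1, rep(2, n_max)))
  data.frame(n = n, a_cos = a_cos, a_sin = a_sin, a = a, modulus = Mod(a))
}

#' Scale-invariant relative L2 distance between profiles
#'
#' Distance up to a global positive intensity scale:
#' `min_{s > 0} ||a - s b||_2 / ||a||_2`, with `b` linearly resampled onto
#' the grid of `a` when the grids differ. This implements the package-wide
#' convention that absolute image intensity is non-physical.
#'
#' @param a,b [image_profile()]s (or lists with `x` and `intensity`).
#' @return Non-negative scalar; 0 means proportional profiles.
#' @export
compare_normalized <- function(a, b) {
  ya <- a$intensity
  if (isTRUE(all.equal(a$x, b$x))) yb <- b$intensity
  else yb <- stats::approx(b$x, b$intensity, xout = a$x, rule = 2)$y
  na2 <- sum(ya^2)
  nb2 <- sum(yb^2)
  if (na2 == 0 || nb2 == 0) stop("zero-norm profile")
  s <- max(0, sum(ya * yb) / nb2)
  sqrt(sum((ya - s * yb)^2) / na2)
}
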