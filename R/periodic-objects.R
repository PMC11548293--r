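# Periodic field-transmittance objects as truncated Fourier series.

#' Periodic object as a truncated Fourier series
#'
#' Represents a periodic complex field transmittance
#' \deqn{A(x_s) = \sum_{n=-N}^{N} a_n e^{i 2\pi n \nu x_s}}
#' with fundamental frequency `nu` (cycles/m). Coefficients are stored
#' sparsely by integer harmonic index; missing indices are zero. A real
#' (non-phase) object has Hermitian coefficients, `a[-n] == Conj(a[n])`.
#'
#' @param nu Fundamental spatial frequency (cycles/m, > 0).
#' @param n Integer vector of harmonic indices.
#' @param a Complex (or numeric) coefficients, same length as `n`.
#' @return Object of class `"fourier_object"` with fields `nu`, `n`, `a`
#'   and `N` (highest populated order).
#' @examples
#' # 50% duty-cycle intensity grating fundamental, 10 cycles/mm:
#' obj <- fourier_object(10e3, n = c(-1, 0, 1), a = c(-0.25, 0.5, -0.25))
#' evaluate_field(obj, c(0, 25e-6, 50e-6))
#' @export
fourier_object <- function(nu, n, a) {
  stopifnot(is.numeric(nu), length(nu) == 1L, nu > 0,
            length(n) == length(a), length(n) >= 1L)
  if (any(n != round(n))) stop("harmonic indices 'n' must be integers")
  n <- as.integer(n)
  if (anyDuplicated(n)) stop("duplicated harmonic indices")
  a <- as.complex(a)
  keep <- a != 0 | n == 0L
  if (!any(keep)) { n <- 0L; a <- 0 + 0i } else { n <- n[keep]; a <- a[keep] }
  ord <- order(n)
  obj <- list(nu = nu, n = n[ord], a = a[ord], N = max(abs(n)))
  class(obj) <- "fourier_object"
  obj
}

#' @export
print.fourier_object <- function(x, ...) {
  cat(sprintf("fourier_object: nu = %.4g cycles/mm, order N = %d%s\n",
              x$nu * 1e-3, x$N, if (is_hermitian(x)) " (real field)" else ""))
  print(data.frame(n = x$n, re = Re(x$a), im = Im(x$a)), row.names = FALSE)
  invisible(x)
}

# coefficient lookup, zero when absent
fo_coef <- function(obj, n) {
  idx <- match(n, obj$n)
  out <- rep(0 + 0i, length(n))
  out[!is.na(idx)] <- obj$a[idx[!is.na(idx)]]
  out
}

#' Test Hermitian coefficient symmetry
#'
#' A field transmittance evaluates to real values if and only if its
#' coefficients satisfy `a[-n] == Conj(a[n])`.
#'
#' @param obj A [fourier_object()].
#' @param tol Absolute tolerance on the coefficient mismatch.
#' @return Logical.
#' @export
is_hermitian <- function(obj, tol = 1e-12) {
  stopifnot(inherits(obj, "fourier_object"))
  all(abs(fo_coef(obj, -obj$n) - Conj(obj$a)) <= tol)
}

#' Built-in sinusoidal test object
#'
#' The simplest non-phase periodic sample: the positive sinusoid
#' \deqn{S(x_s;\nu) = \sin^2(\pi\nu x_s) = \tfrac12(1 - \cos 2\pi\nu x_s),}
#' i.e. coefficients `a0 = 1/2`, `a(+-1) = -1/4` at fundamental `nu`.
#'
#' @param nu Fundamental spatial frequency (cycles/m, > 0).
#' @return A [fourier_object()] of order 1.
#' @examples
#' s <- make_sinusoid(20e3)               # 20 cycles/mm
#' Re(evaluate_field(s, 1 / (2 * 20e3)))  # 1 at the half period
#' @export
make_sinusoid <- function(nu) {
  if (!is.numeric(nu) || length(nu) != 1L || nu <= 0)
    stop("'nu' must be a positive scalar frequency (cycles/m)")
  fourier_object(nu, n = c(-1L, 0L, 1L), a = c(-0.25, 0.5, -0.25))
}

#' Fourier series of the squared modulus
#'
#' Returns the series of `|A(x_s)|^2`, whose coefficients are the
#' autocorrelation of the field coefficients,
#' `b[k] = sum_m a[m] * Conj(a[m-k])`, extending up to twice the input
#' order. The result is Hermitian (a real intensity) with non-negative DC
#' term.
#'
#' @param obj A [fourier_object()] (field transmittance).
#' @return A [fourier_object()] of order `2 * N` holding the intensity
#'   series.
#' @examples
#' sq <- square_series(make_sinusoid(10e3))  # series of sin^4: 3/8, -1/4, 1/16
#' @export
square_series <- function(obj) {
  stopifnot(inherits(obj, "fourier_object"))
  kmax <- 2L * obj$N
  k <- seq.int(-kmax, kmax)
  b <- vapply(k, function(kk) sum(obj$a * Conj(fo_coef(obj, obj$n - kk))),
              complex(1))
  fourier_object(obj$nu, k, b)
}

#' Evaluate a Fourier-series field on a grid
#'
#' Pointwise evaluation of `sum_n a[n] exp(i 2 pi n nu x)`. Exactly periodic
#' with period `1/nu`; real-valued (up to roundoff) when the coefficients
#' are Hermitian.
#'
#' @param obj A [fourier_object()].
#' @param grid Numeric vector of sample-plane positions (m).
#' @return Complex vector of field values.
#' @export
evaluate_field <- function(obj, grid) {
  stopifnot(inherits(obj, "fourier_object"), is.numeric(grid),
            all(is.finite(grid)))
  ph <- exp(2i * pi * obj$nu * outer(grid, as.numeric(obj$n)))
  as.vector(ph %*% obj$a)
}

#' Read / write periodic-object specifications as JSON
#'
#' Interchange format: `{"nu_cycles_per_mm": <num>,
#' "coeffs": [[n, re, im], ...]}`. Frequencies are cycles/mm in the file and
#' cycles/m in R.
#'
#' @param obj A [fourier_object()].
#' @param path File path.
#' @return `read_fourier_object()` returns a [fourier_object()];
#'   `write_fourier_object()` returns `path` invisibly.
#' @export
write_fourier_object <- function(obj, path) {
  stopifnot(inherits(obj, "fourier_object"))
  coeffs <- lapply(seq_along(obj$n),
                   function(i) c(obj$n[i], Re(obj$a[i]), Im(obj$a[i])))
  jsonlite::write_json(list(nu_cycles_per_mm = obj$nu * 1e-3,
                            coeffs = coeffs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fourier_object
#' @export
read_fourier_object <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(spec$nu_cycles_per_mm) || is.null(spec$coeffs))
    stop("not a periodic-object specification: ", path)
  cf <- spec$coeffs
  if (is.list(cf)) cf <- do.call(rbind, cf)
  cf <- matrix(as.numeric(cf), ncol = 3)
  fourier_object(cycles_per_mm(spec$nu_cycles_per_mm),
                 n = cf[, 1], a = complex(real = cf[, 2],
                                          imaginary = cf[, 3]))
}
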