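# Sampled intensity profiles on the detector.

#' Sampled image intensity profile
#'
#' Container for an intensity profile sampled on a detector grid, carrying
#' the magnification convention used for the coordinate mapping: coherent
#' images keep the native magnification `M0`, incoherent images scale with
#' `M(delta)`.
#'
#' @param x Detector coordinates (m).
#' @param intensity Real non-negative intensities (a floor of
#'   `-1e-12 * max` is tolerated as numerical noise and clipped).
#' @param delta Axial defocus (m) the profile was computed at, or `NA`.
#' @param nu Fundamental object frequency (cycles/m), or `NA`.
#' @param magnification_ref `"M0"` or `"M(delta)"`.
#' @param mode `"coherent"`, `"incoherent"` or `"synthetic"`.
#' @return Object of class `"image_profile"`.
#' @export
image_profile <- function(x, intensity, delta = NA_real_, nu = NA_real_,
                          magnification_ref = c("M0", "M(delta)"),
                          mode = c("coherent", "incoherent", "synthetic")) {
  magnification_ref <- match.arg(magnification_ref)
  mode <- match.arg(mode)
  stopifnot(is.numeric(x), length(x) == length(intensity),
            all(is.finite(x)), all(is.finite(intensity)))
  floor_tol <- -1e-12 * max(abs(intensity), 1)
  if (any(intensity < floor_tol))
    stop("negative intensities beyond the numerical floor")
  intensity <- pmax(intensity, 0)
  p <- list(x = as.numeric(x), intensity = as.numeric(intensity),
            delta = delta, nu = nu, magnification_ref = magnification_ref,
            mode = mode)
  class(p) <- "image_profile"
  p
}

#' @export
print.image_profile <- function(x, ...) {
  cat(sprintf("image_profile (%s, %s-referred): %d samples, x in [%.4g, %.4g] mm\n",
              x$mode, x$magnification_ref, length(x$x),
              min(x$x) * 1e3, max(x$x) * 1e3))
  cat(sprintf("  intensity in [%.4g, %.4g]", min(x$intensity),
              max(x$intensity)))
  if (is.finite(x$delta)) cat(sprintf(", delta = %.4g mm", x$delta * 1e3))
  if (is.finite(x$nu)) cat(sprintf(", nu = %.4g cycles/mm", x$nu * 1e-3))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.image_profile <- function(x, ...) {
  data.frame(x = x$x, intensity = x$intensity)
}

#' Write an intensity profile as CSV
#'
#' Columns `x_mm` and `intensity` (UTF-8, header row, '.' decimal).
#'
#' @param profile An [image_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "image_profile"))
  utils::write.csv(data.frame(x_mm = profile$x * 1e3,
                              intensity = profile$intensity),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
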