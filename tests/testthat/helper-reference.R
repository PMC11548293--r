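# Reference system used throughout: green light, NA0 = 0.05, o = 100 mm,
# unit native magnification (the configuration of the package's worked
# examples).
ref_system <- function(m0 = 1)
  imaging_system(wavelength = 500e-9, object_distance = 0.1, na0 = 0.05,
                 magnification = m0)

ref_state <- function(delta, m0 = 1) defocus_state(ref_system(m0), delta)

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# adaptive quadrature of a complex-valued integrand (Re and Im separately)
cintegrate <- function(f, lower, upper, rel.tol = 1e-10) {
  re <- stats::integrate(function(t) Re(f(t)), lower, upper,
                         rel.tol = rel.tol)$value
  im <- stats::integrate(function(t) Im(f(t)), lower, upper,
                         rel.tol = rel.tol)$value
  complex(real = re, imaginary = im)
}
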