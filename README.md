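# cohimg — defocused coherent vs. incoherent imaging of periodic objects

`cohimg` is an analytical model of defocused image formation in a
paraxial, Gaussian-apodized optical system, for periodic objects under
spatially **coherent** (plane-wave) and **incoherent** illumination. It
is aimed at people designing or analyzing brightfield / light-field
microscopy setups who want to understand — quantitatively — why coherent
illumination keeps resolving defocused planes that incoherent imaging has
long blurred away, and what it costs.

## The model in brief

The system is a single-lens imager with Gaussian-apodized pupil of width
σ_l, object distance o, native magnification M₀, Gaussian-equivalent
numerical aperture NA₀ = σ_l/o and focused Airy width
σ₀ = λ/(2√π·NA₀). A periodic object is a truncated Fourier series of its
*field* transmittance, A(x) = Σₙ aₙ e^{i2πnνx}.

* **Incoherent imaging** is linear in intensity: each harmonic of |A|² is
  attenuated by the Gaussian MTF `exp(-2π²σ_inc²(δ)ν²)` with
  σ_inc²(δ) = σ₀²(δ) + σ_CoC²(δ), the circle of confusion
  σ_CoC = δ·NA/(2√π) growing with defocus δ and aperture. The 1/e²
  cut-off is 1/(π·σ_inc), ≈113 cycles/mm at focus for λ = 500 nm,
  NA₀ = 0.05, and ∝ 1/(NA·δ) once defocused.
* **Coherent imaging** is nonlinear (no PSF/MTF exists): defocus applies
  only the phase chirp e^{-iπλδ m²ν²} to the field harmonics before the
  intensity is formed,

      a'ₙ(δ) = Σₘ tₘ·conj(tₘ₋ₙ),   tₘ = aₘ·φ₀(mν)·e^{-iπλδm²ν²},

  so amplitudes feel only the *focused* pupil φ₀ — no circle of
  confusion — while the harmonic content doubles (to order 2N) and
  recombines periodically with defocus: exact self-images at
  δ = 2m/λν², half-period-shifted ones at odd multiples, and planes with
  the fundamental fully suppressed at half-integer multiples.
* **Depth of field** at harmonic-distortion tolerance c:
  δ_max = arccos(1-c)/(πλν²) for coherent imaging — NA-independent,
  ν ≲ 1/√(λδ) — versus the NA-bound ν ≲ 1/(NA·δ) incoherent law.

Every closed form is validated against a brute-force quadrature of the
raw diffraction integrals (`simulate_image()`), typically to 1e-13 or
better in scale-fitted relative L2.

## Worked example

```r
library(cohimg)

sys <- imaging_system(wavelength = 500e-9, object_distance = 0.1, na0 = 0.05)
sys
#> Gaussian-apodized paraxial imaging system
#>   lambda  = 500 nm
#>   o       = 100 mm
#>   sigma_l = 5 mm   (NA0 = 0.05)
#>   M0      = 1
#>   sigma0  = 2.821 um  (focused Airy width)

cutoff(defocus_state(sys, 0)) * 1e-3   # focused 1/e2 cut-off, cycles/mm
#> [1] 112.8379

mtf(defocus_state(sys, 1e-3), 10e3)    # incoherent MTF, 1 mm defocus, 10 c/mm
#> [1] 0.6696601

# coherent coefficients of the sinusoid at the quarter-Talbot plane:
# the fundamental is annihilated, the second harmonic untouched
coherent_coeffs(make_sinusoid(20e3), defocus_state(sys, 2.5e-3), ideal_pupil())
#> coherent_coeffs: nu = 20 cycles/mm, delta = 2.5 mm
#>   n            re im
#>  -2  6.250000e-02  0
#>  -1 -1.530808e-17  0
#>   0  3.750000e-01  0
#>   1 -1.530808e-17  0
#>   2  6.250000e-02  0

special_planes(20e3, 500e-9, c(-7e-3, 7e-3))
#>     delta       kind
#> 1 -0.0050    shifted
#> 2 -0.0025 suppressed
#> 3  0.0000    perfect
#> 4  0.0025 suppressed
#> 5  0.0050    shifted

dof(sys, 10e3, 0.2)            # incoherent: +-0.73 mm at 10 c/mm, c = 20%
#> incoherent DOF at nu = 10 cycles/mm, tolerance c = 0.2:
#>   delta_max = 0.7317 mm  (range +-0.7317 mm)
dof_coherent(10e3, 500e-9, 0.2)  # coherent: +-4.1 mm, NA-independent
#> coherent DOF at nu = 10 cycles/mm, tolerance c = 0.2:
#>   delta_max = 4.097 mm  (range +-4.097 mm)

# closed form vs. brute-force diffraction integral
validate_suite(sys, delta_mm = 1, nu_cycles_mm = 20, n_x = 101)
#>         mode delta_mm nu_cycles_mm       rel_l2
#> 1   coherent        1           20 1.080986e-15
#> 2 incoherent        1           20 3.377698e-15
```

Reading the numbers: at 10 cycles/mm a 1 mm defocus already costs a third
of the incoherent modulation (MTF 0.67), and the 20% tolerance band is
only ±0.73 mm; the coherent band is ±4.1 mm — 5.6× longer — and does not
change if the aperture is halved. At the quarter-Talbot plane (2.5 mm for
20 cycles/mm) the coherent image has *no* fundamental at all but full
second-harmonic contrast: degradation by re-mixing, not blurring.

## Command line

A thin CLI over the same functions (units there: nm, mm, cycles/mm):

```sh
Rscript inst/cli/cohimg map      --nu 20 --delta=-7:7:0.1 --out-dir out/   # x-delta maps (CSV + TIFF)
Rscript inst/cli/cohimg mtf      --nu 0.5,60 --delta 0,1 --na0 0.05,0.025 --out-dir out/
Rscript inst/cli/cohimg dof      --nu 1,10,50 --tolerance 0.2
Rscript inst/cli/cohimg planes   --nu 20 --delta=-7:7:1
Rscript inst/cli/cohimg validate --nu 10,20 --delta 0:3:1
```

`map` reproduces the characteristic defocus–coordinate intensity maps
(coherent revivals vs. incoherent washout); `validate` reruns the
closed-form-vs-quadrature suite and prints the maximum deviations.

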