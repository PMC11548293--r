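# Coherent imaging: pupil spectrum, coefficient transformation, closed-form
# sinusoid images, MTF proxies, self-imaging planes and coherent DOF.

test_that("pupil spectra: ideal is unity; Gaussian matches direct transform
           of the focused response", {
  idl <- ideal_pupil()
  nus <- c(0, 5e3, 40e3)
  expect_equal(idl$phi(nus), rep(1 + 0i, 3))
  expect_equal(idl$phase(nus), rep(0, 3))
  sys <- ref_system()
  pu <- gaussian_pupil_spectrum(sys)
  expect_equal(Mod(pu$phi(0) / pu$phi(0)), 1)
  for (nu in c(0, 10e3, 50e3)) {
    quad <- cintegrate(function(x0) focused_green(sys, x0, 0) *
                         exp(-2i * pi * nu * x0),
                       -14 * sys$sigma0, 14 * sys$sigma0, rel.tol = 1e-12)
    expect_lt(Mod(pu$phi(nu) - quad) / Mod(quad), 1e-8)
  }
  # attenuation is close to the pure-Airy Gaussian envelope
  expect_equal(Mod(pu$phi(20e3) / pu$phi(0)),
               exp(-4 * pi^2 * sys$sigma0^2 * (20e3)^2), tolerance = 1e-5)
})

test_that("coefficient transformation: perfect imaging at focus, harmonic
           doubling, defocus-independent attenuation", {
  nu <- 20e3
  s <- make_sinusoid(nu)
  # focus + ideal pupil = coefficients of sin^4 (up to global scale)
  cc0 <- coherent_coeffs(s, ref_state(0), ideal_pupil())
  b <- cc0$a[match(0:2, cc0$n)]
  expect_equal(b, c(3 / 8 + 0i, -1 / 4 + 0i, 1 / 16 + 0i))
  # |a'_2| independent of delta for the ideal pupil
  mods <- vapply(c(0, 0.7e-3, 1e-3, 2.5e-3, 6e-3), function(d) {
    cc <- coherent_coeffs(s, ref_state(d), ideal_pupil())
    Mod(cc$a[cc$n == 2])
  }, numeric(1))
  expect_equal(mods, rep(1 / 16, length(mods)), tolerance = 1e-14)
  # with the Gaussian pupil, |a'_n| still only involves the focused pupil
  pu <- gaussian_pupil_spectrum(ref_system())
  mods_g <- vapply(c(0, 1e-3, 3e-3), function(d) {
    cc <- coherent_coeffs(s, ref_state(d), pu)
    Mod(cc$a[cc$n == 2])
  }, numeric(1))
  expect_equal(mods_g / mods_g[1], rep(1, 3), tolerance = 1e-12)
  # Hermitian coefficients (real intensity)
  cc <- coherent_coeffs(s, ref_state(1.3e-3), ideal_pupil())
  expect_equal(cc$a[match(-cc$n, cc$n)], Conj(cc$a), tolerance = 1e-15)
})

test_that("harmonic content doubles to exactly 2N for field orders 1..4", {
  set.seed(23)
  for (N in 1:4) {
    n <- -N:N
    a <- complex(real = rnorm(length(n), sd = 0.3),
                 imaginary = rnorm(length(n), sd = 0.3))
    a[n == N] <- a[n == N] + 0.5  # make the top order generically nonzero
    obj <- fourier_object(6e3, n, a)
    cc <- coherent_coeffs(obj, ref_state(1.7e-3), ideal_pupil())
    expect_equal(max(abs(cc$n)), 2L * N)
    expect_gt(Mod(cc$a[cc$n == 2 * N]), 1e-6)
    # and reconstruction is the squared modulus of the chirped field series
    st <- ref_state(1.7e-3)
    th <- pi * st$system$wavelength * st$delta * obj$nu^2
    x <- seq(-1e-4, 1e-4, length.out = 64)
    tm <- obj$a * exp(-1i * th * as.numeric(obj$n)^2)
    E <- vapply(x, function(xx)
      sum(tm * exp(2i * pi * obj$nu * as.numeric(obj$n) * xx)), complex(1))
    rec <- reconstruct_intensity(cc, x)
    expect_equal(rec$intensity, Mod(E)^2, tolerance = 1e-12)
  }
})

test_that("infinite-aperture sinusoid image: perfect planes, shifted planes,
           suppressed fundamental, axial revivals", {
  nu <- 20e3
  lam <- 500e-9
  x <- seq(-1e-4, 1e-4, length.out = 161)
  img0 <- image_sinusoid_ideal(0, nu, lam, x)
  expect_equal(img0$intensity, 4 * sin(pi * nu * x)^4, tolerance = 1e-12)
  expect_equal(img0$intensity[which.min(abs(x))], 0, tolerance = 1e-12)
  expect_equal(image_sinusoid_ideal(0, nu, lam, 1 / (2 * nu))$intensity, 4)
  # quarter-Talbot plane (delta = 1/(2 lambda nu^2) = 2.5 mm): fundamental
  # vanishes, leaving 3/2 + cos(4 pi nu x)/2
  img_q <- image_sinusoid_ideal(2.5e-3, nu, lam, x)
  expect_equal(img_q$intensity, 1.5 + 0.5 * cos(4 * pi * nu * x),
               tolerance = 1e-9)
  # half-Talbot plane (5 mm): image shifted by half a period
  img_h <- image_sinusoid_ideal(5e-3, nu, lam, x)
  expect_equal(img_h$intensity, 4 * cos(pi * nu * x)^4, tolerance = 1e-9)
  # full revival at 2/(lambda nu^2) = 10 mm
  img_r <- image_sinusoid_ideal(10e-3, nu, lam, x)
  expect_equal(img_r$intensity, img0$intensity, tolerance = 1e-9)
})

test_that("generic-pupil closed form reduces to the ideal one and exposes the
           defocus-independent second harmonic", {
  nu <- 20e3; lam <- 500e-9
  x <- seq(-1.2e-4, 1.2e-4, length.out = 301)
  for (d in c(0, 1e-3, 3.3e-3)) {
    a <- image_sinusoid_generic(ideal_pupil(), d, nu, lam, x)
    b <- image_sinusoid_ideal(d, nu, lam, x)
    expect_equal(a$intensity, b$intensity, tolerance = 1e-12)
  }
  sys <- ref_system()
  pu <- gaussian_pupil_spectrum(sys)
  # low frequency at focus: ~ 4 sin^4 after scale fit
  xl <- seq(-1.5e-3, 1.5e-3, length.out = 301)
  g <- image_sinusoid_generic(pu, 0, 1e3, lam, xl)
  ref <- image_profile(xl, 4 * sin(pi * 1e3 * xl)^4, mode = "synthetic")
  expect_lt(compare_normalized(g, ref), 1e-3)
  # second-harmonic amplitude |phi(nu)/phi(0)|^2 / 2, independent of delta
  r2 <- Mod(pu$phi(nu) / pu$phi(0))^2
  for (d in c(0, 2e-3)) {
    img <- image_sinusoid_generic(pu, d, nu, lam, x)
    h <- extract_harmonics(img, nu, 1, 2)
    expect_equal(Mod(h$a[h$n == 2]), r2 / 4, tolerance = 1e-6)
  }
})

test_that("central-FoV Gaussian image: correct fundamental weight, reduces to
           the ideal form as sigma0 -> 0, M0 coordinate scaling", {
  nu <- 20e3
  st <- ref_state(1e-3)
  x <- seq(-1e-4, 1e-4, length.out = 201)
  img <- image_sinusoid_central(st, nu, x)
  h <- extract_harmonics(img, nu, 1, 2)
  # fundamental coefficient -2 exp(-4 pi^2 sigma0^2 nu^2) cos(pi lam nu^2 d),
  # here ~ -1.427 in the cosine basis (complex coefficient -1.427/2)
  expect_equal(2 * Re(h$a[h$n == 1]), -1.4270, tolerance = 1e-4)
  # sigma0 -> 0 limit: equals the infinite-aperture form (tiny-Airy system)
  tiny <- suppressWarnings(defocus_state(
    imaging_system(500e-9, 0.1,
                   pupil_width = 500e-9 * 0.1 / (2 * sqrt(pi) * 1e-9)), 1e-3))
  expect_equal(tiny$system$sigma0, 1e-9)
  a <- image_sinusoid_central(tiny, 1e3, x)
  b <- image_sinusoid_ideal(1e-3, 1e3, 500e-9, x)
  expect_lt(max(abs(a$intensity - b$intensity)), 1e-9)
  # coordinates scale with the native magnification, not M(delta)
  st2 <- defocus_state(ref_system(m0 = 2), 4e-3)
  x2 <- seq(-2e-4, 2e-4, length.out = 201)
  img2 <- image_sinusoid_central(st2, nu, x2)
  h2 <- extract_harmonics(img2, nu, 2, 2)   # fit in M0-referred units
  hm <- extract_harmonics(img2, nu, magnification(st2), 2)
  expect_gt(Mod(h2$a[h2$n == 2]), Mod(hm$a[hm$n == 2]))
  expect_equal(img2$magnification_ref, "M0")
})

test_that("full Gaussian image: FoV envelope, central-FoV limit, axial
           periodicity at the ideal-pupil scale", {
  nu <- 20e3
  st <- ref_state(1e-3)
  # centre of FoV agrees with the central closed form
  xc <- seq(-0.5 / nu, 0.5 / nu, length.out = 201)
  a <- image_sinusoid_gaussian(st, nu, xc, envelope = FALSE)
  b <- image_sinusoid_central(st, nu, xc)
  expect_lt(compare_normalized(a, b), 1e-3)
  # envelope width tracks sigma0^2 + (sigma_l/(2 sqrt(pi)))^2
  p <- gaussian_coherent_params(st, nu)
  sys <- st$system
  expect_equal(p$env_sigma2,
               sys$sigma0^2 + (sys$pupil_width / (2 * sqrt(pi)))^2,
               tolerance = 1e-10)
  # the parameters behave as imaging conditions dictate
  expect_equal(p$c0, exp(-4 * pi^2 * sys$sigma0^2 * nu^2), tolerance = 1e-4)
  expect_equal(p$nu_prime / nu, 1, tolerance = 1e-5)
  expect_lt(p$nu_dprime / nu, 0.01)
  expect_lt(abs(p$delta0), 1e-5)
  # axial periodicity with period 2/(lambda nu^2), central FoV
  st_rev <- ref_state(1e-3 + 2 / (sys$wavelength * nu^2))
  a2 <- image_sinusoid_gaussian(st_rev, nu, xc, envelope = FALSE)
  expect_lt(compare_normalized(a, a2), 5e-4)
})

test_that("MTF proxies: values, bounds, oscillation and NA independence", {
  st0 <- ref_state(0)
  p0 <- mtf_proxies(st0, 0)
  expect_equal(unlist(p0[c("mtf_inc", "mtf_coh1", "mtf_coh2")]),
               c(mtf_inc = 1, mtf_coh1 = -1, mtf_coh2 = 1))
  p10 <- mtf_proxies(st0, 10e3)
  expect_equal(p10$mtf_coh1, -0.969, tolerance = 1e-3)
  expect_equal(p10$mtf_coh2, 0.939, tolerance = 1e-3)
  # proxy 1 oscillates in delta with NA-independent zeros at (m+1/2)/(lam nu2)
  nu <- 20e3
  ds <- seq(0, 6e-3, by = 5e-4)
  v <- vapply(ds, function(d) mtf_proxies(ref_state(d), nu)$mtf_coh1,
              numeric(1))
  expect_true(any(v > 0) && any(v < 0))
  expect_true(all(abs(v) <= 1))
  # proxy 2 is defocus independent
  v2 <- vapply(ds, function(d) mtf_proxies(ref_state(d), nu)$mtf_coh2,
               numeric(1))
  expect_equal(v2, rep(v2[1], length(v2)))
  # zero positions in nu coincide for NA 0.05 and NA 0.025
  z1 <- mtf_coh1_zeros(ref_state(1e-3), 60e3)
  z2 <- mtf_coh1_zeros(
    defocus_state(imaging_system(500e-9, 0.1, na0 = 0.025), 1e-3), 60e3)
  expect_equal(length(z1), 2L)
  expect_equal(z1[1] * 1e-3, sqrt(1 / (2 * 500e-9 * 1e-3)) * 1e-3,
               tolerance = 1e-6)   # ~31.62 cycles/mm
  expect_lt(max(abs(z1 - z2) / z1), 1e-12)
})

test_that("self-imaging plane table enumerates perfect/shifted/suppressed
           planes with 1/nu^2 spacing", {
  tab <- special_planes(20e3, 500e-9, c(-7e-3, 7e-3))
  expect_equal(tab$delta[tab$kind == "perfect"], 0)
  expect_equal(sort(tab$delta[tab$kind == "shifted"]) * 1e3, c(-5, 5))
  expect_equal(sort(tab$delta[tab$kind == "suppressed"]) * 1e3,
               c(-2.5, 2.5))
  # nu -> nu/sqrt(2) doubles all spacings
  tab2 <- special_planes(20e3 / sqrt(2), 500e-9, c(-14e-3, 14e-3))
  expect_equal(sort(tab2$delta[tab2$kind == "shifted"]) * 1e3, c(-10, 10),
               tolerance = 1e-9)
  # delta = 0 is always a perfect plane
  expect_true(0 %in% special_planes(3e3, 500e-9, c(-1e-3, 1e-3))$delta)
})

test_that("coherent DOF: closed form, 1/nu^2 scaling, increasingly favorable
           ratio over the incoherent bound", {
  r <- dof_coherent(10e3, 500e-9, 0.2)
  expect_equal(r$delta_max * 1e3, 4.097, tolerance = 1e-3)
  expect_equal(r$modality, "coherent")
  expect_equal(dof_coherent(20e3, 500e-9, 0.2)$delta_max / r$delta_max,
               1 / 4, tolerance = 1e-12)
  # NA independence: the bound ignores every system parameter but lambda
  expect_equal(dof_coherent(10e3, 500e-9, 0.2)$delta_max,
               acos(0.8) / (pi * 500e-9 * (10e3)^2))
  # coherent imaging keeps a finite DOF beyond the focused incoherent
  # cut-off, where the incoherent bound ceases to exist
  sys <- ref_system()
  expect_error(dof(sys, 60e3, 0.2), "unresolvable")
  expect_gt(dof_coherent(60e3, 500e-9, 0.2)$delta_max, 0)
  # and always exceeds the incoherent bound at the frequencies both resolve
  ratio <- vapply(c(5e3, 10e3, 20e3), function(nu)
    dof_coherent(nu, 500e-9, 0.2)$delta_max /
      dof(sys, nu, 0.2)$delta_max, numeric(1))
  expect_true(all(ratio > 1))
})
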