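Package: cohimg
Title: Defocused Coherent and Incoherent Imaging of Periodic Objects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical model of defocused image formation for periodic
    objects under spatially coherent and incoherent illumination in a
    paraxial, Gaussian-apodized optical system. Provides the paraxial
    Green's functions and their closed-form Fresnel composition, the
    defocus transformation of Fourier coefficients under coherent
    illumination (harmonic doubling, Talbot-like self-imaging planes),
    incoherent MTF and cut-off models, MTF proxies for coherent imaging,
    depth-of-field bounds for both modalities, and a brute-force
    diffraction-integral oracle used to validate every closed form.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
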