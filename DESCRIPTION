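Package: quenchbind
Title: Fluorescence Quenching, Serum-Albumin Binding and Cocrystal
    Physicochemistry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of drug-serum-albumin interactions from fluorescence
    quenching titrations and of pharmaceutical cocrystal physicochemistry.
    Provides inner-filter correction of titration intensities, Stern-Volmer
    regression with quenching-mechanism classification, double-logarithmic
    binding regression (binding constant and site number) with affinity
    classification, site-marker competition assignment to Sudlow sites,
    Van't Hoff thermodynamics (enthalpy, entropy, Gibbs energy) with
    interaction-force typing, CHN elemental composition checks, apparent
    solubility ratios, volume-corrected cumulative dissolution release, and
    powder X-ray diffraction new-phase detection. A forward simulator
    generates titration, competition and dissolution data with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
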