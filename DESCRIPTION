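Package: phantomqa
Title: Virtual Phantom Simulation and Quality Assurance for Cardiac T1/T2 Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and quality-assuring a nine-tube
    nickel-chloride/agarose relaxometry phantom for cardiovascular magnetic
    resonance T1 and T2 mapping. Fits linear relaxivity models linking
    ingredient concentrations to relaxation rates and inverts them to design
    tube recipes for target T1/T2; rasterizes a virtual 3x3 tube phantom and
    simulates inversion-recovery gradient-echo, single-echo spin-echo, MOLLI,
    T2-prepared bSSFP, dual-echo field-mapping and double-angle acquisitions
    with Rician noise and B0/B1 inhomogeneity; reconstructs pixel-wise T1, T2,
    off-resonance and relative flip-angle maps; and computes the standard
    phantom quality-assurance statistics (bias versus spin-echo reference,
    coefficients of variation, long-term reproducibility, temperature trends).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
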