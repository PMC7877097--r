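Package: speckit
Title: Decode, Analyze and Compose One-Dimensional Analytical Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless toolkit for one-dimensional analytical spectra as
    handled in synthetic-chemistry data management: a JCAMP-DX reader and
    writer covering the compressed ordinate forms (SQZ/DIF/DUP), an mzML
    reader with scan selection and conversion to JCAMP-DX peak tables,
    automatic spectrum-type detection, threshold-based peak picking with
    user edit tracking, NMR-specific analysis (residual-solvent referencing,
    signal integration, multiplicity and coupling-constant inference),
    basic FID processing (apodization, Fourier transform, automatic phase
    and baseline correction), IR band-intensity classification, and
    generation of the edited-file plus image bundle used by embedded
    spectra-management workflows. Includes a seeded synthetic-fixture
    generator for NMR, IR and MS data and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    mzR,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
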