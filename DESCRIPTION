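Package: slicelogp
Title: Slice-Selective 19F NMR Determination of Octanol/Water log P
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plan, simulate and process slice-selective (spatially encoded)
    19F NMR experiments for reference-free determination of the n-octanol/water
    partition coefficient (log P) from a single partitioned sample. Provides
    pulsed-field-gradient slice geometry calculations (slice thickness, slice
    position from pulse offsets, shaped-pulse durations), a synthetic-data
    generator that emulates two-phase partitioned samples as pseudo-2D
    free-induction-decay datasets (Lorentzian lines, T1 saturation, spin-echo
    T2 attenuation, seeded time-domain noise), readers and writers for a
    Bruker-style directory dialect and a portable fixture format, and an
    automated processing chain (Fourier transform, zeroth-order phasing,
    scout-scan carrier placement, slice extraction, spectral summation,
    windowed integration, signal-to-noise estimation) that reports log P with
    an uncertainty propagated from signal-to-noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
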