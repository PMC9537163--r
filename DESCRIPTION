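Package: cetscope
Title: Time-Resolved Coherent Energy Transfer Between Mid-Infrared Fields and Solvated Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the complete linear energy exchange between broadband
    mid-infrared waveforms and vibrating molecules in solution. Provides
    few-cycle and chirped Gaussian field synthesis, a multi-mode
    Lorentz-oscillator description of the sample, exact and thin-sample
    propagation through a liquid cuvette, the time-resolved coherent energy
    transfer CET(t) with its transiently-absorbed/re-emitted energy budget,
    first-order vibrational coherences with and without the rotating-wave
    approximation, impulsive-regime closed forms with duration and
    concentration scans, Lorentzian line-shape fitting with trace
    normalization and error propagation, and a Fourier-grid Hamiltonian
    eigensolver with dephasing-rate estimation from dipole autocorrelation
    functions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    pracma,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
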