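Package: epscdeconv
Title: Blind Deconvolution of Multiphasic Excitatory Postsynaptic Current Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects exocytotic release events in noisy whole-cell recordings of
    excitatory postsynaptic currents (EPSCs) by blind deconvolution. A sparse,
    positive release signal and a stereotyped, everywhere-negative impulse
    response are inferred jointly from a single current trace: the signal by
    maximum a posteriori estimation under a quantified maximum-entropy prior
    with the regularization strength and noise level selected automatically by
    the evidence framework, and the impulse response by sign-constrained
    Wiener-Hopf estimation, the two steps alternating in the manner of
    expectation maximization. Includes a stochastic AMPA-receptor simulator for
    ground-truthed synthetic records, benchmark assays for temporal resolution,
    amplitude sensitivity and multiquantal amplitude histograms, a Gaussian-prior
    (Wiener filter) fallback mode, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    purrr,
    ggplot2,
    generics,
    jsonlite,
    pracma,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
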