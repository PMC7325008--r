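Package: ctorsim
Title: Communication-Theoretic Simulation of Object Recognition in the Ventral Visual Stream
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested simulator of a communication-theoretic model of object
    recognition (CTOR) along the primate ventral visual stream. A binary object
    representation is tangled by a rate-1/N convolutional encoder standing in
    for the retina/LGN/V1 stages, perturbed by a discrete memoryless (or
    additive-noise) channel, and untangled by an inferior-temporal-cortex
    decoder implementing Viterbi maximum a posteriori sequence estimation with
    memory-derived transition priors. Downstream operations cover feature
    interleaving, majority-representative memory compression, transition-prior
    estimation from decoded streams, and a linear category readout. Seeded
    Monte-Carlo drivers compute bit/symbol/category correct rates across
    message lengths and channel dispersiveness, and compare maximum-likelihood
    with iterative maximum a posteriori decoding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
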