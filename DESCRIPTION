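Package: tfscape
Title: Mutation Bias and Composition Bias on Transcription Factor Binding
    Affinity Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds genotype-phenotype landscapes of transcription factor
    binding affinity from 8-mer protein-binding-microarray score tables,
    and analyses how a transition/transversion bias in the mutation supply
    interacts with the composition bias of the landscape to shape adaptive
    evolution. Provides canonical double-stranded k-mer primitives,
    genotype-network construction with replicate-based noise thresholds,
    composition-bias statistics over landscapes and accessible mutational
    paths, an origin-fixation Markov chain with exact navigability and
    path-entropy calculations, Wright-Fisher simulation with biased
    mutation, quasispecies stationary distributions, and population
    statistics (overlap coefficients, Shannon and nucleotide diversity,
    mutational robustness, allele-frequency spectra, evolvability).
    A synthetic landscape generator with tunable GC skew, size and
    ruggedness supports fully reproducible analyses without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
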