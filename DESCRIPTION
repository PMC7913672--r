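Package: noseq
Title: m6A Detection in Amplicon Sequencing After Partial Chemical Deamination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects N6-methyladenosine (m6A) in targeted amplicon sequencing
    libraries that were partially deaminated with nitrous acid before reverse
    transcription. Unmethylated adenosines are read out as a mixture of A and G
    signals (via inosine), cytidines as C/T, while m6A resists deamination and
    retains a pure A signal. The package provides a deamination-aware
    seed-and-extend aligner with an asymmetric substitution matrix and strict
    perfect-score/anchor retention filters, per-position base-composition and
    conversion-rate tables, a cumulative-normal probability caller for m6A
    candidate sites with stoichiometry calibration, UMI-based redundancy
    assessment, and a chemistry-faithful read simulator that replaces wet-lab
    inputs for testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    S4Vectors,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
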