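Package: mida
Title: Mass Isotopomer Distribution Analysis by Least-Squares Deconvolution
Version: 1.0.0
Authors@R:
    person("MIDA", "Maintainers", email = "mida@example.org", role = c("aut", "cre"))
Description: Converts experimental mass-spectrometric intensity patterns of
    isotope-labelled metabolites and their fragments into natural-abundance
    corrected isotopomer-group distributions and absolute isotope enrichments.
    Natural abundance is modelled by a binomial expansion over the labelable
    atoms; correction is performed by least-squares deconvolution of a
    lower-triangular Toeplitz abundance matrix via the Moore-Penrose
    pseudoinverse. Includes a reader and writer for '#'-separated '.ls'
    metabolite records (with locale-aware decimal marks), a synthetic-spectrum
    generator with known ground truth for validation, and a command-line
    interface for batch analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
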