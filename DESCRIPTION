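Package: hypermutr
Title: Hypermutator Population Dynamics, Mutation-Rate Estimation and
    Parallel-Evolution Tests for Gut-Commensal Experimental Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward Wright-Fisher simulation of clonal bacterial
    populations carrying deleterious, neutral and beneficial mutations
    under several distributions of fitness effects, including
    two-subpopulation mutator/nonmutator competitions with optional
    negative frequency-dependent selection on a marker locus.
    Luria-Delbruck fluctuation-assay analysis with the Ma-Sandri-Sarkar
    maximum-likelihood estimator of mutation rate and Stewart-style 95
    percent confidence intervals; mutation-selection-balance mutator
    strength from equilibrium resistant-mutant frequencies; selection
    coefficients from log-ratio competitive-fitness series. A
    spectrum-preserving randomisation (G-score) test for parallel
    mutational targets across hypermutator clones, and observed,
    expected and spectrum-normalised dN/dS with a binomial test. A
    synthetic-data module generates genomes, SNP tables, fluctuation
    counts and competition series with known ground truth so the whole
    pipeline runs at desk scale without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
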