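Package: favat
Title: Feature-Amplified Voting with Three-Profile Alignment for
    Functional Residue Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts candidate functional residues of a target protein by
    contrasting two groups from the same superfamily: proteins that share the
    target's function despite low sequence identity (the A group) and close
    homologues that lack it (the ~A group). The target sequence and the two
    pre-aligned group profiles are aligned jointly by three-profile dynamic
    programming with affine gap costs, then every target residue receives a
    voting score (V-score) for each (A, ~A) sequence pair from BLOSUM62
    substitution-score differences; the accumulated total (T-score) is
    normalized to 0-100 and thresholded to rank candidates. Includes a
    brute-force alignment oracle, a synthetic family generator with planted
    functional positions, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
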