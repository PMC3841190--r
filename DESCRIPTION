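Package: sapick
Title: Position-Specific Protein Fragment Picking from Structural
    Alphabet Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects position-specific candidate structural fragments
    (6 to 27 amino acids) for a query protein by comparing structural
    alphabet probability profiles against a bank of profiles derived
    from known structures.  A 27-state hidden Markov model with
    Gaussian emissions over four-residue geometric descriptors encodes
    C-alpha traces into letter strings (Viterbi) and posterior
    probability profiles (forward-backward).  Fragment similarity is
    scored with the maximum Jensen-Shannon divergence over paired
    profile columns; hits are reduced by incremental cRMSD clustering,
    and surviving cluster representatives are filtered through a
    calibrated expected-precision grid before redundancy elimination.
    Includes a synthetic structure generator (idealized helices,
    strands, hairpins and coil) so the whole protocol can be exercised
    and calibrated without external structure collections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    withr,
    generics,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
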