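Package: zfstall
Title: Ribosome Collision on C2H2 Zinc-Finger Domains and No-Go mRNA Decay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit linking ribosome collisions (disome footprints)
    on tandem C2H2 zinc-finger domains to Znf598-dependent mRNA decay.
    Provides a C2H2 zinc-finger pattern scanner with a fixed 28-residue
    domain convention, peptide net-charge and isoelectric-point calculation
    from Henderson-Hasselbalch terms, per-codon disome occupancy and the
    disome localization score with tertile grouping, nascent-chain net-charge
    profiles upstream of stalled A-sites with a randomized-position null,
    fold-change arithmetic with maternal/zygotic classification and
    intron-adjusted changes, a BRIC-Seq half-life estimator using nested
    prefix fits with spike-in renormalization, and seeded synthetic-data
    generators with ground truth for every recoverable quantity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
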