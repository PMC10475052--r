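Package: cultrecruit
Title: Recruitment of Cultured Marine Bacteria in 16S Amplicon Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how much of a marine prokaryotic community,
    characterized by 16S rRNA amplicon sequence variants (ASVs), is
    recovered by a heterotrophic culture collection. Extracts the V4-V5
    region shared by isolate and amplicon primer sets via degenerate IUPAC
    primer search, finds every isolate-ASV pair identical at 100% identity
    with the ASV fully covered and ungapped, rarefies count tables by
    permutation (multivariate hypergeometric subsampling), and reports
    per-sample and per-stratum percentages of ASVs and reads matched, with
    rRNA operon copy-number correction. Also classifies ASVs into
    abundant / mid-abundant / rare biosphere classes, genera into station
    occurrence categories, computes plate-count cultivability fractions,
    and ships a synthetic ocean-community generator with planted ground
    truth so every stage can be validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
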