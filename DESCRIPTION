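Package: pepscreen
Title: In Silico Screening of Bioactive Peptides Released by Enzymatic Proteolysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates enzymatic proteolysis of protein sequences with a
    declarative cleavage-specificity rule grammar (Schechter-Berger P2-P2'
    positions with exceptions), matches released fragments and protein
    substrings against a catalogue of activity-annotated short peptides
    (ACE and DPP-IV inhibitors and other activities), and ranks enzymes by
    the number of bioactive peptides they release. Also provides peptide
    monoisotopic/average mass and m/z arithmetic for MS-based identification
    support, the standard hydrolysate assay computations (degree of
    hydrolysis, ACE and DPP-IV inhibition percentages, inhibition efficiency
    ratio, OPA standard-curve quantification), and seeded synthetic-data
    generators for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
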