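Package: hsp70ifr
Title: Indel-Free Regions and Allosteric Interdomain Contacts in Hsp70 Chaperones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking insertion/deletion (indel) patterns in protein
    multiple sequence alignments to allosteric interdomain interfaces in
    two-domain chaperones such as bacterial Hsp70 (DnaK). Implements indel
    calling and indel-free-region (IFR) detection with a single-sequence
    fusion rule, Wu-Kabat variability and conservation profiling, Kimura
    protein distances per subdomain, Calpha-Calpha distance-map differencing
    between open (ATP) and closed (ADP) conformations, threshold-based
    interdomain contact extraction, contact-to-alignment annotation with
    Welch-test enrichment summaries, and PCA plus kernel-density clustering
    of contact pairs. A seeded synthetic-data generator produces alignments
    with planted IFRs and two-conformation bead structures with planted
    contacts so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
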