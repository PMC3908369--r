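Package: swfscreen
Title: Screening and Verification Toolkit for swf-Type Mono-Modular PKS/FAS Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to re-run, end to end, the computational screen by which
    swf-type mono-modular type I polyketide synthase / fatty acid synthase
    (PKS/FAS) gene clusters are detected in sponge metagenomes and verified
    at the protein level. The package designs minimally degenerate primers
    from conserved acyltransferase protein motifs, performs in-silico PCR on
    contigs with IUPAC-aware mismatch and 3'-clamp rules, classifies
    translated amplicons into PKS families by ketosynthase/acyltransferase
    signature motifs, builds neighbour-joining trees with bootstrap support,
    outgroup rooting and support-cutoff condensation, and predicts isotope
    patterns and multiply charged ESI m/z values for acyl carrier protein
    proteoforms, including the phosphopantetheinylation (apo to holo) mass
    shift. A seeded synthetic-metagenome generator with ground-truth
    manifests makes every stage testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
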