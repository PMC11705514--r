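Package: modomap
Title: Mapping and Relative Quantification of tRNA Modifications by Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-silico ribonuclease digestion (RNase T1, cusativin) of
    modified RNA, monoisotopic mass and c/y fragment-ion calculation for
    oligonucleotides, spectrum matching and modification localization
    (e.g. mannosyl-queuosine at the wobble position of tyrosine tRNA),
    relative quantification of tRNA modifications from nucleoside
    extracted-ion-chromatogram peak areas across a blood-feeding time
    course, construction of mature and precursor tRNA reference sets from
    tRNAscan-SE predictions with TPM-based expression calls, and codon
    usage statistics (RSCU, Fisher codon-enrichment tests) for
    vitellogenin-class transcripts. Includes seeded synthetic-data
    generators so the full workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
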