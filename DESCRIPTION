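Package: cansine
Title: Can-SINE Insertion Dynamics, Subfamily Discovery and Dating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the dynamics of Carnivora-specific SINE
    (Can-SINE) retrotransposons from genome assemblies and RepeatMasker
    annotations: fragment-aware parsing of RepeatMasker output, genome-wide
    repeat summaries and divergence landscapes, flank-based presence/absence
    calling of insertions at orthologous loci across species, target site
    duplication (TSD) detection, discovery of element subfamilies from
    co-segregating diagnostic mutations, median-joining consensus networks,
    CpG-aware age estimation, and relative activity chronologies from nested
    (transposition-in-transposition) insertions. Includes a multi-species
    genome simulator that plants SINE insertions with recorded ground truth
    so every stage of the pipeline can be validated by truth recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    ape,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
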