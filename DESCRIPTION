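Package: cdzminer
Title: Mining Bacterial Genomes for Cdz-Like Contact-Dependent Bacteriocin
    Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Discovery of Cdz-like contact-dependent bacteriocin systems in
    bacterial genomes. Implements a type I secretion system (T1SS) anchored
    genomic-context search: candidate open reading frames (60-200 residues)
    are enumerated in windows flanking T1SS loci, scored with a profile
    hidden Markov model built from a seed alignment of glycine-zipper
    toxins, enriched by iterative (jackhmmer-style) search, and filtered
    with a rule-based classifier requiring an RTX-type secretion leader
    ending in G[G/A/S], one or two uninterrupted GxxxG glycine-zipper
    motifs, and a short charged or polar C-terminal tail. Companion modules
    provide the >=3-of-4 aggregation-propensity consensus combiner,
    co-culture competition statistics (CFU arithmetic, competitive index,
    reporter fold induction, propidium-iodide fractions), and a seeded
    synthetic-genome generator with planted clusters, single-violation
    decoys and ground-truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
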