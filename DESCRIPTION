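Package: crkscan
Title: Identification and Domain-Architecture Classification of
    Cysteine-Rich Receptor-Like Kinases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for genome-wide identification and classification
    of cysteine-rich receptor-like kinases (CRKs), the plant receptor
    family defined by the extracellular DUF26 (PF01657, Gnk2,
    Stress-antifungal) domain.  Reads protein FASTA, GFF3 gene models and
    precomputed domain-scan tables (Pfam-Scan and InterProScan dialects),
    filters DUF26-bearing candidates, resolves overlapping domain hits
    into one ordered architecture per protein, and assigns three class
    labels per gene: a run-collapsed major-class signature, a repeat-aware
    subclass signature, and a compact sd/dd/td/qd CRRSP/CRK nomenclature
    name generated by a small reversible grammar.  Also computes protein
    physicochemical statistics (length, molecular weight, charge,
    isoelectric point, GRAVY), chromosomal density, tandem gene clusters
    and terminal-arm localization, and cross-species class-by-species
    summary tables.  A synthetic-proteome generator with planted
    ground-truth architectures, clusters and scanner noise makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
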