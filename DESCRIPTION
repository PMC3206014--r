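Package: rrgenesis
Title: Recycled Regions: De Novo Enhancer Candidates After Whole Genome
    Duplication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery and characterisation of "recycled regions":
    ancestrally protein-coding sequences that lost their coding function
    after whole genome duplication and are retained because they acquired
    a de novo regulatory (enhancer) function.  Implements an
    exon-to-genome homology mapping step with hit fusion, a filtering
    funnel (ortholog presence, ortholog proximity, exon/EST overlap,
    synteny, developmental Gene Ontology, reading-frame disruption),
    cross-species evolutionary diagnostics (six-frame stop scans,
    nucleotide identity versus amino-acid similarity, Nei-Gojobori Ka/Ks
    with indel and stop-codon stripping), position weight matrix scanning
    with Fitch parsimony ancestral reconstruction for lineage-specific
    binding-site calls, binding-site density (S200) statistics, and a
    seeded synthetic-scenario generator that plants recycled regions and
    per-filter decoys for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
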