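Package: bcfitness
Title: Barcoded Deep Mutational Scanning Fitness Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for barcoded deep mutational scanning (DMS)
    growth-competition experiments. Builds barcode-to-allele lookup tables
    from paired-end subassembly reads, demultiplexes and counts barcodes
    with Hamming-distance error correction, converts count time courses
    into per-generation log2 selection coefficients relative to wild type,
    removes outlier barcodes with robust fences, aggregates scores into
    masked amino-acid fitness matrices with error estimates, and compares
    fitness landscapes across chemical conditions (difference maps,
    Lorentzian residual fits, shared and perturbation-specific mutation
    calls, position-bin transitions). A synthetic-data generator produces
    ground-truthed libraries, subassembly reads and competition counts so
    that every stage can be validated against known selection coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
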