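Package: oxmut
Title: Oxidation-Induced Mutagenesis Profiling Across Chromatin and Replication Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the genomic landscape of oxidative
    (8-oxoguanine-driven) mutagenesis: consensus filtering of multi-caller
    somatic variant calls, extraction of single-nucleotide 8-oxoG lesion
    positions from damage-capture sequencing alignments, SBS96 and ID83
    mutation spectrum construction and comparison (cosine similarity,
    differential spectra, non-negative least-squares signature refitting),
    chromatin-state density normalisation, trinucleotide-normalised
    observed/expected profiling around nucleosome dyads and transcription
    factor binding sites with Savitzky-Golay smoothing and least-squares
    periodogram periodicity estimation, and replication/transcription strand
    asymmetry statistics. Includes a fully seeded synthetic-data generator
    that plants known rotational/translational periodicities, strand biases,
    chromatin-state rate multipliers and caller error processes so every
    analysis can be validated against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    pracma,
    signal,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
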