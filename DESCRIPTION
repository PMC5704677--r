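Package: cagescape
Title: CAGE Promoter Landscapes: CTSS Quantification, Peak Calling,
    Cross-Species Projection and Annotation Rescue
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building promoter landscapes from CAGE (Cap Analysis
    of Gene Expression) data in species with incomplete gene annotation.
    Extracts single-base CAGE transcription start site (CTSS) profiles from
    alignments, calls promoter regions (tag clusters) with permissive and
    robust single-position thresholds, associates peaks with gene models,
    projects peaks between assemblies through UCSC chain files, and rescues
    un-annotated peaks via matched, annotated peaks of a well-characterised
    reference species and an orthology table ("Rescued CAGE Peaks").
    Includes TATA/CpG promoter architecture classification, TMM
    normalization, Spearman replicate QC, classical MDS sample clustering,
    and a seeded synthetic-data generator emulating a pair of related toy
    genomes so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
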