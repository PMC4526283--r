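Package: hmmasm
Title: Profile-HMM-Guided Gene-Targeted Assembly of Metagenomic Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Gene-targeted assembly of protein-coding genes directly from
    shotgun metagenomic reads.  A profile hidden Markov model of the target
    protein family steers an A* traversal of the de Bruijn graph built from
    the reads, so that assembly and annotation happen in one step.  Includes
    starting-kmer identification by six-frame peptide-kmer hashing against
    aligned references, a modified Yen's K-shortest-path search for
    microheterogeneity, and post-processing: length and HMM bit-score
    filtering, complete-linkage clustering at a fixed amino-acid identity,
    split-count kmer coverage, and single-copy-gene-normalised abundance
    estimation.  A synthetic-community generator provides planted-gene
    fixtures with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    parallel,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
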