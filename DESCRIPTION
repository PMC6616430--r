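Package: trnacode
Title: Primordial tRNA Models, Genetic Code Sectoring, and aaRS Homology
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for a tRNA- and anticodon-centric analysis of early
    translation evolution. Builds the primordial tRNA precursor from GCG,
    CGC and UAGCC repeats plus inverted-repeat stem-loop-stems, applies
    the internal 9-nucleotide deletions that yield type I and type II
    tRNA models, and scores modern tRNA sequences against the segmented
    primordial model. Represents the genetic code as a 32-cell
    codon-anticodon table under wobble purine/pyrimidine collapse,
    simulates the stepwise sectoring of the code from an all-glycine
    state to the standard code, and audits amino-acid displacements
    against the C>(U~G)>A anticodon preference scale. Builds homology
    networks, maximum-score spanning trees and best-hit digraphs from
    directed aminoacyl-tRNA synthetase (aaRS) score matrices, with
    permutation tests for genetic-code column coherence. A synthetic-data
    module generates mutated tRNAomes and planted-tree score matrices so
    every analysis stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
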