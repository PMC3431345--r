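Package: ppievol
Title: Structural Evolution of Protein-Protein Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of the structural evolution of heteromeric protein-protein
    interfaces. Detects interface residues and classifies them into core, support
    and rim sub-regions from burial indices; computes solvent-accessible surface
    areas and per-residue buried areas; types inter-chain contacts (atomic,
    charged, salt bridge, hydrogen bond, apolar); identifies apolar patches and
    anchor residues; scores contact conservation between pairs of homologous
    complexes (interologs) with a weighted Jaccard index; detects residues
    switching out of the interface, charge exchanges and charge-fate scenarios;
    and fits and applies logistic-regression predictors of residue switching-out
    and contact conservation from six sequence and geometric features. Includes a
    synthetic-structure generator that plants salt bridges, hydrogen bonds, apolar
    patches and anchor residues with known ground truth, plus bootstrap and
    rank-sum statistics for aggregate analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
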