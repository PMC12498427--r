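Package: glycomine
Title: Genome Mining and Spectral Dereplication of Oligosaccharide and
    Aminoglycoside Natural Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts oligosaccharide and aminoglycoside structures from
    biosynthetic gene cluster (BGC) gene content and identifies them in
    tandem mass spectrometry data. Gene classes are annotated with profile
    HMMs and grouped into fixed-width BGC windows; candidate monomer
    multisets are ranked with a probabilistic gene-presence model (with a
    Fisher's exact baseline); backbones are assembled combinatorially
    under reactive-group bond-formation rules; tailoring-enzyme
    modifications are applied by a SMILES graph-rewriting engine; and
    candidates are matched against MGF spectra with a simplified
    shared-peak scorer, a mass-shift-tolerant variable mode, and
    decoy-based empirical p-values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ChemmineOB,
    igraph,
    IRanges,
    jsonlite,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
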