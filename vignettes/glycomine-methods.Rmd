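---
title: "glycomine: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{glycomine: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

glycomine predicts the 2D structures of oligosaccharide and aminoglycoside
natural products from the gene content of their biosynthetic gene clusters
(BGCs), and identifies candidates in tandem mass spectrometry data. This
vignette explains the models, the tunable parameters, and the design
choices a user should understand before trusting the output.

## The biosynthesis logic the pipeline encodes

Saccharide natural products are built in three stages: sugar or
aminocyclitol monomers are synthesized from central metabolites by
BGC-encoded enzymes; glycosyltransferases condense the monomers into a
linear backbone through glycosidic, ether or amide linkages; and tailoring
enzymes (methyltransferases, aminotransferases, acetyltransferases,
oxidoreductases, ...) decorate the assembled backbone. Two complications
dominate: the monomer order in the chain is not read off the gene order in
the cluster, and several common monomers (glucose, mannose, glucosamine,
N-acetylglucosamine, xylose, ribose — the six "primary" monomers) come
from primary metabolism, so their biosynthesis genes are never in the BGC.
The pipeline therefore predicts *sets* of monomers probabilistically,
enumerates *all* chain orders and linkage choices, and defers the final
decision to a spectral match.

All chemistry is 2D and achiral: tandem mass spectra cannot distinguish
stereoisomers, so stereocenters are stripped on input and epimerizations
are identity operations. Glucose and mannose, for example, share one
molecular graph; they remain separate catalog records because they carry
different biological meaning, but their structures deduplicate.

## Knowledge base

Four TSV catalogs ship with the package (`inst/extdata/kb/`): 50 gene
classes, 26 monomers (6 primary + 20 secondary), 5 bond-formation rules in
3 families, and 49 postassembly-modification rules. The gene-class list
and the monomer/rule assignments were curated from the published
biosynthetic pathways of the classic aminoglycosides and oligosaccharides
(streptomycin, kanamycin, neomycin, butirosin, gentamicin, spectinomycin,
kasugamycin, fortimicin, avilamycin, acarbose/trestatin, and relatives).
Where the literature did not pin an assignment down, a chemically
plausible default was chosen and is marked by its description; the catalog
format is versioned, diffable TSV precisely so such entries can be
refined by hand.

Monomer records carry a SMILES string, a monoisotopic mass derived from
elemental composition, the required gene classes (empty for primary
monomers), and *reactive groups*: typed atom positions (hydroxyl, amine,
activated-anomeric, carboxyl, ketone; atom indices are 1-based in SMILES
atom-appearance order). The nucleotide-diphosphate activating group
(NDP/GDP/UDP/dTDP) that real glycosyl donors carry is modelled as the
anomeric hydroxyl oxygen flagged `activated-anomeric`; it leaves when the
glycosidic bond forms. This collapses four interchangeable activating
chemistries into one placeholder and makes every bond family a clean
condensation losing H2O, which keeps mass bookkeeping exact.

Modification rules are motif + program pairs: a substrate motif (SMILES
fragment) and an ordered command program over `add`, `remove`, `connect`,
`disconnect`, with stable 1-based atom indices (added atoms continue the
numbering). `connect i j k` sets the bond order between i and j to k.
Every rule stores its expected mass delta; on load each rule is replayed
against its own motif and rejected unless the product is valence-legal,
connected, and the observed mass change matches the stored delta within
1e-4 Da.

## BGC detection

Proteins are annotated against per-class profile HMMs with hmmsearch
(HMMER 3); the per-sequence e-value cutoff defaults to 1e-5 and one class
is kept per protein (best score). Because profile libraries are heavy and
external, a precomputed annotation TSV is accepted everywhere a live
search is, and is the default path in tests and examples. Every annotated
gene seeds a window of 10 kb up- and downstream; overlapping windows on a
contig are merged into one BGC region (merging keeps a multi-gene cassette
in one region; it is a configurable choice). Coordinates are 1-based
inclusive internally, with a 0-based half-open BED export. Genes outside
every region are dropped — the models below compensate for missed genes
rather than the detector chasing them.

## Monomer-set models

Let G = 50 gene classes and K = 6 primary monomers. A BGC is the binary
presence vector b; a molecule is the binary pair (g, m): g_i = 1 if class
i is required by the molecule's secondary monomers (a class shared by two
monomers counts once), m_j = 1 if primary monomer j is present.

The **baseline** scores a candidate set by the upper-tail Fisher's exact
probability of the overlap O between the M classes the set requires and
the N classes annotated in the region,

$$P=\sum_{i\ge O}\binom{M}{i}\binom{G-M}{N-i}\Big/\binom{G}{N},$$

computed as an explicit log-scale sum (and cross-checked against the
hypergeometric tail to 1e-12 in the tests). Classes that carry only
tailoring roles are excluded from N and G in this mode: the enrichment
question concerns biosynthesis genes.

The **probabilistic model** scores the full pattern:
P(g, m | b) = prod_i P(g_i | b_i) x prod_j P(m_j), with
P(g=1|b=1) = alpha, P(g=1|b=0) = beta, P(m=1) = gamma. alpha is the
probability that a gene found in the cluster is really used by the
product; beta the probability that a required gene was missed by
annotation or lies outside the cluster; gamma the marginal rate of a
primary monomer. The maximum-likelihood estimates from labelled
(molecule, BGC) pairs are the closed-form ratios alpha = a/(a+b),
beta = c/(c+d), gamma = e/(e+f) over the aggregated label counts. One
convention note: with these count definitions (c counts required-but-
absent classes) the likelihood is alpha^a (1-alpha)^b beta^c (1-beta)^d,
which fixes beta = P(g=1 | b=0); the degenerate case alpha = 1, beta = 0
then makes g coincide with b, as it should. `fit_monomer_model()` returns
a classed object with `print`, `summary`, `coef`, `logLik`, `predict` and
`simulate` methods; the packaged default training table is a curated
reconstruction of a 20-molecule aminoglycoside/oligosaccharide benchmark
mapped onto the catalog (on it, the fit is roughly alpha 0.74, beta 0.04,
gamma 0.18).

Candidate sets are all monomer multisets within limits: `max_monomers = 7`
(the largest benchmark molecule has seven monomers), `max_multiplicity =
3` (repeated glucose units occur in real oligosaccharides), `max_primary
= 2` (at most two primary monomers per set), `top_n = 500` ranked sets
kept. A secondary monomer is eligible once at least one of its required
classes is present; `relax = TRUE` admits the rest through the beta
penalty. Multiplicity does not change a set's score (the score depends
only on the union of required classes and the primary flags), so ties are
broken by the lexicographic monomer-id signature to keep rankings
byte-reproducible.

## Backbone assembly

For a ranked set, every distinct ordering of the multiset is considered;
at each junction every compatible (rule, donor group, acceptor group,
orientation) choice is enumerated, under reactive-group accounting: each
group instance is consumed at most once, so terminal monomers lose one
group and internal monomers two. Chemically, the donor's leaving oxygen is
excised and its carbon bonded to the acceptor heteroatom; the implicit-
hydrogen model rebalances hydrogens, so each junction loses exactly one
H2O and the emitted mass always equals the monomer-mass sum minus one
leaving group per bond (asserted for every candidate). Products are
deduplicated by canonical SMILES (OpenBabel canonicalization,
stereochemistry-free). Branching is not enumerated; the accounting layer
would permit a branching flag later. An optional `cyclize` flag attempts
one terminal-to-terminal closure, off by default because no closure rule
is part of the bond catalog. Because no order predictor exists, full order
enumeration with a per-set cap (default 5000) is used — an interpretation,
controlled by deduplication and the cap.

## Modification engine

Motif matching is subgraph embedding: igraph's LAD solver with element
domains, then a bond-order filter, then a hydrogen-availability filter — a
motif heteroatom drawn with an implicit hydrogen (the hydroxyl O in motif
`CO`) only matches structure atoms that still carry one, so ring and
ether oxygens are never mistaken for hydroxyls. Automorphic duplicate
embeddings collapse to one site signature (the sorted matched-atom set).

A rule is active when *all* of its enzyme classes are present (multi-
enzyme rules exist in the catalog). Whether tailoring reactions compose is
not knowable in general, so enumeration-with-caps semantics are used: the
backbone itself plus all products of applying active rules at matching
sites, composed up to `depth = 3` applications, deduplicated by canonical
SMILES, cap `max_candidates` (default 1000; 200 per backbone in the
pipeline). Application order is normalized (sorted rule id) and any site
where replay breaks valence, connectivity or the stored mass delta is
skipped, so output is independent of rule iteration order and every
mature candidate satisfies mass = backbone + sum of applied deltas.

## Spectral matching

The scorer is deliberately a simplified, fully specified stand-in for a
full fragmentation-graph engine; its scores are not comparable to
published integer scores of other tools. Theoretical spectra cut up to
`max_cuts = 2` bridge bonds — acyclic bonds with at least three heavy
atoms on each side, which approximates inter-monomer linkages without
needing assembly provenance — and emit every connected component's neutral
mass, the freed valences capped with one hydrogen per cut end (the
implicit-hydrogen recount does this automatically). Scoring is a greedy
one-to-one shared-peak count at `tol = 0.01` Da against adduct-adjusted
fragment m/z; intensity is ignored (an intensity-weighted mode exists
behind a flag of `score_match`'s peak table). Adducts default to [M+H]+,
[M-H]- and [M+NH3]- (the last because oligosaccharides are observed as
ammonia adducts in negative mode); precursor tolerance is 10 ppm.

The **variable** mode absorbs one wrong or missing monomer/modification:
for each bridge-cut side of the candidate (each 1-cut fragment's atom
set, plus the whole molecule), the fragments containing that side may be
shifted by a single global mass shift; candidate shifts are data-driven
(peak-minus-fragment differences within the bounds, smallest magnitude
preferred on ties), and shift 0 is always included so the variable score
dominates the standard score. Significance is an empirical p-value
against decoy theoretical spectra (fragment count preserved, masses
resampled uniformly over the observed range; decoys inherit the real
candidate's cut structure in variable mode): p = (1 + #{decoy >=
observed}) / (n_decoys + 1), 999 decoys and a reporting threshold of
1e-3 by default. These p-values are valid but conservative by
construction; a candidate whose spectrum has a single fragment (an
unfragmentable monomer) can never reach significance, which is the
correct behaviour for a precursor-only match.

## Synthetic data

The fixture generators produce exactly the statistical structure the
models assume: training pairs drawn from known (alpha, beta, gamma) with
b ~ Bernoulli(0.3) per class; toy genomes with implanted gene cassettes
(and hmmbuild-built toy profiles for the live-annotation path); spectra
from known structures with seeded dropout, sub-tolerance jitter (0.002
Da), uniform noise peaks kept two tolerances away from true peaks, and
optional global shifts. They deliberately do not emulate correlated gene
loss, homologous cross-matching between profiles, isotope envelopes,
chimeric spectra or intensity structure — so green tests demonstrate
correctness of the algorithms under the stated model, not performance on
real genomes or real LC-MS/MS runs. Generators are byte-reproducible for
a fixed (specification, seed).

Test and example problem sizes are chosen to keep the full suite in a few
minutes: enumeration oracles run on a 5-monomer toy alphabet, pipeline
fixtures use one implanted cassette with sets of at most two monomers,
and null-calibration uses 200 spectra at 199 decoys. The packaged
defaults (top 500 sets, 999 decoys, depth 3) are the intended analysis
settings.

## Known limitations

- Gene-class-to-monomer assignments are literature-curated defaults;
  a wrong assignment propagates to eligibility and ranking.
- Linkage regiochemistry is enumerated, not predicted; positional isomers
  collapse only when their 2D graphs coincide.
- The fragmentation model knows nothing about charge retention, neutral
  losses beyond bond cuts, or intensities.
- Tanimoto similarities use linear-path fingerprints (paths up to 7
  atoms); absolute values are fingerprint-dependent and only comparable
  within one configuration, which is why the choice is logged.
- Real BGC boundaries matter: genes outside the 10 kb windows are
  invisible to the models except through the beta parameter.
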