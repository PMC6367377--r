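---
title: "Methods: the nsLTP census pipeline, its models and its choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the nsLTP census pipeline, its models and its choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsltpscan)
```

## The scientific problem

Non-specific lipid transfer proteins (nsLTPs) are small secreted plant
proteins, 6.5–10.5 kDa, with a basic isoelectric point and a conserved
eight-cysteine motif (ECM)

    C - Xa - C - Xb - C C - Xc - C X C - Xd - C - Xe - C

whose four disulfide bonds stabilize the hydrophobic cavity where lipids
bind. Because the five inter-cysteine gap lengths (a, b, c, d, e) are
diagnostic of sub-family membership, a family census reduces to three
operations: find the motif, read off its spacing vector, and match the
vector against per-type gap sets. In tomato the family comprises 64
curated genes in six sub-families (types I, II, III, IV, X and XI), one
of which encodes the fruit allergen Sola l 3; this package re-implements
the full census plus the downstream gene-structure, expression and
biophysical analytics as reusable, tested functions.

## Motif detection

`find_ecm()` exploits a structural fact: since no gap of a valid motif
may contain a cysteine, any match must use eight *consecutive* cysteines
of the sequence. The scanner therefore slides an eight-cysteine window
along the cysteine positions and tests the skeleton (third and fourth
cysteine adjacent; fifth and sixth separated by exactly one non-cysteine
residue) and the per-gap bounds. This is exhaustive and linear in the
number of cysteines — the test suite checks it against a brute-force
enumeration over all eight-subsets of cysteine positions.

Two free choices had to be fixed:

* **Search bounds.** No bounds are canonical for manual motif checking.
  The default (`default_ecm_bounds()`) is the elementwise envelope of the
  six published tomato type ranges widened by ±2 residues:
  a ∈ [5,12], b ∈ [10,24], c ∈ [6,27], d ∈ [10,27], e ∈ [4,16]. This
  accepts every catalogued tomato motif with margin for novel variants
  while rejecting degenerate cysteine arrangements. Bounds are an
  explicit argument, never hidden state.
* **Tie-breaking.** If several windows satisfy the bounds, the leftmost
  start wins, then the smallest span — a deterministic rule mirroring a
  greedy N-to-C manual scan.

The ambiguity letter X is allowed in sequences but never matches a motif
cysteine: a conservative calling rule, since an X *might* be a cysteine
but cannot be proven to be one.

## Spacing-rule classification

`classify_spacings()` matches a spacing tuple against the published
tomato gap sets (`boutrot_rules()`), reproduced verbatim:

| type | a | b | c | d | e |
|------|------|-------------|----------|----------|--------|
| I | 9 | 12–14, 16 | 19 | 21–23 | 13, 14 |
| II | 7, 8 | 13, 14, 17 | 8 | 23 | 6 |
| III | 9 | 14, 16 | 9 | 12 | 6 |
| IV | 9 | 15 | 9 | 24 | 6, 7 |
| X | 9, 10 | 14, 17 | 19–21 | 20, 21 | 12, 13 |
| XI | 9 | 18–20, 22 | 13 | 24, 25 | 9 |

These sets are *almost* disjoint: exactly one tuple, (9, 14, 19, 21, 13),
satisfies both the type I and the type X row (it is the intersection
corner a=9, b=14, c=19, d=21, e=13). One catalogued tomato gene carries
that tuple and is assigned to type I in the reference table. The package
therefore resolves ambiguity by canonical type precedence
(I, II, III, IV, X, XI; first match wins), which reproduces the reference
assignments 64/64; callers who prefer a hard failure can pass
`on_ambiguous = "error"`. Tuples matching no row are labelled `"n.d."`.

An optional nearest-pattern mode (`mode = "nearest"`) assigns the type
minimizing the summed absolute gap deviation, capped by `max_deviation`
(default 3). It is off by default because the census classifies only
exact-fitting motifs; novelty handling should be a visible decision.

For the same reason the synthetic proteome generator redraws the single
ambiguous corner tuple when planting type X motifs, so planted-type
recovery is exact by construction rather than by luck.

The Edstam-scheme column of the reference table is stored verbatim but
never recomputed: its assignment rules (which involve GPI modification
and intron position) are not part of this package's scope, and a large
fraction of genes do not fit that scheme at all.

## Candidate curation

`curate()` applies the census filters in a fixed order: candidates
lacking an N-terminal signal peptide are removed, then candidates with a
chloroplast or mitochondrial transit peptide, then GPI-anchored
candidates are *set aside* (they remain in the output with a
disposition, because GPI-anchored nsLTPs are tabulated separately and
follow their own intron-position convention), then members of related
families (alpha-amylase/trypsin inhibitors, proline-rich, hybrid
proline-rich, glycine-rich proteins). Dispositions are mutually
exclusive and exhaustive, so the ledger always satisfies
`n_input = n_retained + removals + set_asides`. The package performs no
signal-peptide, transit-peptide or GPI *prediction* — those are upstream
tools whose outputs arrive as annotation columns.

The default synthetic scenario mirrors the census arithmetic: 107
candidates, of which 4 lack the signal peptide, 3 + 1 carry transit
peptides, 23 are GPI-anchored and 64 are clean; the remaining 12 family
outliers are *derived* by subtraction (that count is never stated
directly in published summaries and is labelled accordingly).

## Gene structure

Coordinates are GFF3-native (1-based, inclusive) throughout; CDS
segments are stored in transcript orientation, so all intron arithmetic
is strand-agnostic after construction.

* **Intron position.** The reported quantity is the distance from the
  last ECM cysteine to the intron: precisely, the junction's CDS offset
  minus the CDS position of the *final nucleotide of the eighth
  cysteine's codon*, downstream positive, so 0 means the junction sits
  immediately at that codon boundary. This convention reproduces the
  catalogued values (5 nt downstream for intron-bearing type I genes,
  4 nt for GPI-anchored genes, 10 nt for the one type I exception)
  coherently on both strands.
* **Intron phase** is the junction CDS offset modulo 3.
* **Chromosome census** covers the full 12-chromosome karyotype
  including zero-count chromosomes. On the shipped reference table the
  occupied-chromosome count is 8 (chromosomes 1, 2, 3, 6, 8, 9, 10, 12,
  with maxima of 15 genes on chromosomes 3 and 8 and a single gene on
  chromosome 12) — this is the count the table's own gene identifiers
  force.
* **Tandem clusters.** `detect_clusters()` groups genes into maximal
  runs where consecutive same-chromosome genes lie within `max_gap`
  start-to-start; runs of ≥ 3 are clusters, runs of 2 pairs. The default
  gap of 200 kb was chosen once so that the catalogued multi-gene
  clusters (which span up to ~300 kb with inter-gene gaps below 200 kb)
  cohere as single runs, while "pairs" (a few kb apart) stay distinct
  groups; with it, 70% of the reference genes sit in groups of ≥ 2.
  Whether runs must be type-homogeneous is exposed as
  `same_type_required` (default `FALSE`, a declared choice — published
  cluster figures do not state the rule). Output is order-invariant, and
  widening the gap can only grow the grouped fraction (tested).

## Expression summaries

Distances between expression profiles use one minus the Spearman rank
correlation (average ranks on ties), the metric under which the
published tissue heatmap was clustered; `hierarchical_cluster()` feeds
it to average-linkage agglomeration (the linkage of the original
heatmap tool is unstated; average linkage is the declared default,
configurable). Zero-variance profiles, for which rank correlation is
undefined, are excluded with a warning rather than silently assigned a
distance.

"Expressed" means RPKM at least the threshold *and strictly positive*;
the default threshold of 1 RPKM is a declared choice (no threshold is
canonical) and is echoed in all outputs. With this convention a
threshold of 0 degrades gracefully to "any positive signal".
`tissue_specific_genes()` returns genes expressed in exactly one tissue;
`fruit_expressed_genes()` returns genes expressed in *every* listed
ripening stage (mature green, breaker, red ripe). Both filters are
monotone in the threshold.

Relative quantification follows the comparative-CT identity
RQ = 2^−ΔΔCT with ΔΔCT = (CT_target − CT_reference) −
(CT_target − CT_reference)_calibrator, so RQ = 1 at the calibrator and
log2 RQ = −ΔΔCT exactly.

## Protein physicochemistry

Average residue masses are carried to two decimal places with water at
18.02 Da, the resolution at which deconvoluted ESI-TOF masses are
compared; monoisotopic masses sit behind a flag. Disulfide formation
subtracts exactly 2 × 1.00794 Da per bond — with four bonds this bridges
a reduced chain of 10278.05 Da to 10269.99 Da, within 0.05 Da of the
observed oxidized peak of the recombinant tomato allergen the package's
mass arithmetic was validated against. Loss of the initiator methionine
subtracts the Met residue mass, 131.20 Da.

The isoelectric point bisects the Henderson–Hasselbalch net-charge
function on pH 0–14 using the EMBOSS pKa set (N-terminus 8.6,
C-terminus 3.6; K 10.8, R 12.5, H 6.5; D 3.9, E 4.1, C 8.5, Y 10.1),
fixed and documented rather than configurable: the original census used
a web calculator whose constants are unpublished, so the package commits
to one published set. Net charge is monotone in pH, so bisection to a
10^-6 pH interval leaves |charge| < 10^-3 for any ordinary sequence.

## Ligand-binding biophysics

Titration curves of relative fluorescence (F − F0)/F0 against ligand
concentration are fitted with the Hill equation
y = A·x^n / (K_D^n + x^n) by Levenberg–Marquardt least squares
(`minpack.lm`), with deterministic initialization — A at the maximal
response, K_D at the half-maximal concentration by linear interpolation,
n = 1 — relative tolerance 10^-8 and at most 500 iterations. The Hill
coefficient is *fitted* by default (fitting reports what the data say);
`fix_n = TRUE` gives the classic one-site binding interpretation. The
fit is scale-equivariant in concentration units and recovers noiseless
generator parameters to numerical precision for n ∈ {0.5, 1, 2}
(tested).

CD signals convert to mean residue ellipticity as
θ(mdeg) / (10 · c(M) · l(cm) · N_residues), and thermal reversibility is
scored as the ratio of the helix-diagnostic θ222 signal after a
heat/cool cycle to its native value (1.0 = complete recovery). Blank
subtraction and the averaging of emission intensities around the peak
are treated as preprocessing of the input table, not modelled.
Secondary-structure deconvolution of CD spectra is out of scope.

## The synthetic-data generators

Every pipeline input can be generated with known ground truth
(`gen_proteome()`, `gen_gff3()`, `gen_expression()`, `gen_titration()`,
`gen_candidate_set()`). A single integer seed is threaded through
documented substreams, one per generated entity, so regeneration under a
seed is byte-identical and adding entities never perturbs earlier ones
(both tested).

Design of the emulation, and what it does *not* capture:

* Planted proteins draw gaps uniformly from the target type's gap sets
  (minus the one I/X-ambiguous corner), carry a cysteine-free signal
  region of 20–29 residues — the catalogued signal peptides run 20–35 —
  and cysteine-free flanks, so the planted motif is provably the only
  one. Background composition is uniform over the 19 non-cysteine
  letters; real proteomes have biased composition and decoy cysteine
  clusters, so perfect recovery here bounds scanner correctness, not
  real-proteome specificity. Decoys carry at most 7 cysteines.
* Synthetic gene models realize requested intron offsets from the last
  ECM cysteine on either strand, with intron lengths drawn from
  100–500 nt and a stop codon included in the CDS; offsets needing more
  than a 60-residue C-terminal tail are rejected as infeasible.
* Expression matrices plant single-tissue and all-ripening-stage
  patterns at 10 RPKM over a log-normal background centred at 0.05 RPKM
  (multiplicative noise, default sd 0.2 on the log scale) — an effect
  size of 10× the default call threshold, mirroring the published counts
  of 13 tissue-specific and 5 fruit-expressed genes. Real RNA-seq has
  count noise, length biases and correlated tissues; none are modelled.
* Titrations use 12 points log-spaced over two decades up to 500 µM
  around a default K_D of 85.5 µM with 2% multiplicative noise,
  emulating the reported binding assay of the tomato allergen; the
  Monte-Carlo suite (200 seeded replicates) checks that the median
  fitted K_D stays within the ±6 µM uncertainty reported for that
  assay.

## Problem sizes and numerical choices

The shipped reference census (64 genes) drives all fixture-based checks
and runs in well under a second. Simulation-based checks use 60–72
planted proteins, 64-gene expression matrices and 200 Monte-Carlo
titration fits — sizes chosen so each property is exercised with
comfortable statistical margin while the whole suite stays quick on a
single core. Tolerances: noiseless fit recovery at 10^-6 relative;
mass arithmetic at the 0.01 Da table resolution; pI to |charge| < 10^-3.
Degenerate inputs fail loudly (constant profiles, all-zero responses,
empty FASTA, missing annotation columns) rather than returning
placeholder values.

## Known limitations

* The classifier encodes the tomato gap sets only; other species have
  additional types (V–IX) that would need their own rule rows.
* The spacing rules are exact set-membership tests; nearest-pattern mode
  is a pragmatic aid, not a statistical model of motif evolution.
* No profile-HMM scoring, no alignment, no tree inference: candidate
  discovery upstream of curation is out of scope, as are the web-tool
  predictions consumed as annotation columns.
* `isoelectric_point()` ignores local electrostatic environment;
  published web calculators using different pKa sets will differ by a
  few tenths of a pH unit.
* The GFF3 reader covers gene/mRNA/CDS hierarchies; exotic features
  (trans-splicing, multi-parent CDS) are not supported.

```{r example}
# the worked example: census of the shipped reference table
t1 <- load_table1_fixture()
types <- apply(fixture_spacings(t1), 1, classify_spacings)
census_by_type(types)
family_length_stats(t1$full_length)[c("mean", "min", "max")]
```
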