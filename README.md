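# nsltpscan

Census and characterization of the tomato non-specific lipid transfer
protein (nsLTP) gene family — and a general toolkit for the same
analysis in any plant proteome.

nsLTPs are small secreted plant proteins (6.5–10.5 kDa, basic pI) built
around the eight-cysteine motif (ECM)

    C-Xa-C-Xb-CC-Xc-CXC-Xd-C-Xe-C

whose four disulfide bonds enclose a hydrophobic lipid-binding cavity.
The five inter-cysteine gap lengths `(a, b, c, d, e)` are diagnostic of
sub-family membership, and several nsLTPs — including the tomato fruit
allergen Sola l 3 — are major food allergens, which is why the family
census matters. `nsltpscan` is aimed at researchers curating such gene
families: it provides

* **ECM detection** (`find_ecm`): an exhaustive eight-cysteine window
  scan with explicit per-gap bounds, deterministic tie-breaking, and
  canonical descriptor strings (`C-X9-C-X13-CC-X19-CXC-X22-C-X13-C`);
* **spacing-rule classification** (`classify_spacings`,
  `boutrot_rules`): exact set-membership typing into tomato sub-families
  I, II, III, IV, X, XI, with explicit handling of the one ambiguous
  corner tuple shared by the type I and X rules;
* **candidate curation** (`curate`): the signal-peptide / transit-peptide
  / GPI-anchor / family-outlier filter ledger, with mutually exclusive
  dispositions;
* **gene structure** (`read_gff3`, `intron_offset_from_ecm`,
  `intron_phase`, `chromosome_census`, `detect_clusters`): exon counts,
  intron position in nucleotides downstream of the last ECM cysteine,
  intron phases, chromosome occupancy and tandem-cluster detection;
* **expression summaries** (`spearman_distance`,
  `hierarchical_cluster`, `tissue_specific_genes`,
  `fruit_expressed_genes`, `relative_quantity`): one-minus-Spearman
  clustering, tissue-specificity and ripening-stage filters, and
  comparative-CT quantification (RQ = 2^−ΔΔCT);
* **protein physicochemistry and biophysics** (`average_mass`,
  `disulfide_adjusted_mass`, `met_loss_mass`, `isoelectric_point`,
  `fit_hill`, `mre_convert`, `thermal_recovery`): ESI-TOF mass
  arithmetic, Henderson–Hasselbalch pI, Hill-equation fits of
  fluorescence titrations and CD conversions;
* **seeded synthetic-data generators** (`gen_proteome`, `gen_gff3`,
  `gen_expression`, `gen_titration`, `gen_candidate_set`): every input
  the pipeline consumes, with known ground truth and byte-identical
  regeneration under a fixed seed.

The package ships a curated 64-gene tomato nsLTP reference table
(`load_table1_fixture()`; `inst/extdata/table1_nsltp.tsv`, documented
column by column in the function help) that anchors all census-level
checks.

## Worked example

```r
library(nsltpscan)

# --- the family census from the shipped reference table -----------------
t1 <- load_table1_fixture()
types <- apply(fixture_spacings(t1), 1, classify_spacings)
census_by_type(types)
#>    I   II  III   IV    X   XI n.d.
#>   24    6    2    3    6   23    0

# --- scan a synthetic protein with a planted motif ----------------------
p <- gen_proteome(c(I = 1L), seed = 99)
find_ecm(p$proteins$sequence[1], protein_id = p$proteins$id[1])
#> <ecm_match> SYNT_I_001  [25-112]  C-X9-C-X14-CC-X19-CXC-X23-C-X14-C

# --- disulfide mass arithmetic ------------------------------------------
disulfide_adjusted_mass(10278.05, 4)   # reduced mass, 4 S-S bonds
#> [1] 10269.99

# --- fit a noisy titration curve ----------------------------------------
tt <- gen_titration(K_D = 85.5, noise_sd = 0.02, seed = 11)
fit_hill(tt$curve$concentration_uM, tt$curve$rel_fluorescence)
#> <hill_fit> K_D = 78.42, n = 1.02, A = 0.9543 (residual norm 0.0208)

# --- tandem clusters on the reference coordinates -----------------------
cl <- detect_clusters(data.frame(gene_id = t1$gene_id,
                                 chromosome = t1$chromosome,
                                 start = t1$start))
cl
#> <cluster_set> 7 cluster(s), 4 pair(s), 19 singleton(s) (max_gap = 200000 bp)
grouped_fraction(cl)
#> [1] 0.703125

# --- comparative-CT quantification --------------------------------------
relative_quantity(25, 20, 28, 20)      # ddCT = -3
#> [1] 8
```

Reading the numbers: the 64 reference motifs classify into the six
sub-families with types I and XI dominating (24 and 23 members); a
reduced chain of 10278.05 Da forming four disulfide bonds loses eight
hydrogens and lands at 10269.99 Da; a 2%-noise titration generated at
K_D = 85.5 µM fits back within the assay's reported uncertainty; and at
the default 200 kb gap, 70% of the reference genes sit in 7 clusters and
4 pairs along the chromosomes.

A command-line wrapper over the same functions is installed at
`inst/scripts/nsltp` (`nsltp scan`, `nsltp census`, `nsltp ddct`,
`nsltp fit-binding`).

## Package layout

```
R/                   implementation (motif, classify, curate, structure,
                     expression, biophysics, generators, pipeline)
inst/extdata/        table1_nsltp.tsv — the 64-gene reference table
inst/scripts/nsltp   thin CLI wrapper
tests/testthat/      unit, property and acceptance suites
vignettes/           methods vignette: models, conventions, design choices
scripts/acceptance.R headline-quantity recomputation
```
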