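# pepcleft

Charge-interaction analysis of HLA class I immunopeptidomes.

HLA class I (HLA-I) molecules present 8–13-mer peptides to CD8+ T cells.
Binding is dominated by anchor residues at peptide position 2 (B pocket) and
the C-terminus, pΩ (F pocket), but eluted-ligand repertoires also show a
marked enrichment of acidic residues (D/E) at peptide position 4, driven by
salt bridges with basic residues R65/K66 on the α1 helix of the binding
cleft, and a reciprocal dependence of basic p1 residues (K/R) on the cleft
configuration at positions 62/66/163. `pepcleft` provides the full toolchain
for quantifying these effects:

- **QC and repertoire handling** — Mascot ion-score / source-gene TPM /
  length filtering (inclusive thresholds, score ≥ 25, TPM ≥ 0.3, 8–13-mers),
  deduplication, background compositions from proteome FASTA, HLA allele
  sequences under mature-protein numbering (signal-peptide offset 24 for
  HLA-A) and binding-cleft residue extraction.
- **Positional statistics** — dual-end position labels (p1…p5 from the
  N-terminus, pΩ…pΩ−3 from the C-terminus), position × residue frequency
  matrices, residue-class proportions (D/E4, K/R1), wild-type-vs-mutant
  frequency-difference matrices, and the test family used for repertoire
  comparisons: two-proportion Z without continuity correction
  (z² = χ² of the 2×2 table), Welch's t, Brown–Forsythe unequal-variance
  ANOVA, and Dunnett's T3 via the studentized maximum modulus distribution.
- **Motifs** — pseudocount-regularized PWMs, Kullback–Leibler sequence-logo
  matrices (letter heights p·log2(p/q) in bits), and margin-based motif
  assignment of eluted peptides to allotypes.
- **Co-occurrence** — K/R1 × D/E4 contingency tables, odds ratios with Wald
  intervals, and cross-allotype Pearson/Spearman correlation of class
  frequencies.
- **Allotype catalog** — grouping of allotypes by basic-residue count at
  cleft positions 65/66 or by the p62/p66/p163 configuration, with grouped
  class-frequency comparisons (allotypes as replicates).
- **Structure contacts** — PDB reading (multi-model ensembles, altloc
  policy), salt-bridge / hydrogen-bond / π-cation / π-stacking detection
  with configurable geometric criteria, contact prevalence across
  conformations, coulombic pair energies
  (E = k/ε · Σ qᵢqⱼ/rᵢⱼ, k = 332.0636 kcal·Å/mol·e²), Kabsch superposition,
  per-residue RMSD, and minimum-distance metrics.
- **Synthetic data** — generators for repertoires (anchored motifs, tunable
  D/E4 and K/R1 frequencies, p1–p4 coupling by odds ratio), WT/mutant pairs
  with planted shifts, grouped allotype panels, and coordinate ensembles
  with planted contacts — every analysis stage is testable offline with
  known ground truth.

## Worked example

Simulate a wild-type repertoire and a cleft double-mutant-like repertoire
(planted: D/E4 down 10 percentage points, K/R1 up 45 points, 70% repertoire
contraction), then quantify the motif change:

```r
library(pepcleft)

base <- repertoire_spec(n = 5000, seed = 42)   # WT world: D/E4 = K/R1 = 0.25
pair <- generate_wt_mutant_pair(base,
                                shifts = c(p4_DE = -0.10, p1_KR = 0.45),
                                size_ratio = 0.3)
length(pair$wt); length(pair$mut)
#> [1] 5000
#> [1] 1500

class_frequency(pair$wt,  "p4", class_DE())$proportion   # 0.250
class_frequency(pair$mut, "p4", class_DE())$proportion   # 0.162
class_frequency(pair$wt,  "p1", class_KR())$proportion   # 0.255
class_frequency(pair$mut, "p1", class_KR())$proportion   # 0.689

de_wt  <- class_frequency(pair$wt,  "p4", class_DE())
de_mut <- class_frequency(pair$mut, "p4", class_DE())
two_proportion_z(de_mut$x, de_mut$n, de_wt$x, de_wt$n)
#> <pc_test> two-proportion Z: statistic = -7.07745, p = 1.46827e-12
```

The mutant repertoire lost acidic-p4 ligands (16.2% vs 25.0%, highly
significant by the two-proportion Z test) and gained basic-p1 ligands
(68.9% vs 25.5%) — the planted motif shift, recovered. The per-position
information content of the wild-type motif shows the expected anchor
structure (values in bits):

```r
round(kl_logo(frequency_matrix(pair$wt))$position_ic, 3)
#>       p1       p2       p3       p4       p5   pOmega pOmega-1 pOmega-2 pOmega-3
#>    0.113    1.719    0.002    0.100    0.003    1.781    0.003    0.003    0.001
```

p2 and pΩ carry ~1.7 bits each (the primary anchors); p1 and p4 carry the
small but real class enrichments.

The pipeline is also scriptable end to end:

```sh
Rscript -e 'pepcleft::pepcleft_cli()' full --config run.json --out out/ --seed 1
```

with subcommands `qc`, `stats`, `logo`, `cooccur`, `group`, `contacts`,
`simulate`, `full`; reruns on identical config + seed are byte-identical.

## Vignette

See `vignettes/charge-interactions.Rmd` for the model, parameter defaults
and their rationale, what the synthetic generators do and do not emulate,
and numerical/design choices.
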