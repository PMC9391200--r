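---
title: "Charge interactions in HLA class I immunopeptidomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge interactions in HLA class I immunopeptidomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepcleft)
```

## The scientific problem

HLA class I molecules sample 8–13-mer peptides from cytosolic proteins and
display them for CD8+ T-cell surveillance. The canonical binding model is
end-anchored: peptide position 2 docks into the B pocket and the C-terminal
residue (pΩ) into the F pocket. Beyond these anchors, eluted-ligand
repertoires show a reproducible *secondary* signal: acidic residues
(aspartate/glutamate) are enriched at peptide position 4, where they can
form salt bridges with basic cleft residues — arginine 65 and lysine 66 of
the α1 helix (mature-protein numbering). Removing those basic residues
shrinks the presented repertoire, depletes D/E4 ligands, and reshapes the
motif, including a striking reciprocal effect: allotypes whose cleft lacks
basic residues near the peptide N-terminus (positions 62, 66, 163) strongly
favour basic residues (K/R) at peptide position 1, and K/R1 co-occurs with
D/E4 within peptides, consistent with an intrapeptide salt bridge.

`pepcleft` implements the quantitative machinery for this analysis as a
reusable, fully tested pipeline, with a synthetic-data layer standing in
for the mass-spectrometry and molecular-dynamics inputs that cannot ship
with a package.

## Repertoires and quality control

A *repertoire* is a deduplicated set of peptide sequences for one
allotype/variant; all frequency statistics are per-repertoire. QC follows
standard immunopeptidomics practice: Mascot ion score, source-gene
expression (TPM from RNA-seq cross-referencing), and a length window.

Defaults and rationale:

| parameter | default | units | why |
|---|---|---|---|
| `min_ion_score` | 25 | Mascot score | the conventional identity threshold; *inclusive* — "minimum score" is read as pass-at-minimum |
| `min_tpm` | 0.3 | transcripts/million | source-gene expression validation; inclusive |
| `length_range` | 8–13 | residues | the HLA-I ligand length window |
| `max_delta_mass_ppm` | Inf | ppm | delta mass is a recognized QC axis but no published cutoff exists; off by default, configurable |

Records missing an optional field pass that check by default (`require_*`
flags tighten this), because QC pipelines apply multiple orthogonal filters
and silently dropping records with absent metadata would bias repertoire
sizes. Deduplication is by exact sequence within one repertoire; the same
sequence may legitimately appear in different repertoires.

Allele sequences are handled under mature-protein numbering. The
signal-peptide offset is a parameter (default 24, correct for HLA-A heavy
chains) because cleft positions such as 65/66 are always cited in mature
coordinates. The bundled FASTA
(`inst/extdata/hla_alleles_synthetic.fasta`) is a *synthetic stand-in*: it
is exact at the documented analysis positions (the 57–73 α1 segment and
position 163) and scaffold elsewhere; tests only ever assert the documented
positions.

## Dual-end positional statistics

Peptides of different lengths are aligned from both ends: labels p1…p5
index from the N-terminus, pΩ…pΩ−3 from the C-terminus. For 8-mers, p5 and
pΩ−3 resolve to the same residue; labels are *views*, not a partition, so
that residue is counted under each label (and never double-counted within
one label). Every peptide contributes exactly one residue to every label,
so the per-label denominator is the repertoire size.

Class frequencies (D/E at p4; K/R at p1) are binomial proportions x/n.
Motif change between a variant and a reference is the elementwise frequency
difference; per-label rows of the difference sum to zero by construction,
which the pipeline asserts on serialization.

The test family mirrors standard immunopeptidome comparisons:

- **Two-proportion Z, no continuity correction** for per-cell frequency
  comparisons. The pooled-variance statistic satisfies z² = χ² of the 2×2
  table without Yates correction, which the tests verify against
  `prop.test` on random tables to 1e-10. Degenerate pools (p̂ ∈ {0, 1})
  return a flagged p = 1 rather than raising, so sparse synthetic runs
  complete.
- **Welch's t** with Welch–Satterthwaite degrees of freedom for two-mean
  comparisons.
- **Brown–Forsythe ANOVA** for multiple means under unequal variances.
  This name is overloaded: the 1974 Brown & Forsythe paper gives both a
  variance test (ANOVA on absolute deviations from medians) and an
  unequal-variance ANOVA on means (F\*). Since it is used here for
  "comparisons of multiple means with unequal variances", the F\* form is
  implemented: F\* = Σ nᵢ(x̄ᵢ − x̄)² / Σ (1 − nᵢ/N)sᵢ², with a
  Satterthwaite denominator df.
- **Dunnett's T3** for pairwise follow-up: each pair's Welch statistic is
  referred to the studentized maximum modulus (SMM) distribution with
  m = number of pairs and the pair's Welch df. The SMM CDF is computed by
  numerical integration over the scaled-chi mixing density
  (`stats::integrate`, absolute tolerance 1e-10, well inside the 1e-6
  documentation target); a seeded Monte-Carlo implementation (`psmm_mc`)
  agrees within 0.005 and serves as the validation fallback. Adjusted p
  values are clamped to be no smaller than the unadjusted Welch p.

Two-sided tests throughout; no multiplicity correction is applied to the
20-residue × position heat-map Z tests (stars are per-cell), T3 being the
only adjusted procedure.

## Motifs: PWMs, KL logos, assignment

PWMs are log2-odds of pseudocount-regularized frequencies over a
background composition: log2((count + α·q)/(n + α)/q) with total
pseudocount α = 1 distributed by background — enough to keep sparse mutant
matrices finite without washing out real signal.

The logo matrix is the Kullback–Leibler (PSSM-style) form: letter score
p·log2(p/q) in bits with 0·log 0 = 0, per-position information content the
sum over residues (always ≥ 0; negative letter scores mark depleted
residues and are retained for below-axis rendering). Logo tools offer
several weighting schemes; this package deliberately implements the plain
KL logo *without* sequence weighting or Hobohm clustering — a documented
divergence, acceptable because repertoires here are deduplicated sets.

Allotype assignment scores each peptide against every PWM (sum of per-label
log-odds) and assigns the argmax only when the best-minus-second margin is
at least `min_margin` bits (default 1). Ties and sub-margin peptides are
reported unassigned, never force-assigned, because real elutions contain
ligands of co-expressed endogenous allotypes that no transduced-allele
motif should claim.

## Co-occurrence and coupling

The K/R1 × D/E4 association within a repertoire is summarized by the 2×2
contingency table, the odds ratio (Haldane–Anscombe 0.5 correction on zero
cells, flagged), a Wald 95% CI on the log OR, and a p value from the same
two-proportion Z used everywhere else, applied to P(D/E4 | K/R1) vs
P(D/E4 | not K/R1) — one statistic family across the package, by design.
Cross-allotype correlation treats each allotype's (K/R1, D/E4) frequency
pair as one equally weighted point (repertoire-size weighting is exposed
but off by default, since allotype repertoire sizes vary by orders of
magnitude for technical reasons).

## Allotype grouping

Allotypes are grouped either by the number of basic residues at cleft
positions 65/66 (0, 1, or 2; histidine is *not* counted basic — the charge
argument concerns R/K specifically and His protonation is
context-dependent) or by the p62/p66/p163 configuration key
(`"62X/66Y/163Z"` plus has_R62/has_K66/has_R163 flags). Group comparisons
treat allotypes, not peptides, as replicates, matching analyses where each
point is an allotype; the omnibus is Brown–Forsythe, follow-up is T3.

## Structure contacts

Conformations are atom tables (chain, residue, insertion code, residue
name, atom, element, xyz); multi-model PDB files map models to ensemble
frames sharing one topology. Altloc resolution keeps the highest occupancy
(ties by label order); waters and heteroatoms are excluded by default.

Interaction criteria are configurable and recorded in output provenance;
the defaults follow common structural-biology practice because the
published contact analyses used an external tool without printed
thresholds:

| contact | criterion | default |
|---|---|---|
| salt bridge | Arg NH1/NH2/NE or Lys NZ — Asp OD1/OD2 or Glu OE1/OE2 | ≤ 4.0 Å |
| hydrogen bond | donor–acceptor heavy atoms (+ D–H…A ≥ 120° only when an explicit H exists) | ≤ 3.5 Å |
| π-cation | Lys NZ or Arg guanidinium centroid — Phe/Tyr/Trp ring centroid | ≤ 6.0 Å |
| π-stacking | ring centroid — ring centroid | ≤ 5.5 Å |

Histidine is neutral by default (`his_charged` enables imidazolium
participation). Contact prevalence across an ensemble is the fraction of
frames in which at least one qualifying atom pair exists for a
(kind, residue pair) identity — the quantity that alluvial-plot line widths
encode.

Coulombic pair energies use E = k/ε · Σ qᵢqⱼ/rᵢⱼ with
k = 332.0636 kcal·Å/(mol·e²) and ε = 1 by default (vacuum-style pairwise
decomposition, as trajectory post-analysis tools report). The default
charge set places unit formal charges on one representative atom per
charged group (Arg CZ, Lys NZ, Asp CG, Glu CD); full per-atom force-field
tables belong to the out-of-scope MD layer but can be supplied, with a
configurable skip/error policy for uncovered atoms. Numeric agreement with
published MD energy panels is *not* an acceptance surface — those came
from force-field charges over full trajectories.

Superposition is the closed-form Kabsch least-squares fit with the proper
rotation (det = +1) correction, validated against an independent
quaternion-method oracle to 1e-8 Å. Per-residue RMSD superposes each frame
on a fit selection (e.g. cleft backbone), then measures the target residue
without refitting — the side-chain mobility measure used to compare
variants.

## The synthetic world

The generators encode the stated experimental world, not tunable dials:

- Background composition: D + E = 0.117 (D 0.055 / E 0.062), the vertebrate
  proteome acidic-residue background; the other 18 residues carry
  proteome-like proportions rescaled to fill the remaining mass.
- Length distribution: 9-mer dominant (0.55), tails to 13, as in eluted
  ligand data.
- Anchor preferences: A2-like (L2, L/VΩ) and A24-like (Y2, FΩ) motif
  presets with disjoint dominant anchors.
- Class frequencies: D/E4 default 0.25 (the elevated HLA-A level; the
  survey range 0.117–0.42 appears throughout the tests), K/R1 default 0.25
  (wild-type A2 level).
- WT→mutant defaults: D/E4 −0.10, K/R1 +0.45 (25% → 70%), size ratio 0.3
  (the >70% repertoire contraction of the double mutant).
- Coupling: the (K/R1, D/E4) indicator pair is drawn from the exact 2×2
  joint distribution with requested margins and odds ratio (closed-form
  quadratic solve; infeasible combinations error).
- Ensembles: planted contacts satisfy their criteria with ≥ 0.2 Å margin,
  decoy atoms of *participating* types sit on a 10 Å grid (no accidental
  contact possible), absent-frame partners are displaced 500 Å, and
  Gaussian jitter up to ~0.05 Å cannot flip a contact given the margins.

What the generators do **not** emulate: proteasomal cleavage and TAP
transport biases, MS intensity/noise and acquisition artifacts, shared
peptides between allotypes, length-dependent motif changes, and real
conformational dynamics. A green test therefore establishes that the
*estimators recover planted truth under the stated sampling model* — not
that biological repertoires satisfy the model.

Every generator is a pure function of (spec, seed): reruns are
byte-identical, and each generated dataset carries a truth record.

## Numerical and degenerate-input choices

- Peptide positions are 1-based in labels; internal indices 0-based
  half-open; conversion centralized in `resolve_position`.
- Empty repertoires yield flagged NaN frequencies, not exceptions;
  degenerate tests (zero-variance, saturated pools) return flagged results
  with p ∈ {0, 1} so pipeline runs on sparse data complete.
- TSV reports serialize at 6 significant digits (diff-stable); JSON keeps
  full precision. The manifest's config hash excludes the output directory
  and log level, because results are pure functions of inputs + config +
  seed, not of where they are written or what is logged.
- Repertoire deduplication resamples until exactly n unique peptides exist
  (cap 100·n draws, then error) so that "unique peptides" accounting is
  exact.
- Assignment tie-break: exact ties are unassigned, deterministically.

## Known limitations

- Single-pass PWM scoring only; no mixture-model (EM) deconvolution of
  multi-allelic elutions.
- The hydrogen-bond detector is heavy-atom based unless explicit hydrogens
  are present; protonation states are not predicted.
- Trajectory formats beyond multi-model PDB are out of scope.
- The Brown–Forsythe/T3 machinery assumes approximately normal group
  values; per-allotype class frequencies at realistic repertoire sizes
  satisfy this well, tiny repertoires may not.
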