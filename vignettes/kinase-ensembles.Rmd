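---
title: "Methods: kinase conformational ensembles from crystal structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinase conformational ensembles from crystal structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinens)
```

## The ensemble model

A corpus of crystal structures of one kinase is treated as a sample from
the enzyme's conformational ensemble. Each deposited structure contributes
one or more molecules (copies in the asymmetric unit), and each molecule
contributes one observation of every geometric observable. The package
makes two kinds of measurement on each molecule:

* **Distance triplets** — three named probe atoms whose pairwise Cα–Cα (or
  Cζ, for the DFG phenylalanine) distances summarise one structural
  feature. Distances are coordinates-only: no superposition is required,
  and the measurement is exactly invariant under rigid-body motion of the
  crystal frame.
* **B′ profiles** — per-residue, z-score-normalised temperature factors
  that allow flexibility to be compared across structures refined at
  different resolutions and overall displacement scales.

Observations are grouped by the structure's *catalytic state*, assigned
from the ligand occupying the active site: substrate/product (ATP or ADP,
with or without a bound peptide), inhibitor (non-hydrolysable analogue such
as AMP-PNP, or a Type-I ATP-competitive inhibitor), peptide-only, and apo.
The priority order substrate/product > inhibitor > peptide > apo is total:
a nucleotide always wins over a peptide, matching the chemistry (the
nucleotide defines the catalytic step). Classification is by ligand
identity only; the package deliberately does not verify active-site
occupancy geometrically, and a het code known to neither the
substrate/product, inhibitor, nor ignore list is a hard
"unclassifiable" error so that corpus curation stays explicit.

## B′ normalisation

For an atom modelled in several alternate locations $I$ with occupancies
$\pi_I$, the effective temperature factor is the occupancy-weighted sum
$B_i = \sum_I \pi_I B(i, I)$. Occupancies that do not sum to one are used
as given (partial-occupancy models are legitimate) with a warning.

Outliers — typically mis-modelled side chains, terminal residues, or atoms
riding on disordered ligands — are removed with the median-based modified
z-score: with $\tilde B$ the median and
$\mathrm{MAD} = \mathrm{median}\,|B_i - \tilde B|$,

$$M_i = 0.6745\,\frac{|B_i - \tilde B|}{\mathrm{MAD}},$$

and atoms with $M_i > 3.5$ are excluded in a single pass (the filter is not
iterated). The constant 0.6745 makes the MAD consistent with the standard
deviation under normality, so the 3.5 cutoff reads as "about 3.5 sigma". If
the MAD is zero the chain is (near-)constant and nothing is excluded. The
absolute-deviation form is the default; a squared-deviation variant of the
denominator, which appears in some of the B-factor literature's typography,
is available behind `mad_method = "squared"` but is not the standard
estimator. The absolute value in $M_i$ makes the exclusion two-sided;
with the 3.5 cutoff this additionally removes only grossly *under*-dispersed
atoms, which a one-sided reading would silently keep.

Surviving atoms are z-scored against the post-exclusion mean and *sample*
standard deviation (the $n-1$ convention; at chain scale, several hundred
atoms, the distinction is negligible, and the choice is recorded in the
profile's report). By construction the included atoms then have mean 0 and
sd 1 to numerical precision — a property the test-suite asserts at 1e-9 —
and the whole pipeline is exactly invariant under positive affine
transforms $B \mapsto aB + b$ of the raw column.

Residue values are the atomic-mass-weighted mean of the residue's included
atoms, $B'(\mathrm{res}) = \sum_a M_a B'(a) / \sum_a M_a$, using standard
atomic weights of the heavy elements (hydrogens are absent from the
analysed structures and are dropped by the parser). Three atom selections
are supported — all heavy atoms, backbone (N, CA, C, O; the default and the
headline analysis), and Cα-only — and all normalisation statistics are
computed *within* the selection in use, so each analysis mode is
self-contained. A residue whose selected atoms were all excluded is
reported missing rather than imputed.

Normalisation is per chain (one molecule), not per file: multi-copy
asymmetric units yield one profile per copy, consistent with per-molecule
profiles entering the PCA.

## Ensemble statistics

**Summary tables.** Each (state, triplet, pair) cell reports mean, median,
sample sd, N, min, quartiles, max. Quartiles use linear interpolation
between order statistics (R's default type-7 convention; the convention is
unstated in much of the comparative literature and alternatives move the
quartiles by under ~0.1 Å at these sample sizes). Missing distances —
unresolved probe residues — are dropped per pair, so N may differ between
pairs of the same triplet within one state; this mirrors real corpora where
e.g. the C-tail's D328 is frequently unresolved in apo structures.

**Confidence bands.** The per-residue mean B′ of a state is accompanied by
a percentile bootstrap interval obtained by resampling *structures* (not
residues), 1000 resamples by default, seeded and therefore bit-reproducible.
Resampling structures is the only reading consistent with a per-residue
band describing between-structure variability. Bands on synthetic Gaussian
profiles agree with the closed-form t-interval to well within 25% of the
interval width, and shrink as $n^{-1/2}$.

**Profile PCA.** Rows are structures — only the first molecule of each
asymmetric unit, by chain order in the file, to avoid weighting structures
by copy number — and columns are the residues resolved in *every* included
profile. Imputing missing residues was rejected because it fabricates
flexibility signal precisely where structures disagree. Columns are
mean-centred but not variance-scaled (profiles are already z-scored within
chains); the covariance is eigendecomposed via `prcomp`. Loadings are
orthonormal and map back to residues; `export_loading_pdb()` writes a copy
of a structure with a component's loadings in the B column for putty-style
rendering. Component signs are arbitrary.

**Distance densities and placement.** Each state's distribution of one
distance pair gets a Gaussian KDE with Scott's-rule bandwidth
$h = \hat\sigma n^{-1/5}$ — deterministic given the data. The density is an
evaluable function (a Gaussian mixture over the observations), not a fixed
grid, and its global mode is located by a grid scan refined with local
optimisation. `place_mutant()` (surfaced as `predict()` on a fitted
ensemble) reports each state's density at an observed distance and names
the state whose peak is nearest. The placement is purely descriptive; no
p-value is attached because the comparison the method supports is "which
state's typical conformation does this structure adopt", not a hypothesis
test, and none is reported upstream of it.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `cutoff` (modified z-score) | 3.5 | dimensionless | standard practice for the modified z-score; ~3.5σ under normality |
| `selection` | backbone | — | headline per-residue analysis; side chains add rotamer noise |
| `peptide_max_length` | 30 | residues | substrate/inhibitor peptides run ~5–25 residues; the kinase chain ~350 — the gap makes the threshold unambiguous |
| `n_boot` | 1000 | resamples | percentile CI stable to a few % of the width |
| `ci` | 0.95 | — | conventional band level |
| KDE bandwidth | Scott's rule | Å | deterministic, no tuning parameter |
| `numbering_offset` | 0 | residues | probe numbering assumes the conventional catalytic-subunit numbering; other kinases or shifted constructs supply an offset |

## The synthetic generator

`generate_structure()` writes wwPDB-format files in which every quantity the
pipeline later estimates is known exactly:

* the sixteen probe residues sit at configurable 3-D marker positions
  (defaults reproduce typical closed-state distances; only within-triplet
  distances are ever measured, so triplet groups occupy disjoint regions of
  space and the filler trace — an ideal helix — is irrelevant by
  construction);
* the catalytic state drives ligand emission (ATP, AMP-PNP, a short
  peptide chain, or nothing) plus solvent and ion records that
  classification must ignore;
* atomic B-factors are Gaussian with configurable regional means
  (truncated at a small positive floor, since B ≥ 0), with injectable
  outliers and alternate-location groups whose effective B is recorded;
* coordinates are rounded to PDB precision (3 decimals) *before* both
  manifest computation and writing, so manifest distances and re-measured
  distances agree exactly rather than to rounding error;
* a fixed seed makes the output byte-identical.

`generate_corpus()` emulates the study conditions: 115 structures composed
37 substrate/product, 60 inhibitor, 15 apo and 3 peptide; apo structures
carry a +4 Å displacement of the T51 marker away from A223 (the open-state
inter-lobe signature) and a +5 Å² elevation of the B mean over residues
120–139 (the α-D-region flexibility signature); marker coordinates receive
0.2 Å per-coordinate Gaussian jitter as conformational noise and B columns
2 Å² noise around a 20 Å² base. The B elevation is deliberately moderate:
a grossly inflated region would be excised by the single-pass MAD filter
rather than normalised, exactly as it would be in real data. Every fifth
structure gets a two-copy asymmetric unit and every second
substrate/product structure a bound peptide, exercising the multi-copy and
peptide-priority rules.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: crystal-packing and lattice-disorder
contributions to B-factors, resolution- and refinement-protocol-dependent
B scales, correlated (TLS/anisotropic) displacement, realistic side-chain
chemistry, and genuinely continuous conformational heterogeneity. The
generator validates the *machinery* (parsing, bookkeeping, normalisation
identities, planted-effect recovery), not the biology.

## Numerical choices and degenerate inputs

* Altloc resolution for geometry: highest occupancy, ties broken by
  alphabetically first altloc — deterministic and matching common viewer
  defaults. For B-factors altlocs are occupancy-weighted instead, never
  discarded.
* Only the first MODEL of a file is read (crystal structures).
* Negative B-factors are flagged by the parser but retained; exclusion is
  the MAD filter's job.
* Missing probe residues yield missing distances inside an emitted record,
  never a dropped record, so per-pair Ns stay honest.
* A chain whose post-exclusion σ is zero has no defined profile and errors;
  an empty residue intersection across profiles errors with advice rather
  than imputing.
* MAD = 0 (constant column) excludes nothing by definition.
* The bootstrap, the corpus generator and the fit all take explicit seeds;
  identical seeds give bit-identical outputs.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data: a 115-structure corpus (~1.2k atoms per chain) for corpus-level
checks, a 20-structure corpus for module-level tests, 20 replicates of 30
profiles × 100 residues for the PCA recovery study, and n = 1000 columns
for the false-exclusion rate. These sizes put every Monte-Carlo estimate
well inside the tolerances asserted while keeping a full run in tens of
seconds on one CPU.

## Known limitations

* B-factor comparability across structures relies on z-scoring alone; no
  resolution-dependent or lattice-disorder correction is attempted, so
  state-specific flexibility signals ride on whatever experimental
  confounders the corpus carries.
* Classification is by ligand identity, not geometry: a nucleotide bound
  at a secondary site would be mislabelled (not observed in the curated
  corpus the defaults target).
* The DFG conformation is summarised by spine distances only; dihedral
  classification of DFG-in/out/inter is out of scope.
* Residue numbering is assumed to follow the conventional
  catalytic-subunit numbering; a uniform per-structure offset is supported
  but per-segment renumbering is not.
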