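# kinens

Conformational ensemble analysis of kinase crystal structures.

## The problem

Protein kinases cycle through ligand-dependent conformations — the N- and
C-lobes of the catalytic domain open and close, the glycine-rich loop
(G-loop) repositions over the ATP site, the regulatory spine assembles and
disassembles. For a heavily crystallised kinase such as the PKA catalytic
subunit, the deposited structures form a *de facto* conformational ensemble:
each entry is one snapshot, and the spread of simple geometric observables
across entries reports the dynamics of the enzyme as it traverses its
catalytic cycle.

`kinens` turns that idea into a reusable pipeline for structural biologists:

1. **State classification.** Each structure is assigned one of four
   ligand-defined catalytic states from its active-site contents, with
   priority substrate/product > inhibitor > peptide > apo:
   ATP/ADP-bound (substrate/product), non-hydrolysable analogue or Type-I
   inhibitor bound (inhibitor), peptide-only, or apo. Unknown het codes are
   a hard error — the ligand dictionary must be extended, never guessed.
2. **Distance triplets.** Named three-residue metrics are measured per
   molecule (every copy in a multi-copy asymmetric unit counts):
   T51/H87/A223 (inter-lobe closure), K72(Cα)/F185(Cζ)/L95 (regulatory-spine
   assembly, DFG orientation), D328/G52/E127 (C-tail tethering and G-loop),
   F54/F154/L173 (G-loop vs C-spine), V104/K81/N113 (N-lobe core), plus the
   legacy S53 variant of the inter-lobe metric.
3. **B′-factor profiles.** Raw temperature factors are converted to
   dimensionless per-residue flexibility profiles:
   occupancy weighting over alternate locations, `B(i) = Σ_I π_I B(i,I)`;
   single-pass outlier exclusion by the modified z-score
   `M(i) = 0.6745 |B(i) − B̃| / MAD` with cutoff `M > 3.5`;
   z-scoring over the surviving atoms, `B′(i) = (B(i) − B̄)/σ`; and
   atomic-mass-weighted aggregation to residues,
   `B′(res) = Σ_a M_a B′(a) / Σ_a M_a`.
4. **Ensemble statistics.** Per-(state, pair) summary tables (mean, median,
   sd, N, quartiles), per-residue mean B′ with seeded bootstrap 95%
   confidence bands, PCA of the B′ profiles (first molecule of each
   asymmetric unit, mean-centred covariance), Gaussian KDE of each distance
   distribution per state (Scott's-rule bandwidth), and density-based
   placement of individual structures — "does this mutant sit at its own
   state's density peak, or another state's?".
5. **Synthetic structures.** A generator writes PDB files with fully known
   geometry, ligands, B-factor structure, alternate locations and injected
   outliers, plus a ground-truth manifest, so the entire pipeline is
   verifiable offline.

## Worked example

```r
library(kinens)

corpus_dir <- file.path(tempdir(), "demo_corpus")
corp <- generate_corpus(corpus_dir,
  counts = c(substrate_product = 8, inhibitor = 8, apo = 6, peptide = 3),
  seed = 20)
fit <- kinase_ensemble(corp$files, seed = 20)
print(fit)
#> <kinase_ensemble>
#>   structures: 25 (apo = 6, inhibitor = 8, peptide = 3, substrate_product = 8)
#>   distance records: 180 over 6 triplets
#>   B' profiles: 30 chains, selection backbone
#>   profile PCA: PC1 20.8%, PC2 5.6%, PC3 5.1%

subset(summary(fit, triplet = "lobe_closure"), pair == "51-223")
#>                state      triplet   pair average median std_dev  n   min ...
#> 10               apo lobe_closure 51-223   22.95  22.90    0.31  7 22.46
#> 28         inhibitor lobe_closure 51-223   19.01  18.90    0.36 10 18.44
#> 46           peptide lobe_closure 51-223   19.00  18.92    0.23  4 18.85
#> 64 substrate_product lobe_closure 51-223   19.01  18.99    0.26  9 18.56
```

The apo group sits ~4 Å more open on the T51–A223 inter-lobe distance than
every ligand-bound state — exactly the displacement the generator planted
for apo structures, recovered through the full
write-file → parse → classify → measure → summarise chain. Note `n` counts
molecules, not files: multi-copy asymmetric units contribute each copy.

Placing one apo structure against the fitted per-state densities:

```r
mut <- predict(fit, corp$files[corp$states == "apo"][1],
               triplet = "lobe_closure", pair = "51-223")
mut$placement$table
#>               state      density     peak peak_offset
#> 1 substrate_product 4.759389e-72 18.99193    3.468390
#> 2         inhibitor 2.306050e-37 18.88620    3.574113
#> 3               apo 4.678826e-01 22.87637    0.416048
#> 4           peptide 8.975455e-71 18.89840    3.561915
mut$placement$nearest_peak
#> [1] "apo"
```

`run_pipeline(input_dir, out_dir)` performs the same fit over a directory of
PDB files and writes a reproducible artifact tree (states, tidy distance
table, summary tables, per-chain B′ profiles, state bands, PCA scores and
loadings, a provenance `config.json`, and a collected-failures table).

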