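# terminomix

Deconvolution of peptide terminomes into protease contributions, with
label-free quantification of cleaved proteins.

## The problem

Endogenous peptides in a tissue (the peptidome) are fragments left behind by
proteolysis. The residues flanking each peptide terminus record which bond
was cut: in Schechter–Berger nomenclature the positions P2, P1 run
N-terminally and P1′, P2′ C-terminally from the scissile bond, which lies
between P1 and P1′. Pooling the termini of a quantified peptidome gives a
20 × 4 amino-acid appearance-frequency matrix **X**<sub>p</sub> — the
*terminome matrix* of a sample group. Each protease *k* likewise has a
20 × 4 cleavage-site specificity matrix **X**<sub>k</sub> (derivable from
curated cleavage data such as the MEROPS database). If many proteases acted
on the proteome, the observed terminome is approximately a convex
combination of their specificities:

> **X**<sub>p</sub> = Σ<sub>k</sub> f<sub>k</sub> **X**<sub>k</sub>,
> Σ<sub>k</sub> f<sub>k</sub> = 1, f<sub>k</sub> ≥ 0

terminomix estimates the contribution vector **f** by minimizing

> Z(f) = Σ over all 80 cells ( Σ<sub>k</sub> f<sub>k</sub> X<sub>k</sub>(i,p) − X<sub>p</sub>(i,p) )²

with an exact active-set quadratic program on the probability simplex. Each
f<sub>k</sub> is a composite of protease amount, activity and specificity
overlap — an index of proteolytic regulation, not an activity assay. For
cross-group display, contributions are log-normalized as
f′<sub>ks</sub> = log₁₀( N · f<sub>ks</sub> / Σ<sub>s</sub>Σ<sub>k</sub> f<sub>ks</sub> ).

The package also covers the quantification side of such experiments:
per-run normalization of DIA/SWATH peak areas (each run scaled to sum 1),
shared-peptide and confidence filters (inclusive 80% cutoff),
peptide-to-protein aggregation, and fold changes of cleaved proteins against
a reference group with a strict > 2.0 significance threshold. A synthetic
digestion simulator with known ground-truth **f\*** makes every stage
testable without any external download.

Intended users: proteomics/degradomics analysts working with quantified
peptidomes (e.g. from PeakView-style SWATH exports) and method developers
who need a reproducible terminome-deconvolution benchmark.

## Worked example

Count significantly changed cleaved proteins in the packaged published
fold-change table (135 cleaved proteins from fish skeletal muscle under
air-exposure stress, three experimental groups vs a decapitated control):

```r
library(terminomix)
count_significant(example_fold_changes(), threshold = 2.0)
#>  AirEx1_Decap  AirEx5_Decap AirEx10_Decap
#>            19            21            13
```

19 proteins exceed the 2.0-fold threshold in the 1-minute air-exposure
group. (The published report lists 20 and 14 for the later groups; strict
counting of the *printed, rounded* values gives 21 and 13 — the rounding of
values near 2.0 flips three rows.)

Simulate a digestion with known protease contributions, run the full
pipeline, and recover them:

```r
cfg <- sim_config(seed = 42, n_proteins = 1500, n_events_per_group = 3000)
proteome <- generate_proteome(cfg)
panel    <- generate_protease_panel(cfg)     # 5 sharp specificities
sim      <- simulate_digestion(proteome, panel, cfg)

qt     <- normalize_runs(filter_peptides(sim$quant))
events <- peptidome_cleavage_events(qt, sim$proteome)
xp     <- compute_terminome_matrix(events, group = "AirEx1")
fit    <- fit_contributions(xp, panel)
round(rbind(fitted = fit$f, truth = cfg$f_star[, "AirEx1"]), 4)
#>          [,1]   [,2]   [,3]   [,4]   [,5]
#> fitted 0.2244 0.1797 0.0413 0.1832 0.3714
#> truth  0.2195 0.1793 0.0411 0.1909 0.3692
```

The fitted simplex weights match the generating truth to ~0.005 RMSE at
3,000 events per group; `fit$objective_Z` (here 3.1e-4) is the residual
sum of squares over the 80 matrix cells.

## Command line

```sh
Rscript -e 'terminomix::tmx_main()' simulate --out world --seed 5
Rscript -e 'terminomix::tmx_main()' run-all --config config.json
```

Subcommands: `simulate`, `filter`, `terminome`, `fit`, `foldchange`,
`heatmap`, `run-all` (see `?tmx_main`). `inst/scripts/terminomix` is an
equivalent launcher.

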