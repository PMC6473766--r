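---
title: "Terminome deconvolution: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Terminome deconvolution: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(terminomix)
```

## The model

A quantified peptidome is read as a *terminome*: every peptide maps to its
parent protein and witnesses up to two cleavage events, one at each
terminus. The residues at positions P2, P1 (N-terminal of the scissile
bond) and P1′, P2′ (C-terminal) are tallied, weighted by the peptide's
normalized abundance, into a 20 × 4 frequency matrix $X_p$ per sample
group: entry $(i, p)$ is the abundance-weighted frequency of amino acid
$i$ at flanking position $p$, and every position column sums to 1.

Each protease $k$ in a panel of $N$ has a specificity matrix $X_k$ of the
same shape. The working assumption is the mixture model

$$X_p \;=\; \sum_{k=1}^{N} f_k X_k, \qquad \sum_k f_k = 1,\; f_k \ge 0 ,$$

and the contributions $f$ are estimated by minimizing the residual sum of
squares over all 80 cells,

$$Z(f) = \sum_{i=1}^{20}\sum_{p=1}^{4}
  \Big(\sum_k f_k X_k(i,p) - X_p(i,p)\Big)^2 ,$$

subject to the simplex constraints. Key assumptions, stated plainly:

* **Additivity.** Proteases act independently enough that observed context
  frequencies mix linearly. Sequential digestion, exopeptidase trimming of
  ragged ends, and substrate depletion all violate this to some degree;
  $f$ is therefore an *index* blending amount, activity and specificity
  overlap — not an activity measurement.
* **Four-position sufficiency.** Specificity beyond P2–P2′ is ignored,
  matching the span for which curated per-protease frequencies are
  commonly available.
* **Marginal, not joint, specificity.** $X_k$ stores per-position
  marginals; correlations between positions within one cleavage site are
  not modeled.
* **Complete panel.** An active protease missing from the panel pushes its
  signal onto the nearest available specificities.

## Fitting: an exact small QP

$Z$ plus a ridge term $10^{-9}\lVert f\rVert^2$ is a strictly convex
quadratic, minimized by a primal active-set method: the equality
constraint stays in the KKT system, nonnegativity constraints enter and
leave a working set, and iteration stops when all bound multipliers are
nonnegative. There is no randomness and no step-size tuning; fixed inputs
give bit-stable output. Tolerances: convergence/feasibility $10^{-10}$;
fitted vectors satisfy $\sum f = 1 \pm 10^{-9}$, $f \ge 0$ exactly after
clipping.

The ridge term matters only under degeneracy: curated panels (e.g. 45
matrices for one tissue) contain near-duplicate specificities, for which
the split of weight is not identifiable from $X_p$. The solver then picks
the minimal-norm split and emits a collinearity warning naming the pair;
interpret such contributions jointly, not individually.

An independent brute-force verifier, `grid_oracle()`, enumerates the
simplex lattice $\{f : f_k \in \{0, s, \dots, 1\}, \sum f = 1\}$ and is
used throughout the tests to bound the optimizer from above; the fitted
$Z$ must never exceed the best lattice value.

## Quantification conventions

* **Run normalization.** Each (group, replicate) run is scaled so its peak
  areas sum to 1; idempotent and ratio-preserving. A zero-total run is an
  error, not silently dropped.
* **Filtering.** Shared peptides are removed; the confidence cutoff
  (default 0.80) is *inclusive* — "below 80% excluded" keeps a peptide at
  exactly 0.80.
* **Replicate combination.** Group-level protein areas are the arithmetic
  mean of per-replicate sums (a sum would scale with replicate count;
  the mean tolerates a missing replicate). Terminome matrices instead pool
  replicate weights before the final column normalization, which is
  equivalent to the mean for balanced designs.
* **Fold changes.** Ratio of group to reference protein area; a zero
  reference area makes the ratio undefined (`NA`, excluded from counts)
  rather than infinite. Significance is strict (> 2.0 by default) and only
  increases are counted.
* **Cross-group display.** $f'_{ks} = \log_{10}(N f_{ks} / \sum_s\sum_k
  f_{ks})$; the denominator is computed literally rather than assumed equal
  to the number of groups, so partially fitted group sets stay correct.
  Cells with $f_k = 0$ are masked (`NA`) instead of $-\infty$.
* **Coordinates.** 1-based residue numbering, inclusive peptide spans; a
  cleavage is the bond between P1 and P1′. Contexts truncated by a protein
  terminus are dropped entirely (the matrix has no gap row), so mature
  protein ends never count as cleavage events. Peptides mapping to several
  positions or proteins are excluded by default, mirroring the upstream
  shared-peptide rule; a policy switch keeps them with weight split across
  matches. I and L are distinct residues throughout (identifications come
  from database search against the same ORF set, so residue identity
  holds).

## The synthetic world

`sim_config()` fixes a ground-truth world emulating a 4-group × 3-replicate
air-exposure study on fish muscle: per group, a known simplex vector
$f^\*$; a panel of $N = 5$ proteases with Dirichlet(0.05) position columns
(sharp, nearly one-hot specificity); 20,000 cleavage events per group;
multiplicative log-normal abundance noise with $\sigma = 0.2$; peptide
lengths 5–30 residues, mimicking a 5 kDa molecular-weight-cutoff
extraction window. Proteome: 12,000 uniform-composition sequences of
100–300 residues (defaults chosen once: the size is what a deep proteome
FASTA looks like, and — see below — it must host one implanted site pair
per event; a composition hook exists for realistic amino-acid tables).
Group/replicate streams are seeded deterministically from one master seed.

**How sites are placed.** Selecting bonds of a *finite* random proteome
with probability proportional to the product of $X_k$ frequencies does not
reproduce $X_k$'s marginals when specificity is sharp: the product weights
are so heavy-tailed that the effective number of usable bonds collapses to
a handful (measured: effective sample size 1–20 even on 160,000 bonds,
with marginal errors up to 0.8). In the infinite-proteome limit, however,
that selection scheme induces context residues distributed *exactly* as
independent draws from the four specificity columns. The simulator
implements this limit directly: for every event it draws a protease for
each peptide terminus from $f^\*$, draws the eight context residues from
the two proteases' columns, and implants the pair at its own location in
the proteome scaffold. Both termini of every peptide are therefore genuine
mixture-drawn cleavage sites, and the emitted FASTA, peptide table and
ground-truth sidecar are mutually consistent.

What a green recovery test does establish: the full pipeline (filters,
normalization, mapping, context extraction, pooling, QP) inverts the
stated generative model to ~0.002 RMSE at the stated depth and noise.
What it does not establish: robustness to model violations absent from the
generator — position-correlated specificity, exopeptidase ragged ends,
missed panel members, shared peptides between paralogs, or
abundance-dependent identification bias. Real-data contributions should be
read comparatively (across groups), not absolutely.

## Numerical and format choices

* Amino-acid alphabet fixed to the 20 canonical residues in alphabetical
  order; nonstandard letters (B, J, O, U, X, Z) are rejected at load with a
  warning rather than silently remapped.
* Specificity tables travel as long-format TSV (`protease_id`, `ec_number`,
  `position` ∈ {P2, P1, P1p, P2p}, `residue`, `value`); counts and
  frequencies are both accepted, columns are renormalized, and
  normalization is idempotent to 1e-12. An all-zero position column becomes
  uniform (0.05) with a loud warning, keeping sparse curated data usable.
  There is no live MEROPS access; `example_specificity_panel()` provides a
  deterministic synthetic 45-matrix stand-in.
* The packaged fold-change fixture is a published 135-protein table; only
  its first experimental group's count (19) is asserted against the source,
  because strict counting of printed, rounded values provably differs by
  ±1 from the source's counts in the other two groups.
* Peptide coverage maps tier residues at confidence ≥ 0.95, [0.50, 0.95),
  and < 0.50, best tier winning on overlap — matching common
  identification-software color schemes.

## Known limitations

Contributions are point estimates; no uncertainty is attached (a bootstrap
over peptides would be the natural extension). The QP scales comfortably
to hundreds of proteases, but identifiability — not compute — is the
binding constraint for large panels. The simulator does not model
sequential digestion kinetics, missed cleavages, or PTMs; its role is
pipeline validation, not biological realism.
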