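---
title: "Clonal fate models of pancreas organogenesis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal fate models of pancreas organogenesis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panclonal)
```

`panclonal` models how single pancreatic progenitors, labelled at E9.5 when
the mouse pancreatic bud has just been specified, expand into clones of
mixed ductal (SOX9+), acinar (CPA1+) and endocrine (PAX6+) progeny by
E14.5. This vignette is the package's own account of the model, the
inference machinery around it, and the design decisions taken where the
problem left genuine latitude.

## The branching-process fate model

A clone starts as one progenitor. Replicating cells draw a cell-cycle
length $t_{cc}$ from a gamma distribution; because the founder's cycle
phase at labelling is unknown, its first division happens at an offset
drawn uniformly in $[0, t_{cc}]$. At every division two daughters are
created and each daughter independently

* stays a progenitor with probability $1 - c$,
* becomes endocrine with probability $c\,f(t)$,
* becomes acinar with probability $c\,(1 - f(t))$,

where $c$ is the differentiation probability and $f(t)$ the endocrine
bias, evaluated at the moment of that division. Endocrine cells never
divide again (NEUROG3-committed precursors delaminate and are essentially
post-mitotic at this resolution); acinar cells keep replicating with the
same cycle distribution as progenitors, and all their descendants remain
acinar. There is no cell death — the state diagram has no exit arrow, and
apoptosis is negligible in the early bud.

Two competing forms of the bias are compared:

* **Model 1**: $f = q$, constant over the window;
* **Model 2**: $f(t) = q + \tfrac12 (1 - q)\,(1 + \cos 2\pi t)$, with
  $t = (E - 9.5)/5$ the normalised embryonic time.

Model 2 equals 1 at both window ends and dips to its minimum $q$ exactly
at E12, where NEUROG3+ endocrine precursors are rarest; the cosine is
evaluated only on $[0, 1]$ and never extrapolated, so tracing windows must
lie inside E9.5–E14.5.

Design points worth making explicit:

* **Per-daughter fate draws.** Whether the two daughters of a division
  share one fate draw cannot be settled from the verbal description of
  the process alone; we assign fates per daughter, independently, because
  observed in silico lineages show mixed-fate siblings and each division
  assigns two fresh cycle lengths to two new cells.
* **Bias at division time, not birth time.** Fates are decided at the
  division that creates the daughters, so $f$ is evaluated at the
  division instant.
* **Gamma defaults.** The source measurements behind the cycle-length
  distribution are not printed numerically anywhere we can reach, so the
  package defaults to shape 10, scale 1.35 h: mean 13.5 h, CV ≈ 0.32.
  Over a 120 h window this yields maximal clones of a few hundred cells,
  consistent with the observed 40–250-cell multipotent clones. Both
  parameters are user-settable through `gamma_cycle()`.
* **RNG layout.** An ensemble is simulated vectorised across clones from
  a single R random stream seeded by `params$seed`, which makes ensembles
  bit-reproducible. Statistical independence across the cells of a
  parameter scan is obtained by deriving one seed per grid cell from the
  scan seed and the cell's $(c, q)$ values, so the surface is identical
  under any traversal order or subgrid.

A useful independent check on the simulator is the renewal equation for
the expected clone size under pure expansion ($c = 0$): with
gamma-dispersed cycles and the uniform first-division offset the expected
size at 120 h is ≈ 633 — about a third more than the deterministic
doubling guess $2^{120/13.5} \approx 474$, because cycle-length dispersion
raises the Malthusian growth rate (the test suite integrates this renewal
equation numerically and compares the ensemble mean against it). Naive
doubling arithmetic underestimates clonal expansion and is not used as an
oracle.

## Likelihood, parameter scan, model comparison

Two observed datasets inform the fit:

1. **Clonal acinar fractions**: per-clone acinar fractions at E14.5 from
   clones with at least one progenitor *and* at least one acinar cell
   (both filters are applied by default and can be toggled
   independently — they come from two separate statements of the
   protocol, and their conjunction is the conservative reading).
2. **Pooled population fractions**: acinar and endocrine percentages of
   groups of 100 clones pooled cell-wise, at E10.5, E11.5, E12.5 and
   E14.5, emulating stained whole pancreata. Clones that do not fill a
   complete group are dropped.

For each $(c, q)$ on a grid we simulate 2500 clones, build gaussian
kernel densities of the simulated quantities and evaluate the observed
data under them. The kernel bandwidths follow the reference analysis:
$\sigma = 0.015$ on the fraction scale for dataset 1 and $\sigma = 6.5$
on the percent scale for dataset 2. (A bandwidth of 0.5 is quoted
elsewhere for the clonal dataset; we treat the more specific
per-dataset values as authoritative and expose the bandwidths as
arguments.) Pooled-fraction likelihoods are computed per timepoint and
lineage and summed into one dataset-2 log-likelihood. The two datasets
combine as a product of likelihoods, reported as the deviance
$-2\log(L_1 L_2)$.

Numerical choices:

* **Density floor.** Kernel density values below $10^{-12}$ are floored
  before logging, keeping surfaces finite when an observation falls far
  outside the simulated support; floored evaluations are counted and
  reported per grid cell, and a cell whose simulated ensemble yields *no*
  clone passing the filters is floored wholesale and flagged (`empty`).
* **AIC convention.** The package defaults to the standard
  $\mathrm{AIC} = 2k - 2\ln L$ with $k = 2$ for both models and the
  Akaike relative likelihood $p_i = \exp((\mathrm{AIC}_{\min} -
  \mathrm{AIC}_i)/2)$; this is the only convention under which the
  published AIC pair $(-14.5, -22.1)$ yields the published relative
  probability 0.02. The literal variants without the factor 2 are
  available as `convention = "as_printed"` but are mutually inconsistent
  and not the default.
* **Grid.** The reference grid spacing is not printed; the defaults are
  $c \in \{0.05, \dots, 0.60\}$, $q \in \{0.05, \dots, 0.95\}$ in steps
  of 0.05, fully configurable.

`unipotent_acinar_probability()` carries the commitment-wave prediction:
clones started near the Model 2 bias minimum (E11.5–E12) have a markedly
higher chance of being purely acinar at E14.5 than clones started at
E9.5, where $f = 1$ makes the first differentiating daughters endocrine.

## Clone analytics, geometry and axis mapping

Potency classes are determined solely by which of the three lineages have
non-zero counts. Labelling indices are reported to one decimal and
squared for the double-labelling probability, mirroring the screens'
reporting; the E9.5→E10.5 clone-membership rule chains cells within a
strict 30 µm distance (single linkage — the rule was applied to short
traces where chains are short, and the linkage is configurable through
the threshold only).

Neighbour identification follows the 3D Delaunay tetrahedralization of
cell centroids with distance pruning (default 10 µm, closed comparison;
strictness is not specified upstream, and `<=` keeps the documented
5/10 µm thresholds inclusive). No installed package provides a 3D
Delaunay, so the package implements incremental Bowyer–Watson insertion
directly and the test suite verifies it edge-for-edge against a
brute-force empty-circumsphere oracle on random point sets. Predicate
consistency on degenerate (cospherical) inputs is obtained by a
deterministic symbolic jitter of relative size $10^{-9}$; exact lattices
therefore resolve to one of their valid tetrahedralizations while general
position inputs are unaffected. Neighbour means and CVs exclude the focal
cell by default (`include_focal` includes it; the upstream wording is
ambiguous) and the CV uses the population (divisor $n$) standard
deviation. Degenerate 3D inputs — duplicates, coplanar clouds — raise
errors rather than silently falling back to 2D.

Axis mapping projects xy coordinates orthogonally onto the
distal→proximal landmark line; positions are signed, unclamped distances
from the distal landmark. The top label retainers are the
$\lceil 0.1\,n \rceil$ highest-GFP cells with ties broken by cell id.
Small/large clone comparisons split at the size median with equal group
sizes (an odd middle clone joins neither group) and use a Wilcoxon
rank-sum statistic for the location difference. The 2D KDE bandwidth for
retention maps defaults to 30 µm — a stand-in chosen at the scale of a
few cell diameters, as no value is printed upstream.

## Synthetic cohorts

The generators exist so every analysis runs end-to-end without any
external download; their defaults *are* the study conditions:

* `synth_clone_observations()` draws founders as 12% differentiated
  endocrine cells, 12% NEUROG3-stage precursors and 76% progenitors (the
  measured composition of the E9.5 bud), grows progenitor clones with the
  fate model and maps states to markers (progenitor→SOX9, acinar→CPA1,
  endocrine→PAX6). Driver censoring: `hnf1b` excludes endocrine founders
  entirely and precursors with probability 0.32 (HNF1B is detected in
  67.7% of NEUROG3+ cells); `ptf1a` excludes both and additionally
  conditions clones on ≥ 1 non-endocrine cell at harvest, reproducing
  that screen's absence of endocrine-only clones. Precursor founders
  divide at most once (1–2 endocrine cells); the rarer 3–6-cell
  endocrine clones of the real screens, attributed to replicative
  low-*Neurog3* cells, are not modelled — a known divergence shared with
  the fate model itself, which understates endocrine-only clones.
* `synth_bud_cloud()` packs centroids into a 40 µm sphere with 5 µm
  minimum separation and paints uniform, posterior-gradient or
  lateral-cluster intensity fields plus gaussian noise, emulating the
  homogeneous (PDX1-like), posterior-high (HNF1B-like) and
  lateral-cluster (PTF1A-like) patterns.
* `synth_label_dilution()` halves a nuclear label at each division
  ($\mathrm{GFP} = I_0/2^{n_\mathrm{div}}$). The spatial proliferation
  bias is a multiplicative cycle-scale factor linear in normalised
  distance from the axis midpoint (peripheral cells cycle faster); the
  underlying experiments demonstrate the phenomenon without quantifying
  a centre/periphery cycle ratio, so the default bias of 0.5 at the
  extremes is a free parameter chosen to give clear but not saturated
  dilution contrast over a 3-day trace.
* `synth_bulk_fractions()` pools fresh ensembles into per-pancreas
  fraction tables in exactly the CSV shape the scan consumes.

What passing tests on these cohorts show — and what they do not: the
generators share the fate model's idealisations (no death, no migration,
no niche feedback, perfectly scored markers), so recovery tests
demonstrate the *inference machinery* is consistent, not that real
pancreata satisfy the model.

## Problem sizes and runtime envelope

The test suite exercises the statistical properties at the sizes the
analyses themselves use: 2500-clone ensembles for the parameter scan
(10 repetitions over a 5×5 grid bracketing the generating values),
500-clone ensembles across 20 repetitions for AIC model recovery,
$10^4$-clone ensembles for structural invariants, $10^5$ division events
for fate-frequency checks, and 20-seed comparisons for the spatial
property tests. These sizes give 3-sigma margins on every stochastic
assertion while keeping a full run of the suite within a coffee break on
one core.

## Known limitations

* Acinar proliferation is approximated by the progenitor cycle
  distribution (a small underestimate of acinar expansion).
* The model understates endocrine-only clone frequency by construction,
  since every simulated founder is a progenitor; analyses therefore rely
  on acinar fractions, which this bias does not affect.
* The Delaunay implementation targets bud-scale clouds (hundreds to a
  few thousand cells), not tissue-scale meshes.
* Curved-axis (spline) projection and automatic landmark detection are
  out of scope; the length axis is a straight line between two
  user-supplied landmarks.
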