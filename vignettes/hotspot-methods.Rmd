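---
title: "Methods: interface hotspot calling, cohort statistics, and imaging summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interface hotspot calling, cohort statistics, and imaging summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotspotr)
```

hotspotr chains three analyses that, in structural studies of
channel–GTPase complexes such as TRPM8–Rap1A, are usually run with
separate ad-hoc scripts: calling interaction hotspots on docked
complexes, screening somatic-mutation cohorts for hits on those
residues, and summarising the live-cell imaging used to validate them.
This vignette documents the models, the conventions that had to be
decided, and what the synthetic generators do and do not emulate.

## Residue interaction networks

A docking pose is parsed into residues (chain, sequence number,
insertion code) and their atoms. The RIN has one node per residue; an
undirected edge joins residues whose **minimum heavy-atom distance**
lies in `[d_min, d_max]`, by default **[2.5, 5.0] Å with both bounds
inclusive** (`build_rin()`).

Conventions worth making explicit:

* *Distance between residues* means the minimum over all non-hydrogen
  atom pairs. This is the standard RIN contact convention and the only
  reading compatible with a 2.5 Å lower bound — non-bonded Cα–Cα
  distances never get that small. Hydrogens are kept at parse time but
  excluded from distances: most experimental structures lack them, so
  including them would change contacts inconsistently across inputs.
  The heavy-atom choice is recorded in the RIN metadata.
* The lower bound exists to exclude covalent or clashing geometry;
  pairs below it produce no edge and a warning.
* Sequence-adjacent residues are eligible for edges; an
  `exclude_adjacent` flag is available but defaults to off since the
  contact definition states no exclusion.
* altLoc records resolve to the highest-occupancy conformer (ties:
  first in file); waters and other `HETATM` records are dropped by
  default; each `MODEL` block of a multi-model file becomes its own
  pose.

## Residue centrality and hotspot calling

`residue_centrality()` computes **closeness centrality** with the
Wasserman–Faust correction: for node $i$ with $r_i$ reachable others
among $n-1$,

$$C(i) = \frac{r_i}{n-1}\cdot\frac{r_i}{\sum_{j \in R(i)} d(i,j)},$$

with unweighted shortest paths; an isolated node gets 0. The choice of
closeness (rather than betweenness or degree) reflects the convention
of residue-centrality tooling in this field, but the measure used by
any given upstream analysis is rarely stated — it is therefore flagged
as an assumption in the output metadata. Z-scores use the **population**
standard deviation over all nodes of the analysed network: the network
is a complete finite object, not a sample. Both conventions are
configurable in the sense that `centrality_zscores()` operates on any
centrality vector.

A residue is **central** when $Z \ge 3$, threshold inclusive. A residue
is an **interface residue** when it has at least one cross-partner
contact inside the same `[2.5, 5]` Å window — one distance convention
throughout, rather than a separate interface cutoff. A residue is a
**hotspot** when it is at the interface in at least one pose *and*
central in at least one pose (`consensus_hotspots()`, thresholds
configurable); the maximum Z over poses is retained, and residues are
matched across poses by their key, with inconsistent partner
assignments treated as an error rather than silently merged. Where an
upstream analysis restricted attention to a visually selected candidate
list, the `candidates` argument reproduces the restriction explicitly.

Centrality is computed on whatever complex the pose file contains
(monomer–ligand or tetramer–ligand); the package does not decide the
oligomeric state and simply records what it was given.

## The toy-complex generator

`gen_toy_poses()` produces two-chain poses with planted ground truth.
Scaffold residues are single pseudo-atoms on a ring of chord spacing
4.0 Å, so each contacts its two neighbours; the two rings sit in
parallel planes separated so that cross-partner distances stay outside
the contact window except where planted. A planted hotspot residue
carries six pseudo-atoms: its ring atom, an interface atom meeting its
partner hotspot at `contact_radius` (default 4.2 Å, mid-window), and
four anchor atoms, each bridging a pair of scaffold residues spread at
the ring fifth-points. That gives planted residues 10+ contacts versus
2–4 for scaffold residues and shortcuts across the ring, which is what
makes closeness $Z \ge 3$ geometrically reachable — on a bare ring or
chain no node ever stands three standard deviations above the rest.
Residues are pseudo-atom clusters of 1–6 points; no real side-chain
chemistry, secondary structure, or docking-pose physics is modelled.

Per pose, non-planted residues receive an independent Gaussian offset
(`jitter_sd`, default 0.3 Å — thermal-scale positional noise); planted
geometry is held fixed so the ground truth survives. Defaults (40
residues per partner, two planted hotspots per partner at the ring
quarter points, five poses) were fixed once from the geometry above.
Passing tests on these toys show that the pipeline's graph machinery
and consensus rules behave as specified; they do not show that real
docking poses of a real complex would yield the same hotspots, since
real interfaces are irregular, contacts are chemically heterogeneous,
and pose ensembles are correlated.

## Cohort genomics

`mutational_burden(n, patients, length)` returns
$n / (\text{patients} \times \text{length} \times 10^{-6})$ —
mutations per patient per megaresidue — unrounded, with a two-decimal
display attribute. Protein-change strings are parsed from the HGVS-like
short form `p.<ref><pos><alt>` with one-letter codes; the mutation
generator draws per-gene Poisson counts (the simplest count model
consistent with a per-patient rate) with positions uniform over the
protein, plus forced entries at watch-list codons.

Labeling applies, in precedence order: GTEx → healthy (checked first,
GTEx rows carry no staging); then metastatic when the AJCC m category
starts with `M1`, the AJCC stage is IV or an equivalent encoding
(`Stage IV`, `IV`, `IVA`–`IVC`, case-insensitive), or the FIGO stage is
III/IV (including subtypes); otherwise not metastatic. The exact sets
of "equivalent" encodings are not standardised across clinical exports,
so both lists are arguments. Cohort assembly routes GTEx tissues and
TCGA projects into Breast/Prostate/Uterus and drops TARGET samples,
logging the counts.

### The normality gate

For each group, normality is accepted when **n > 30** or when a
two-sided KS test against a normal reference is non-significant at
`alpha = 0.05`. By default the reference uses the group's own estimated
mean and sd. This is the pragmatic choice when no external reference
exists, but it has a known cost: with estimated parameters the KS test
is conservative (the Lilliefors effect), so its realised type-I rate on
truly Gaussian groups is far below the nominal 5% and the parametric
branch is chosen almost always. When the reference distribution *is*
known — as in calibration simulations — `ks_mean`/`ks_sd` fix it, and
the gate then runs at nominal size (the calibration test verifies
~95% parametric decisions on Gaussian groups of n = 20). Groups with
n < 2 cannot be tested and fail with an explicit reason. Levene's test
is reported for homoscedasticity but is informational only and never
changes the plan.

`run_de()` executes the gated plan with the standard implementations
(`aov` + `TukeyHSD`, or `kruskal.test` plus an in-package Dunn's
all-pairs test with tie correction and Bonferroni adjustment — written
here because no installed package provides it; for two groups its
$z^2$ equals the tie-corrected Kruskal–Wallis $H$, which the tests
exploit as an exact cross-check). With only two groups the omnibus test
falls back to Welch's t or the Wilcoxon rank-sum test, flagged in the
report. Pairwise differences are reported as differences of means
(parametric) or of medians (nonparametric), with the nonparametric flag
(`np`) carried alongside.

## Imaging statistics

* `cytoplasmic_translocation()`: $R = (I_{cs} - I_m)/I_m$, requiring
  $I_m > 0$; scale-invariant by construction. Per-cell aggregation over
  ROI pairs is the **mean** by default (median by flag) — the choice is
  not dictated by the definition, and the mean keeps the planted-step
  recovery unbiased under multiplicative noise. Fewer than four ROI
  pairs per cell triggers a warning (the recommended minimum), and
  unpaired ROIs are rejected rather than imputed. R traces are reported
  raw; any baseline subtraction before group statistics is left to the
  caller.
* `migration_rate()`: mean over a track of step distance / step
  duration, in µm/min, after excluding flagged cells (e.g. cells that
  left the field or divided) and single-point tracks.
* `peak_amplitude()`: max − min over `[stim, stim + 300 s]`; the window
  length matches the usual post-agonist observation span and is a
  parameter.
* `delta_f_over_f0()`: $F_0$ is the mean over the 100 s before the
  stimulus; the release slope is a least-squares fit of $\Delta F/F_0$
  over a post-stimulus window. No convention fixes that window, so it
  is explicit: default 60 s, configurable — it must be stated to be
  testable.
* `normalized_ratio()`: (sample ratio)/(control ratio), optionally
  log2; densitometry values enter as numbers, gel-image quantification
  is out of scope.

Trace/track generators plant a known step, speed, or decay; tracks use
a fixed per-step displacement so the true speed is exact, and traces
carry 2% multiplicative intensity noise. Microscope noise physics,
photobleaching, segmentation and ROI placement are not emulated.

## Pipeline and determinism

`run_stage()` dispatches one named stage on a config list or YAML file
(flags win over the file in the CLI wrapper), validates inputs before
computing, and writes outputs plus a provenance JSON (parameters, input
MD5 digests, package version — deliberately no timestamp, so repeated
runs of deterministic stages are byte-identical). All generators draw
through a seed-scoped RNG that restores the caller's state.

## Numerical choices and test scale

Closeness agreement with the independent BFS oracle is asserted to
1e-12 (pure graph arithmetic, no meaningful rounding); PDB round-trips
to the format's three decimals; burden identities exactly. The test
suite sizes were chosen to keep the full run near twenty seconds on one
core while still covering the regimes of interest: ~50 random
structures up to 200 residues against the brute-force contact oracle,
100 random graphs up to 100 nodes against the BFS oracle, 20 generator
seeds for hotspot recovery and for each imaging recovery property, and
1000 replicates for the gate calibration and threshold-semantics
properties.

## Known limitations

* The centrality measure and sd convention of any particular upstream
  RIN tool are assumptions (closeness, population sd) and are recorded
  in output metadata rather than hidden.
* Contact edges are untyped and unweighted; hydrogen bonds, salt
  bridges and π-stacking are not distinguished.
* The toy complex validates machinery, not biology (see above); the
  published four-of-seven candidate outcome for a real complex can only
  be reproduced from the original docking poses, which are consumed as
  input files, never recomputed.
* Multi-model PDB reading assumes all models share one atom table, the
  usual layout for docking ensembles.
* The KS gate with estimated parameters is conservative by design;
  interpret "parametric branch chosen" accordingly.
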