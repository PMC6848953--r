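---
title: "Methods: FTICR-MS metabolome profiling with fticrms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FTICR-MS metabolome profiling with fticrms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fticrms)
```

## Scope and model of the data

`fticrms` analyses peak lists from ultrahigh-resolution, direct-injection
negative-mode electrospray FTICR mass spectrometry of plant extracts. A
peak is a triple (m/z, intensity, S/N); compounds appear as singly charged
deprotonated ions, so a neutral of monoisotopic mass $M$ is observed at

$$ m/z = M - m_p, \qquad m_p = 1.00727646688\ \mathrm{Da}, $$

with the electron mass folded into the proton-mass convention. All mass
arithmetic uses monoisotopic atomic masses with at least nine significant
digits (`atomic_masses()`); anything coarser breaks sub-ppm reasoning.
Multiply charged species, isotopologues and adducts other than $\pm$H are
out of scope: at the resolution modelled here, singly charged
deprotonated ions dominate negative-mode spectra of polar plant extracts.

## Peak filtering and alignment

Peaks are kept when S/N strictly exceeds 7 and intensity is at least 100
(the peak picker's absolute default), inside the acquired window of
100–1200 m/z. The S/N comparison is strict because the assignment
criterion is stated as an inequality (S/N > 7); both thresholds are
arguments of `filter_peaks()`.

Cross-sample alignment (`align_samples()`) is greedy single-linkage over
the merged, sorted m/z list: a cluster break is placed wherever the gap
between neighbours exceeds the tolerance (default 1 ppm, the instrument's
mass accuracy). The consensus m/z is the intensity-weighted mean of the
cluster. A sample may contribute at most one peak per cluster; within-
sample collisions keep the peak nearest the consensus and log the other.
The procedure is deterministic and order-independent because it only ever
looks at the sorted merged list.

## Internal calibration on CH2 homologous series

Natural organic matter spectra contain long homologous series separated
by exactly one CH~2~ (14.015650 Da). `find_homologous_series()` chains
peaks whose successive spacing matches the repeat-unit mass within
tolerance (evaluated at the larger m/z) and discards chains shorter than
three members; each peak joins at most one chain.

Each series is *anchored*: its lowest-mass member is converted to a
neutral mass and assigned a formula, and the theoretical ladder follows
from the anchor mass plus integer multiples of the repeat unit. Three
numerical safeguards matter here, all consequences of how dense CHONSP
composition space is:

1. **CHO prior.** Within a relaxed window, the lowest-error candidate
   under drift is often a heteroatom-rich near-degenerate alternative
   (exchanging C$_7$+N+S for H$_2$+O$_8$ changes a mass by only
   0.18 mDa). Organic-matter CH~2~ ladders are overwhelmingly CHO
   compounds, so anchoring prefers the candidate with the fewest
   heteroatoms.
2. **Ambiguity rejection.** Above roughly 600 Da even two CHO
   compositions can sit a few mDa apart (C$_{18}$ vs H$_8$O$_{13}$ =
   3.4 mDa). When the heteroatom-poorest level of the anchor window
   contains more than one candidate the series is skipped rather than
   guessed.
3. **Robust trimming.** Calibrants are pooled across series and a Siegel
   repeated-median line (50% breakdown) is used to flag series whose
   median residual exceeds 0.75 ppm — a mis-anchored ladder is off by
   millidaltons, two orders of magnitude above the jitter floor — before
   the ordinary least-squares refit.

Calibration is two-pass: the first pass opens the anchor window to the
drift scale an instrument can plausibly accumulate (8 ppm unless the
configured tolerance is larger), fits a provisional model, and the second
pass re-anchors at the configured tolerance (default 3 ppm) on
drift-corrected masses, refitting against the *original* observed m/z so
a single linear model `ppm ~ m/z` is reported. The model is applied as
$m_{\mathrm{corr}} = m / (1 + e(m)\cdot 10^{-6})$, leaving intensities,
S/N and peak order untouched.

Under the synthetic error model (linear systematic drift plus Gaussian
jitter), drift up to 5 ppm — flat or mass-dependent — is reduced below
0.5 ppm RMS at a jitter of 0.2 ppm; the test suite pins this at seed
31 with 150 compounds and six planted ladders of eight rungs.

## Molecular formula assignment

For a neutral mass $M$ and tolerance $t$ ppm (default 1, strict),
`enumerate_formulas()` returns every formula over C, H, O, N, S, P within
the element bounds whose mass lies inside the window, subject to:

* $P \ge 1 \Rightarrow O \ge 4$ (phosphorus chemistry of metabolites:
  phosphate esters);
* DBE $= C - H/2 + N/2 + P/2 + 1 \ge 0$.

The default bounds (C 1–100, H 0–200, O 0–50, N 0–5, S 0–2, P 0–2) span
plant-extract organic matter at desk-scale cost. The enumerator loops
over the (C, O, N, S, P) grid — about 275,000 points under the default
bounds, cached per bounds signature — and solves H per query mass by
rounding, which makes a single query a vectorised window scan. A
brute-force full-grid oracle over small bounds verifies the enumerator
exactly on random masses in the test suite. The nitrogen (H-parity) rule
is deliberately *not* enforced: only the two rules above are part of the
published selection procedure, and radical-looking candidates are instead
handled by the selection and ambiguity reporting below.

Selection (`select_formula()`) is lexicographic: smallest $|$error$|$,
then fewest heteroatoms (N+S+P), then the formula string as a final
deterministic tie-break. Because CHONSP space contains sub-ppm
near-degeneracies above a few hundred Da, `assign_formulas()` also
reports `n_candidates`, the population of the tolerance window. Rows
with `n_candidates == 1` are *unique assignments* — on synthetic data
with 0.2 ppm jitter these recover the true formula essentially always,
and the acceptance suite requires $\ge$ 99% over a 500-compound sample.
Peaks whose window is empty are `"unknown"`; with `ambiguous = "drop"`
multi-candidate peaks are flagged `"ambiguous"` instead of resolved.
This mirrors the practical reality that exact-mass-only assignment
cannot be unique at high mass without isotope fine structure, and lets
downstream consumers choose their own strictness.

## Van Krevelen classification

Assigned formulas are placed at molar (O:C, H:C) coordinates and binned
into seven rectangular compound-class regions (lipid, unsaturated
hydrocarbon, protein, amino sugar, lignin, tannin, condensed aromatic),
applied in listing priority so the overlapping lipid/unsaturated-
hydrocarbon corner resolves deterministically to lipid. Endpoint
open/closed conventions follow the published inequalities exactly. Two
documented quirks: the condensed-aromatic range is read as
$0 \le$ O:C $\le 0.95$, treating a stray "200" in the printed range as a
typographical error (the only reading that yields a valid interval); and
no printed bin covers high-O:C sugars such as glucose (O:C 1, H:C 2), so
an opt-in carbohydrate bin (0.65 < O:C ≤ 1.1, 1.5 ≤ H:C ≤ 2.5) is
shipped but disabled by default — `vk_classes(carbohydrate = TRUE)`
enables it. Class abundances are count-based fractions over assigned
formulas (unassigned peaks excluded, unmatched formulas counted as
`unclassified`), so each sample's vector sums to one.

## Transformation networks

`build_network()` connects two m/z values when their difference matches
a named transformation within an absolute tolerance (default 1 mDa — a
mass *difference* needs an absolute window; ppm of a difference is not
meaningful). The shipped dictionary of 42 transformations (homologation,
hydration, carboxylation, redox, amination, sulfation, phosphorylation,
glycosylation, amino-acid residues, isoprene units, ...) is defined by
molecular formulas; every Δm is recomputed from the atomic-mass table at
load, never hard-coded. Edges are undirected, stored low→high for
reproducible serialisation, and parallel edges with distinct
transformation names are allowed. A sorted-scan finder keeps construction
near-linear; it is verified against an all-pairs double loop in the test
suite. `first_neighbors()` induces the subnetwork of seed nodes plus
everything one transformation away (unique-node semantics, so a neighbour
shared by several seeds counts once), and `annotate_network()` attaches
formulas and classes, labelling unassignable nodes `"unknown"`. Export is
GraphML (via igraph) plus plain edge/node CSV tables.

## Reference matching with isomer collapse

Direct injection cannot separate isomers: compounds sharing a molecular
formula share one exact m/z. `distinct_mz()` therefore collapses a
reference panel to distinct theoretical m/z values with isomer-group
bookkeeping, and `match_reference()` cross-checks observed peaks against
them in m/z space at 1 ppm (the matching tolerance is configurable since
the original workflow does not state one). The packaged panel of 17
antimicrobial compounds from a medicinal-plant comparison collapses to
15 distinct deprotonated masses, with two isomer pairs (C15H10O6 and
C21H20O11). Name-token helpers count "acid" and "glycoside/glucoside"
compounds — name-level summaries of a panel's chemical character.

## Class-abundance PCA

`class_pca()` performs column-mean-centered PCA by SVD on the samples ×
classes composition matrix. Compositional fractions share a scale, so
variance scaling is off by default (opt-in). Signs are fixed by making
the largest-magnitude loading of each component positive, which makes
output unique across BLAS implementations. `group_distances()` ranks
Euclidean centroid distances between sample groups in score space — a
quantitative reading of which plants cluster together. The decomposition
is verified against an independent covariance-eigendecomposition oracle
to 1e-8.

## The synthetic-data generator

`generate_sample()` emulates what this analysis assumes about real
negative-mode plant-extract spectra, with full ground truth per peak:

* CHONSP formulas drawn by rejection sampling inside the van Krevelen
  class windows to hit a target class mixture (default dominated by
  lignin-like compounds, as in moss extracts), with neutral masses in
  150–800 Da; heteroatoms (N up to 3 at 25%, S at 5%, P at 4% where four
  oxygens exist) leave the (O:C, H:C) coordinates untouched. Drawn
  compounds are even-electron molecules: H parity is adjusted so DBE is
  a non-negative integer, since radicals are not plausible metabolites.
* Mass error `observed = true × (1 + (a + b·m/z + ε)·10⁻⁶)` with linear
  systematic drift and Gaussian jitter ε (default sd 0.2 ppm, the sub-ppm
  accuracy regime).
* Log-normal intensities and S/N, so a small tail of real compounds
  falls below the S/N filter, as in practice.
* Planted structure: CH~2~ ladders spread across the mass range,
  transformation chains cycling named dictionary steps, and optional
  reference spike-ins; contaminant peaks are drawn at random m/z and
  *verified formula-free* by running the enumerator at a 2 ppm window at
  generation time, guaranteeing a true-negative set for the unknown
  path.
* Determinism: one seed; each stage draws from its own derived substream
  (seed + fixed offset), so changing one stage's draws does not cascade
  into the others. Identical specs produce byte-identical output.

What the generator does *not* emulate — chromatography, isotopic
envelopes, ion suppression, charge states, centroiding artefacts —
bounds what green tests mean: they validate the numerical pipeline, not
instrument physics. Companion generators produce class-structured
concentration tables (log-normal, rescaled to exact class totals, floored
at the 1 µM detection limit) and multinomial subclass count tables with
embedded totals consistent by construction.

## Pipeline orchestration

`run_pipeline()` executes the stages in fixed order — filter, per-sample
calibration, alignment, per-sample assignment, classification, network on
the consensus m/z set (with first neighbors of configured reference
seeds), reference matching, PCA — with explicit file hand-offs when an
output directory is given and a per-stage count report. Stage toggles are
validated (unknown keys rejected). Disabling a downstream stage never
changes upstream outputs. There is no shell entry point: the package is a
library, and the pipeline function plus the acceptance script are its
executable surfaces.

## Problem sizes and numerical choices

The shipped tests and acceptance runs use 40–500 synthetic compounds per
sample, three-sample cohorts, six to eight planted ladders, and networks
of up to ~400 nodes — sizes chosen so the full validation suite exercises
every code path in well under a minute each while keeping sampling error
small enough for 3-standard-deviation mixture checks. Tolerances used
throughout: 1 ppm (alignment, assignment, matching), 3 ppm (anchor,
second pass), 1 mDa (network), 0.75 ppm (series trim), 1e-9 Da
(conversion round-trips).

## Known limitations

* Exact-mass assignment is reported honestly as ambiguous where it is;
  no isotope-pattern or MS/MS evidence is modelled.
* The calibration model is linear in m/z in ppm space; higher-order ICR
  field effects are not modelled, and fewer than two trustworthy series
  leave a sample uncalibrated (with a warning).
* Van Krevelen classes are proxies: a rectangle in ratio space is not a
  compound-class assay, and the carbohydrate region is an opt-in
  extension.
* Network edges assert mass-difference compatibility, not reaction
  feasibility; first-neighbor candidates are hypotheses for assays, not
  identifications.
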