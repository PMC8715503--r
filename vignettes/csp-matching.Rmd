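---
title: "Matching HSQC peak lists and mapping chemical shift perturbations"
author: "cspmatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching HSQC peak lists and mapping chemical shift perturbations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cspmatch)
```

## The problem

Protein-observed NMR screening compares a 2D heteronuclear spectrum of the
free protein with the spectrum of a protein:ligand mixture. Residues whose
chemical environment changes on binding move their peaks; the magnitude of
the move — the chemical shift perturbation (CSP) — reports on proximity to
the binding event. The experimental bottleneck handled here is peak
*correspondence*: deciding which peak in the mixture spectrum is which peak
of the free protein, so that assignments made on the free protein can be
transferred and CSPs read off per residue. `cspmatch` works entirely from
picked peak lists; peak picking itself, exchange-regime analysis and
docking are out of scope.

The package assumes one set of peaks per spectrum. That holds for systems
in fast exchange, and for slow-exchange systems when the protein is
saturated with ligand; it also presumes the two lists have similar peak
counts (missing peaks are tolerated and reported as unmatched).

## The CSP metric

For a reference peak at $(\delta_H, \delta_{het})$ and a candidate target
peak, the distance is

$$\mathrm{CSP} = \sqrt{\Delta\delta_H^2 +
  \left(\Delta\delta_{het}/\mathrm{HetScale}\right)^2}$$

with $\mathrm{HetScale} = 5$ by default, applied identically to every
residue type (per-residue weighting such as a special glycine factor is a
minority practice and deliberately not used). For ¹H–¹³C spectra the same
formula applies with the ¹³C shift difference. Two conventions deserve
note:

* **No global prefactor.** Some CSP formulas carry a constant such as
  $1/\sqrt{2}$. Every algorithm in this package — greedy selection,
  optimal assignment, and both sequence-aware refinements — is invariant
  under multiplying all distances by a positive constant (the tests assert
  this), so such a factor changes no pairing and no accuracy; it would
  only rescale reported CSP magnitudes. We omit it and report the bare
  root-sum-of-squares.
* **HetScale as a divisor.** The heteronuclear difference is divided by
  HetScale, i.e. weighted by $1/5 = 0.2$, compensating the larger ppm
  dispersion of ¹⁵N/¹³C relative to ¹H.

## The four matching algorithms

All four operate on the $n \times m$ matrix of pairwise CSP distances and
return a one-to-one matching covering the shorter list; unmatched peaks of
the longer list are reported, never dropped silently.

**SD (Sorting Distances).** Greedy: take the globally smallest remaining
entry, fix that pair, delete its row and column, repeat. This emulates the
manual workflow — assign the unshifted peaks first, resolve the rest by
proximity.

**RA (Resource Allocation).** The same objective treated exactly: a
minimum-cost bipartite assignment (agents = reference peaks, tasks =
target peaks, cost = CSP), solved with the Hungarian algorithm in the
shortest-augmenting-path/potential formulation (implemented in C++; no
assignment solver is assumed from the R ecosystem). Rectangular matrices
are handled by transposition; `min(n, m)` pairs are always produced. This
is the *Proximity* mode: it needs no assignments.

**SDS (Sorting Distances Smart).** Pure cost minimisation mis-assigns when
a strongly shifted peak lands nearer to a neighbour's peak than to its
own. The empirical regularity that rescues such cases is that CSPs cluster
along the sequence: residues adjacent in sequence tend to move by similar
amounts. SDS therefore scores a candidate pair $(i, j)$ not by its raw
distance $d_{ij}$ but by $|d_{ij} - \overline{\mathrm{CSP}}_i|$, where
$\overline{\mathrm{CSP}}_i$ is the mean CSP of the residues within a
7-residue window centred on residue $i$ — excluding residue $i$ itself, so
a candidate cannot vote for itself. The profile starts at zero for every
residue (hence the first pass reproduces the SD ordering exactly), is
updated after every accepted pair, and whole passes are repeated, each
seeded with the previous pass's final profile, until two consecutive
passes produce the identical pairing.

**RAS (Resource Allocation Smart).** The *Smart* mode and default. Solve
RA; compute each residue's neighbourhood average
$\overline{\mathrm{CSP}}_i$ from that solution; rescale row $i$ of the
*original* cost matrix by $1/\max(\overline{\mathrm{CSP}}_i, \epsilon)$;
re-solve; repeat until the pairing is stable. Rows in high-CSP
neighbourhoods become cheap, letting the global optimiser accept the large
shift that the raw costs rejected. Reported CSPs are always recomputed
from the unscaled distances — they are physical quantities; the rescaling
is a search heuristic only.

### Numerical and tie-break policy

* Wherever a "smallest" element is selected, ties break by lowest
  reference row, then lowest target column, making every algorithm
  deterministic. SDS score ties additionally prefer the smaller raw
  distance first (so on identical lists the zero-distance diagonal wins).
* Convergence for SDS/RAS means the pairing is identical between
  consecutive passes/rounds; a cap of `max_iter = 50` guarantees
  termination, with `converged = FALSE` reported if hit. Detecting
  stability needs at least two passes, so `iterations` is ≥ 2 even on
  trivial input.
* The RAS divisor is floored at `epsilon` ($10^{-6}$ ppm) to avoid
  division by zero where a neighbourhood average is 0; when *all*
  averages are 0 the rescaling is uniform, the pairing cannot change, and
  RAS converges in round 2.
* SDS updates its profile with accepted pairs overwriting the previous
  pass's values; residues not yet (re-)assigned in the current pass
  contribute their previous-pass CSPs to the averages. The alternative —
  using only current-pass values — discards information early in a pass
  for no benefit.
* Smart methods require reference assignments; partially assigned
  reference lists have their unassigned peaks neglected (with a warning),
  since a peak without a sequence position has no neighbourhood.

## Classification and structure mapping

`classify_residues()` implements the whole-protein statistical cut used to
make mapping reproducible rather than threshold-by-eye: compute the mean
and standard deviation of all per-residue CSPs; CSPs more than 4 SD above
the mean are likely outliers and are excluded from highlighting; more than
2 SD = highly perturbed; at least 1 SD but not more than 2 SD = moderately
perturbed. Choices the wording leaves open, fixed here:

* **SD convention:** population SD (divide by $N$) — a descriptive
  statistic of the full residue set, not a sample estimate.
* **Boundaries:** "exceeding by twice the SD" is strict ($>$); "at least
  one SD" is inclusive ($\geq$); a degenerate profile with SD = 0 maps
  everything to background rather than flagging an unperturbed protein
  wholesale.
* **Recomputation:** the protocol lists computation before outlier
  removal and never mentions recomputing, so by default the mean/SD are
  computed once. Because recomputing after outlier removal genuinely
  changes borderline sets — small-CSP systems can gain or lose several
  highlighted residues through one or two assignments — both behaviours
  are available (`recompute_after_outliers`, default `FALSE`).

`pymol_script()` transcribes a classification into viewer commands: heavy
atoms of highly perturbed residues as red spheres at sphere scale 1.0,
moderately perturbed as pink spheres at 0.7, gray cartoon backbone, green
ligand (sticks for small molecules, cartoon for peptides). Residue numbers
are enumerated individually, never as ranges, so the script is a faithful
string-level image of the classification; coordinates are never parsed and
rendering is the viewer's job.

## Accuracy scoring

When the target list carries independently curated assignments,
`score_accuracy()` reports the percentage of predicted pairs whose target
peak is curated to the same residue as the reference peak. Pairs whose
target peak no human assigned are excluded from the denominator — the
algorithm is not penalised for them — and reported separately. Accuracies
are given at full precision and rounded half-up to integers for
benchmark-table comparison. Note the combinatorial grain: a single
transposition breaks two assignments, so on 10 scored pairs one swap costs
20 points.

## The synthetic generator

`simulate_hsqc_pair()` provides ground-truthed test data emulating an
amide HSQC: peaks uniform over ¹H 6–11 ppm × ¹⁵N 100–135 ppm, a planted
contiguous binding site whose residues are displaced by up to
`site_csp_scale`, off-site residues by up to `noise_csp_scale`, with the
site magnitude tapering linearly over two residues on each side — the
sequence-clustering structure the Smart algorithms exploit. Displacement
directions are isotropic in the $(\Delta\delta_H,
\Delta\delta_{het}/\mathrm{HetScale})$ plane, so planted magnitudes are
controlled directly in CSP units; magnitudes are drawn uniformly between
half the scale and the scale. A rejection sampler enforces a minimum
pairwise peak separation (`min_separation`), and `drop_fraction` removes
target peaks to emulate broadening beyond detection.

Default study conditions, chosen once as a realistic weak-binder screen on
a well-dispersed 100-residue protein: site of ~12% of the sequence
(residues 41–52 at $n = 100$), `site_csp_scale` 0.08 ppm,
`noise_csp_scale` 0.01 ppm, `min_separation` 0.25 ppm, no dropped peaks.
Because the maximum displacement (0.08) is below half the separation floor
(0.125), each target peak provably remains nearest to its true partner and
the planted truth is the per-row minimum of the cost matrix — hence all
four algorithms recover it exactly, which the test suite asserts over 20
seeds. Harder regimes (tests and the acceptance script use
`site_csp_scale` 0.35, `noise_csp_scale` 0.02, `min_separation` 0.12)
allow genuine confusions and exercise the ranking among algorithms.

What the generator does *not* emulate — and therefore what passing tests
do not demonstrate about real data: peak overlap and missing assignments
in crowded regions, intensity changes and line broadening in intermediate
exchange, spectra where both states contribute peaks, correlated
displacement directions within a site, and referencing offsets between
spectra. Results on experimental lists will degrade where those effects
dominate.

### A deterministic case where sequence context matters

The test suite carries a 9-peak fixture constructed so that the raw-cost
optimum is wrong: residues 7–9 form a 0.30-ppm binding-site cluster;
residue 10 (also in the site's window) has its true partner 0.30 ppm away
but a decoy — the true partner of background residue 2 — only 0.03 ppm
away, and the swapped pairing undercuts the truth in total cost (1.29 vs
1.30 ppm). SD and RA both take the swap (7/9 correct); the neighbourhood
averages (≈0.01 ppm around residue 2, ≈0.30 ppm around residue 10) pull
SDS and RAS onto the planted truth (9/9). The geometry was solved by hand
(circle intersections in the CSP plane) and the key distances are asserted
in the tests.

## Problem sizes and performance

The Hungarian kernel is $O(n^2 m)$ in C++ and handles the 50–250-peak
lists of practical HSQC work in milliseconds; SDS is $O(n^3)$ per pass in
vectorised R and stays interactive at those sizes. The test suite runs
~1000 brute-force oracle comparisons at $n \le 7$ and twenty 100-residue
recovery replicates in well under a minute; the acceptance script's
benchmark uses twelve 100-residue systems. These sizes were chosen to
exercise the asymptotics that matter at instrument scale while keeping the
suite fast to iterate on.

## Known limitations

* Assignment transfer is only as good as the fast-exchange/saturation
  assumption; with two visible state ensembles the one-set-of-peaks model
  is wrong.
* The accuracy denominator ignores uncurated target peaks, so reported
  percentages are conditional on the curated subset.
* The 4 SD outlier screen can misfire on very small proteins (few
  residues inflate the SD); `classify_residues()` refuses profiles with
  fewer than two residues but applies no small-sample correction beyond
  that.
* CSP magnitudes are convention-dependent (no $1/\sqrt{2}$); compare
  magnitudes across tools only after normalising conventions. Pairings
  and accuracies are convention-free.
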