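# cspmatch

Automated chemical shift perturbation (CSP) analysis for protein-observed
NMR ligand screening, working from peak lists alone.

In a protein-observed screen, a 2D heteronuclear spectrum (typically a
¹H–¹⁵N HSQC) of the free protein is compared with the spectrum of the
protein:ligand mixture: peaks of residues near the binding site move. With
dozens of ligands and hundreds of peaks, tracking which peak went where by
hand is slow and error-prone. `cspmatch` automates the step in between peak
picking and structural interpretation: given the two picked peak lists, it
decides which target peak corresponds to which reference peak, transfers
the residue assignments of the free protein to the mixture spectrum, and
reports the per-residue CSPs

```
CSP_i = sqrt( Δδ_H² + (Δδ_het / HetScale)² )        HetScale = 5.0 by default
```

where Δδ_H and Δδ_het are the ¹H and ¹⁵N (or ¹³C) shift changes of residue
*i* in ppm. It is intended for spectroscopists running fragment or ligand
screens who have peak lists (csv exports from any NMR processing software)
and want binding-site maps without manual peak tracking. The method assumes
one set of peaks per spectrum, i.e. fast exchange or slow exchange at
ligand saturation.

## Matching algorithms

Peak correspondence is a one-to-one matching between the two lists that
covers the shorter list. Four algorithms are provided via
`match_peaks(ref, tgt, method = ...)`:

| method | idea | needs assignments? |
|--------|------|--------------------|
| `sd`  | greedy: repeatedly match the two closest unmatched peaks | no |
| `ra`  | minimum-cost bipartite assignment over the CSP matrix (Hungarian algorithm) — the *Proximity* mode | no |
| `sds` | greedy, but a candidate pair is scored by the deviation of its CSP from the average CSP of the residue's sequence neighbours (window of 7), iterated to convergence | reference |
| `ras` | repeated optimal assignment on a matrix whose rows are rescaled by the inverse neighbourhood-average CSP — the *Smart* mode (default) | reference |

The Smart variants exploit the empirical observation that residues adjacent
in sequence tend to show CSPs of similar magnitude, which rescues cases
where a strongly shifted peak lands closer to a neighbour's peak than to
its own. Reported CSPs always come from the raw distances; the rescaling is
only a search heuristic.

Downstream, `classify_residues()` applies a whole-protein statistical cut
(mean and SD of all CSPs: > 4 SD above the mean = outlier, > 2 SD = highly
perturbed, ≥ 1 SD = moderately perturbed) and `pymol_script()` turns the
classification into a PyMOL script (red spheres at scale 1.0 for high, pink
at 0.7 for moderate, gray cartoon, green ligand) for binding-site mapping.
`score_accuracy()`/`compare_labeled()` score a matching against curated
target assignments, and `simulate_hsqc_pair()` generates realistic paired
peak lists with a planted ground truth for validation.

## Worked example

Simulate a 100-residue protein whose residues 41–52 form a binding site
with CSPs up to 0.35 ppm in a tightly packed spectrum, then match with the
Smart algorithm and map the perturbed residues:

```r
library(cspmatch)
sim <- simulate_hsqc_pair(n_residues = 100, site_csp_scale = 0.35,
                          noise_csp_scale = 0.02, min_separation = 0.12,
                          seed = 11)
fit <- match_peaks(sim$ref, sim$tgt, method = "ras")
summary(fit)
#> Peak match (RAS): 100 pairs, total CSP 4.8053 ppm
#>   reference 'free protein (simulated)' (100 peaks) vs target 'protein:ligand (simulated)' (100 peaks), HetScale 5
#>   3 iteration(s), converged
#>   CSP per residue (n = 100): min 0.0101, median 0.0157, max 0.3429 ppm
#>   largest CSPs: 48=0.343, 46=0.307, 51=0.282, 52=0.269, 50=0.261
#>   accuracy vs curated target assignments: 100.0% (100/100)

classify_residues(coef(fit))
#> CSP classification of 100 residues (mean 0.0481, SD 0.0812 ppm)
#>   outlier      0
#>   high        11: 41, 42, 43, 44, 45, 46, 48, 49, 50, 51, 52
#>   moderate     2: 40, 47
#>   background  87
```

Every matched pair is correct (100/100), the largest CSPs sit inside the
planted site, and the >2 SD / ≥1 SD cuts recover the site almost exactly
(residues 40–52 highlighted vs 41–52 planted). `plot(fit)` draws the
per-residue CSP histogram with the threshold lines;
`pymol_script(classify_residues(coef(fit)))` emits the viewer commands.

## Command line

A thin wrapper in `inst/cli/cspmatch` exposes the same pipeline as
subcommands:

```sh
cspmatch simulate --n-residues 100 --site 41:52 --seed 1 --out-dir sim/
cspmatch match --mode smart --labeled --out-dir out/ sim/ref.csv sim/tgt.csv
cspmatch map --chain A --ligand organic --out-dir map/ out/csp_profile.csv
```

`match` accepts `--mode smart` (RAS; reference must be assigned) or
`--mode proximity` (RA; no assignments needed), `--algorithm` to pick
sd/sds/ra/ras explicitly, `--hetscale`, `--window` and `--labeled`. Every
run writes a JSON manifest recording the mode, algorithm, parameters and
file paths needed to reproduce it. Exit codes: 0 success, 1 input error,
2 internal error.

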