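---
title: "Fingerprint search and chain tracing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprint search and chain tracing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natrace)
```

## The problem

Interpreting a nucleic-acid electron-density map means deciding where the
ribose sugars and phosphate groups sit and how they link into chains.
`natrace` does this in two stages, both built for speed: (i) a fingerprint
search locates candidate sugar and phosphate fragments near a view centre,
and (ii) the candidates are grown into backbone chains using a database of
nucleotide conformers taken from a reference structure.

## The fingerprint model

A rigid fragment is described by paired probe points in its local frame:
*high* probes $\delta x^h_i$ where density must be high if the fragment is
present, and *low* probes $\delta x^l_i$ where it must be low (the counts
are constrained to be equal, $n$ pairs). For a placement with rotation $R$
and translation $t$, two scores over the map $\rho$ are used:

$$ s_\mathrm{mean} = \frac{1}{n}\sum_i \rho(R\,\delta x^h_i + t)
   - \frac{1}{n}\sum_i \rho(R\,\delta x^l_i + t) $$

$$ s_\mathrm{minmax} = \min_i \rho(R\,\delta x^h_i + t)
   - \max_i \rho(R\,\delta x^l_i + t) $$

$s_\mathrm{mean}$ is the sensitive score; $s_\mathrm{minmax}$ is crude but
has the property that it can only get worse as probe pairs accumulate, so
scoring a placement can stop the moment the partial score drops below a
threshold. The search (`search_local()`) exploits this three ways: probe
offsets are rounded to the nearest grid vector once per orientation so
density lookups are array reads; translations whose *first* high-probe
density is below mean + 1 sigma of the map are eliminated before any
scoring; and a running best-list of size `n_best` keeps the live threshold
at the worst retained score. Survivors are re-scored with trilinearly
interpolated $s_\mathrm{mean}$ and placements with
$s_\mathrm{mean} \le 0$ are dropped, which also disposes of flat or
featureless regions where every score ties at zero.

The best-list update is continuous rather than periodic: the threshold is
raised every time the list changes. This is strictly tighter pruning with
an identical final answer, which is what the test-suite's exhaustive
oracle verifies placement-by-placement.

Orientations are sampled on a ZYZ Euler grid with uniform $\beta$ rows and
the $\alpha$ count scaled by $\sin\beta$ (the two angles degenerate at the
poles). At the default 18° step this gives 2680 orientations with an
empirical covering radius of about 14°. Several schemes of this size are
defensible; the count is validated as a range rather than an equality.

## Deriving the probe points

Probe points are derived from an ensemble of conformers superposed on the
conserved atoms of the search fragment (`derive_default_targets()`):

* uncommon conformations are pruned by repeatedly removing the fragment
  whose probe atom (O2′ for sugars; C5′ and C3′ for phosphates) lies more
  than 1 Å from the ensemble mean, recomputing the mean after each
  removal (the worst offender goes first, which makes the result
  order-independent);
* a density map is synthesized per conformer and the pointwise minimum
  and maximum maps are formed. High values in the minimum map are density
  conserved across every conformer; low values in the maximum map are
  conserved holes;
* high probes are placed on the named fragment atoms — C1′ (first, the
  anchor of the immediate-elimination rule), C2′, C3′, C4′, O4′, C5′, O3′
  and the base anchor N9 for the sugar; P (first), OP1, OP2, O5′, O3′ for
  the phosphate;
* low probes follow a rising contour on the maximum map: the first sits
  at its minimum within 6 Å of the fragment centre, and as the contour
  rises a probe is added whenever a disconnected density region first
  appears, subject to a 1.5 Å separation from existing probes. Counts are
  equalized by truncating the longer list.

The shipped targets (`default_targets()`, a JSON fixture labelled
synthetic) come from 50 perturbed trinucleotides (0.25 Å RMS, ring atoms
at half amplitude). With them, every high probe's minimum-map value
exceeds every low probe's maximum-map value by a wide margin.

## Growing chains

Sugar hits become nucleoside seeds directly (the template is placed by the
hit's rotation and translation; the terminal phosphate is arbitrary until
growth fixes it). Phosphate hits need one extra step: every adjacent pair
in the conformer database is superposed via its intervening phosphate
group, both flanking sugars are scored with $s_\mathrm{mean}$, and the
best pair is kept as a binucleotide seed.

Growth alternates 3′ and 5′ extension. Candidates come from superposing
each database sugar ring on the terminal ring and extracting its
neighbour; each is scored as sugar $s_\mathrm{mean}$ plus intervening
phosphate $s_\mathrm{mean}$, interpolated. The best candidate is accepted
if its **sugar** score exceeds the stopping threshold — the phosphate
score ranks candidates but does not gate them — and if its C1′ is at
least 3 Å from every C1′ already in the trace. The anti-backtrack rule is
ours: the strongest candidate at any end is usually the retrace of the
previous nucleotide, and without the rule the grower oscillates.

The stopping threshold is calibrated per map (`calibrate_threshold()`):
100 000 uniformly random placements are scored with $s_\mathrm{mean}$ and
the threshold is the empirical 99.9th percentile, so a random placement
exceeds it with probability 0.1%. Calibration is done once per map, not
per region.

Chains shorter than three nucleotides are rejected. Overlapping traces
(two or more consecutive C1′ pairs within 1 Å, same 5′→3′ direction) are
merged score-greedily: traces are taken in decreasing total-score order,
a lower-scoring trace may only extend the ends of the chain it overlaps,
and at branch points the higher-scoring continuation wins. Reversed-chain
duplicates do not satisfy the same-direction criterion and are left as
separate chains, as happens in practice with real maps.

## Synthetic data: what it emulates and what it does not

The package is exercised end-to-end on synthetic fixtures built by
`make_fixture()`:

* **Geometry.** An idealized ribonucleotide template (main-chain atoms
  plus O2′ and N9) placed compatibly with A-form helical symmetry —
  32.7° twist, 2.81 Å rise, C1′ at 9.5 Å from the axis, O3′–P link
  1.60 Å. Helices are generated by iterating the helical operator.
* **Density.** Each atom contributes one isotropic Gaussian of integrated
  weight equal to its electron count, with variance
  $B/(8\pi^2) + \sigma_\mathrm{res}^2$ and $\sigma_\mathrm{res}$ = 0.8 Å,
  giving maps that behave like roughly 2.5 Å data; contributions are
  truncated at 4.5 Å and wrapped over an orthogonal P1 cell. The default
  grid step is 0.5 Å (behaviour is also exercised at 0.7 Å).
* **Phase error.** `degrade_map()` Fourier-transforms the map, adds to
  each coefficient's phase a von Mises deviate whose concentration solves
  $E[\cos\Delta\varphi] = m$ (the standard acentric relation), with
  per-coefficient $m$ drawn as mean FOM + N(0, 0.1) clipped to [0, 1],
  and transforms back. Friedel mates get opposite shifts so the map stays
  real; amplitudes are preserved exactly. A mean FOM of 1 leaves the map
  untouched, 0 randomizes the phases.

What this does *not* emulate: measurement noise in amplitudes, solvent
and bulk-solvent contributions, crystal packing contacts, non-helical
folds, base pairing (bases are reduced to their N9 anchor), resolution-
and magnitude-dependent FOM profiles, and non-P1 symmetry. Passing the
recovery tests therefore shows the machinery is self-consistent on
helical RNA-like density with realistic phase error — not that the
shipped synthetic targets match the discrimination of targets derived
from a real high-quality structure.

## Numerical choices and degenerate inputs

* Nearest-node lookups round half away from zero; the same rule is used
  in the compiled search and the R oracle so they agree bit-for-bit.
* Ties in the search best-list keep the earliest candidate in scan order;
  final hits are ordered by $s_\mathrm{mean}$, then distance to the view
  centre, then rotation index, making every run reproducible.
* Ties in binucleotide seeding resolve to the lowest database index.
* A constant map calibrates to a threshold of exactly 0 and is flagged;
  searches on all-zero maps return no hits because re-scored
  $s_\mathrm{mean}$ must be strictly positive.
* Superposition uses the SVD form of least-squares fitting with the
  determinant sign forced to +1; mirrored point sets are fitted with
  non-zero residual rather than reflected. Collinear point sets are
  flagged.
* The empirical quantile uses the k-th largest score with
  $k = \lceil n \cdot p \rceil$, the value exceeded by fewer than $k$
  samples.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `radius` | 6 Å | translation search radius around the view centre |
| `step_deg` | 18° | rotation search step (2680 orientations) |
| `n_best` | 50 | search best-list size per target; the value is a design choice balancing seed diversity against growth cost |
| `threshold_samples` | 100 000 | random placements for threshold calibration |
| `tail_prob` | 0.001 | calibrated exceedance probability |
| `min_chain` | 3 | minimum chain length kept |
| `match_radius` | 1 Å | C1′ radius for trace merging |
| `sigma_res` | 0.8 Å | synthetic-map resolution blur |
| `b_iso` | 20 Å² | synthetic-map displacement parameter |

Problem sizes used by the test-suite and the acceptance script — a 12-mer
helix in a ~34 × 34 × 50 Å cell at 0.5 Å spacing, a 32³ oracle-equivalence
map, 100 000-placement calibrations and 10 000-placement checks — were
chosen so a full run completes in a few minutes on one core while leaving
every statistical check comfortably powered.

## Known limitations

* Whole-cell search treats the supplied map as a full P1 cell; symmetry
  expansion is the caller's job.
* Bases are neither identified nor built; sugar puckers are only implicit
  in the backbone conformation. Output residues are written as U with a
  REMARK.
* The default conformer database is synthetic (an ideal A-form helix plus
  perturbed copies). It suffices for helical density; for real maps a
  database built from a high-quality reference structure via
  `build_database()` is strongly preferable.
* Merging is score-greedy and does not re-grow chains after merging.
* With badly degraded phases (FOM ≲ 0.4) the tracer can build short
  chains in spurious density; they pass the length filter but cover
  nothing — the same failure mode seen with real low-quality maps.

## A worked check

```{r, eval = FALSE}
fix <- make_fixture(helix_spec(12), fom = 0.8)
db <- default_database()
center <- colMeans(fix$fragments[[6]][c("C1'", "C2'", "C3'", "C4'", "O4'"), ])
traces <- trace_all(fix$grid, db, center = center, seed = 1)
c1_coverage(traces, fix$fragments)
```

On this fixture the tracer rebuilds the full helix (coverage 100%,
phosphorus error ≈ 0.3 Å); at FOM 0.6 coverage drops but stays well above
half, and the trend with decreasing FOM is monotonic.
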