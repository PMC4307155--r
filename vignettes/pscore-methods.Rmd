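---
title: "Peak scoring for GC-MS metabolite identification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak scoring for GC-MS metabolite identification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pscore)
```

This vignette documents the model behind `pscore`, the parameters that
matter, the synthetic-data generator used to test it, and the design
decisions taken where the problem left room for choice.

## The scoring model

A GC-MS sample is a scan grid: strictly increasing retention times
(minutes) with one intensity per nominal m/z per scan. Readings are
binned to integer mass by rounding half-up and summing within a scan —
the instruments this targets scan unit masses (typically m/z 10–300) —
and scans are the time resolution throughout: all scores are computed
from observed scan intensities, never from interpolated values.

The spectral library describes each target compound by its expected
retention time $E_{RT}$, the m/z of its four most abundant ion mass
fragments $M_1 \dots M_4$, and the relative intensities
$R_i = I_i / I_1$ for $i = 2,3,4$ (so $0 < R_i \le 1$ by construction).
Compounds with fewer than four usable fragments have the existing
fragments recycled cyclically in abundance order — a two-fragment
compound is analysed as $(M_1, M_2, M_1, M_2)$ — so the engine always
sees four slots. The recycled copy of $M_1$ carries ratio 1 and a
recycled copy of $M_i$ carries $R_i$; this cyclic ratio assignment is
our choice (the recycling rule itself fixes only the fragment order),
and it is idempotent on complete entries. Using exactly four fragments
is deliberate: beyond the top four, fragment intensities of volatile
metabolites sit near the noise floor and degrade identification more
than they help.

For a compound $M$, candidate retention times are the apices of the
$M_1$ extracted ion trace inside the closed window
$[E_{RT} - w,\, E_{RT} + w]$: scans strictly greater than both
neighbours, with plateaus reported at their first scan and series
endpoints compared against their single neighbour. Candidates are
defined by $M_1$ alone because $t_j$ is, by definition, where the
quantifier fragment's peak is observed; the other fragments influence
the score, not the candidate set.

Each candidate $t_j$ receives three stage scores:

* **Stage 1 — co-occurrence, 0–12.** Each fragment earns up to three
  points: its intensity at $t_j$ is positive; one of its apices lies
  within one scan step of $t_j$; and its intensity at $t_j$ equals its
  maximum over the neighbourhood $t_j \pm \Delta$ (intersected with the
  search window).
* **Stage 2 — spectral similarity, 0–3.** The observed ratio
  $\hat R_i = \hat I_i / \hat I_1$ earns a point when it lies in the
  closed interval $[f R_i,\ (2-f) R_i]$ defined by the match factor
  $f \in (0,1)$. The interval is symmetric in the ratio
  $\hat R_i / R_i$ around 1, and it shrinks as $f \to 1$. Ratios are
  undefined when $\hat I_1 = 0$ and score 0.
* **Stage 3 — co-elution, 0–3.** Fragments of one compound rise and
  fall together, so over $t_j \pm \Delta$ each fragment trace should be
  close to proportional to $M_1$'s. Each of the three fragment/$M_1$
  Pearson correlations earns a point when $\rho \ge ct$. With fewer
  than 3 scans in the neighbourhood, or zero variance in either series,
  the correlation is undefined and scores 0 — the conservative choice.

The compound's identification is the candidate maximising
$S = S_1 + S_2 + S_3$ (ties: smallest $|t_j - E_{RT}|$, then earliest
$t_j$); its abundance is the $M_1$ intensity at that scan. After all
compounds are scored, candidates of different compounds landing on the
same scan are resolved in favour of the highest score (ties: smallest
RT error, then compound name); losers are reported absent rather than
reassigned, since a displaced second-best RT would have lost its own
contest for a reason.

### The Stage-1 dominance neighbourhood

The condition "intensity equal to the highest observed for the
fragment" needs a region over which that maximum is taken. Taking it
over the whole search window $[E_{RT} \pm w]$ makes the score of a
clean, well-separated peak depend on unrelated compounds that share a
fragment m/z elsewhere in the window — with the bundled library, the
three dimethylbenzene isomers share $M_1 = 91$ within 0.3 min, so under
a whole-window reading the weaker isomers could never reach the maximum
score no matter how clean their signal. We therefore assess dominance
over the peak's own neighbourhood $t_j \pm \Delta$: a perfect isolated
peak always earns the point, while genuinely coeluting signals (within
$\Delta$) still compete. This also keeps the stage's degradation
behaviour: a fragment apexing 0.2 min away from $t_j$ is still rising
or falling across $t_j \pm \Delta$, fails both the apex and dominance
conditions, and contributes only its presence point.

## Parameters

| parameter | meaning | units | default |
|---|---|---|---|
| $w$ | search half-window around $E_{RT}$ | min | 0.5 |
| $f$ | match factor; ratio interval $[fR, (2-f)R]$ | — | 0.70 |
| $ct$ | minimum fragment/$M_1$ Pearson correlation | — | 0.95 |
| $\Delta$ | correlation / dominance neighbourhood half-width | min | 0.07 |
| $s_t$ | total-score threshold for the cutOff table | — | 13 |

$f$, $ct$ and $s_t$ defaults are the values used in the validation runs
the method was introduced with; $\Delta = 0.07$ min is the empirically
optimal neighbourhood there, roughly the width of a sharp capillary-GC
peak. $w$ has no published value; 0.5 min is our default, wide enough
for run-to-run RT drift on a 35-min programme and narrow enough to keep
candidate sets small, and it is user-overridable. Match factors quoted
on the 0–100 scale (e.g. 70) are divided by 100 on input. Raising $f$
or $ct$ can only remove points (monotonicity, verified by tests), so
thresholds can be tightened without re-running earlier stages.

Interval conventions: RT windows, match-factor intervals and the
$\Delta$ neighbourhood are all closed, so a scan or ratio exactly on a
boundary counts. Degenerate inputs follow explicit conventions rather
than erroring: an absent m/z yields an all-zero trace, an all-zero
window yields no candidates, and undefined ratios or correlations score
zero.

## Reporting

Per-sample identifications are merged by compound name into the Total
table (abundance, assigned RT and score per compound × sample).
Missing cells are `NA`, distinct from an abundance of zero: zero means
"identified with $M_1$ measured at zero", `NA` means "not identified or
removed by the score cut" — the distinction downstream statistical
tools expect. The cutOff table keeps, cell by cell, abundances whose
score reaches $s_t$, dropping compounds with no surviving cell; rows
are filtered cellwise rather than whole-compound because a compound
confidently present in some samples should not vanish everywhere on the
strength of one bad sample.

The biomarker screen mirrors standard two-condition practice: a
prevalence filter (detected in at least `min_per_group` samples of
*every* condition, default 2) removes sporadic identifications, then a
two-sided Welch $t$-test per compound compares conditions on raw
abundances. No multiple-testing correction is applied by default —
raw $p < 0.05$ flags a biomarker, matching the screening convention
this reproduces — with Benjamini–Hochberg available as an option.
Identification error against a known truth is summarised as false
positives $100\,|reported \setminus truth| / |reported|$ (0 when
nothing is reported) and false negatives
$100\,|truth \setminus reported| / |truth|$.

## The synthetic-data generator

Real validation of an identification algorithm needs samples with known
content. The generator emulates a standard-mixture experiment: each
present compound contributes one Gaussian peak per fragment, centred at
$E_{RT}$ plus an optional offset and scaled by the library ratio, on a
regular scan grid, with optional additive Gaussian detector noise
(clipped at zero) and optional interferent peaks not tied to any
compound. Peak centres are snapped to the nearest scan so that,
noise-free, the generated $M_1$ apex height equals the specified height
*exactly* and the fragment ratios at the apex equal the library ratios
exactly — which is what makes "a perfect signal scores 18" a testable
identity rather than an approximation.

Defaults, chosen once as typical of capillary GC with a quadrupole
detector: peak $\sigma$ = 0.02 min, scan interval 0.005 min (so the
$\Delta$ = 0.07 neighbourhood holds ~28 scans), apex heights log-uniform
in $[10^4, 10^6]$ detector units, noise off. Two-condition cohorts add
per-sample log-normal height variation (sd 0.2 on the log scale, a
~20% biological CV) and multiply the heights of designated compounds by
a fold-change in condition B. The simulation studies in the test suite
use 5 + 5 samples, detector noise sd 100, and a 3-fold effect on one
compound — sizes at which one cohort analyses in about a second.

What the generator does *not* emulate: chromatographic tailing,
retention-time drift within a run, matrix background, correlated
(intensity-proportional) noise by default, and spectral overlap beyond
what shared library fragments and explicit interferents produce.
Passing tests therefore demonstrate correctness of the scoring
machinery and realistic statistical behaviour of the pipeline, not
instrument-grade robustness; on real data the score threshold $s_t$
absorbs much of what the generator idealises away.

## Numerical choices and limitations

* Apex detection uses strict inequality against both neighbours with
  deterministic plateau (first scan) and endpoint handling; all
  tie-breaks (candidate selection, conflict resolution, recycling
  order) are deterministic, so repeated runs are bit-identical.
* Conflict resolution treats "same RT" as "same scan"; a tolerance
  window across compounds would need a cross-compound clustering step
  the per-scan data model does not require.
* Equality with the neighbourhood maximum in Stage 1 is exact floating
  point equality; both values come from the same stored trace, so no
  tolerance is needed.
* The library is trusted after validation: `validate_library()` flags
  invariant violations and warns when two compounds share $M_1$ within
  0.1 min (coelution risk for Stage 3), but the engine does not
  second-guess entries.
* Retention *indices* (relative to alkane standards) are not
  supported; matching is on raw RT only, so libraries must come from
  the same chromatographic method as the samples.
* Quantification uses the $M_1$ height at one scan, not peak area;
  comparisons across samples are consistent (always the same fragment)
  but absolute values are detector units, not concentrations.

## Problem sizes used in the test suite

Unit fixtures use short grids (a few hundred scans). The end-to-end
simulations use the full 13-compound library on its native 6–39 min
grid at 0.005 min/scan (~6,600 scans): one noise-free full-recovery
run, 200 random two-compound samples cross-checked scan-by-scan
against a brute-force oracle, and 100 replicate 5-vs-5 cohorts for the
biomarker power/type-I study. These sizes give stable pass/fail
behaviour (binomial noise on 100 replicates is ±3 at the 90% power
mark) while keeping a full suite run to a few minutes.
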