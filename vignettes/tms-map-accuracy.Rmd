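---
title: "Bootstrap accuracy assessment of grid-based TMS motor maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrap accuracy assessment of grid-based TMS motor maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmsmapr)
```

## The problem

Navigated TMS motor mapping stimulates a grid of cortical targets and records
the motor evoked potential (MEP) of a muscle at each stimulus. Summary
parameters of the resulting map — its area, weighted area and centre of
gravity (COG) — are used to track the state of the motor system over time.
Two statistical facts complicate their use:

* MEP amplitudes are extremely variable from trial to trial (heavy-tailed,
  spanning orders of magnitude), so any parameter computed from a finite
  number of stimuli per grid cell is noisy **and** possibly biased;
* responses below the detection threshold $\theta$ (50 µV peak-to-peak) are
  unrecordable — the data are **left-censored** at $\theta$.

`tmsmapr` quantifies how the accuracy of each parameter depends on the number
of stimuli per cell, and whether day-to-day parameter changes exceed what
within-session MEP variability alone would produce.

## Data model

A map is a `grid_spec` (rows × columns of square cells, default 7 × 7 cells
of 7.63 mm — a 53 mm grid) plus an ordered amplitude sample per cell. A
censored sample records only the flag; its amplitude is unknown in
$[0, \theta)$. Per-cell summaries use the conservative convention that
censored responses contribute 0 to means and maxima; consequently a cell mean
$\ge \theta$ implies at least one suprathreshold response. "Suprathreshold"
is $\ge \theta$ everywhere (the threshold is inclusive by the protocol's
definition); one convention is applied consistently.

Coordinates are planar (mm): the navigated system's curved peeled surface is
flattened, which is an acceptable approximation at the 53 mm scale of the
grid.

## The eight parameters

With cell area $a$, per-cell mean $\bar{A}_i$ (censored = 0), maximum
$M_i$, and suprathreshold fraction $\hat{p}_i$:

1. area of cells with $\bar{A}_i \ge \theta$;
2. area of cells with at least one suprathreshold MEP ($M_i \ge \theta$);
3. area of cells with more than half suprathreshold MEPs
   ($n_{s,i} > n_i/2$, i.e. $\ge 6$ of 10, $\ge 5$ of 9 — the strict
   majority of each cell's own sample, which produces the even/odd pattern
   in the number of stimuli);
4. amplitude-weighted area ("map volume") $a \sum_i \bar{A}_i$;
5. probability-weighted area $a \sum_i \hat{p}_i$;
6. – 8. COG $\sum_i w_i \mathbf{r}_i / \sum_i w_i$ with weights
   $w_i \in \{\bar{A}_i, M_i, \hat{p}_i\}$.

Weighted areas and COGs sum over **all** cells without an additional
thresholding step (non-responding cells contribute zero weight); whether the
original map-volume definition restricted the sum is not documented, and the
all-cells convention is the natural one for a linear statistic.

## Bootstrap accuracy assessment

`resample_map()` draws, independently per cell, $k$ amplitudes with
replacement from the measured ones — simulating a protocol with $k$ stimuli
per cell, including $k$ larger than the measured count. Over $B$ such maps
(default $B = 1000$) the package computes, per parameter $P$ with observed
value $P_0$:

* normalized bias $B_\mathrm{norm}(P) = (\overline{P} - P_0)/P_0$;
* coefficient of variation $\mathrm{CV}(P) = \mathrm{sd}(P)/\overline{P}$;
* between-session variability
  $V(P) = (P_\max - P_\min)/(P_\max + P_\min)$, averaged over $B$ bootstrap
  triples (one resampled map per session); "averaged" is taken as the
  arithmetic mean;
* COG error: mean distance (mm) between the experimental COG and the $B$
  resampled COGs.

Degenerate cases are handled explicitly rather than silently: maps with
$P_0 = 0$ have undefined normalized bias and are excluded from bias/CV
medians with a logged count; triples with $P_\max + P_\min = 0$ contribute
$V = 0$ (no observable change); bootstrap replicates with an undefined COG
(all weights zero) are skipped and counted.

Both weighted areas are linear in the per-cell resampled means, so their
expected bootstrap bias is exactly zero at every $k$; the thresholded areas
are biased (e.g. the any-suprathreshold area has exact expected bias
$-\sum_i (1-\hat p_i)^k / \#\{i: \hat p_i > 0\}$, always $\le 0$ and
shrinking with $k$). The test suite checks the bootstrap engine against
these closed forms and against full enumeration of resampling outcomes on
tiny maps.

Reproducibility: each (map, parameter, $k$) combination consumes its own RNG
stream derived from the master seed by a 32-bit multiplicative mix, so
profiles are reproducible and insensitive to evaluation order.

## Censored-data session statistics

**Gehan test.** Cell-wise session comparisons use Gehan's generalization of
the Mann–Whitney test: pairs score $\pm 1$ only when definitely ordered.
With a single censoring threshold, censored < observed is always definite
and censored vs censored is indeterminate, so the scoring reduces to
comparing amplitudes with all censored values mapped to one common value
below $\theta$. p-values come from the permutation distribution of $W$:
exact enumeration when the pooled sample has $\le 12$ values (the 5-vs-5
protocol case has $\binom{10}{5} = 252$ assignments), otherwise Monte-Carlo
with 9999 permutations and an add-one correction. Significance diagrams mark
cells with uncorrected $p < \alpha = 0.05$; `+1` means greater in the later
epoch. No multiplicity correction is applied, by design — the diagrams are
descriptive, like statistical parametric maps.

**Histogram overlap** uses 30 equal-width bins over the pooled range by
default (configurable); each histogram is normalized to unit mass and the
bin-wise minima are summed.

**BICC.** The bootstrapping-based between-session intraclass correlation is
the one-way random-effects ICC, $(\mathrm{MSB} - \mathrm{MSW}) /
(\mathrm{MSB} + (n-1)\mathrm{MSW})$, applied to the three per-session
bootstrap value sets. It is reported unclamped.

An important calibration subtlety, discovered while validating the package:
when three sessions are *independent* draws from one excitability surface,
the between-session spread of a parameter equals its within-session sampling
spread, so the BICC concentrates near **0.5**, not 0 (the one-way ICC equals
$\sigma_b^2 / (\sigma_b^2 + \sigma_w^2)$ in the large-$B$ limit, with
$\sigma_b = \sigma_w$ here). The "no change beyond resampling noise"
situation in which BICC ≈ 0 corresponds to *identical* session maps, and
that is the calibration the test suite asserts. Observed BICC values on real
repeated sessions should therefore be read against a ≈ 0.5 noise floor, not
against 0.

**Page's trend test** checks monotone trends of CV, $V$ and COG error across
$k = 1..10$, with maps as blocks: $L = \sum_j j R_j$, exact by convolving
the per-block permutation distribution for $\le 4$ untied conditions and
$\le 5$ blocks, else the standard normal approximation.

## Grid coverage for gridless maps

For adaptively mapped (gridless) point clouds, the fraction of the
representation covered by a candidate square grid centred on the hotspot is
estimated conservatively: a suprathreshold point counts as covered only if it
lies within the circle inscribed in the grid (radius = half the grid side),
i.e. covered under *any* grid orientation. "Fraction of the representation"
is operationalized as the fraction of suprathreshold points — per-point area
weights are not available for adaptive point sets. Candidate sides default to
38–69 mm (10–18 cells in the Nexstim grid tool).

## The synthetic generator: what it emulates and what it does not

`excitability_surface()` models the log-median amplitude as a Gaussian bump,
$\mu(d) = \log\mu_\mathrm{peak} - d^2 / (2\sigma_\mathrm{mm}^2)$, with
lognormal trial-to-trial spread `log_sigma` and left-censoring at $\theta$.
The implied suprathreshold probability is
$p(d) = 1 - \Phi((\ln\theta - \mu(d))/\texttt{log\_sigma})$.

Defaults state the world the analysis assumes, chosen once:

* grid: 7 × 7 cells of 7.63 mm, hotspot-centred; 10 stimuli per cell
  (490 per session); $\theta = 50$ µV;
* `log_mu_peak = log(300)`: a median hotspot MEP of 300 µV at 110 % RMT,
  giving $p \approx 0.96$ at the centre — a high-probability core
  ($p \ge 0.9$ out to ~10 mm) with an intermediate fringe across the rest of
  the grid, matching the core/fringe structure of real probability maps;
* `log_sigma = 1`: amplitudes spanning roughly two orders of magnitude,
  the heavy-tailed variability reported for MEPs;
* `sigma_mm = 10` mm: a representation that fills the central part of the
  53 mm grid without reaching its corners.

Session drift is modelled as a random hotspot translation
(`center_shift_mm`) plus a random log-gain shift (`gain_shift_log`), both
per session. Not modelled: coil-orientation effects, spatial correlation of
trial-to-trial noise, excitability fluctuations within a session
(amplitudes are i.i.d. given location), and the curved cortical geometry.
A green synthetic test therefore establishes that the *estimators and tests
behave correctly under the stated generative assumptions* — not that real
maps satisfy those assumptions.

The gridless protocol is emulated as radial walks from the hotspot (default
8 rays, 5 mm spacing), one stimulus per point, each ray stopping after two
consecutive sub-threshold responses; the real adaptive geometry is only
loosely described and this is a stated approximation.

## Numerical and design choices

* Exact permutation enumeration limits (pooled $n \le 12$; Page
  $m \le 4, b \le 5$) trade memory for exactness where the protocol's
  sample sizes live; beyond them Monte-Carlo / normal approximations are
  used and labelled in the returned `method`.
* Histogram overlap returns 1 when all pooled values coincide (the
  distributions are identical point masses).
* Hotspot and COG ties break to the lowest index.
* CSV I/O writes amplitudes with 17 significant digits so the round-trip is
  exact.
* Bootstrap resampling is vectorized for maps with a uniform per-cell
  sample count; ragged maps (operator-error cells with 7–12 stimuli) fall
  back to an equivalent per-cell path, tested against the fast one.

## Limitations

* The bootstrap treats each cell's empirical amplitude distribution as the
  truth; its validity rests on the ten-stimulus sample being a fair sketch
  of that distribution.
* Bias/CV are undefined for maps whose observed parameter is zero; such
  maps are excluded and counted, which slightly biases cohort medians for
  weakly responding muscles.
* The acceptance checks run at a desk scale ($B = 200$, 8 synthetic
  subjects) — smaller than the production default $B = 1000$ — with
  correspondingly widened Monte-Carlo tolerances in the tests that need
  them.
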