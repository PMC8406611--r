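---
title: "Read-depth CNV detection on targeted panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-depth CNV detection on targeted panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`panelcnv` infers copy number from coverage depth alone. For a diploid
sample, the captured depth of a region scales with its copy number: a
heterozygous deletion halves it, a heterozygous duplication multiplies it by
3/2, a homozygous deletion removes it, and a mosaic single-allele deletion
present in a cell fraction $f$ scales it by $1 - f/2$. The statistic is the
per-window log copy-number ratio

$$\mathrm{logCNR} = \log_2
\frac{\tfrac{1}{L}\sum_{i \in \text{window}} d_i}
     {\tfrac{1}{n}\sum_{j=1}^{n} \tfrac{1}{L}\sum_{i \in \text{window}} d_{ij}}$$

where $d_i$ is the query's depth at position $i$, $d_{ij}$ the depth of the
$j$-th of $n$ reference samples, and $L$ the window length. The numerator is
the query's window mean; the denominator is the reference pool's stored
per-window mean (`mean_trsw`), an unweighted mean over members of their
window means — the two-level averaging is kept exactly as written, and
scoring never re-derives the denominator from raw member depths. Expected
values are $0$ for two alleles, $-1$ for one, $\log_2 1.5 \approx +0.58$ for
three, and $\log_2(1 - f/2)$ for mosaics (about $-0.234$ at $f = 0.3$).

The key assumptions are (i) capture efficiency per region is stable across
samples sequenced with the same capture-kit lot, so it cancels in the ratio;
(ii) overall depth differences between samples are approximately
multiplicative and are controlled by matching the query to a pool of similar
mean depth; (iii) residual noise is small relative to the ±0.58/−1.0 event
signals at panel depths of hundreds×.

# Sliding windows

Each target region (exon/UTR ± intronic flank, 0-based half-open BED
coordinates internally) of length $L_{TR}$ is tiled with windows of length
$L_{SW}$ advancing by $L_{SL}$:

$$N_{SW} = \left\lfloor \frac{L_{TR} - L_{SW}}{L_{SL}} \right\rfloor + 1$$

The division is an integer floor: the traversal slides until the remaining
length is shorter than one slide, and that remainder
$L_{ADD} = (L_{TR} - L_{SW}) \bmod L_{SL}$ is absorbed into the last window,
whose length is $L_{SW} + L_{ADD}$. A region with $L_{TR} \le L_{SW}$ gets
one window of the region's own length. Windows are anchored at region starts
and never cross region boundaries. One boundary case deserves note: a region
with $L_{SW} < L_{TR} < L_{SW} + L_{SL}$ yields a *single* extended window
(the formula gives $N_{SW} = 1$ with absorption), not two; the same rule
falls out of the cursor enumeration the tests use as an oracle.

Defaults are $L_{SW} = 75$ nt (half a 150 nt read) and $L_{SL} = 10$ nt,
giving a 65 nt overlap between adjacent windows. Smaller slides raise
breakpoint resolution linearly in cost; window size should stay near half
the read length so single windows respond strongly to sub-exon events.
Adjacent or overlapping BED intervals of the same gene are merged at load so
duplicate capture probes cannot double-count windows; overlapping intervals
of *different* genes are rejected as a panel defect.

# Reference pools

Normal (CNV-free) samples above a configurable mean-depth cutoff (default
100×) are sorted by increasing mean depth, ties broken by sample id for
reproducibility. Pool $j$ contains samples $j$ … $j+K-1$, so $N$ normals
give $M = N - K + 1$ overlapping pools whose mean depths are non-decreasing.
The pool size $K$ has no silent default; the worked examples use $K = 8$,
large enough to average out member noise and small enough that members have
similar depth. Two open conventions were fixed as follows:

* a pool's "mean depth" is the unweighted mean of member sample means
  (matching the $1/n$ structure of the score's denominator), not a
  position-weighted grand mean;
* a sample's mean depth is the mean over unique targeted positions —
  averaging over windows would multiply-count the bases shared by
  overlapping windows.

Pool selection minimises $|$pool mean − query mean$|$, ties going to the
lower-depth pool. Pools carry the capture-kit lot they were built from, and
selection refuses a cross-lot query unless explicitly overridden: capture
batch effects are region-specific multipliers that do not cancel across
lots. Run-wise pools (all samples of the query's own run) are built with the
same code path; the query itself is excluded, since including it would bias
its own reference toward its CNV.

# Scoring rules and degenerate inputs

Two guard rules keep scores finite and make the known failure mode of
read-depth callers — poorly captured regions — explicit rather than silent:

* **no-call floor** (`min_pool_depth`, default 20×): windows whose pool
  mean depth is below the floor are masked (`NA`), not scored; low-coverage
  reference windows are where false positives concentrate;
* **zero-query cap** (`floor_score`, default −6): a query mean of 0 against
  an adequately covered pool returns the cap, flagged
  `possible_homozygous_deletion`, instead of $-\infty$.

Scores are deterministic in their inputs; scaling the query's depths by $c$
shifts every defined score by exactly $\log_2 c$, which is why pool matching
(and the deviation QC below) matters.

# Quality control

Three checks, in the order a lab would apply them:

1. **query vs pool**: percentage deviation
   $100\,|\bar d_q - \bar d_p| / \bar d_p$ against a cutoff (default 5%). On
   failure the documented escalation is re-selection against an updated,
   larger pool set, then a hard failure advising re-sequencing or an
   orthogonal assay. Note that a large CNV legitimately shifts the sample's
   own mean depth, so this is a sample-acceptance gate, not part of the
   detection statistic.
2. **pool uniformity**: coefficient of variation of member mean depths
   ($n-1$ denominator), default limit 15%. The CV is this package's
   operationalisation of "uniform coverage depth among pool members"; no
   numeric criterion is standard.
3. **static vs run-wise**: per-window absolute score differences on
   mutually called windows, flagging those above 0.3 log2 units —
   pool-dependent windows deserve scrutiny before interpretation.

# Candidate flagging and breakpoints

Interpretation is table- and plot-driven; the flagger is an advisory
shortlist and never suppresses the full output. It reports maximal runs of
at least `min_consecutive` (default 3) called windows with score ≤ −0.5
(deletion) or ≥ +0.3 (duplication). The thresholds sit near the midpoints
between 0 and the theoretical values, the duplication threshold
proportionally closer to 0 because the +0.58 duplication signal is weaker
than the −1.0 deletion signal. No-call windows break runs, and spans never
cross gene boundaries. An optional low-stringency pass (score ≤ −0.15 over
≥ 10 windows, labelled `possible_mosaic`) targets mosaic deletions, whose
expected signal at 30% mosaicism (≈ −0.234) is invisible to the default
thresholds; mosaic hits contained in a standard deletion call are dropped as
redundant.

Breakpoint refinement exploits a geometric fact: the depth ratio
$2^{\mathrm{logCNR}}$ is linear in the fraction of a window's bases inside
the event, so a window whose *midpoint* sits exactly on a breakpoint carries
exactly half the event signal. Each candidate edge is refined by
interpolating, over window midpoints, where the ratio crosses the midpoint
between baseline and the candidate's plateau (median ratio of the run core,
trimmed of ramp windows). The baseline is estimated from called windows away
from any candidate (margin of one window length, falling back to 1 when
fewer than five such windows remain) so that an overall depth shift of the
query does not bias the crossing. Edges coinciding with a region boundary
have no ramp and keep the flagged-window-union coordinate, which is already
exact there. This recovers intra-exon breakpoints to roughly the sliding
length; windows are anchored at multiples of $L_{SL}$, so $L_{SL}$ is the
resolution claim the package makes.

# The coverage simulator

`simulate_sample()` draws depth at position $i$ of region $r$ as

$$d_i = \mathrm{round}\big(D \cdot s \cdot e_r \cdot b_{lr} \cdot
c(i) \cdot \varepsilon_i\big)$$

with base depth $D$ (default 200×), per-sample scale
$s \sim \mathrm{LogNormal}(0, \sigma_s)$ (default $\sigma_s = 0.1$),
per-region capture efficiency $e_r \sim \mathrm{LogNormal}(0, 0.3)$ shared
by all samples, per-lot per-region batch multipliers
$b_{lr} \sim \mathrm{LogNormal}(0, 0.05)$, the event copy ratio $c(i)$
applied only over in-span positions (so partial-exon breakpoints exist), and
multiplicative noise $\varepsilon_i$ with mean 1 and CV `noise_cv` (default
0.05). Noise is applied per *position*: windows overlap and share bases, so
window-level noise is not well defined on a single per-base depth vector;
the per-position formulation with the stated CV is the per-base analogue.
Rounding is half-up, and the ratio is applied before rounding. All draws
descend from one seed; a fixed configuration reproduces byte-identical
coverage files.

What the simulator emulates: region-to-region capture variability,
between-sample depth scaling, lot batch effects, depth-proportional noise,
and every event class (whole-gene/multi-exon/single-exon heterozygous
deletions and duplications, homozygous deletions, partial-exon events,
mosaics). What it does not emulate: GC-dependent and mappability-dependent
coverage waves, pseudogene cross-mapping, probe-site SNPs that depress
capture, within-sample correlated noise beyond the region level, and
read-level artefacts. Passing the simulated validation therefore shows the
statistical machinery is correct at realistic depths and noise; it does not
certify performance on panels with homologous or repetitive regions, which
real deployments handle by QC, orthogonal testing and curated exclusion
lists.

# Validation study

`validation_study()` (driven by `scripts/acceptance.R` and the acceptance
tests) re-runs the pipeline on freshly simulated data at the package's
default study conditions: a 126-region, 21-gene panel, 20 normals at 200×
with 5% noise, $K = 8$ pools, and the ten-event canonical set of
`example_event_set()`. It measures event sensitivity, window-level
specificity and false-positive candidate spans on five event-free queries,
mosaic recovery (at 500×), partial-exon breakpoint error, and zero-noise
exactness. Detection metrics are measured on the scoring path (pool
selection → scoring → flagging); the deviation QC gate is evaluated
separately, because simulated event samples can fail it for the legitimate
reason above. The mosaic, breakpoint and zero-noise sub-studies use
depth-matched queries (no per-sample scaling) so the measured quantity is
the event's own signal — on real samples the deviation gate bounds exactly
this nuisance. These problem sizes run the whole study in seconds on one
core while keeping per-gene window counts (tens per region) at production
scale.

# Known limitations

* Sensitivity degrades in regions whose pool depth sits near the no-call
  floor; those windows are masked rather than scored, which trades recall
  for explicitness.
* Duplication signals (+0.58) are intrinsically weaker than deletion
  signals (−1.0); the asymmetric default thresholds reflect but do not
  remove this.
* The method compares depths, not normalised profiles; it therefore needs
  pools per capture-kit lot and cannot pool across lots.
* No segmentation model or statistical confidence is attached to
  candidates; the intended use is advisory flagging on top of manual review
  of tables and plots, which matches small per-sample gene lists but would
  need score-based cutoffs with error control for exome-scale panels.
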