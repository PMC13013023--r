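---
title: "Asymmetric branching morphometrics with branchflow"
author: "branchflow maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Asymmetric branching morphometrics with branchflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(branchflow)
```

## The model

Neuronal dendrites and glial processes are hierarchically branching
networks. At a bifurcation, each daughter branch relates to its parent by a
radius scale factor $\beta_i = r_{\mathrm{daughter},i}/r_{\mathrm{parent}}$.
Because real junctions are asymmetric, the two daughters carry different
ratios, summarized by the mean and half-difference

$$\bar\beta = \frac{\beta_1+\beta_2}{2}, \qquad
  \Delta\beta = \frac{\beta_1-\beta_2}{2},$$

with the inverse $\beta_1 = \bar\beta + |\Delta\beta|$,
$\beta_2 = \bar\beta - |\Delta\beta|$ (`betaPair()`). Lengths scale
analogously through $\gamma_i = l_{\mathrm{daughter},i}/l_{\mathrm{parent}}$.
We order daughters so that daughter 1 is the longer one, which fixes
$\Delta\gamma \ge 0$ and makes $\Delta\beta$ signed: positive when the
longer daughter is also the wider one. When the two path lengths tie, the
wider daughter is taken as daughter 1 (so $\Delta\beta \ge 0$); ties are
detected at a relative tolerance of $10^{-9}$ because reconstructed path
lengths are floating-point sums of coordinate distances and geometrically
identical daughters differ in their last bits.

Position within the arbor is measured by the leaf number $L_n$, the number
of terminal tips distal to a branch, normalized per cell as
$L_{n,rel} = \log_2(L_{n,\max}/L_n)$: zero at the branch nearest the soma,
increasing toward the tips. We adopt the convention that a tip has
$L_n = 1$. (One sometimes sees tips described with leaf number zero, but
parents of two tips must then sum to zero rather than the value 2 they are
always depicted with, and $\log_2(L_{\max}/L_n)$ would be undefined at
tips; the tip-equals-one convention is the only internally consistent
reading, and we flag the alternative here deliberately.)

Under the cable/resistor approximation a branch of length $l$ and radius
$r$ has resistance $\rho l/(\pi r^2)$; we normalize $\rho/\pi \equiv 1$
(`branchResistance()`). For a schedule of per-level scale factors
$(\bar\beta_j, |\Delta\beta_j|, \bar\gamma_j, |\Delta\gamma_j|)$,
$j = 0,\dots,N-1$, the dissipated power of signal current through the
network is

$$P = R_{N,TOT}\sum_{k=0}^{N}\ \prod_{j=k}^{N-1}
  \left[\frac{(\bar\beta_j+|\Delta\beta_j|)^2}{\bar\gamma_j+|\Delta\gamma_j|}
      + \frac{(\bar\beta_j-|\Delta\beta_j|)^2}{\bar\gamma_j-|\Delta\gamma_j|}
  \right],$$

with the empty product ($k = N$) equal to one (`powerLoss()`). The
denominator of the second bracket term deserves a note: the asymmetric
reading $\bar\gamma - |\Delta\gamma|$ pairs the thinner daughter with the
shorter one, mirroring exactly how $\beta_1,\beta_2$ are recovered from
mean and difference, and is the package default; a `denominator =
"symmetric"` switch evaluates both terms over
$\bar\gamma + |\Delta\gamma|$ instead. The two coincide whenever
$\Delta\gamma = 0$. We make no claim that this recursion equals a
series-parallel reduction of an explicit branch tree; it is evaluated as
written.

## From SWC files to features

SWC reconstructions store one sample per row (ID, type, x, y, z, radius,
parent). `readSWC()` validates structure (unique IDs, resolvable parents,
acyclicity) and rejects non-positive radii outright: silently repairing
them would bias $\beta$, and the legitimate resolution artifact is handled
by the junction filter instead. `extractBranches()` groups samples into
maximal unbranched chains, detecting branch points topologically (a sample
with two or more children) rather than via gaps in parent-ID numbering —
the numbering heuristic is an artifact of contiguous file numbering and
breaks under renumbering, while the two rules agree on well-formed files.
Soma samples are never assigned to branches.

Per branch, the radius is the arithmetic mean of its samples' radii and
the path length is the polyline length including the segment connecting it
to its parent branch's last sample. `computeJunctions()` emits one row per
bifurcation; branches with three or more daughters fall outside the binary
theory and are skipped (counted in an attribute). `filterJunctions()`
removes junctions where either daughter has $\beta \ge 0.999$: when traced
radii saturate at the image pixel size deep in an arbor, daughter and
parent radii become equal and produce a spurious symmetric peak at
$\beta \approx 1$.

Classification consumes the raw per-junction rows; `levelProfile()`
averages $\bar\beta$ and $\Delta\beta$ at each distinct $L_{n,rel}$ per
cell or class for visualization only. The $\gamma$ features are computed
and exported but never used for classification — the discriminative theory
here concerns radius scaling, and a meaningful length-scaling analysis
needs a tip-upward (Horton–Strahler) relabeling that is out of scope.
Whether classifiers should see the signed $\Delta\beta$ or its magnitude
is genuinely open; the empirical difference-factor distribution is
two-sided around zero, so the signed value is the default and `absDiff =
TRUE` is a switch.

## The synthetic-arbor generator

`generateArbor()` builds complete binary trees: topology is deterministic
and only the ratio draws (and a small perpendicular sample jitter, active
only when noise is on) are random. This choice makes expected features
closed-form — in a complete tree of depth $D$, a junction at generation
$g$ has parent leaf number $2^{D-g}$ and hence $L_{n,rel} = g$ exactly —
so level-dependent profiles directly program a feature-vs-level
relationship. Ratio noise is additive truncated normal, clipped so
daughter ratios stay within $(0.01, 0.998)$ (clip events are counted);
`quantizeRadii()` applies the pixel floor
$\max(p, p\cdot\mathrm{round}(r/p))$ that manufactures the $\beta = 1$
artifact the filter must remove. Per-cell seeds in `generateCohort()`
derive from the cohort seed by a counter rule, so cohorts are reproducible
regardless of generation order.

Defaults describe a mid-size dendritic arbor: depth 6 (64 tips), root
radius 1 µm, root length 40 µm, $\bar\beta = 0.7$, $|\Delta\beta| = 0.1$,
$\bar\gamma = 0.8$ with symmetric lengths, ratio noise SD 0.02, five
samples per branch. What the generator does *not* emulate: random or
biased topology, tapering within branches, tortuosity, spines, multiple
neurites per soma, or correlated noise along paths. Tests passing on this
generator therefore validate the *mechanics* of the pipeline (parsing,
branch decomposition, feature algebra, filtering, evaluation protocol) and
the *direction* of the classifier comparisons, not quantitative claims
about any real cell type.

## The classifier comparison

`runComparison()` evaluates seven standard classifiers — logistic
regression, radial-kernel SVM, k-nearest neighbours, random forest, a
single decision tree, Gaussian naive Bayes, and a small neural network —
on 2D ($\bar\beta, \Delta\beta$) versus 3D (adding $L_{n,rel}$) feature
spaces. The protocol guards against the two classic leaks: classes are
first balanced by *image* count (junction counts per image cannot be
controlled), and the train/test split assigns whole cells, stratified by
class, with 75% of cells (the middle of the customary 70–80% range) to
training and at least one test cell per class.

Hyperparameters the comparison needs but that have no canonical values are
fixed and recorded in every report: SVM cost 1 with the median heuristic
for the kernel width; KNN scans odd $k \in \{1,\dots,51\}$ maximizing AUC
on a held-out quarter of the training cells; the network has one hidden
layer of 8 logistic units, weight decay $10^{-4}$, at most $10^4$
iterations. Features are standardized with training-set mean/SD for the
margin/distance-based methods (LR, SVM, KNN, NN); trees and naive Bayes
consume raw features. AUC is the tie-aware Mann–Whitney statistic and its
95% confidence interval uses the DeLong variance (via pROC); an
independent exhaustive pair-counting implementation serves as the test
oracle. Image-level accuracy thresholds each row's score at 0.5 strictly
and majority-votes rows within a cell, with an exact 0.5 tie resolved to
class 0. No multiple-testing correction is applied across the 14
method-by-mode cells; the table is descriptive.

The benchmark scenario that exercises the third feature is
*level-localized* class structure with matched marginals: two classes
whose $\bar\beta$ profiles swap a low and a high value between early
generations (31 junctions per cell at depth 6) and the last generation (32
junctions), so pooled 2D feature distributions agree up to one junction
per cell while the $(\bar\beta, L_{n,rel})$ joint distributions differ
sharply. On such cohorts the 2D AUC is statistically indistinguishable
from chance while 3D random-forest AUC approaches 1 — the qualitative
pattern whereby flexible methods gain most from the positional feature,
and methods blind to interactions (logistic regression, naive Bayes on
matched marginals) gain least.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: a single-sample root branch has
path length 0; a parent with path length 0 yields undefined $\gamma$ but
the junction is kept for radius features; all-tied score vectors give AUC
0.5 with a zero-width DeLong interval. The test suite runs cohorts of 8–24
cells at depths 5–6 (63–127 branches per cell) and 10–20 seeded
replicates per simulation-based property — sizes at which every
distributional check is comfortably powered while the whole suite stays
interactive.

## Known limitations

Real NeuroMorpho reconstructions carry tracing pathologies (broken trees,
duplicate points, soma contours) that `readSWC()` deliberately does not
repair beyond its stated validation. The power-loss recursion is evaluated
per printed formula over aggregate per-level schedules and is not derived
from, or checked against, an explicit electrical reduction of a given
arbor. Classifier hyperparameter defaults are reasonable, recorded, and
fixed — not tuned per dataset. Horton–Strahler ordering, length-scaling
classification, and Sholl-type features are out of scope.
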