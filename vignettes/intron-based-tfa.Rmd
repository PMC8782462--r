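---
title: "Estimating transcription factor activity from intronic reads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating transcription factor activity from intronic reads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronTFA)
```

## The problem

A transcription factor's (TF) activity — how strongly it is driving its
target promoters right now — is not directly measurable in routine RNA-seq.
The standard workaround scores the expression of the TF's regulon (its set
of curated activation targets). But mature mRNA is a *low-pass filter* of
transcription: a transcript with half-life $t_{1/2}$ integrates
transcriptional input over a window of order $1/\gamma = t_{1/2}/\ln 2$,
so regulon expression lags and smooths the underlying activity, badly for
stable transcripts. Intronic reads, in contrast, originate almost entirely
from unspliced pre-mRNA, which turns over within minutes (splicing is ~90%
complete in 5–10 min). Averaging the *intron-level* expression of a
regulon therefore estimates the TF's instantaneous activity.

## Kinetic model

Each target gene follows

$$\frac{du}{dt} = \alpha\,\frac{TF^n}{TF^n + K_d^n} - \beta u,
\qquad \frac{ds}{dt} = \beta u - \gamma s,$$

with $u$ unspliced and $s$ spliced mRNA, Hill-type activation
($n = 2$), splicing rate $\beta = \ln 10 / t_{spl}$ (so 90% of pre-mRNA is
spliced within the splicing time $t_{spl}$, 5–10 min) and decay
$\gamma = \ln 2 / t_{1/2}$. The driving activity is a basal-to-peak cosine

$$TF(t) = A_{basal}\tfrac{1+\cos(2\pi t/T)}{2}
        + A_{max}\tfrac{1-\cos(2\pi t/T)}{2} + \varepsilon(t),$$

with defaults describing oscillatory p53 after DNA damage:
$A_{basal} = 0.06$ µM, $A_{max} = 0.5$ µM, $T = 5.5$ h,
$\varepsilon \sim N(0, (0.2 A_{basal})^2)$. Gaussian noise can push a
concentration below zero; we clip at zero before the Hill function, since
the model's input is a concentration (the clipping is our choice; at the
default noise level it affects < 0.1% of draws). Per-gene parameters are
drawn as $\alpha \sim U(100, 200)\,h^{-1}$ and
$K_d \sim U(0.05, 0.25)$ µM. Simulations run for 20 h at a 0.001 h step,
initialised at the steady state under basal TF.

Two integrators are provided. `simulate_ode()` uses an adaptive
stiff-capable solver (`deSolve::lsoda`, rtol $10^{-8}$; $\beta$ up to
~55 h$^{-1}$ makes the system moderately stiff) with output on the fixed
grid. `simulate_tau_leap()` is a stochastic tau-leap propagator: per step,
each reaction (production, splicing, degradation) fires a Poisson number
of times at its current propensity, and splicing moves molecules from $u$
to $s$ in the same draw. Because the model is written in concentrations,
the stochastic variant needs a molecule-count scale; we introduce
$\Omega$ (molecules per µM, default 100) as an explicit, configurable
parameter. At $\Omega = 100$ typical counts are $10^2$–$10^5$, so
intrinsic noise is modest and the 0.001 h step keeps per-step event counts
a few percent of the molecule pool (a warning fires if the leap condition
is violated).

## What the simulator shows

`ensemble_benchmark()` simulates a regulon of genes (one per supplied
half-life; pass repeated half-lives to average over the random
TF-affinity draw within a bin — we use six genes per bin so the bin mean
reflects the half-life, not one gene's $K_d$) across cells sharing a TF
realisation, and correlates each gene's $u$ and $s$, and the across-gene
means of $u$ and $s$ (the regulon-mean estimators), with the cell's TF
input. Correlations are Pearson, computed after discarding the first
waveform period as burn-in: transient handling is not canonical for this
kind of benchmark, and one period is the shortest window that removes the
fast ($1/\beta$) transient.

Typical results at study scale (100 cells): corr$(u, TF)$ sits near
0.92–0.95 at every half-life, while corr$(s, TF)$ falls from ~0.84 at
20 min to ~0.35 at 100 min and ~0.13 beyond 500 min. The regulon-mean
unspliced estimator correlates with the true activity at ~0.94
(deterministically ~0.95), the spliced one at ~0.17.

**A known limitation worth stating precisely.** Under these exact
conditions corr$(s, TF)$ is *not strictly monotone* to the end of the
half-life axis: it reaches a shallow minimum near $t_{1/2} \approx
1000$ min and rises by ~0.001–0.002 at 2000 min. The reason is that the
20 h window is much shorter than $1/\gamma$ (48 h at 2000 min), so the
correlation in that regime is dominated by the initial relaxation ramp
rather than the attenuated oscillation, and the decline plateaus. The
effect is systematic (it survives burn-in choices of 0, 1 or 2 periods
and is far larger than the Monte-Carlo standard error of a 600-trajectory
bin mean). Statements about the spliced readout degrading with half-life
should therefore be read as "decreases then plateaus", not as strictly
monotone to arbitrary stability.

`detection_sweep()` studies sparse capture: counts are binomially thinned
at capture efficiencies 5–30%. The series is realised by *nested*
thinning — counts at a lower $p$ are a further thinning of the counts at
the next higher $p$ (valid since thinning composes), so the degradation
across $p$ is measured on the same underlying cells rather than on
independent noise. The sweep's single gene uses $\alpha = 100\,h^{-1}$, a
100 min half-life, and mid-range values for the parameters the protocol
leaves open ($K_d = 0.15$ µM, $t_{spl} = 7.5$ min).

## Quantification

`cpm()` implements the shared-denominator convention: for either layer,
CPM is $10^6$ times the layer count over the *intron plus exon* total of
the sample. The two layers therefore jointly sum to one million per
sample, and an intron CPM changes when any gene's exon counts change —
this coupling is deliberate and tested. No gene-length normalisation is
applied: intronic priming means the effective intron length generating
reads is unknown. Genes without annotated introns carry a structural
`has_intron = FALSE` flag rather than plain zeros, so exclusion rules are
explicit. Replicate averaging (`average_replicates()`) operates on CPM,
not raw counts, so replicates of different depth weigh equally.

## Activity estimation

`tfa_mean()` is the estimator of interest: the unweighted mean CPM of the
TF's regulon targets, using activation edges of confidence grade A or B
by default (`max_grade` loosens this, e.g. to C for sparsely curated
TFs). On the intron layer, intronless targets are excluded — they cannot
produce intronic reads, and their structural zeros would dilute the mean.
Whether the *exon* layer should also drop intronless targets is genuinely
ambiguous; we keep all targets by default (the literal reading) and
provide `matched_gene_set = TRUE` to force identical gene sets when a
head-to-head layer comparison must control for gene-set composition.

`tfa_rank_auc()` is the rank-based alternative (AUCell-style): genes are
ranked by descending expression with ties broken by gene id, and the area
under the regulon's recovery curve over the top fraction of the ranking
(default 5%, the conventional choice) is normalised to [0, 1]. The
ranking universe is all genes in the matrix. Repressor-aware signed
scoring and likelihood-weighted regulons are out of scope.

Null calibration uses `random_regulons()` (uniform samples from the gene
universe minus the true targets; the sample size matches the real
regulon so the null is comparable under averaging) and
`null_percentile()`, which applies the add-one empirical rule
$p = (1 + \#\{null \ge actual\})/(1 + n)$.

## Dynamics analyses

Rhythmicity uses a single-harmonic cosinor at a fixed 24 h period: least
squares for $m + a\cos\omega t + b\sin\omega t$, an F-test of
$(a,b) = 0$, amplitude $\sqrt{a^2+b^2}$ and phase (peak time)
$P\,\mathrm{atan2}(b,a)/2\pi \in [0, P)$. Ensemble detectors such as
meta2d combine several tests and are somewhat more sensitive on
non-sinusoidal shapes; we deliberately substitute the closed-form cosinor
(transparent, exactly calibrated — its type-I error at $\alpha = 0.05$ is
5% by construction under Gaussian noise) and consequently make no claim
of reproducing any specific count of rhythmic TFs from ensemble-detector
analyses. TFs are classified by which layer detects the rhythm (class 1:
both; class 2: intron only; class 3: exon only), and
`phase_difference()` wraps exon-minus-intron peak times into
$(-P/2, P/2]$ so that *positive values mean the exon-based activity lags
the intron-based one* — the direction the kinetic model predicts, with
lag $\approx \arctan(\omega/\gamma)/\omega$.

Surrogate comparison (e.g. against measured DNA-binding or
nuclear-localisation series) linearly interpolates both series onto a
shared 0.5 h grid over their overlapping range; no extrapolation is ever
performed. `replicate_robustness()` re-tests rhythmicity on
replicate-subset averages; among the possible subset schemes we default
to leave-one-out (all proper subsets of size ≥ 2 are available via
`subsets = "all"`). `cluster_modules()` groups TFs by activity-profile
similarity using $1 - r$ (Pearson) as distance, average-linkage
agglomeration, and a cut at $k = 2$; linkage and cut height are not
canonical choices anywhere, and average linkage on correlation distance
is the common default for expression-profile trees. Constant series are
excluded with a warning rather than propagating NaN distances.

## The fixture generator

`generate_fixture()` plants ground truth: TF activities are basal-to-peak
cosines (peak times 6 h and 18 h for the two planted modules) or flat
midpoint levels for null TFs; target kinetics are drawn as in the
simulator with log-normal half-lives (median 300 min, sdlog 0.5 — typical
of stable tissue mRNAs and long enough for a clear exon-layer lag);
dynamics are integrated with one full period of burn-in before the first
sample so sampling happens in the oscillatory regime. Read counts are
Poisson around depth-scaled $u$ (intron layer) and $s$ (exon layer) —
making "intronic reads ≈ unspliced mRNA" an explicit modelling
assumption — with optional binomial thinning. Default design: samples
every 2 h from 0 to 22 h, 4 replicates, expected library 2 × 10⁶. The
regulon table carries the true activation edges at grades A/B plus decoy
repression and C-grade edges; ~10% of genes lack half-life entries; TSS
coordinates and a peak track over the first TF's intron-bearing targets
exercise the ± 2 kb refinement rule.

What the fixture does *not* emulate: mapping ambiguity and intronic-polyT
priming artefacts, scRNA-seq dropout beyond binomial thinning,
batch/biological replicate structure beyond Poisson resampling, and
repressive regulation. Passing the end-to-end tests therefore shows the
estimators behave as designed under the model's own assumptions, not that
those assumptions hold in any particular real dataset.

## Numerical choices and problem sizes

Tolerances: ODE rtol $10^{-8}$/atol $10^{-10}$; CPM conservation asserted
to $10^{-6}$ relative; cosinor phase recovery to $10^{-6}$ h on noiseless
input. Ties: gene-id order breaks ranking ties (`tfa_rank_auc`) and
median ties (`split_by_halflife`), making both deterministic. Degenerate
inputs (constant series, zero libraries, empty target sets) raise
explicit errors or warnings with defined sentinel outputs, never silent
NaN. The test and acceptance workloads use 100-cell ensembles with six
genes per half-life bin, a 1000-cell ensemble for tau-leap/ODE agreement
(time-averaged relative error well under 5%; the residual bias is the
first-order tau-leap discretisation, about $\beta\,dt/2 \approx 1.4\%$),
20 fixture seeds for end-to-end recovery and module clustering, and, for
p-value calibration, 1000 independent replications each scoring a fresh
candidate regulon against its own fresh 1000-regulon null. The
independent-replication design matters: scoring many candidates against
one shared null set leaves the Kolmogorov–Smirnov distance floored by
the sampling error of that single null ECDF (~0.03 for 1000 nulls),
whereas independent replications make the p-values exactly iid uniform
(up to the 1/1001 grid), so the KS statistic shrinks as
$1.36/\sqrt{1000} \approx 0.043$ at the 95th percentile. Everything is
seeded; one top-level seed is split deterministically per stage.
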