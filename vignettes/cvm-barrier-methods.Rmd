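---
title: "Methods: mucus barrier properties from particle tracking and community state types"
author: "cvmbarrier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mucus barrier properties from particle tracking and community state types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvmbarrier)
```

## The scientific problem

Cervicovaginal mucus (CVM) is a selectively permeable gel: its mucin
fibre network traps particles sterically (by mesh size) and adhesively
(by surface chemistry). A tight mucus barrier is thought to protect the
upper reproductive tract from ascending bacteria during pregnancy, and a
compromised barrier is one proposed mechanism linking vaginal dysbiosis
to preterm birth (PTB). This package implements the quantitative chain
used to test that idea: multiple particle tracking (MPT) of probe
nanoparticles in CVM to measure barrier properties, 16S-style
composition clustering into vaginal community state types (CSTs), and
cohort statistics linking CSTs and demographics to delivery outcome.
Because the raw study materials (videos, reads, records) are not
shippable, the package includes first-class synthetic-data generators
that emulate each input under controlled ground truth; every claim the
package makes is backed by a recovery test against that ground truth.

## Particle tracking

Videos are emulated as an EM-CCD acquisition: 25 nm/px, 15 Hz, 20 s
(300 frames), 512×512 px by default (`optics_config()`), with particles
rendered as symmetric Gaussian spots plus Poisson shot noise in unsigned
16-bit counts. Detection (`detect_spots()`) follows the Crocker–Grier
recipe: a band-pass filter (Gaussian blur of scale 1 px minus a boxcar
background of the refinement-window radius, edges replicated), local
maxima above the 99.5th intensity percentile, and intensity-weighted
centroid refinement in an 11 px window, re-centred up to three times.
Maxima closer together than the window cannot be attributed reliably to
distinct particles; they are reported once and flagged ambiguous, and
ambiguous spots are excluded from linking so identity swaps cannot
corrupt downstream MSDs. Note that two spots much closer than the
point-spread function merge into a single maximum and are
indistinguishable from one particle — the ambiguity flag starts where
resolvability ends.

Linking (`link_trajectories()`) performs per-frame-pair globally optimal
assignment by minimum total squared displacement (a Hungarian/shortest
augmenting path implementation, written here because no installed R
package provides weighted bipartite assignment), with a hard gate of
`max_displacement` = 0.5 µm per link — generous for D ≤ 1 µm²/s at
15 Hz — a `memory` of 2 frames across which a vanished particle can be
re-linked, and a minimum track length of 30 frames (2 s), which
guarantees at least 15 displacement pairs at the 1 s lag. These defaults
are declared choices of this package: the thresholds of the original
MATLAB tooling this pipeline stands in for are not published.

## MSD and the trapped/mobile decomposition

Per particle, the time-averaged MSD uses overlapping windows over all
valid start frames; gaps contribute no pairs. A non-overlapping
estimator is available behind a flag for variance studies. The headline
statistic is MSD at τ = 1 s (15 frames). Exact zeros (possible for
synthetic stationary particles) are floored at 10⁻⁶ µm² inside the log
so mixture fitting never sees −∞; the floor is configurable.

Each sample's log₁₀(MSD) values, pooled across the several videos taken
per probe, are fitted with a two-component Gaussian mixture by EM
(`fit_mixture()`), re-implemented here rather than wrapped so that its
initialization and degeneracy handling are fully specified:
deterministic initialization (means at the 25th/75th percentiles, equal
weights, pooled SD), a variance floor of 10⁻⁴ (log₁₀ units)² against
singular collapse, convergence when the log-likelihood improves by less
than 10⁻⁸, at most 500 iterations. Components are always reported in
ascending-mean order. The fit is deterministic; a seed matters only if
optional multi-start is enabled. In tests the fit is cross-checked
against an independent mixture implementation (mclust) and the EM
log-likelihood trace is asserted non-decreasing.

**Mobile fraction.** If the fit is bimodal, the mobile fraction is the
mixing weight of the higher-MSD component (a posterior-count variant is
available; the weight is the default because the quantity of interest is
the population fraction, not a per-particle classification). If the fit
reveals only one peak, the fixed cutoff log₁₀(MSD) = −1.3 (MSD in µm²)
is used: the mobile fraction is the proportion of particles above it.

**Bimodality rule.** "Revealed only one peak" needs an explicit test.
We declare the fit bimodal only when (i) EM converged, (ii) both weights
are ≥ 0.02, (iii) the means are separated by at least 1 pooled SD, where
the pooled SD is the mixture-implied SD of the pooled data, and (iv) the
two-component model beats a single Gaussian on BIC. The BIC condition is
not decorative: on genuinely unimodal data EM frequently converges to a
"split halves" optimum — two heavily overlapping components whose
separation exceeds any fixed threshold in component-SD units (≈2.6 for a
single Gaussian) — while gaining almost no likelihood over one Gaussian.
A separation rule alone would route an all-trapped sample to the mixture
method with a spurious ≈50% mobile weight; the model comparison sends it
to the cutoff, which is the behaviour the single-peak fallback exists to
provide. Samples with fewer than 10 particles are marked insufficient
rather than estimated.

## Pore size from hindered diffusion

Only the PEG-coated, mucoinert probes (MPPs) enter the pore-size
estimate, since their hindrance is purely steric. For each probe
diameter d ∈ {100, 200, 500} nm the ensemble-average MSD at τ = 1 s
gives D_eff = MSD/(4τ); the free-water reference is Stokes–Einstein
D₀ = k_BT/(3πηd) at T = 298.15 K and η = 8.9×10⁻⁴ Pa·s (room-temperature
acquisition in essentially aqueous medium). The hindrance ratio is
inverted through the obstruction-scaling form

$$ D_\mathrm{eff}/D_0 = \exp\!\left[-\frac{\pi}{4}
   \left(\frac{d + d_f}{\xi + d_f}\right)^{2}\right], $$

with fibre diameter d_f = 7 nm (mucin fibres), all constants
config-overridable. The functional form is pluggable behind
`sample_pore_size()`: obstruction-scaling models exist in several
variants and the package fixes this one as its tested default, verified
by forward→invert round trips to 10⁻⁶ relative over ξ ∈ [50, 2000] nm.
Hindrance ≥ 1 carries no confinement information ("unbounded", excluded
from the sample mean); a sample whose probes are all unbounded is
undefined. Because the per-sample MSD is the ensemble average over *all*
tracked particles of a probe — trapped ones included — the estimate is
deliberately an *effective* pore size: in the synthetic cohort it is
attenuated below the generating ξ (e.g. ≈180 nm estimated for a 250 nm
generating mean in CST I), while remaining monotone in it, so ordering
and contrast statements are meaningful even though absolute values
depend on the trapped fraction.

## Community state types

Samples are clustered jointly on Bray–Curtis dissimilarities
(`vegan::vegdist`) by partitioning around medoids (`cluster::pam`,
deterministic BUILD + SWAP) with k fixed at 5 — the five canonical CSTs
— rather than selected by silhouette. Clusters are named by their
medoid's dominant taxon at a 0.5 relative-abundance threshold
(conventional "dominance"): *L. crispatus* → I, *L. gasseri* → II,
*L. iners* → III, *L. jensenii* → V, anything without a dominant
*Lactobacillus* → IV. If two clusters claim the same *Lactobacillus*,
the higher medoid dominance keeps the name and the other falls through
to IV with a warning. Longitudinal bookkeeping: for participants lost to
follow-up the last sampled CST is carried forward to delivery
(`carry_forward_cst()`), and mobility is averaged per participant per
CST per probe (`participant_cst_mobility_average()`) so unevenly sampled
participants do not dominate group comparisons.

## Cohort statistics

Samples flagged for blood or recent unprotected intercourse are excluded
before any mucus analysis, with per-reason logging (a doubly flagged
sample is removed once, logged twice). For 2×2 exposure-by-outcome
tables, RR and OR use the plain ratio formulas with no continuity
correction — zero numerators print as 0, matching the convention of the
cohort table the package reproduces — while CIs use Katz (RR) and Woolf
(OR) log methods with a 0.5 Haldane–Anscombe correction applied inside
the CI only when a zero cell occurs (flagged). CI methods in commercial
packages vary and are often undocumented, so point estimates, not CI
bounds, are the reproduction surface. The p-value is the two-sided
Fisher exact test (point-probability rule, via `stats::fisher.test`).
Group comparisons use Welch's t (Satterthwaite df; two constant equal
groups return t = 0, p = 1 by convention) and one-way ANOVA with Tukey
HSD (Tukey–Kramer SEs under unequal n; all-identical input returns F = 0
rather than 0/0). Trend tests are OLS slope t tests reporting both R²
and p.

## The synthetic cohort: what it emulates, and what it does not

`cohort_config()` defines the study conditions: ~30 enrolled
participants by default in the workflow scripts (92 in the study the
package mirrors; 20 in the fast demo config), enrolment at weeks 8–16,
visits every 4 weeks until week 36, ~12% attrition, term deliveries
≈39.3 ± 1.2 weeks and preterm ≈34.5 ± 2 weeks (truncated at 37 weeks on
either side). CST paths follow a persistent first-order Markov chain
whose most common off-diagonal moves are III→I and III→IV, started from
the study-scale CST mix (29/4/32/28/7%). Compositions are Dirichlet
draws per CST archetype with concentrations chosen so dominant taxa
average ≳0.85 in Lactobacillus CSTs and no taxon exceeds 0.3 in
expectation in CST IV. Ground-truth mobile fractions per CST and probe
are centred on the contrast the package is built to detect (e.g. 100 nm
MPP: 0.725 in CST I vs 0.871 in CST IV, SD 0.06 between samples), and
ground-truth pore sizes are centred at 250 nm (CST I) to 420–450 nm
(CST IV/II), SD 40 nm. Preterm risk is the risk of the highest-risk CST
a participant ever occupies (I/II/V: 4–5%, III: 12%, IV: 35%). Trapped
particles are modelled as fractional Brownian motion (exact-covariance
Cholesky synthesis) with α = 0.5 and MSD(1 s) = 10⁻²·⁵ µm²; slow-Brownian
trapping is also available, since the true microdynamics of caged
particles are not characterized — tests exercise both.

What the generator does *not* emulate: localization error and
heterogeneous photobleaching (videos are ideal Gaussian spots), spatial
heterogeneity within a sample (one ξ per sample), sequencing depth and
compositional zero-inflation, confounding between demographics and CST,
and calendar-time effects. Passing recovery tests therefore demonstrates
the *estimators* are correct and well calibrated under the stated model,
not that real CVM data are this clean.

## Problem sizes and determinism

The shipped workflow and tests use deliberately modest sizes — 6–30
participants, 60 particles per sample-probe, 128 px demo videos, 200
samples for CST recovery, 1000 replicates for calibration checks —
chosen so the whole suite runs in about a minute while keeping
Monte-Carlo error well inside the asserted tolerances (closed-form
checks assert within 3 standard errors). Every stochastic stage draws
from explicit seeds; a `run_config()` seed fully determines every output
byte, which the tests assert by re-running the pipeline and comparing
written CSVs.

## Known limitations

The pore-size equation is one member of a family of obstruction models;
absolute ξ values shift under other members (the interface accepts
alternative constants, and the estimate is already "effective" in the
sense above). The CST namer assumes species-resolved taxon names; it
performs no taxonomy harmonization. The mixture method reports the
mixing weight, which is not identical to a posterior particle count when
components overlap. PAM at k = 5 is forced even if a cohort genuinely
contains fewer community types; with very few samples of a type, a
cluster can absorb its neighbours (the label-recovery tests quantify
this at study-scale mixes). The risk machinery is row-wise and
unadjusted by design — no multivariable modelling.
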