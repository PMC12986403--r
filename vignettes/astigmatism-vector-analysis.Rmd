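---
title: "Astigmatism vector analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Astigmatism vector analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astigvec)
```

## The problem

Astigmatism is a two-dimensional quantity — a magnitude in dioptres (D) and
an axis in degrees — so "how well did the surgery correct the astigmatism?"
cannot be answered by subtracting cylinder magnitudes. The Alpins method
answers it with vectors. For each eye, three polar astigmatisms are taken at
the corneal plane (preoperative, intended target, achieved postoperative) and
mapped into *double-angle space*, where an astigmatism $(M, \theta)$ becomes
the Cartesian vector $(M\cos 2\theta,\; M\sin 2\theta)$. Because a cylinder
axis is only defined modulo 180°, doubling the angle makes astigmatism
addition and subtraction ordinary vector arithmetic. The three fundamental
vectors are

* **TIA** (target-induced astigmatism) $= \mathrm{target} - \mathrm{pre}$:
  the intended astigmatic change;
* **SIA** (surgically induced astigmatism) $= \mathrm{post} - \mathrm{pre}$:
  the achieved change;
* **DV** (difference vector) $= \mathrm{target} - \mathrm{post}$: the
  correction still needed; algebraically $\mathrm{TIA} - \mathrm{SIA}$.

Four scalars summarize each eye: the correction index
$\mathrm{CI} = |\mathrm{SIA}|/|\mathrm{TIA}|$ (1 is ideal; below 1
undercorrection), the magnitude of error
$\mathrm{ME} = |\mathrm{SIA}| - |\mathrm{TIA}|$ (signed; negative means
undercorrection), the angle of error AE (the signed single-angle difference
between the SIA and TIA vector axes, positive counterclockwise, normalized to
$(-90°, 90°]$), and the index of success
$\mathrm{IOS} = |\mathrm{DV}|/|\mathrm{TIA}|$ (0 is perfect).

Two definitional points deserve a note, because the field's prose is not
always consistent about them. We report ME *signed*: the clinically reported
proportions ("ME within ±0.50 D") and the undercorrection/overcorrection
reading both require the sign, and an absolute ME would fold the two failure
modes together. And AE is computed from the *vector axes* of SIA and TIA
(half the double-angle difference), not from the raw postoperative and
intended cylinder axes; when $|\mathrm{SIA}| = 0$ the achieved change has no
axis and AE is reported as 0. A tie at exactly ±90° is resolved to +90°.

## From spreadsheet to corneal-plane vectors

Input files carry 12 mandatory positional columns per eye — sphere, cylinder,
axis (degrees) and vertex distance (mm) for the preoperative, target and
postoperative refractions — in negative-cylinder notation, the convention
most refractive surgeons use. A plano target is entered as 0, 0, 0, 12.
Corneal astigmatism (keratometry/topography) is analyzed with the same
layout by entering 0 in every sphere and vertex column, which makes the
optics below the identity. Header text is ignored (order defines meaning),
extra columns are dropped with a warning, and blank cells are missing data —
zero is always a value.

Each refraction passes through two deterministic transforms before the
vector step:

1. **Transposition** to positive-cylinder form:
   $(S, C, \theta) \to (S + C, -C, \theta + 90°)$ when $C < 0$. The
   meridional power profile $F(\theta)$ is unchanged.
2. **Vertex correction** to the corneal plane, applied per principal power
   $F \in \{S, S + C\}$ with the standard effectivity relation
   $F' = F / (1 - dF)$, $d$ the vertex distance in metres. A vertex of 0 is
   the identity. The correction is applied uniformly to all three
   refractions, including a non-plano target: the target is a refraction
   like any other and its astigmatic component must live at the same plane
   as the others before vectors are subtracted.

The order of the two transforms does not affect the resulting astigmatism
(a property the test suite checks), and the whole chain is equivalent to
representing each sphero-cylinder as a 2×2 dioptric power matrix,
propagating the matrix, and extracting the traceless part — the independent
oracle the tests compare against at $10^{-8}$ D on a thousand random eyes.

## Exclusion rules

Standard practice excludes eyes whose corneal-plane TIA magnitude is below
0.25 D: with essentially no intended astigmatic change, the ratio indices CI
and IOS divide by a near-zero quantity and are meaningless. The threshold is
closed — exactly 0.25 D is included — and configurable
(`tia_threshold`). Rows with any missing cell among the 12 are excluded. In
a paired (contralateral-eye) design, rows are paired by file position; when
one side of a pair is excluded for any reason the partner is dropped too, so
the two groups stay aligned. The written exclusion log distinguishes the
three reasons. The literature specifies the partner drop only for missing
data; we extend it to low-TIA exclusions because a paired test cannot use an
unpaired row — the log makes the distinction auditable.

## Cohort summaries and group comparisons

Each group is summarized by the arithmetic mean and sample SD of the seven
continuous metrics, the geometric mean of CI and IOS (ratio quantities;
values of exactly 0 cannot enter a geometric mean and are left out, with the
count recorded), and five threshold proportions: ME within ±0.50 D, within
±1.00 D, and AE within ±15°, above 15°, below −15° (closed bounds; the three
AE buckets always sum to 100%).

Two-group comparisons are gated on normality. Each group's values are
z-standardized and tested against the standard normal with a one-sample
Kolmogorov–Smirnov test (asymptotic p). If both groups give p > 0.05 the
comparison is parametric — a paired t-test or a pooled-variance two-sample
t-test; otherwise it is the Wilcoxon signed-rank or rank-sum test. Three
choices here are deliberate:

* The KS test is run on standardized values because a literal KS test of raw
  data against N(0,1) would reject for any nonzero mean regardless of shape.
  We do **not** apply the Lilliefors correction for estimated parameters, to
  stay with the plain KS gate as stated; the practical consequence is a
  conservative gate (it under-rejects mild non-normality, so borderline
  samples tend to be compared parametrically). The gate is evaluated
  per group on each group's own values, not on paired differences.
* The two-sample t-test pools variances, the convention of the MATLAB-style
  clinical tooling this table format comes from (and the form matching the
  pooled-SD Cohen's d reported beside it).
* Binary threshold metrics use a 2×2 chi-square without continuity
  correction (unpaired) or McNemar's test (paired): exact two-sided binomial
  on the discordant counts $b, c$ when $b + c < 25$, else the large-sample
  $(b-c)^2/(b+c)$ form without correction. Degenerate tables (everyone on
  the same side, or no discordant pairs) report p = 1 by convention and are
  logged rather than erroring.

Cohen's d accompanies every continuous comparison — pooled-SD d for
unpaired designs, $d_z$ (mean difference over SD of differences) for paired
— and is reported even when the nonparametric branch was taken, since the
table format expects an effect size for each variable. Groups smaller than
4 report the comparison as not available. p-values are displayed to four
decimal places with a "<0.0001" floor; d to two; percentages to one.

McNemar's test treats pairs as before/after measurements; in a
contralateral-eye design it does not model the within-patient correlation
structure beyond pairing, and users of unpaired or single-group analyses
should contribute one eye per patient — both caveats are the user's
responsibility, not checked by the code.

## The standardized table

The table has a fixed row order: n; TIA, SIA, DV (D); CI (with geometric
mean in parentheses); ME (D); AE (°); IOS (with geometric mean); then the
five proportion rows. Two-group tables append p-value and Cohen's d columns;
the AE > 15° and AE < −15° rows carry no test (the three-bucket partition is
already tested through the ±15° row). Typography is fixed on purpose — the
point of a standardized table is that it looks the same in every paper. The
image is written as a 300-DPI LZW-compressed TIFF ("high resolution" made
concrete: the rendered table is over 2000 px wide), with CSV and JSON
exports carrying exactly the formatted strings shown in the image, byte
identical across runs.

## The cohort simulator

`sim_params()`/`generate_cohort()` produce 12-column datasets with known
ground truth, per eye:

* preoperative spectacle sphere ~ Normal(`sphere_mean`, `sphere_sd`);
  cylinder magnitude ~ Normal(`cyl_mean`, `cyl_sd`) truncated at
  `cyl_floor` (default 0.50 D, which keeps every eye above the 0.25 D TIA
  exclusion when the target is plano); axis uniform on [0°, 180°) or
  clustered (wrapped normal);
* the corneal-plane TIA toward the target is computed with the same optics
  the analysis uses; the achieved SIA has magnitude
  `ci_true`·|TIA| + N(0, `mag_noise_sd`) (floored at 0) and axis rotated by
  N(0, `rot_sd`) degrees;
* the postoperative corneal astigmatism is pre ⊕ SIA in double-angle space;
  the postoperative corneal sphere is the target sphere plus
  N(0, `residual_sphere_sd`); everything is back-propagated to the
  spectacle plane and written in negative-cylinder notation at full
  precision.

With all noise zero the construction is an algebraic identity: every eye
recovers CI = `ci_true`, AE = 0, and (at `ci_true` = 1, plano target) a
postoperative cylinder of exactly 0 — the test suite asserts this to
$10^{-10}$ through the complete write → read → exclude → analyze chain. With
noise, a 2,000-eye cohort at `ci_true` = 0.90, `rot_sd` = 5°,
`mag_noise_sd` = 0.10 D recovers a geometric-mean CI within [0.88, 0.92] and
a mean AE within ±0.5°.

What the simulator does *not* emulate: values quantized to clinical 0.25 D
steps, axis digit preference, measurement error on the preoperative
refraction itself, inter-eye correlation within patients, or dropout.
Passing the recovery tests therefore demonstrates the pipeline's internal
consistency — generator and analyzer agree about the optics and the vector
algebra — not robustness to real-world data pathologies.

The three bundled demonstration trials mirror common study designs — a
paired contralateral-eye laser-vision-correction comparison in hyperopic
astigmats (80 + 80 eyes, `ci_true` 1.00 vs 0.90), a single-group toric
phakic-IOL cohort with moderate-to-high cylinder (60 eyes, floor 1.00 D),
and an unpaired toric-IOL cataract comparison in myopes (70 vs 65 eyes) —
with parameters and seeds committed in `trial_fixture_params()`. They are
scenario-shaped synthetic data, not reproductions of any published dataset.
Fixtures are written as CSV; the reader accepts XLSX (first worksheet) and
CSV interchangeably.

## Numerical choices and degenerate inputs

* Axes are normalized into [0°, 180°); an entered 180 becomes 0. A zero
  magnitude forces axis 0 by convention (the axis of a zero vector is
  undefined).
* Vector cancellations in the simulator snap magnitudes below $10^{-9}$ D to
  exactly 0 so that "perfectly corrected" rows are written as literal zeros.
* Vertex correction refuses powers with $dF = 1$ (focal point at the
  cornea), far outside the clinical range.
* Scalar indices refuse TIA = 0 — unreachable in the pipeline because the
  exclusion rule runs first, but a hard error for direct callers.
* All randomness is seed-controlled; identical inputs produce byte-identical
  CSV/JSON exports.

## Problem sizes used in validation

The test suite exercises 1,000 random eyes against the power-matrix oracle,
10,000 double-angle round trips, a 2,000-eye recovery cohort, 50
cross-implementation statistical reference cases, and 500 null replicates
(n = 60 per arm) for the type-I calibration of the gated comparison, whose
empirical rejection rate is required to fall in [0.03, 0.07] at α = 0.05.
These sizes give stable checks at interactive runtimes.

## Limitations

Single- and two-group designs only; no ANOVA or multi-group post-hoc
machinery. No spherical-equivalent analysis, no flattening/steepening/torque
decomposition, no summated vector means or coupling statistics, and no
standard graph suite — this package produces the *table* and its
machine-readable exports. One worksheet per workbook; no patient IDs or
laterality bookkeeping.
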