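---
title: "Methods: targeted epigenetic age analysis with epiage"
author: "epiage authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted epigenetic age analysis with epiage}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiage)
```

## Scope and model

`epiage` implements the computational side of a blood epigenetic-aging
study design: deep targeted bisulfite amplicon sequencing (BA-seq) of a
small number of age-associated CpG sites, a linear epigenetic clock mapping
their methylation levels to donor age, group comparison of the resulting
delta-ages (predicted minus chronological age), reference-based leukocyte
deconvolution as a compositional covariate, and age-adjusted
telomere-length percentile analysis. The typical application is asking
whether a patient group (here: hospitalized COVID-19 patients, with or
without ARDS) shows epigenetic age acceleration relative to healthy
controls.

The core predictor is a linear clock over percent methylation levels
$\beta_j \in [0, 100]$:

$$\widehat{\mathrm{age}} = \sum_j w_j \beta_j + c,$$

and the package ships one concrete instance, the published three-CpG blood
clock (`three_cpg_clock()`):

$$\widehat{\mathrm{age}} = -0.34\,\beta_{CCDC102B} + 0.83\,\beta_{FHL2}
  + 1.18\,\beta_{PDE4C} + 3.86.$$

The deliberate combination of a hypomethylating site (negative weight) with
hypermethylating sites reduces shared PCR bias in the targeted assay.
Delta-age is $\widehat{\mathrm{age}} - \mathrm{age}$, positive values
meaning acceleration; group differences are tested with Welch's *t*
(two-sided).

### The percent scale

Everything in this package is on the percent scale $[0, 100]$. The
three-CpG coefficients only produce plausible adult ages on percent inputs;
on the fraction scale $[0, 1]$ the same coefficients cap predictions near
six years. Because silently mis-scaled input is the most dangerous failure
mode of a linear clock, `read_beta_matrix()` rejects any matrix whose
maximum value is $\le 1$ unless `fraction = TRUE` explicitly requests a
$\times 100$ conversion.

## Synthetic cohorts and what they do (not) emulate

All validation runs on synthetic data with known ground truth; the
generators are first-class, tested code.

* **Cohorts** (`generate_cohort()`): ages uniform on a configurable range
  (default 18–74 years, the validation range of the targeted assay).
  Uniform is the simplest distribution covering that range; no
  census-weighting is attempted. Group labels are multinomial draws over
  healthy / COVID without ARDS / COVID with ARDS.
* **Clock CpGs** (`simulate_betas()`): per CpG,
  $\beta = a + b\,\mathrm{age} + \mathcal N(0, \sigma^2)$, clipped to
  $[0, 100]$. Clipping biases means near the scale boundaries; the default
  models (baselines 80/10/15 %, slopes $-0.45/0.50/0.60$ % per year,
  $\sigma = 3$ %) keep betas far from the boundaries over the default age
  range, so the bias is negligible there. The assay's real noise magnitude
  is not publicly documented; $\sigma = 3$ % was chosen once so that the
  matched exact clock's analytic mean absolute error,
  $\sigma / |b_{\max}| \cdot \sqrt{2/\pi} \approx 4.0$ years, is comparable
  to published targeted-assay errors (about 4.2 years), and was not revised
  afterwards.
* **The matched exact clock** (`consistent_clock()`): given the generating
  models, returns weights with $\sum_j w_j b_j = 1$ and intercept
  $-\sum_j w_j a_j$, so noise-free betas map back to the generating age
  exactly. The allocation rule puts all weight on the CpG with the largest
  $|b|$ ($w = 1/b$, zero elsewhere): it maximizes signal per unit weight
  and gives the prediction error the closed form
  $\mathcal N(0, \sigma^2 / b_{\max}^2)$ that the parameter-recovery tests
  check against.
* **Bisulfite reads** (`simulate_reads()`): per read, a strand
  (original-top with probability 0.5 by default), an independent Bernoulli
  methylation state per CpG at the requested level, C$\to$T conversion of
  each non-CpG cytosine with probability 0.995 (typical bisulfite
  chemistry), and uniform substitution errors at $10^{-3}$ per base.
  Reads span the whole amplicon, as with 250 bp paired-end sequencing of
  shorter amplicons; read pairs are not simulated separately. PCR
  amplification bias curves and array-style intensities are deliberately
  not modeled. Per-read ground-truth states are attached, so the
  methylation caller can be checked read-for-read.
* **Leukocyte mixtures** (`simulate_cell_mixture_betas()`): profiles are
  fraction-weighted averages of a cell-type reference plus Gaussian noise.
  Per-sample fractions are Dirichlet draws around a healthy preset
  (granulocyte-dominated) or a COVID preset emulating lymphopenia with
  increased monocytes and granulocytes. The shipped 12-CpG reference is
  synthetic and clearly labeled as such (two discriminating CpGs per cell
  type); it is well conditioned but carries no biology. Real references
  load via `read_cell_reference()`.
* **Telomeres** (`simulate_telomeres()`): donor telomere length
  $\mathrm{TL} = 9.5 - 0.05\,\mathrm{age} + \mathcal N(0, 0.7^2)$ kb
  (adult lymphocyte scale), floored at zero, measured in triplicate with
  0.1 kb technical scatter.

Passing tests on these generators show that the pipeline recovers known
linear age signals, known mixtures and known attrition rates under
Gaussian noise; they cannot show robustness to batch effects, probe
failures, PCR bias, immune perturbations of clock CpGs, or non-Gaussian
assay artifacts in real cohorts.

All generators draw from a single integer seed; identical seeds give
byte-identical datasets.

## Amplicon alignment and methylation calling

Alignment targets the amplicon reference sequences themselves, not a
genome build. For a three-amplicon assay the amplicons are unique loci, so
genome-scale bisulfite alignment adds nothing except an external genome
dependency; this deviation from array/genome-based processing is
intentional and is the main respect in which the pipeline differs from a
general-purpose bisulfite workflow.

Each read is scored against every reference, both bisulfite strands, at
every offset, in bisulfite-collapsed space: original-top candidates
compare the C$\to$T-collapsed read against the C$\to$T-collapsed
reference; original-bottom candidates compare the G$\to$A-collapsed
reverse complement of the read against the G$\to$A-collapsed reference.
Collapsing makes methylation states cost-free, as in standard bisulfite
aligners. The lowest-mismatch placement wins if its mismatch fraction is
at most `max_mismatch_frac` (default 0.1); ties break by fewer mismatches,
fixed alphabetical reference order, smaller offset, then top strand.
Alignment is substitution-only: indels beyond the mismatch budget leave a
read unaligned, which is acceptable for amplicon data and keeps the scorer
exact and enumerable (the test suite checks it against a brute-force
all-offset scorer).

Methylation calling counts C versus T at each CpG cytosine in reference
coordinates (G versus A on the complementary strand for original-bottom
reads); other bases are sequencing errors and are ignored. Coordinates are
0-based half-open throughout, and a CpG is identified by the position of
its C on the top strand. CpGs with fewer than `min_coverage` informative
reads (default 100) are flagged and excluded from clock input: at 100
reads, binomial sampling noise on a level is at most
$100\sqrt{0.25/100} = 5$ percentage points sd, already several times the
assay noise model. Quality values are read but unused — no trimming is
applied. Overlapping read pairs, if presented, are counted as independent
single-end reads.

## Clock engine

`predict_age()` is a dot product plus intercept, with an optional
piecewise log/linear age transform (logarithmic below an adult age of 20,
linear above) provided default-off for applying published multi-tissue
coefficient sets that use it; the three-CpG clock uses the identity.
Missing required CpGs raise an error by default, naming the CpGs — silent
imputation distorts clocks; `drop_sample` and `mean_impute` are available
as explicit opt-ins. `fit_clock()` is unregularized OLS of age on betas:
the targeted-clock regime is a handful of CpGs fitted on tens of samples,
where elastic-net machinery of genome-wide clocks is out of place.
Collinear designs are refused with the aliased CpGs named. Coefficient
tables serialize as two-column TSV (`cpg_id`, `weight`) with a reserved
`(Intercept)` row and a `#transform=` comment, a format that accepts
published clock supplements with minimal editing.

## Leukocyte deconvolution

`estimate_cell_fractions()` solves the constrained projection

$$\min_f \|R f - b\|^2 \quad \text{s.t.} \quad f \ge 0,\ \textstyle\sum_k f_k \le 1,$$

with $R$ the reference profile matrix over its discriminating CpGs. The
inequality (rather than equality) sum constraint matches the projection
behavior of reference-based leukocyte estimation; renormalization to
$\sum f = 1$ is a post-hoc flag. The program is solved exactly as a
strictly convex quadratic program with the dual active-set method
(`quadprog::solve.QP`), the same solver family used by the established
methylation deconvolution implementations; an early penalty-row NNLS
formulation was abandoned after the active-set iteration of the available
NNLS routine proved unreliable on the augmented system. The test suite
checks the solver against an independent oracle that enumerates every
support set and solves the KKT conditions directly. Selection of
discriminating CpGs from sorted-cell data is out of scope — the reference
is an input.

## Telomere percentile analysis

Percentile curves over age are fitted by linear quantile regression
(pinball loss). No quantile-regression routine is available in the
package's dependency set, so the line fit is computed exactly: the optimum
of a pinball loss over a two-parameter line sits at a vertex defined by
two data points, and for reference cohorts up to 800 donors every point
pair is scored (the reference use case is a few hundred donors; larger
inputs fall back to a polished Nelder–Mead search from a subsampled exact
fit). Linear — not spline — curves are a deliberate modeling choice: a
few hundred reference points cannot support stable nonlinear quantile
fits, and adult lymphocyte telomere attrition is approximately linear.

Fitted percentiles are made non-crossing within the observed age range by
pooled-adjacent-violators adjustment of the curve values at the two ends
of the range (monotone at both ends of an interval implies monotone on all
of it for lines), with a negligible ($10^{-9}$ kb) strictifying offset on
ties.

A measurement's `delta_kb` is its triplicate mean minus the median (50th
percentile) curve at the donor's age; using the median curve as the
"age-adapted" baseline is a choice the underlying study design leaves
open (a mean regression would be the alternative). The attrition `band`
compares the measurement against the fitted percentiles at or below the
median only: the label is `"<q th"` for the lowest such curve the value
falls below, or `">=50th"` otherwise. Restricting bands to the lower half
keeps the label aligned with the clinical criterion of interest
(attrition below the 10th percentile) and makes a value exactly on the
median read `">=50th"` rather than `"<90th"`. Group comparison uses
Welch's *t* on `delta_kb` plus Fisher's exact test on the 2×2
below-10th-percentile counts — exact by design because those counts are
small; a zero row is legitimate and handled.

Ages more than 5 years outside the fitted range trigger an extrapolation
warning and a flag rather than an error.

## Statistics

Welch's *t* (two-sided throughout; the package wraps the standard
implementation and adds the degenerate-variance conventions: equal-mean
zero-variance groups give $p = 1$, unequal-mean ones $p = 0$).
`regression_metrics()` reports $R^2$, slope, intercept and the regression
F-test p-value of predicted on chronological age, with MAE computed on the
raw pairs — a constant prediction offset therefore inflates MAE while
leaving $R^2$ at 1, which is exactly why delta-age is reported separately.
PCA runs on centered, unscaled betas (all features share the percent
unit). No multiple-testing correction is applied by default across
per-clock or per-cell-type panels, mirroring raw pairwise reporting;
Bonferroni is available as a flag.

## Numerical choices and degenerate inputs

* Beta clipping to $[0, 100]$ happens after noise; documented bias near
  boundaries.
* Deconvolution fraction entries below $10^{-10}$ are snapped to zero.
* Alignment ties are resolved deterministically (mismatches, reference
  order, offset, strand), so results are order-independent.
* Zero aligned reads yield an empty call set with a warning; zero
  requested coverage yields an empty read set silently.
* All randomness flows from one integer seed per generator call; no
  generator touches the global RNG state.

## Validation scale

The shipped validation suite runs entirely on synthetic data at the
study's own scale: cohorts of 95 healthy + 47 COVID samples, 200-sample
parameter-recovery cohorts over 20 replicates, 3 amplicons × 3000 reads
for caller exactness, 200 random mixtures for deconvolution, 10,000 null
simulations for the type-I error of Welch's test, 356-donor telomere
references, and 50 independent replicas of the full null study. On the
null replica — COVID groups differing only in leukocyte composition, never
in methylation age — the pipeline must report non-significant delta-age
tests in at least 90 % of comparisons while still detecting the
composition shift, reproducing the design's qualitative headline under
its own null.

## Known limitations

* Placeholder amplicon sequences are synthetic; real assay references
  (primers, coordinates) must be supplied by the user.
* The shipped cell-type reference is synthetic; biological deconvolution
  requires a real sorted-cell reference.
* Array preprocessing (idat parsing, background correction) is upstream
  and out of scope; the pipeline consumes beta matrices.
* Indel-containing reads beyond the mismatch budget are dropped, not
  realigned.
* Telomere values are consumed as calibrated kb; instrument-level
  processing (internal-control scaling) is out of scope.
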