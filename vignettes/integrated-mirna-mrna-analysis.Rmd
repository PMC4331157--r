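---
title: "Integrated miRNA and mRNA differential expression analysis: models and methods"
author: "mirmeso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated miRNA and mRNA differential expression analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirmeso)
```

# The analysis problem

Distinguishing malignant pleural mesothelioma (MPM) from benign
asbestos-related pleural effusion (BAPE) on pleural specimens is a genuinely
hard diagnostic problem, and molecular markers measured on the effusion or
biopsy are an attractive complement to histology.  `mirmeso` implements a
complete two-platform analysis for this setting: a qPCR microRNA panel
quantified by the comparative cycle-threshold (CT) method, a normalized
microarray mRNA matrix analysed with a variance-floored signal-to-noise
statistic, per-marker ROC evaluation, and a Bayesian model-based gene set
analysis (MGSA) that integrates the two platforms at the pathway level.  The
pipeline is written for the unbalanced two-group design (18 cases vs 6
references) but accepts any binary labelling, so histology or stage
subgroups can be compared with the same functions by changing
`case_label`/`ref_label` in `meso_config()`.

Because no raw per-sample data ship with the package, a synthetic-data
generator reproduces the statistical structure of such a study with known
ground truth; every claim the test suite makes about recovery, error rates
and ranking is computed against that planted truth.

# Comparative-CT quantification of the miRNA panel

Each well of the qPCR panel yields a cycle threshold $C_T$; lower values
mean more template.  The analysis chain is:

1. **Truncation.** $C_T$ values above the detection limit (35 cycles) are
   set to 35 and flagged as censored.  Truncated wells stay in all
   downstream means and tests: dropping them would bias weakly expressed
   assays toward significance, truncating merely bounds them.
2. **Normalization.** $\Delta C_T = C_T(\text{assay}) - C_T(\text{U6})$ is
   computed per sample against the sample's own endogenous control.  Group
   means of per-sample $\Delta C_T$ coincide with the difference of
   group-mean CTs whenever the control is stable, so this per-sample
   granularity is consistent with the classical "average minus average"
   formulation while also providing the per-sample values the t-test and
   ROC analysis require.
3. **Fold change.** With the reference-group mean as calibrator,
   $\Delta\Delta C_T = \overline{\Delta C_T}_{case} -
   \overline{\Delta C_T}_{ref}$ and fold change $= 2^{-\Delta\Delta C_T}$.
   Fixing the calibrator at the reference mean (rather than an arbitrary
   sample) is the only choice under which the reported group-mean pairs and
   fold changes of a published panel are mutually consistent, and it is the
   package's convention.
4. **Testing.** A two-sided Student t-test (pooled variance; Welch behind
   `meso_config(welch = TRUE)`) per assay on the per-sample
   $\Delta C_T$ values, corrected across assays by Storey q-values.
5. **Reporting filters.** An assay is called *up* only if $q < 0.05$, fold
   change $> 1$, **and** at most 3 case-group wells were censored — a
   heavily censored assay is never reported as upregulated regardless of
   its q-value.  Assays that amplified in no well at all are *excluded*.
   The *down* call uses nominal $P < 0.05$ with fold change $< 1$; it is
   deliberately looser because it only feeds the miRNA-target side of the
   integrated analysis, not a reported marker list.  Assays with fewer than
   two usable wells in a group keep an `ns` call with `testable = FALSE`
   rather than disappearing.

Degenerate inputs are resolved explicitly: an assay with zero variance in
both groups gets $p = 1$ when the group constants agree (no evidence) and
$p \to 0$ when they differ (infinite t-statistic).

# ROC evaluation

Low $\Delta C_T$ means high expression, so a sample is classified as a case
when its value falls at or below a cutoff.  The AUC is computed by the
Mann–Whitney pair-counting definition (ties count one half), and the
package's empirical ROC polyline is constructed so that its trapezoidal
area equals that statistic to $10^{-9}$ — an identity the tests verify
against the independent `pROC` implementation.  Cutoffs are chosen among
midpoints of adjacent distinct pooled values (plus $\pm\infty$) by maximum
Youden $J$; midpoints are used because an optimal threshold need not be an
observed value.  $J$-ties break toward higher specificity, then the lower
cutoff, making the output deterministic.

# Variance-floored SNR for the mRNA matrix

The pipeline consumes an already-normalized log2 intensity matrix (typical
range 2–15).  Probesets are ranked by

$$\mathrm{SNR} = \frac{m_{case} - m_{ref}}{s_{case} + s_{ref}},
\qquad s_g = \max(0.4\, m_g,\ \mathrm{sd}_g),$$

a standardized difference whose spread term is floored at 40% of the group
mean so that near-constant probesets cannot produce explosive ratios.  The
floor makes SNR scale-consistent where it binds (multiplying all
intensities by $c$ leaves SNR unchanged) and antisymmetric under label
swap.  Reporting requires $q < 0.01$, positive SNR and a case-group mean
above 3.5 log2 units — intensities below that floor are unreliable on such
chips.  A looser selection (SNR $> 0.2$ and nominal $P < 0.01$) feeds the
integrated analysis.  Downregulated probesets are computed and retained in
the table but never selected: in the motivating setting they did not
survive multiple-testing correction, and the package mirrors that
asymmetry while keeping the values transparent.

# Storey q-values

Both differential stages correct with Storey q-values rather than plain
Benjamini–Hochberg (BH).  The null proportion is estimated as
$\hat\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))$ over
$\lambda = 0.05, 0.10, \ldots, 0.95$, smoothed with a cubic spline
(df = 3) and evaluated at the largest $\lambda$, clamped to $(0, 1]$.
Below 100 tests the grid estimate is too noisy and a fixed
$\lambda = 0.5$ is used instead — relevant for the ~100-assay miRNA panel.
The q-values follow the step-up recursion
$q_{(m)} = \hat\pi_0\, p_{(m)}$,
$q_{(i)} = \min(\hat\pi_0\, m\, p_{(i)}/i,\ q_{(i+1)})$, which reduces
*exactly* to BH when $\pi_0 = 1$; the tests exploit this as an oracle
against `p.adjust`.

# Model-based gene set analysis

MGSA scores gene sets jointly instead of testing each set in isolation.
Each set $k$ has a hidden activation state $a_k \sim \mathrm{Bernoulli}(p)$;
a gene is hidden-on iff it belongs to at least one active set; the observed
study set is a noisy readout of the hidden gene states with false-positive
rate $\alpha$ (hidden-off gene observed) and false-negative rate $\beta$
(hidden-on gene missed).  The reported *estimate* per set is the marginal
posterior $P(a_k = 1 \mid \text{data})$.  Because all sets compete for the
same observations, redundant sets split posterior mass instead of all
inheriting significance — the property that makes the method suitable for
integrating overlapping canonical pathways.

Two inference routes are implemented.  Exact enumeration sums over all
$2^K$ activation vectors (feasible to $K = 20$; per-state sufficient
statistics are updated in Gray-code order so each state costs one set
update).  The Metropolis sampler (C++) uses single-set toggle proposals
plus independence moves over discrete hyperparameter grids, maintaining
the same sufficient statistics incrementally; estimates are post-burn-in
activation frequencies.  Defaults: $10^6$ steps, 20% burn-in,
$\alpha, \beta$ on 10-point grids over $[0.01, 0.3]$, $p$ on a 10-point
grid from $1/K$ to 0.3, uniform hyperprior, all marginalized.  Fixed
scalar hyperparameters are supported and are what the agreement tests use,
since enumeration and sampling must then target the identical posterior;
agreement within 0.03 at $10^6$ steps is verified on dozens of random
models.  Acceptance rates below 1% are recorded in the fit's diagnostics —
with a sharply concentrated posterior a low rate is expected and harmless,
which is why it is a diagnostic rather than an error.

The pathway-selection threshold (estimate $\ge 0.4$) is applied in the
integration stage, not inside `mgsa()`: the scorer is generic.

# Integration

The study set is the union of the overexpressed genes (integration
selection rule) and the targets of the downregulated miRNAs, intersected
with the population — the union of the pathway collection's members, which
is also the universe MGSA conditions on.  Per pathway the result table
reports population and study-set member counts, the posterior estimate,
and the three-way split of study genes (mRNA-derived, miR-target-derived,
both); the count identities (`n_both <= min(n_mrna, n_mir_target)` etc.)
are asserted property-style on every synthetic run.  Two further outputs
mirror the tables such a study reports: the genes both overexpressed and
targeted by a downregulated miRNA (one representative probeset per symbol,
chosen by maximum |SNR|, sorted by fold change) and the genes recurring in
two or more selected pathways.  miRNA naming differences between assay
panels and target collections are bridged by a normalization that strips
the species prefix and lowercases.

# The synthetic-data generator

The generator is first-class, tested code: it defines the conditions under
which every downstream claim is validated.  Defaults emulate the
motivating study design:

* 18 case vs 6 reference samples; 96 miRNA assays with 11 planted
  upregulated and 5 planted downregulated (the counts such a panel
  reported), shift magnitude 3 cycles, per-well Gaussian noise sd 0.5
  cycles, control assay at 20 ± 0.25 cycles, per-assay baselines uniform
  on [24, 33] so that down-shifted assays can cross the 35-cycle limit and
  exercise censoring; 1% of wells undetermined.  Censoring is simulated as
  *true CT above the limit* (raw values are not pre-truncated), so the
  truncation rule is genuinely exercised downstream.
* 2000 probesets with 40 planted overexpressed at log2 effect 3.5 and
  noise sd 0.7 (the scale of the strongest reported probesets), baselines
  uniform on [2, 15], planted baselines on [3, 4.5] — matching the
  reference-group means of reported probesets and keeping the clamping at
  the range floor from biasing the planted effect; 15% of probesets
  unannotated; a 1600-symbol gene pool so symbols recur across probesets.
* 10 pathways of 20–60 genes, one planted active at 80% enrichment from
  the planted signal genes; one target set of 100 genes per planted
  downregulated miRNA, each seeded with 3 planted overexpressed genes so
  the overexpressed-and-targeted intersection is non-empty by
  construction.  The gene universe is the union of pathway members.

Gaussian CT noise is the standard qPCR assumption; nothing in the
generator models amplification efficiency, probe-level microarray effects,
batch structure, or correlated noise, so passing tests demonstrate the
statistical machinery under idealized independence — not performance on
real chips.  A note on recovery bands: with noise sd 0.7 and $n = 18/6$
the group-mean difference of one probeset has standard error
$0.7\sqrt{1/18 + 1/6} \approx 0.33$, so a ±0.5 band can only hold about
87% of the time; the tests therefore check the tight band at its
theoretical rate and a 2-SE band at 95%.

# Problem sizes and numerical choices

The test-suite and acceptance-script problem sizes are the package's
validation design: 100-seed recovery runs at the full default design for
the expression arm; 50–60 random models for sampler/enumeration agreement
at $10^6$ steps; 1000 random datasets for the ROC/Mann–Whitney identity;
200-replicate Monte-Carlo checks of the generator's contracts.  Row-wise
t-tests are computed vectorized (validated against `stats::t.test`),
which keeps a full 2000-probeset analysis at a few milliseconds.
Tolerances: algebraic identities at $10^{-9}$–$10^{-12}$; Monte-Carlo
agreement at 0.03 for $10^6$-step chains; BH equivalence at $10^{-12}$
(floating-point associativity only).

# Known limitations

* The comparative-CT model assumes perfect doubling per cycle; efficiency
  corrections and multi-plate batch effects are out of scope.
* Whether censored wells should enter group means at the limit or be
  omitted is a genuine ambiguity of the method; the package
  truncates-and-includes, and records censoring counts so users can apply
  stricter policies.
* $\pi_0$ estimation is noisy below a few hundred tests; the fixed-λ
  fallback trades a little conservatism for stability.
* MGSA estimates are Monte-Carlo quantities; two seeds agree only within
  sampling tolerance unless enumeration applies.
* Probeset-to-gene collapse keeps the single max-|SNR| probeset per
  symbol for reporting; alternative summarizations (mean, median polish)
  are not offered.
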