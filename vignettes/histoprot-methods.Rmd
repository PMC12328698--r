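---
title: "Methods: histotype stratification of ovarian tumor proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: histotype stratification of ovarian tumor proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoprot)
```

# Overview

`histoprot` implements an end-to-end analysis of a label-free DIA proteomic
cohort of epithelial ovarian tumors: presence filtering and log2
transformation of a wide protein-abundance table, empirical-Bayes
moderated-t differential abundance per histotype, elastic-net prefiltered
stepwise SVM biomarker-panel selection, preranked gene-set enrichment and
hypergeometric over-representation analysis, and a proteome-wide prognostic
Cox screen with bootstrap validation. Because real patient-level data are
not bundled, every stage is exercised on a synthetic cohort generator whose
statistical structure matches the assumptions the downstream methods make,
so that parameter recovery — not reproduction of any particular clinical
dataset — is the testable claim.

# Ingest

The input is a proteins-by-samples grid of raw MS2 intensities. Cells that
are empty, non-numeric, `NaN`, `Filtered`, or exactly zero are treated as
missing: a DIA intensity of zero encodes non-detection. A protein is
retained when at least one sample group (histotype) quantifies it in at
least 70% of its members; the threshold is inclusive (`>= 0.70`), and
proteins that sit exactly on the boundary are reported, because the two
natural readings of a "70% rule" (strictly over vs at least) differ only
for these rows. Retained values are log2-transformed once; the container
tracks its scale so a second transform is an error. Missing values are
never imputed at ingest — each downstream stage defines its own handling,
which keeps the ingest layer free of modeling decisions.

# Differential abundance

For a contrast between sample sets $A$ and $B$, each protein is tested on
its complete observations with a pooled-variance two-sample statistic whose
variance is shrunk toward an empirical-Bayes prior. With per-protein pooled
variance $s^2$ on $df = n_A + n_B - 2$ degrees of freedom and prior
$(d_0, s_0^2)$,

$$ s^2_{\text{post}} = \frac{d_0 s_0^2 + df\, s^2}{d_0 + df}, \qquad
   t = \frac{\bar{x}_A - \bar{x}_B}{s_{\text{post}}\sqrt{1/n_A + 1/n_B}}, $$

referred to a t-distribution on $df + d_0$ degrees of freedom. $d_0 = 0$
recovers the ordinary pooled t-test and $d_0 = \infty$ fixes all variances
at $s_0^2$; both limits are asserted numerically in the test suite.

The prior is estimated by method of moments on the log variances:
$e = \log s^2 - \psi(df/2) + \log(df/2)$ has mean
$\log s_0^2 + \psi(d_0/2) - \log(d_0/2)$ and variance
$\psi'(df/2) + \psi'(d_0/2)$, so $d_0$ solves
$\psi'(d_0/2) = \operatorname{Var}(e) - \overline{\psi'(df/2)}$ by monotone
root-finding on the strictly decreasing trigamma function. When the excess
dispersion is non-positive the prior is infinite and $s_0^2$ is taken from
the mean of $e$ (matching the mean of the log variances); note that this
geometric-mean-flavored estimator is the one consistent with the moment
identity above, and it is what the package reports in the degenerate case.
With heterogeneous per-protein variances the whole estimator agrees with
limma's to high precision, which the test suite uses as an independent
cross-check.

One-vs-rest contrasts label all other samples as a single combined group;
Benjamini-Hochberg adjustment is applied within each contrast separately.
A protein is a DAP when FDR $< 0.05$ (strict) and its linear fold change
is at least 1.5, i.e. $|\log_2 FC| \ge \log_2 1.5 \approx 0.585$; the
fold-change cutoff is interpreted on the linear scale (a log2-scale
reading of "1.5" would exclude markers with $\log_2 FC$ below 1.5 that
are unambiguously reported as DAPs in this kind of analysis) with an
inclusive boundary. Pairwise Wilcoxon rank-sum tests (BH-adjusted across
the pairs of one protein) provide figure-style group comparisons.

# Biomarker panels

Candidates for a two-class comparison are the comparison's DAPs, reduced
by elastic-net-penalized logistic regression ($\alpha = 0.5$) with 5-fold
cross-validation scored by AUC; proteins with non-zero coefficients at the
AUC-optimal $\lambda$ ("lambda min") form the pool. Panel construction
then uses one stratified 80/20 train/test split fixed by the seed and
shared by every model of the search:

1. each candidate is evaluated alone and the best test AUC seeds the
   panel;
2. remaining candidates, in descending single-protein test AUC (ties
   lexicographic), are tentatively added and kept only on a strict AUC
   increase, repeating until a full pass adds nothing;
3. candidates keep being added while the resulting AUC stays within one
   percentage point (absolute 0.01) of the maximum achieved, enlarging
   the panel without penalizing performance, capped at five proteins.

The SVM is a C-classification machine with a linear kernel and cost 1 by
default — the kernel is a genuinely open choice at $p \gg n$, and the
linear machine is stable, deterministic, and interpretable; an RBF kernel
is available via a parameter. Features are standardized on the training
split; missing abundances are imputed with training-split medians so no
test information leaks into the model. AUC is the rank-based (Mann-Whitney)
statistic with ties credited one half, identical to the trapezoidal area
under the empirical ROC. Sensitivity and specificity are reported at
decision threshold 0. Comparisons with fewer than two DAPs are skipped,
mirroring the exclusion of comparisons that yield too few DAPs for SVM
modeling.

One shared split per comparison (rather than a fresh split per candidate
model) was chosen so that AUCs of competing panels are comparable and the
procedure is a deterministic function of `(data, seed)`; whether the
original procedure reused one split is not documented, so the reproducible
variant is implemented.

# Enrichment

GSEA operates on the full tested proteome ranked by one-vs-rest log2 fold
change, highest to lowest, ties broken by smaller p then symbol, duplicate
symbols collapsed to the largest-magnitude entry. The enrichment score is
the classic weighted Kolmogorov-Smirnov running sum (weight 1): members
increment by $|s|^w / \sum_{\text{hits}} |s|^w$, non-members decrement by
$1/(N - N_{\text{hit}})$, and the score is the maximal signed deviation.
The null is gene permutation — random member sets of matching size drawn
from the ranked universe — with the normalized score defined as the
observed ES divided by the mean absolute null ES of matching sign, and a
one-sided permutation p with the standard $+1$ correction. This fully
specified permutation scheme is used instead of a multilevel/adaptive
estimator precisely because it is testable against hand-computed running
sums and calibration checks. Default set-size bounds are 10-500 and the
default FDR cutoffs are 0.05 for GO-style collections and 0.20 for
hallmark-style collections, both configurable. Null permutations are
shared across sets of equal size, and the per-permutation score is
evaluated in $O(k)$ from the sorted hit positions (the running-sum
extremes can only occur at a hit or immediately before one); the test
suite verifies this fast path against the full running sum.

ORA is the hypergeometric upper tail $P(X \ge k)$ for $k$ hits among a
term's $K$ universe members given $n$ hits in a universe of $N$, BH
adjusted across terms. Collections are user-supplied GMT files; no
ontology graph is downloaded or propagated.

# Survival screen

Per histotype and endpoint (OS, DSS) the cascade is: univariate Cox on
each protein's log2 abundance (complete cases; at least 10 cases and 3
events) keeping Wald $p < 0.05$; median-split log-rank filter at
$p < 0.05$ (values equal to the median go to the low stratum, a
deterministic convention); L1-penalized Cox over the clinical covariates
only (stage, age, log CA-125, residual tumor size) with $\lambda$ by
5-fold cross-validated partial likelihood, the non-zero coefficients
becoming the adjustment set; covariate-adjusted Cox per protein with BH
adjustment of the protein Wald p across the stream's proteins; and
bootstrap validation — 1000 patient resamples with replacement, refitting
the adjusted model with the covariate set fixed from the full data, and
averaging the protein Wald p over resamples that fit (resamples with too
few events, a constant covariate, or a failed fit are skipped and
counted; more than 50% skips marks the validation unreliable). A protein
is classified favorable (HR $< 1$) or unfavorable (HR $> 1$) only when the
95% Wald CI excludes 1, FDR $< 0.05$, and the mean bootstrap p is below
0.2. Ties use the Efron correction throughout. Covariates missing in more
than 30% of a stratum are dropped from candidacy rather than imputed.

Two points are worth noting for interpretation. First, the covariate set
is selected once on the full data and held fixed inside the bootstrap;
re-running selection per resample would mix selection variability into
the robustness estimate of the protein coefficient, which is the quantity
of interest. Second, the mean bootstrap p of a null protein is not 0.5:
resampling preserves whatever chance association the observed data
carries, so the null mean sits near a third in simulation — the 0.2 gate
still rejects the large majority of null proteins while retaining planted
effects essentially always, which is exactly the behavior the test suite
asserts.

# Synthetic cohort generator

The generator is first-class, tested code and defines the study
conditions. Defaults: 300 samples in eleven groups (HGSC 122, LGSC 8, EC
42, MC 35, CCC 45; borderline SBL 16, MBL 10, SMBL 4, EBL 1; benign SB
11, MB 6); 1000 proteins with baseline log2 intensities
$\mathcal{N}(20, 1.5^2)$; per-protein residual variances drawn from a
scaled inverse-chi-square with $d_0 = 4$, $s_0^2 = 0.5$ — exactly the
prior family the moderated t assumes, which is what makes prior recovery
a testable property; a deterministic effect table planting 12 up- and 8
downregulated markers (|log2 FC| 1-3) in each of the four main carcinoma
histotypes, mimicking strong histotype-private markers.

Missingness is missing-not-at-random through a logistic link on the
latent log2 intensity, $P(\text{miss}) = \max(r_0,
\operatorname{logit}^{-1}(a + b \cdot x))$ with defaults $a = 14.5$,
$b = -0.8$, floor $r_0 = 0.01$: low-abundance proteins drop out
preferentially, the dominant DIA mechanism. Under the defaults about a
quarter of cells are missing and a few percent of proteins fall below
the 70% presence rule, a deliberately DIA-like regime.

Survival uses a Weibull baseline (shape 1.2, scale 2500 days) under a
proportional-hazards linear predictor via the closed-form inverse
transform, exponential censoring (rate 1/4000 per day), and
disease-specific deaths thinned from overall deaths with probability 0.8,
giving OS and DSS endpoints with a shared risk structure. Default
covariate effects are stage (+0.35 per stage) and two proteins
($\pm 0.35$ per log2 unit). All of these are calibration choices of the
generator, not estimates of any real cohort: the generator does not
attempt peptide-level effects, retention time, batch structure,
correlated protein modules, or non-proportional hazards, so passing tests
demonstrate correctness of the statistical machinery under its assumed
model, not performance on real tissue data.

Everything is a deterministic function of the configuration including its
seed; the generator saves and restores the caller's RNG state.

# Numerical choices and degenerate inputs

- Trigamma inversion brackets geometrically and solves with `uniroot` to
  `1e-10`; the test suite checks it against plain bisection.
- Proteins with fewer than two complete observations on a contrast side
  are skipped with a reason, never imputed.
- The GSEA tie between equal positive and negative running-sum deviations
  resolves to the positive peak.
- Separation / monotone-likelihood Cox fits are flagged `converged =
  FALSE` (also when $|\hat\beta| > 15$) rather than errored, and are
  skipped inside the bootstrap with explicit bookkeeping.
- The SVM decision function is re-oriented so larger values indicate the
  positive class regardless of the solver's internal label order.
- BH adjustment delegates to `p.adjust(method = "BH")`; a hand-coded
  step-up oracle in the tests pins the definition.

# Problem sizes used in the checks

The bundled drivers and tests run the default 1000-protein, 300-sample
cohort for end-to-end stages; calibration properties use 200-5000
replicated draws per seed with 10-100 seeds depending on the Monte-Carlo
error of the quantity; bootstrap validation is exercised at its full
default depth of 1000 resamples where the claim concerns the default, and
at 40-250 resamples inside broader cascade checks. The analysis drivers
cap the bootstrap stage at the 10 most significant proteins per stream;
`survival_screen(max_proteins = Inf)` removes the cap for a full screen.

# Known limitations

- The moderated-t model is two-group only; covariate-adjusted abundance
  models are not implemented.
- GSEA reproduces the classic gene-permutation statistic, not the
  adaptive multilevel p-value estimator of modern implementations, so
  very small enrichment p-values saturate at the permutation resolution.
- The prognostic screen treats DSS by cause-thinning rather than
  competing-risks modeling, and no proportional-hazards diagnostics are
  run.
- The synthetic generator's independence assumptions (no protein-protein
  correlation beyond planted effects) make recovery tasks easier than in
  real proteomes; tolerances in the tests are calibrated to the
  generator, not to real-data difficulty.
- The prognostic cascade computes BH-FDR on proteins that already passed
  two p < 0.05 filters, and the bootstrap resamples the same data that
  produced the candidate; both inherit the selection bias of this
  screen-then-validate design. On null streams the cascade therefore
  still classifies a handful of its top hits — the screen ranks and
  filters candidates, it does not certify them, and the synthetic null
  runs in `analysis/05_survival_screen.R` make that visible.
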