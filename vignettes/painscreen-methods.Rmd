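---
title: "painscreen: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{painscreen: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
statistical model behind each stage, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the places where
the design was genuinely open and a choice had to be made.

## 1. The disease-specific phenotype index

The index assumes that the *fraction* of a disease's literature that is
co-annotated with a phenotype heading is a usable proxy for how central the
phenotype is to the disease. For disease $d$ with $n_{tot}(d)$ citations of
which $n_{ph}(d)$ carry the phenotype annotation, the ratio is
$r_d = n_{ph}(d)/n_{tot}(d) \in [0,1]$. Two consequences of this definition
drive the implementation:

* **Inclusion rule.** A disease enters the index only with at least one
  co-citation ($n_{ph} \ge 1$). Ratios are not weighted by publication
  volume: a rarely studied but consistently painful disease counts as much
  as a heavily studied one.
* **Ties.** Many diseases share a ratio (notably 1.0 at small $n_{tot}$).
  `build_index()` assigns midranks — the average of the tied rank
  positions — which is the Spearman convention and makes the downstream
  correlation well defined without inventing an order among tied diseases.
  The deterministic presentation order (ratio, then total citations
  descending, then id) exists only so output files are reproducible; it
  never influences a statistic.

The default ordering is ascending (least phenotype-associated first), so a
positive screen correlation means expression rises with phenotype
association. Veterinary-disease removal is supported as a caller-supplied
id blocklist; the package has no species knowledge of its own.

## 2. Rank Product differential expression

Per disease, a case/control study on the log2 scale is reduced to

* a signed fold change per gene, `mean(case) − mean(control)`, and
* Rank Product significance: in each of the $K$ pairwise case×control
  comparisons genes are ranked by their expression difference (descending
  for the up test, ascending for down) and
  $RP_g = (\prod_k \mathrm{rank}_{g,k})^{1/K}$.

The null replaces each comparison's rank vector by a uniformly random
permutation; p-values pool null statistics over genes and permutations,
$p_g = (\#\{RP^{null} \le RP_g\} + 1)/(G \cdot B + 1)$, with an exhaustive
mode that enumerates all $(G!)^K$ assignments on tiny problems (this
exhaustive enumeration is also what the test suite's independent oracle
recomputes). Directions are combined by keeping a gene if either one-sided
q-value passes the threshold (default 0.05), the signed fold change
carrying direction — both positively and negatively trending genes must
survive to the screen.

**Known limitation.** With all pairwise comparisons over shared samples the
observed comparisons are correlated while the permutation null draws them
independently, so null p-values are over-dispersed (small p-values enriched;
we measure $P(p \le 0.05) \approx 0.13$ under a 3×3 null). This is a
property of the published unpaired Rank Product recipe itself, not of this
implementation; the permutation machinery is exactly calibrated when
comparisons share no samples (e.g. one case vs one control), which is what
the calibration test asserts. Downstream, the q ≤ 0.05 filter therefore
behaves as a generous inclusion gate rather than an exact FDR guarantee —
acceptable because the screen's own permutation pFDR, not the DE q-value,
controls the final candidate list.

Storey q-values are computed in-package: $\hat\pi_0$ from the
$\lambda$-grid 0.05–0.95 (step 0.05) with a cubic smoothing spline
evaluated at the grid maximum, clipped to $(0,1]$; with fewer than 100
p-values the smoother is unstable and $\pi_0 = 1$ is used, which reduces
the estimator to Benjamini–Hochberg (slightly conservative).

## 3. The correlation screen and its permutation pFDR

Fold changes are assembled into a gene × disease matrix in index order;
genes must be observed in at least $\lceil 0.10 \cdot D \rceil$ of the $D$
disease columns ("at least 10%" is a floor, hence the ceiling). Per gene,
Spearman's $\rho$ is computed pairwise-complete against the index midranks,
re-ranking both sides within the gene's observed columns (tie-corrected via
Pearson on midranks). Since Spearman depends only on ranks, the screen is
invariant to any strictly increasing transform of the fold changes — which
is also why the choice between raw and rank-transformed fold changes on the
input side is immaterial, and the package does not offer it as an option.

The pFDR estimator permutes the disease ranks (one shuffle per replicate,
shared by all genes), recomputes every gene's correlation on its own
missingness pattern, and sets, for each gene's threshold $|\rho_g|$:
$R$ = observed genes at or above the threshold, $E[V]$ = average number of
null correlations at or above it per permutation (pooled over genes), and
$\mathrm{pFDR}_g = E[V]/R$, clipped at 1 and made monotone nonincreasing in
$|\rho|$. Three choices here were open and are deliberate:

* **Per-gene thresholds** (rather than one global rejection threshold):
  each gene is assigned the pFDR of the smallest rejection region that
  contains it, the shape a per-gene significance column requires.
* **Missingness handling:** permutations shuffle rank labels, not values,
  so each gene's null is matched to its own number of observations.
* **Pooling the null across genes** borrows strength (at 1000 permutations
  and hundreds of genes the null tail is well resolved) at the price of
  mixing null distributions across different $n_{obs}$; since the
  per-gene observed statistic is compared against the same pooled
  reference used for $R$'s peers, calibration holds on average, which the
  fully-null calibration test measures directly (fraction of genes at
  pFDR < 0.01 stays ≈ 0).

An exhaustive mode enumerates all $D!$ disease-rank permutations for
$D \le 8$ and is the internal oracle the sampled estimator is tested
against.

## 4. ROC validation

Priority = pFDR ascending with $|\rho|$ descending as tie-break, reduced to
a single score by (mid)rank reversal. The AUC is the Mann–Whitney
concordance probability with tie correction, identical to trapezoidal
integration of the curve on tie-free data (asserted to 1e−12 in tests);
the reported cutoff maximizes Youden's $J$. Confidence bands repeat the
whole scoring on delete-$d$ subsets of the diseases (default: keep 90% per
replicate) and summarize replicate curves pointwise on a fixed
false-positive-rate grid; both a normal-theory standard-error envelope and
empirical 2.5/97.5% quantiles are returned because the choice between them
is a reporting convention, not a modelling one.

## 5. Twin association by pair-averaged GLS

Rather than modelling within-pair correlation explicitly, each twin pair is
collapsed to one observation: phenotype transformed per individual
(identity for heat in °C; log for the positive, right-skewed cold times;
optionally rank-based inverse-normal with the Blom offset
$(r - 3/8)/(n + 1/4)$), then averaged; dosages averaged (MZ pairs stay
integer, DZ pairs may take half-integers); sex coded −1/1 and averaged so
mixed-sex DZ pairs sit at 0. The transform is applied *before* averaging so
the regression error model lives on one scale. Units carry a variance-group
label (MZ-M, MZ-F, DZ-M, DZ-F, DZ-mixed, singleton-M/F; groups with fewer
than 2 units merge into their zygosity pool) and the model

$$\bar y = \beta_0 + \beta_g \bar g + \beta_{sex}\,sex + \beta_{dep}\,dep
  + \varepsilon,\qquad \mathrm{Var}(\varepsilon) \text{ diagonal, constant
  within group}$$

is fitted by iterated feasible GLS: OLS start, group variances from
residual sums of squares over leverage-adjusted group degrees of freedom
(floored), reweighting, iterating to a relative coefficient change below
1e−8 (max 50 iterations). Forcing a single variance group reproduces OLS
coefficients exactly, which is the regression's sanity anchor.

**Small-sample correction.** Because the weights are estimated, the
model-based covariance $\Phi = (X'\hat\Sigma^{-1}X)^{-1}$ understates the
sampling variance of $\hat\beta$; at ~200 units across 5–7 groups this
inflates the nominal 5% test to ≈ 6.5% (plugging in the *true* generator
weights gives 4.95% over 4000 replicates, isolating estimated-weight noise
as the cause). A first-order
propagation of the group-variance estimation error (Kackar–Harville-type)
gives the reported covariance

$$\widehat{\mathrm{Var}}(\hat\beta) = \Phi + 2\sum_k
  \frac{\Phi\,X_k'X_k\,\Phi}{\nu_k\,\hat\sigma_k^2},$$

with $\nu_k$ the group's leverage-adjusted degrees of freedom. With it the
null rejection rate at $\alpha = 0.05$ is 0.054 over 4000 replicates of
pairs-only 200-pair cohorts — the residual half-point of anticonservatism
is the higher-order remainder of the same effect. Wald p-values use a
$t_{n-p}$ reference.

Surrounding machinery follows the standard association recipe: dosages are
oriented so 0 counts the cohort-major (wildtype) allele (ties keep the
supplied reference orientation); QC removes SNPs with call rate < 90%,
MAF < 5%, or 1-df HWE $\chi^2$ p < 0.01; allele frequencies, HWE and
composite LD $r^2$ (squared Pearson correlation of dosage vectors) use one
member per MZ pair so duplicated genomes cannot bias them — the package
extends the same deduplication to MAF for the same reason. Missing
genotypes impute to homozygous wildtype (dosage 0) per the stated
population rule; when that contradicts an observed non-wildtype MZ co-twin
a warning is raised rather than silently copying the co-twin, because the
rule, not the genome, is the contract. Cold-threshold observations at the
180 s test ceiling are flagged as outliers and excluded. Bonferroni uses
$m$ = SNPs passing QC, applied per phenotype; $m$ is recorded and
configurable since the original multiplier convention is ambiguous.
Cohen's $d$ (pooled-SD standardized mean difference) and Welch's t
(via `stats::t.test`) serve the group-contrast reporting.

## 6. What the synthetic data does and does not emulate

* **Citations:** phenotype propensity is 0 with probability 0.3, otherwise
  Beta(0.6, 4) — many near-zero ratios, occasional ratios near 1, and a
  population of diseases excluded by the inclusion rule. Totals are
  negative-binomial (mean 200, heavy-tailed). The mixture's closed-form
  mean is the oracle for the generator's own test. The point-mass/Beta
  shape is a modelling choice for the observed ratio-distribution shape,
  not a claim about literature dynamics.
* **Expression:** planted genes get a true case-minus-control difference
  linear in the index midrank (`planted_slope` per rank step, sign
  randomized per gene, centred); per-sample noise is scaled so the fold
  change has standard deviation `noise_sd`; genes go missing from a study
  independently with `missing_fraction`. Defaults (slope 0.05, noise 0.3,
  so fold-change signal-to-noise ≈ 2 across a ~35-disease index; 500 genes
  with 25 planted) are the package's "moderate signal" study condition,
  chosen by power reasoning once. Probe-level intensities, batch effects
  and platform heterogeneity are *not* simulated — passing tests show the
  statistics behave as designed, not that real microarray curation is
  solved.
* **Twins:** genotypes come from explicit parental-haplotype transmission
  (MZ identity exact, DZ correlation 0.5 in expectation, HWE by
  construction); phenotypes follow the GLS mean model with group-specific
  individual-level residual variances (defaults 0.8–1.4, female and DZ
  groups noisier) split into a pair-shared environmental part
  (`pair_env_corr` = 0.3) and an individual remainder; depression is a
  clipped negative-binomial Beck-like integer score. Cohort scale defaults
  (90 pairs, 70% MZ, 5% singletons) mirror a mid-sized twin panel. There
  is no LD structure between simulated SNPs — LD code is exercised on the
  null expectation and on designed proxies only — and no real phenotype
  scale calibration: cold times are log-normal around 12 s/45 s with a
  180 s ceiling, picked for testability.

## 7. Numerical and procedural choices

* Permutation defaults: 1000 for both the Rank Product and the screen
  pFDR; exhaustive enumeration bounds: 8 diseases ($8! = 40320$ rank
  permutations), $(G!)^K \le 2 \times 10^5$ assignments for RP.
* p-value smoothing `+1/+1` keeps permutation p-values off 0.
* pFDR clipping at 1 and monotone enforcement in $|\rho|$ follow standard
  step-up practice; the raw ratio $E[V]/R$ can exceed 1 and invert.
* Degenerate inputs have defined behaviour: monomorphic SNPs are HWE-p 1
  (nothing testable) and LD-undefined (NA); constant-dosage designs and
  all-excluded indices raise typed errors; a fully tied vector
  quantile-normalizes to zeros; genes observed in < 3 diseases are
  excluded from correlation with a logged NA.
* The pipeline derives per-stage sub-seeds from the single run seed, so
  stages rerun independently still reproduce; no output carries a
  timestamp, making whole-pipeline reruns byte-identical.
* Problem sizes in the test-suite study conditions (e.g. 60-disease
  index, 500 genes/25 planted, 200 pairs, 500 null replicates for GLS
  calibration) are the package's chosen benchmark scale: large enough for
  the Monte-Carlo bands asserted, small enough to run as routine tests.

## 8. Known limitations

* The index inherits literature bias: a painful but under-studied disease
  ranks low. Nothing in the package corrects for publication attention.
* The screen favours genes with *gradual* expression trends across many
  diseases; genes acting in a few specific conditions, or in tissues not
  sampled by disease studies, are invisible to it.
* The unpaired Rank Product null's over-dispersion (Section 2) makes the
  DE gate permissive; consumers needing strict per-disease FDR should
  tighten `de_q` or supply their own DE tables.
* The GLS stage tests one SNP at a time with additive dosage coding; no
  kinship matrix, no haplotype phasing, no epistasis.
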