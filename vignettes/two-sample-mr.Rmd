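---
title: "Two-sample Mendelian randomization for microbiome exposures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization for microbiome exposures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micromr)
```

## The problem and the model

Microbiome–disease associations from observational cohorts are confounded by
diet, medication, and reverse causation. Two-sample Mendelian randomization
(MR) sidesteps this by using germline variants as instruments: a SNP that
shifts the abundance of a gut taxon (or the level of a microbial metabolite,
or the activity of a microbial pathway) is randomized at conception, so its
downstream association with a disease outcome estimates the causal effect of
the exposure, provided the instrument assumptions hold — relevance,
independence from confounders, and exclusion (no path to the outcome except
through the exposure).

The package works entirely from GWAS summary statistics: per-SNP effect
sizes $\hat\beta_{Xj}$ on the exposure (one GWAS, e.g. a 16S-based taxon
abundance study of $n \approx 18{,}000$ individuals) and $\hat\beta_{Yj}$ on
the outcome (a second, non-overlapping GWAS, e.g. a respiratory-infection
case–control cohort; effects on the log-odds scale). The per-SNP causal
estimate is the Wald ratio $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$
with first-order standard error
$\mathrm{se}_j = \mathrm{se}_{Yj}/|\hat\beta_{Xj}|$, and the five estimators
combine the $\hat\theta_j$ in ways that trade efficiency against robustness
to pleiotropy:

* **IVW** — fixed-effect inverse-variance meta-analysis,
  $\hat\theta = \sum_j w_j \hat\theta_j / \sum_j w_j$ with
  $w_j = \hat\beta_{Xj}^2/\mathrm{se}_{Yj}^2$. Efficient; biased if any
  instrument is pleiotropic.
* **MR-Egger** — weighted regression of $\hat\beta_{Yj}$ on
  $\hat\beta_{Xj}$ with a free intercept, after orienting all
  $\hat\beta_{Xj} \ge 0$. The slope is consistent under InSIDE (instrument
  strength independent of direct effects); the intercept estimates the mean
  directional pleiotropic effect and is the pleiotropy test.
* **Weighted median** — the weighted 50% quantile of the
  $\hat\theta_j$; consistent while valid instruments carry more than half
  the weight.
* **Simple and weighted mode** — the argmax of a Gaussian kernel density
  over the $\hat\theta_j$; consistent while the largest cluster of
  instruments is valid.

Binary-outcome effects stay on the log-odds scale throughout and are
reported as $\mathrm{OR} = e^{b}$ with
$\mathrm{CI} = e^{b \mp z_{0.975}\,\mathrm{se}}$.

## Instrument selection

Defaults reproduce the thresholds conventional in microbiome MR, and every
comparison is strict:

| parameter | default | meaning |
|---|---|---|
| `p_threshold` | $1\times10^{-5}$ | suggestive-significance cutoff (microbiome GWAS rarely yield genome-wide-significant instruments); `p < threshold` kept |
| `maf_min` | 0.01 | minimum minor-allele frequency |
| `r2_threshold` | 0.001 | LD r² above which the weaker SNP is clumped away |
| `window_kb` | 10,000 | clumping window |
| `f_min` | 10 | weak-instrument cutoff; `F >= 10` kept |

Per-SNP variance explained uses
$R^2 = 2\,\mathrm{EAF}(1-\mathrm{EAF})\beta^2$ when fewer than ten
instruments are available (a standardized-trait approximation that can
exceed 1 for extreme effect sizes — we cap sums at 1 where a correlation is
formed from them) and the bounded form
$R^2 = \beta^2/(\beta^2 + N\,\mathrm{se}^2)$ otherwise. Instrument strength
is $F = \frac{R^2}{1-R^2}\cdot\frac{N-1-i}{i}$. The weak-instrument screen
is applied per SNP (each SNP's own $R^2$ with $i=1$, so
$F_j = \frac{R^2_j}{1-R^2_j}(N-2)$); the set-level $F$ with $R^2$ summed
over the clumped (hence approximately independent) instruments is reported
for each exposure. Whether the published convention sums or screens per SNP
is not stated anywhere we could verify; the per-SNP screen is the
conservative reading and the reported set-level F makes the other
convention recoverable from our output.

LD clumping is greedy on ascending p-value. Without a genotype reference
panel the package accepts a precomputed pairwise r² table; when none is
supplied, *distance-only* mode removes every same-chromosome SNP within the
window — a strictly more aggressive approximation, appropriate when
instruments are expected to be far apart (as the synthetic generator
guarantees by construction).

Confounder screening is file-based: a local TSV mapping SNPs to confounder
traits (HDL cholesterol, smoking, adiposity measures, ...) replaces any
live annotation-service query, keeping runs reproducible and offline.

## Harmonization

Outcome effects are re-expressed on the exposure's effect allele: swapped
alleles negate $\beta$ and reflect EAF; opposite-strand records are
complemented before matching. Palindromic SNPs (A/T, G/C) cannot be
strand-resolved from the letters, so strand is inferred from frequency:
kept only when both traits' EAFs fall on the same side of 0.5 **and** both
minor-allele frequencies are below `palindromic_eaf_limit` (default 0.42 —
frequencies closer to 0.5 than that are too uninformative to call). With a
missing outcome EAF a palindromic SNP is dropped unconditionally. Duplicate
SNP ids within a trait keep the smallest p-value. Every exclusion carries a
reason code in the harmonization log. Harmonization is idempotent, and
rewriting outcome records (swap and/or strand-complement with the matching
$\beta$/EAF adjustments) leaves the harmonized set bit-identical — both
properties are tested on randomized rewrites.

## Sensitivity analyses

* **Cochran's Q** with first-order weights,
  $Q = \sum_j (\hat\beta_{Yj} - \hat b\,\hat\beta_{Xj})^2/\mathrm{se}_{Yj}^2$,
  against $\chi^2_{n-1}$ (IVW) or, with the intercept model's residuals,
  $\chi^2_{n-2}$ (Egger). Heterogeneity is flagged at p < 0.05.
* **Egger intercept** with a $t_{n-2}$ test for directional pleiotropy.
* **Steiger directionality**: instrument-explained variance in the exposure
  ($\sum_j 2p_j(1-p_j)\hat\beta_{Xj}^2$) versus the outcome
  ($\sum_j z_j^2/(z_j^2+N_Y)$, an observed-scale approximation for binary
  outcomes); direction is exposure→outcome iff the exposure side is larger,
  with a Fisher-z two-sided p-value. Liability-scale conversion for
  case–control outcomes is deliberately not attempted; the observed-scale
  choice is conservative for common outcomes and is recorded in the output.
* **Bonferroni correction** per exposure category with divisors
  order 1, family 3, genus 15, metabolite 9, pathway 20 (configurable —
  these divisors are post-hoc counts of initially significant exposures in
  the motivating study design, not universal constants), strict comparison.

P-value conventions: IVW and weighted median use the normal distribution;
MR-Egger uses $t_{n-2}$; the mode estimators use $t_{n-1}$. The mode choice
follows the reference implementations of the mode estimator, whose
published tables are reproducible only under $t_{n-1}$ — we verified this
against the internally consistent rows of a published five-method report
table before freezing the convention into the tests.

## Estimator numerics

* Egger's coefficient standard errors use multiplicative residual inflation
  floored at 1 ($\hat\sigma^2 = \max(1, Q/(n-2))$); a perfect fit therefore
  degenerates gracefully to zero standard error rather than NaN.
* Median/mode standard errors come from a seeded parametric bootstrap
  (default `n_boot = 1000`; every pipeline run requires an explicit seed,
  so there is no silent nondeterminism). Point estimates are deterministic.
* Mode bandwidth is the modified Silverman rule
  $\phi \cdot 0.9\min(\mathrm{sd}, \mathrm{mad})\,n^{-1/5}$ with the MAD
  scaled to be sd-consistent and $\phi = 1$ by default; if both spread
  measures vanish (all ratios identical) the common ratio is returned. If
  only the MAD vanishes the sd is used, so a majority of identical ratios
  does not zero the bandwidth.
* Ties in clumping are broken by SNP id after p-value, making the greedy
  order deterministic.
* The Egger orientation flip ($\hat\beta_X \ge 0$) interacts badly with
  instruments whose observed exposure effect is near zero: noise can flip
  the sign and with it the sign of that SNP's pleiotropic effect, biasing
  both coefficients. In practice such instruments never reach Egger because
  the $p<10^{-5}$ selection bounds $|\hat\beta_X|$ away from zero; our
  pleiotropy simulations therefore apply selection before fitting, exactly
  as the pipeline does.

## What the synthetic generator emulates — and what it does not

`simulation_scenario()` / `simulate_pair()` draw summary statistics
directly at the summary level (no individual genotypes): for instrument
$j$, $\mathrm{EAF}_j \sim U(\texttt{eaf\_range})$, exposure effect
$\gamma_j = |N(0, \texttt{gamma\_sd}^2)|$,
$\mathrm{se}_{Xj} = (2p_j(1-p_j)N_X)^{-1/2}$,
$\hat\beta_{Xj} = \gamma_j + N(0, \mathrm{se}_{Xj}^2)$, pleiotropy
$\alpha_j = \mu_\alpha + N(0, \sigma_\alpha^2)$ (plus $0.3\gamma_j$ when
InSIDE violation is requested),
$\mathrm{se}_{Yj} = (2p_j(1-p_j)N_Y\,cf(1-cf))^{-1/2}$ for a binary outcome
with case fraction $cf$, and
$\hat\beta_{Yj} = \theta\gamma_j + \alpha_j + N(0, \mathrm{se}_{Yj}^2)$.
Null SNPs use $\gamma = 0$; reverse scenarios swap the generative roles.
The half-normal $\gamma$ encodes the field's convention of orienting effect
alleles to increase the exposure; it is also what makes directional
pleiotropy produce the classic upward IVW bias that Egger corrects, which a
sign-symmetric draw would wash out.

Default cohort sizes mirror a microbiome-exposure MR study: exposure GWAS
$N_X = 18{,}340$; binary outcome $N_Y = 218{,}792$ with case fraction
0.164. `gamma_sd = 0.05` puts per-SNP exposure heritability near 0.1%,
so roughly a third to a half of 100 candidate instruments clear
$p < 10^{-5}$ at that exposure sample size — the regime a real taxon-level
GWAS produces. The reverse preset uses a moderate mediated effect
($\theta = 0.2$): because the observed-scale outcome $r^2$ is deflated by
$cf(1-cf)$ relative to the exposure formula, a very strong reverse effect
would paradoxically look forward-causal; the preset is chosen so the
variance comparison is decisive in the direction being tested.

Fidelity boundaries, stated plainly: no LD between simulated SNPs (the
pipeline assumes post-clumping independence anyway — synthetic positions
are spaced 20 Mb apart, outside any clumping window); only non-palindromic
allele pairs are emitted, so harmonization of simulated data exercises the
letter-matching paths while palindromic and strand-flip handling is tested
with purpose-built records; no winner's-curse correction (selection on the
same exposure GWAS that estimates $\hat\beta_X$, as in the real design);
log-odds effects with a variance approximation rather than a liability
model; no compositional structure among taxa. Passing tests therefore
establish correctness of the statistical machinery under the stated model,
not robustness to LD misspecification or abundance compositionality.

## Simulation sizes used by the test suite

Chosen to make Monte-Carlo bands decisive while keeping a full run inside a
few minutes on one core: estimator recovery uses $\theta = 0.1$, $J = 100$
strong instruments ($N = 5\times10^5$ per trait, where attenuation from
exposure-effect noise is an order of magnitude below the 3-MCSE band) and
500 replicates; type-I error uses 2000 null replicates at cohort scale;
pleiotropy recovery uses $\mu_\alpha = 0.02$, $J = 200$ with selection and
200 replicates; Steiger accuracy uses 200 forward and 200 reverse
replicates. Bootstrap size inside simulation loops is 100 (the minimum the
estimators accept); reported studies default to 1000.

## Known limitations

Distance-only clumping is stricter than panel-based clumping and can
discard conditionally independent signals on the same chromosome. The
small-$i$ $R^2$ formula presumes a variance-standardized exposure; for
unstandardized traits the large-$i$ form is the safer choice and is used
whenever ten or more instruments are present. Steiger calls for binary
outcomes use observed-scale $r^2$; a liability-scale treatment could flip
borderline calls for rare outcomes. MR-PRESSO-style outlier removal,
multivariable MR and leave-one-out analyses are out of scope.
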