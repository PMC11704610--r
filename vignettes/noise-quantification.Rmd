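---
title: "Quantifying transcriptional noise: models, filters and method scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcriptional noise: models, filters and method scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noisebench)
library(dplyr)
```

## The model

noisebench works in the negative binomial (Gamma–Poisson) limit of the
two-state model of transcription. A gene bursts at frequency $f$ (bursts
per mRNA lifetime; lifetimes are normalised to 1, so all kinetic estimates
are *relative*) and each burst contributes a geometrically distributed
number of transcripts with mean $b$ (the burst size). The stationary mRNA
copy number is then negative binomial with

$$\mathrm{mean} = b f, \qquad \mathrm{Fano} = \frac{\sigma^2}{\mu} = 1 + b,
\qquad \mathrm{CV}^2 = \frac{\sigma^2}{\mu^2} = \frac{1 + b}{b f}.$$

We parameterise the NB by (size $= f$, success probability
$p = f/(f + \mu)$), because that choice makes the two identities above
exact rather than approximate. $b = 0$ is the Poisson limit; the package
treats it explicitly (counts $\sim$ Poisson($f$)) rather than as a limit of
huge NB sizes.

*Homeostatic noise amplification* by a factor $c$ maps $(b, f) \mapsto
(c\,b,\; f/c)$: the mean $bf$ is untouched, the Fano factor rises from
$1+b$ to $1+cb$. On the log scale the fold changes are exactly reciprocal,
$\log_2 \Delta b + \log_2 \Delta f = 0$, which is what
`reciprocity_regression()` tests (slope $-1$, intercept $0$).

### The measurement layers

Two observation models sit on top of the bursting model.

**smFISH-like counting** (`simulate_smfish()`) observes the true copy
number, but cells differ in size. Extrinsic variability enters
multiplicatively on the Poisson rate as $(A/\bar A)^\eta$, with $A$ the
cell's area (lognormal; arbitrary units — only relative areas are ever
used) and $\bar A$ the mean area of the replicate's pooled
control + treated population. A single exponent $\eta$ is the simplest
mechanism that reproduces the linear size–expression correlation the
extrinsic filter is designed to remove; $\eta = 0$ recovers pure intrinsic
noise with exactly NB marginals.

**Sequencing-like counting** (`simulate_umi_matrix()`) additionally thins
every true count binomially with a per-cell capture probability $\beta$
(logit-normal around `capture_mean`; `capture_sd = 0` gives the constant-β
mode used for analytic checks). Thinning an NB($f$, $b$) with constant β
gives NB($f$, $\beta b$): burst frequency is invariant, burst size is
scaled. Hence the observed Fano fold change under amplification,

$$\Delta \mathrm{Fano}_\mathrm{obs}
  = \frac{1 + \beta c b}{1 + \beta b}
  \;<\; \frac{1 + c b}{1 + b} = \Delta \mathrm{Fano}_\mathrm{true},$$

is compressed toward 1. This single inequality is the mechanism behind
sequencing pipelines underestimating noise changes relative to smFISH, and
the package reproduces it end to end: fold-change tables computed from the
thinned arm score $\chi_{\mathrm{CV}^2}, \chi_\mathrm{Fano} > 0$ against
the un-thinned reference while $\chi_\mu \approx 0$.

## Parameters and defaults

`sim_config()` fixes the simulated study conditions. Defaults were chosen
once, as a realistic desk-scale analogue of a paired smFISH/scRNA-seq
noise-perturbation experiment, and are not tuned per analysis:

| parameter | default | rationale |
|---|---|---|
| `n_cells` | 200 per condition per replicate | a few hundred segmented cells per gene/condition is typical for smFISH; leaves > 50 cells after filtering |
| `n_replicates` | 3 | the usual minimum for replicate-level SEM and signed-rank tests |
| `extrinsic_coupling` η | 1 | expression proportional to cell volume is the standard null for size coupling |
| `area_log_mean`, `area_log_sd` | log 200, 0.25 | ~25% CV in projected area, typical for adherent mammalian cells; units arbitrary |
| `capture_mean` β | 0.1 | the order of magnitude of UMI capture efficiency in droplet scRNA-seq |
| `capture_sd` | 0 (logit scale) | constant β keeps the thinned-NB identities exact; raise it to add per-cell depth variation |
| `amplification` c | 2 | a two-fold burst-size shift, large enough to resolve at these sample sizes |
| `area_shift_treated` | 1 | set to 1.3 to exercise the extrinsic filter with mismatched area distributions |

Ground truth (per-gene parameters, per-cell area and capture) is stored
alongside every simulated dataset but is never consumed by an analysis
stage; it exists so tests and benchmarks can compare estimates with truth.

### What the generator does and does not emulate

It emulates: per-gene NB counts from bursting, a lognormal cell-size
factor coupled to expression, per-cell binomial capture, depth variation
(via `capture_sd`), a treated condition with reciprocally changed burst
parameters, multiple replicates, and mitochondrial-tagged genes (any gene
id beginning with `mt-`) for QC exercises. It does **not** emulate promoter
state trajectories or multi-state kinetics, cell-cycle structure beyond
the size surrogate, gene–gene correlation, amplification bias, doublets or
ambient RNA. Passing tests therefore demonstrate correctness of the
estimators under the stated generative model, not robustness to every
artefact of real droplet data.

## Noise metrics and their conventions

`noise_summary()` uses the unbiased ($n - 1$) sample variance — at ~50
cells per replicate the bias of the ML variance would be material — and
reports `cv2 = var/mean^2` and `fano = var/mean`, so `fano == cv2 * mean`
holds to machine precision. Genes with zero mean are flagged `undefined`,
never dropped silently. Fold changes are treated/control ratios computed
on depth-normalized values for UMI matrices and on raw spot counts for
cell tables; both paths share `noise_summary()`.

`replicate_average()` keeps a gene only if it passed filtering in *every*
replicate (intersection rule). With no imputation rule available, averaging
over a varying subset of replicates would make fold changes incomparable
across genes.

QC thresholds follow printed-inequality semantics: minima are inclusive
(`>=`), maxima and the mitochondrial fraction strict (`<`). The gene
coverage filter (mean count ≥ 0.1, detection in ≥ 5% of cells, per
condition) is a configurable analogue of default-parameter gene filtering
in scRNA-seq noise pipelines; the thresholds are deliberately exposed
because no canonical values exist.

## The extrinsic-noise filter

`iterative_extrinsic_filter()` restricts the analysis to cells of similar
size: an initial 5th/95th percentile trim of the pooled (both-condition)
area distribution, then repeated 2nd/98th percentile trims of the pooled
survivors until (i) a permutation test can no longer distinguish the two
conditions' area distributions ($p > \alpha$, default $\alpha = 0.01$,
strict) **and** (ii) the count–area Pearson correlation satisfies
$|r| < 0.45$ in *both* conditions.

Numerical and design choices, all of which were genuinely open:

- **Permutation statistic**: the absolute difference in mean area — the
  simplest location statistic consistent with testing "the area
  distributions are indistinguishable". The default mode resamples labels
  *with replacement* (bootstrap-style); classical without-replacement and
  exhaustive-enumeration modes are provided because the with-replacement
  convention is unusual, and the sampled p is validated against exhaustive
  enumeration in the tests. Sampled p-values use the add-one estimator
  $(1 + \#\{t^* \ge t\})/(1 + n_\mathrm{perm})$, which can never return 0.
- **Percentile convention**: linear interpolation between order statistics
  (`quantile()` type 7), with inclusive bounds, so an all-equal area vector
  is a fixed point rather than an error.
- **Pooled recomputation**: iterative trims are recomputed on the pooled
  surviving population each round, mirroring the initial combined-population
  rule and keeping the procedure free of per-group sample-size bias.
- **Stopping**: `max_iter` defaults to 25 on the reasoning that each round
  removes at least ~4% of pooled cells, so deeper recursion runs into the
  50-cell floor for populations of ~300 pooled cells. For larger
  populations the cap, not the floor, binds: with 600 pooled cells and a
  1.3× area shift, runs that need ~30 rounds still retain > 130 cells, so
  analyses of such populations should raise `max_iter` to ~40 and let
  `min_cells` be the binding stop. Fewer than `min_cells = 50` cells per
  condition triggers a warning and an unconverged result with full
  diagnostics (`trace`), never a silent pass.

`size_corrected_noise()` implements the regression-based correction:
per condition, counts are regressed on area by OLS and the corrected
variance is the residual variance (same $n-1$ denominator, so corrected
$\le$ raw always); corrected CV² and Fano reuse the raw mean. On
size-decoupled data the correction is a no-op up to sampling error, which
is the package's check that the iterative filter has done its job.

## Burst-parameter inference

`fit_negative_binomial()` maximises the NB likelihood with a 1-D profile:
for any fixed size $r$, the MLE of the mean is the sample mean, so the fit
reduces to a bracketed derivative-free search over $\log r$ (12 natural-log
units either side of the method-of-moments start, `optimize()` with
tolerance 1e-10). When the sample variance does not exceed the mean there
is no interior optimum; the fit returns an explicitly flagged Poisson
boundary ($b = 0$, $f = \mu$) instead of an unstable huge-$r$ estimate,
and downstream fold changes involving boundary fits are reported as `NA`
with a warning rather than as spurious ratios. Fits with fewer than ~25
cells trigger a warning. The reported log-likelihood always equals the
direct summation of the NB log-pmf at the estimates (tested at 1e-8
relative), and the implied quantities satisfy mean $= bf$ and Fano
$= 1 + b$ exactly by construction.

Replicate aggregation reports both the mean of per-replicate
$\log_2 \Delta$ with its SEM (the default, since replicate spread is the
honest error estimate at 3 replicates) and a pooled-counts fit per gene
and condition.

`homeostasis_report()` classifies genes with configurable thresholds: a
gene is *mean-shifted* when $|\log_2 \Delta\mu| > \log_2 1.5$ (the 1.5
default separates genuine mean changes from sampling scatter at these
sample sizes); otherwise *homeostatic* when burst size and frequency moved
in opposite directions, else *non-reciprocal* — the pattern of a gene whose
burst size and frequency both rise. Population-level tests are Wilcoxon
signed-rank against 1: two-sided for the mean; one-sided (greater) for
CV², Fano and burst size; one-sided (less) for burst frequency.

## Exact small-sample tests

`compare_populations()` implements both Wilcoxon tests with exact
enumeration where feasible: all $2^n$ sign patterns for the signed-rank
test at $n \le 14$ (exact even under tied absolute differences, where the
classical no-ties tables do not apply), and all $\binom{n}{n_x}$ label
assignments for the rank-sum test while that count is $\le 2 \times 10^5$.
Zero differences are dropped (Wilcoxon's original policy; all-zero input
returns $p = 1$). Outside the enumeration range the exact no-ties
distributions (`psignrank`, `pwilcox`) are used when applicable, and
otherwise a mid-rank normal approximation with tie-corrected variance and
continuity correction. Two-sided p-values are twice the smaller tail,
capped at 1. Comparisons with ≥ included the tolerance `1e-9` on rank sums
to guard against floating-point representation of mid-ranks.

## Method scoring

For each method $k$ and metric $i \in \{\mu, \mathrm{CV}^2,
\mathrm{Fano}\}$, with per-gene fold changes $D_{jk}$ (method) and $E_j$
(smFISH reference),

$$\chi_{ik} = \operatorname{median}_j
  \left( \frac{D_{jk} - E_j}{E_j} \right)^{\!2},
\qquad S_k = \chi_{\mu k} + \chi_{\mathrm{CV}^2 k} + \chi_{\mathrm{Fano} k}.$$

$D$ and $E$ are *fold changes* (treated/control) of each metric, not
absolute values — the reading consistent with scoring how well a method
reproduces a reference's *changes* in noise. The median is the standard
one (mean of the central pair for even $n$); genes with $E_j = 0$ or
missing are excluded pairwise with counts reported. Because χ is a median
of per-gene terms it has the usual 50% breakdown: corrupting fewer than
half the genes cannot drag the score outside the clean genes' range.
`rank_methods()` sorts ascending by $S$ with lexicographic tie-breaking,
and `underestimation_report()` makes the compression diagnostic explicit
(fraction of genes with $|\log_2 D| < |\log_2 E|$, ties counting as
neither, plus the median log2 attenuation).

`simulate_method_tables()` manufactures synthetic "method" outputs by
shrinking a reference's log fold changes toward 0 by a factor $s$ with
optional lognormal jitter; $S$ is monotone in $s$ at zero jitter, which is
the scoring module's main correctness property.

## Problem sizes used in the tests

The test and acceptance suites run the analyses at sizes chosen to make
the stated tolerances comfortable rather than marginal: moment-fidelity
checks at $n = 10^5$ cells (3% tolerance on mean and Fano), NB recovery at
$n = 10^3$ cells over 50 seeds (median relative error < 10%),
summary-level homeostasis at $n = 5000$ cells and 5 replicates (5%
tolerances), thinning compression at $n = 5 \times 10^4$ cells, and the
extrinsic filter on 300 cells/condition over 10 seeds with the full
10,000-resample permutation test. The end-to-end `run_pipeline()` demo
runs smaller (≈ 100 cells/condition) since it checks plumbing, not
estimator precision.

## Known limitations

- All burst-parameter estimates are relative (lifetimes normalised to 1);
  absolute kinetics require measured mRNA half-lives, which the model
  deliberately does not take.
- The NB is the *effective* stationary distribution; multi-state promoter
  kinetics or feedback that produce non-NB distributions will be absorbed
  into effective $(b, f)$ rather than flagged.
- With `amplification` $c > 1$, a $b = 0$ (Poisson-limit) gene does not
  stay mean-homeostatic under the literal $(cb, f/c)$ substitution; the
  Poisson limit is intended for $c = 1$ sanity checks.
- The extrinsic filter assumes the pre-curated cell table of a manual
  segmentation workflow; it does not detect dividing cells, doublets or
  segmentation errors.
- χ/S scoring compares methods through a *common* gene panel; with very
  few genes the median is coarse, and scores between methods that differ
  on fewer than half the genes can tie.
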