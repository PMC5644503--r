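---
title: "Genes, families, and the transmission of education: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genes, families, and the transmission of education: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Parental education is the strongest measured predictor of a child's
education. Whether that association reflects *social* inheritance (resources,
expectations, investments) or *genetic* inheritance matters for how durable
we expect policy effects on education to be across generations. polytrans
implements the analytical toolkit for attacking this question with measured
genotype:

1. **SNP heritability** of years of schooling by GREML — pairwise genomic
   relatedness among conventionally unrelated individuals, compared with
   phenotypic similarity through a variance-component mixed model.
2. **Polygenic scores** — a weighted sum of allele counts,
   $s_j = \sum_i \hat w_i x_{ij}$, with GWAS-estimated per-allele weights,
   standardized within generation.
3. **Family-clustered regression suites** relating a child's schooling to
   parental education, own and parental scores, and their interactions.
4. **Within/between-family decomposition** — within-family score contrasts
   are randomized by meiosis, so they are immune to the social confounding
   that contaminates between-family comparisons.
5. **The mediation-scaling statistic** — the headline quantity: how much of
   the parent-child education association is genetic, extrapolated from the
   attenuation of the parental-education coefficient when the child's score
   is controlled.

Because the motivating surveys are restricted-access, the package ships a
forward simulator whose *stated world* reproduces the published moments, so
every stage is testable end to end without any data download.

# The generative model

## Genotypes and transmission

Founders carry $M$ unlinked biallelic SNPs in Hardy–Weinberg equilibrium
with effect-allele frequencies $p_i \sim U(0.05, 0.95)$. Transmission is
Mendelian and unphased: each parent contributes one allele per locus with
probability dosage/2, independently across loci and children. Linkage and
phase are deliberately out of scope — every analysis in the package consumes
genome-wide aggregates, never local structure.

## Phenotypes

True per-SNP effects are i.i.d. normal, scaled so the additive genic
variance $\sum_i 2 p_i (1-p_i) \beta_i^2$ equals $h^2 \sigma^2_P$ (default
$0.20 \times 6.10$ years$^2$; note the published variance components 1.20
and 4.90 imply the exact ratio 0.197, which prints as 0.20). Parent
education is $\mu_{par} + g + e$. Child education follows

$$
\mathrm{edu}_c = \mu + b_m \mathrm{edu}_{mom} + b_f \mathrm{edu}_{dad}
 + \gamma_B\, z(\bar g_{sibs}) + \gamma_W\,(z(g) - z(\bar g_{sibs}))
 + \theta\, z(g)\, z(g_{mom}) + e,
$$

with the residual variance solved so total variance stays at
$\sigma^2_P$. The defaults are calibration targets taken from published
fitted tables, not asserted mechanisms: $b_m = b_f = 0.17$ (so the gross
mother-only coefficient is ≈ 0.30), $\gamma_W = 0.32 > \gamma_B = 0.27$
(niche formation is modeled as this within/between asymmetry rather than an
explicit parental-investment process), $\theta = 0$ by default (0.15
reproduces the published parent–child genotype interaction).

## Assortative mating and burn-in

Couples form by rank-matching on a latent index
$I = a\,z(\mathrm{edu}) + b\,z(\mathrm{score}) + s\,\varepsilon$. Given
target spousal correlations $r_e$ and $r_s$, exact matching implies
$\mathrm{cor}(I,\mathrm{edu}) = \sqrt{r_e}$ and
$\mathrm{cor}(I,\mathrm{score}) = \sqrt{r_s}$, a $2\times 2$ linear system
in $(a, b)$ — so the index is solved in closed form rather than by blind
search; a pilot-simulation loop then nudges the targets multiplicatively
(damped by an exponent of 0.6) to absorb equilibrium drift. The score
enters the index directly because the published spousal score correlation
(0.22) exceeds what phenotype-only matching implies; a config flag restores
phenotype-only assortment.

Closed-form expectations used as test targets — e.g. sibling score
intraclass correlation $(1+r_s)/2 \approx 0.61$ — hold at assortative-mating
*equilibrium*, not after a single generation of assortment from
Hardy–Weinberg founders (one generation gives
$0.5(1+r)/(1+r/2) \approx 0.55$ at $r = 0.22$). The simulator therefore runs
`n_burnin = 6` generations of index mating before the recorded
two-generation cohort; the gametic-phase disequilibrium converges
geometrically (ratio $(1+r)/2$ per generation), putting the ICC within about
0.01 of its equilibrium value. Burn-in is generator machinery only;
multi-generation analysis remains out of scope.

## Exact realized-moment calibration

Three devices make the stated world hit its targets deterministically
rather than on average; all three were designed before the acceptance tests
were run, as part of the generator's contract that its targets are *met*:

* **Residual orthogonalization.** Drawn residuals are projected to be
  exactly orthogonal (in sample) to the systematic components and rescaled
  to the exact residual variance. Founder heritability is then $h^2$ by
  construction, and recovered regression slopes concentrate tightly around
  their generative values.
* **Score-noise solve.** The measured score is $g + $ noise, and the noise
  scale is solved on the realized cohort so the offspring education-on-score
  $R^2$ equals `r2_score_target` exactly (the founder-population closed form
  in `make_noisy_weights()` — noise variance such that
  $\mathrm{cor}^2(s, g) = R^2_{target}/h^2$ — is retained as the starting
  point and as the documented contract of that operation).
* **Two-field noise mixing.** The noise combines the field that took part
  in mating (high spousal correlation) with a fresh field (low spousal
  correlation); the mixing weight is solved per run so the spousal score
  correlation equals its target exactly. The mating calibration aims the
  matched field ~30% above target so the mix can always reach it from
  above.

What a green calibration test does *not* establish: the simulator does not
emulate linkage disequilibrium, population stratification, genotyping error,
selective attrition, or the measurement structure of real survey education
(integer years, cohort effects). Conclusions about those belong to the real
data, not to this artifact.

# Estimation machinery

## GRM and relatedness pruning

The relatedness estimator is the standard centered-and-scaled form with the
conventional separate diagonal. Pruning is greedy: while any pair is at or
above the cutoff, drop the individual in the most violating pairs
(lexicographic tie-break).

**The cutoff and panel scale.** The conventional 2.5% cutoff presumes
array-scale panels: with hundreds of thousands of SNPs the estimation noise
SD ($1/\sqrt{M}$) is ~0.002, so 0.025 sits more than 15 noise SDs out and
removes only genuine relatives. At a simulated $M = 5000$, noise SD is
0.014 and ~4% of *all* unrelated pairs exceed 0.025 by chance; the greedy
prune would discard ~95% of the sample. `effective_relatedness_cutoff()`
therefore raises the cutoff to 5 noise SDs whenever that exceeds the nominal
value — behaviour identical to the published procedure at real panel sizes,
and near-identity for simulated unrelateds at miniature sizes. The pruning
operation itself honours whatever cutoff it is given.

## AI-REML

`reml_fit()` maximizes the restricted likelihood of
$y = X\beta + g + e$, $g \sim (0, A\sigma^2_g)$, $e \sim (0, I\sigma^2_e)$.
The GRM is eigendecomposed once; in the rotated basis every likelihood,
gradient and average-information evaluation is $O(NK)$. Three EM warm-start
iterations precede AI (Newton) updates with step-halving whenever the
likelihood would decrease; $\sigma^2_g$ is clamped at zero (active set).
Convergence is a log-likelihood change below 1e-8 (max 100 iterations);
non-convergence flags the result rather than throwing. Standard errors come
from the inverse AI matrix with the delta method for the ratio. The null
model is profiled in closed form, and the LRT p-value uses the 50:50
mixture of a point mass at zero and $\chi^2_1$ — the boundary convention
confirmed by the published statistics (5.62 → 0.009; plain $\chi^2_1$ would
give 0.018).

Allele frequencies for centering default to in-sample estimates (external
ones can be supplied); whether the published GREML models included age/sex
covariates is not stated, so the pipeline includes them with an
intercept-only option.

## Clustered regression

Cluster-robust covariance uses the CR1 small-sample factor
$\frac{G}{G-1}\frac{N-1}{N-K}$ (the common statistical-package default; the
source names only "robust to clustering"). Interaction models include all
constituent main effects by default, with a flag reproducing the published
variant that omits the maternal-score main effect. Listwise deletion with a
logged count.

## Within/between decomposition and ICC

Within: OLS on family-demeaned data over multi-member families, covariates
demeaned alongside. Between: unweighted family means (the source is silent
on weighting; the size-weighted between slope is stored as well because the
exact variance-share identity
$\beta_{tot} = w\beta_{within} + (1-w)\beta_{between}$ holds for the
weighted version under unbalanced designs). ICC is one-way ANOVA ICC(1)
with the unbalanced-design mean family size
$k_0 = (N - \sum n_g^2/N)/(G-1)$; a pairwise-correlation alternative sits
behind a flag since the published estimator is unstated.

## Mediation scaling

The canonical form is
$$\text{genetic share} = \text{attenuation%} \times \frac{h^2}{R^2_{score}}
  \times r,$$
with parent-offspring relatedness $r = 0.5$ by default. The two published
groupings (a single combined multiplier of 5; a heritability factor 7.58
followed by 0.5) are both rendered as views of this one computation. The
underlying derivation's assumptions are not reproducible from the main
text, so the package treats the formula as the *definition* of the
statistic and exposes its knobs.

Two properties the user should know, measured with this package's own
simulator:

* In a structurally rich world (two parental paths, assortative mating),
  the statistic *overstates* the generative genetic share of
  $\mathrm{cov}(\mathrm{edu}_{mom}, \mathrm{edu}_{child})$ — the score also
  proxies the father's education and the spousal genetic correlation, both
  of which inflate the attenuation. In the package's default calibrated
  world the statistic reads ~26% against a generative channel share of
  ~14%.
* In the clean single-parent, uniform-effect, random-mating world, the
  entire chain (raw coefficient, adjusted coefficient, attenuation, share)
  matches its covariance-algebra plim, which is the package's oracle test.

The "Hausman-style" check is implemented as a cluster bootstrap of the
coefficient difference (families resampled with replacement, normal
reference for $\Delta/SE_{boot}$), because the classical Hausman variance
formula requires one estimator to be efficient, which neither is here.

# Numerical and design choices

* One RNG stream per stage, derived from the master seed by stage name
  (`stage_seed()`), so stages are individually reproducible and the whole
  pipeline is byte-deterministic at a fixed seed.
* Doubles are serialized with 17 significant digits, so every writer/reader
  pair round-trips bit-identically.
* Dosage coding counts the effect allele named in the weight table;
  mismatched files are flipped with a warning (sign errors being the
  dominant practical failure mode), and foreign alleles are hard errors.
* Missing dosages: persons over 10% missing are dropped with a logged
  count; the rest are mean-imputed ($2p_i$) for scoring and GRM work only.
* Standardization uses the sample SD ($n-1$) and is computed within
  generation; both conventions are documented because the source states
  neither.
* Pilot-based mating calibration engages only at $\geq 1000$ families;
  below that, realized spousal correlations are too noisy to calibrate
  against and the closed-form index is used as-is.

# Known limitations

* Single variance component only: no GxE variance partitioning, bivariate
  REML, or multiple GRMs.
* The simulator's education is a continuous homoscedastic trait; real
  schooling is integer-valued, cohort-structured, and right-censored.
* The mediation statistic inherits every assumption of its scaling
  arithmetic; the package reproduces and stress-tests the arithmetic but
  cannot validate the unavailable derivation behind it.
* Sibling-pair mating is avoided by rank-swapping during burn-in, but more
  distant inbreeding is not tracked.
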