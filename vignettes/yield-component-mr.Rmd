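---
title: "Estimating causal effects of yield components on rice yield: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating causal effects of yield components on rice yield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricemr)
```

# The inference chain

`ricemr` estimates how strongly each of the three yield component traits
of rice — grains per panicle (GPP), kilo-grain weight (KGW, g) and
tillers per plant (TP) — causally drives yield per plant (YD, g), using
genetic variants as instrumental variables. The chain is:
per-dataset mixed-model GWAS → cross-dataset meta-analysis → instrument
selection → two-sample Mendelian randomization (MR) → superior-allele
pyramiding. This vignette records the statistical models, the tunable
parameters, and the design decisions that were genuinely open, so a
reader can judge what the package's results do and do not establish.

## Mixed-linear-model association

Each dataset (one population grown in one environment) is scanned with
the EMMAX convention. The null model is

$$y = \mu + g + e,\qquad g \sim N(0, \sigma_g^2 K),\quad e \sim N(0, \sigma_e^2 I),$$

where $K$ is the VanRaden genomic relationship matrix built from
column-standardised dosages (missing dosages mean-imputed per SNP).
Variance components are REML estimates obtained by eigendecomposing $K$
once and maximising the restricted likelihood over
$h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)$ on $[0,1]$ with the scale
profiled analytically (`optimize()`, tolerance `1e-8`; the endpoints are
checked explicitly so boundary solutions are exact). Per SNP, the scan
is generalised least squares of $y$ on $[1, x]$ under
$V = \sigma_g^2 K + \sigma_e^2 I$ with the components *fixed at the null
estimates*, solved in the eigenbasis so the per-SNP cost is $O(n)$.

Three conventions matter and are deliberate:

* standard errors come from the GLS information matrix
  $(X^\top V^{-1}X)^{-1}$ — no per-SNP residual rescaling. With
  $\sigma_g^2 = 0$ the coefficients equal ordinary least squares exactly,
  while the SE is the known-variance form $\sqrt{\sigma_e^2/S_{xx}}$;
* p-values are two-sided normal, matching the meta stage's normal
  theory;
* no covariates or principal components are included by default (a
  fixed-covariate argument exists); the GRM itself absorbs relatedness
  and broad structure.

Degenerate cases: a GRM whose eigenvalues are all equal (e.g. the
identity) makes $h^2$ unidentifiable — the fit returns $h^2 = 0$ with a
warning rather than an arbitrary interior value. SNPs with zero dosage
variance are skipped and listed in an attribute.

## Quality control

SNPs are retained when MAF is *strictly above* `maf_min` and the missing
fraction *strictly below* `missing_max` (defaults 0.05 and 0.20; the
larger public panel in the motivating design is conventionally held to
MAF > 1%, so the pipeline accepts per-population thresholds). Because
these rates are ratios of small integer counts, the strict comparisons
are decided at a `1e-9` tolerance — a SNP whose allele counts put its
MAF exactly at 0.05 must be removed even though neither 0.05 nor the
count ratio has an exact binary representation.

## Meta-analysis

Per SNP, the fixed-effect model weights each dataset by the inverse of
its squared standard error; heterogeneity is assessed with Cochran's Q
($df = k-1$) and $I^2 = \max(0, (Q-df)/Q)$, with $Q = 0$ defined to give
$I^2 = 0$ and a single study defined to give $p = 1$. Where
$I^2 \ge 50\%$ the DerSimonian–Laird random-effects model replaces the
fixed-effect combination:
$\tau^2 = \max\!\big(0, (Q-df)/(\sum w - \sum w^2/\sum w)\big)$,
re-weighting by $1/(se_i^2+\tau^2)$. DL was chosen over
likelihood-ratio random-effects machinery because it is fully specified
by closed formulas and therefore exactly testable against brute-force
oracles; no reproduction target in this package depends on the
difference. Alleles are aligned on A1/A2 with a beta sign-flip when
swapped; irreconcilable alleles drop the SNP with a warning. SNPs
present in only a subset of datasets are combined over that subset
(METAL behaviour). Genome-wide significance is strict: `P < 1e-6`.

## Instrument selection

The three instrumental-variable assumptions are operationalised as:

1. *relevance* — exposure meta `P < 1e-6`;
2. *no confounder association* — not testable from summary data; in the
   synthetic validation studies it holds by construction (instruments
   are planted causal SNPs, confounding is limited to the polygenic
   background the GRM absorbs);
3. *exclusivity* — meta `P > 0.05` in **every** other component trait.
   Meta-analytic p-values are used (rather than per-dataset ones)
   because the meta table is the only association summary the pipeline
   reports.

Surviving candidates are greedily LD-pruned: scanning in ascending order
of exposure p (snp id breaks ties deterministically), a SNP is accepted
only if its squared dosage correlation with every already-accepted SNP
is at most `r2_max = 0.01` — SNPs in LD are discarded by larger
p-value. The scan order was an open choice; ascending-p is the one that
makes "discard the larger p" well-defined and deterministic.

Note a statistical consequence of the exclusivity screen worth keeping
in mind when interpreting recovery experiments: at a SNP with no true
effect on the other two components, the two exclusivity p-values are
uniform, so each planted instrument survives the screen with probability
$0.95^2 \approx 0.90$. Exact recovery of a full planted set is
correspondingly less likely as the set grows; the package's tests
therefore also assert the conditional property (recovery given the
screens pass).

## MR estimators

All estimators consume Wald ratios $\hat\beta_j = \beta_{Y,j}/\beta_{X,j}$
with first-order standard errors $se_{Y,j}/|\beta_{X,j}|$ (exposure
error ignored — the standard two-sample construction; with the strong
instruments selected at `P < 1e-6` the second-order term is negligible)
and inverse-variance weights $w_j = \beta_{X,j}^2/se_{Y,j}^2$.

* **IVW**: $\hat\theta = \sum w_j \hat\beta_j / \sum w_j$. The SE uses a
  multiplicative random-effects model,
  $se = \max\!\big(1, \sqrt{Q/(k-1)}\big)\big(\sum w_j\big)^{-1/2}$:
  over-dispersed sets get wider intervals, under-dispersion is never
  rewarded, and $k=1$ reduces exactly to the single Wald ratio.
* **Weighted median**: sort ratios, form standardised cumulative weights
  $s_j = \sum_{i\le j}\tilde w_i - \tilde w_j/2$, linearly interpolate
  the ratio at $s = 0.5$ (clamped to the extreme ratios outside the
  grid). The point estimate is deterministic; the SE is the SD of the
  estimate over `n_boot = 10000` parametric bootstrap draws
  $\hat\beta_j^* \sim N(\hat\beta_j, se_j)$ under an explicit seed.
* **MR-Egger**: instruments are first oriented so every exposure beta is
  positive (flipping $\beta_X$ and $\beta_Y$ jointly — the orientation
  changes the intercept, so it is part of the method definition), then
  $\beta_Y$ is regressed on $\beta_X$ with intercept by WLS with weights
  $1/se_Y^2$. Coefficient SEs from the information matrix are inflated
  by $\max(1, \sqrt{RSS_w/(k-2)})$; the residual scale is computed
  directly rather than via `summary.lm()`, which warns on numerically
  perfect fits.

Confidence intervals are always `estimate ± 1.959964·se`, with the
conventional reporting constant used literally so the CI is an exact
affine function of the SE. The weighted median and Egger require
`k >= 3`; heterogeneity `k >= 2`.

When an instrument set carries Wald ratios of both signs — as the KGW
instruments do in the shipped published tables — the set is additionally
split by ratio sign and each subgroup analysed separately, a zero ratio
going to the positive side by convention. Sign-of-ratio was adopted as
the split criterion because it is the direction of the locus's genetic
effect on yield per unit exposure, the quantity the subgroup analysis is
about.

## Published instrument tables and SE back-derivation

The shipped fixtures print only beta and p per SNP. `derive_se()`
inverts the two-sided normal test, $se = |\beta|/\Phi^{-1}(1-p/2)$,
implemented through the upper-tail quantile `qnorm(p/2, lower.tail =
FALSE)` so that p-values as small as `1e-12` invert to `1e-10` relative
accuracy (the naive `qnorm(1 - p/2)` loses ~5 significant digits there).
Printed p-values are rounded to ~3 significant figures; for rows with
p near 1 (three KGW outcome rows print 0.948, 0.955, 0.997) the
reconstructed SEs, and hence the KGW subgroup estimates, inherit a
relative error of a few percent. This is a property of the printed
inputs, not of the estimators.

## The synthetic-data generator

`simulate_genotypes()` draws, per line, two haplotypes from a
first-order copying process: along a chromosome the allele at SNP $j$
copies SNP $j-1$'s allele with probability `ld_rho`, else it is a fresh
Bernoulli draw at that SNP's frequency (drawn uniformly in `maf_range`).
LD therefore decays geometrically with marker distance, restarts at each
of the 12 chromosomes, and has a closed-form two-SNP distribution that
the tests enumerate as an oracle. Defaults: `maf_range = (0.05, 0.5)`,
`ld_rho = 0.25` — enough local structure to exercise the pruning step
while keeping planted loci (spaced ≥ 25 markers apart in exclusive mode)
effectively in linkage equilibrium.

`simulate_study()` builds component traits as
`intercept + causal effects + polygenic background + environment shift +
noise`. The polygenic background lives on 200 non-causal SNPs per trait
and is rescaled to contribute `polygenic_prop = 0.3` of the genetic
variance, giving the GRM genuine signal; the noise SD is then tuned so
the in-sample genetic-variance fraction equals the requested
heritability (`h2 = 0.5` per component by default — hybrid rice
component traits are moderately heritable, yield much less so). Yield is

$$YD = 0.1\,GPP + 1.0\,KGW + 1.9\,TP + \text{direct loci} + N(0, 2^2),$$

so each component's true causal effect on yield is *exactly* its weight
— the reference for all parameter-recovery tests. The default weights
follow the linearised product rule $YD \approx GPP \cdot TP \cdot
KGW/1000$ at typical trait means (150 grains, 25 g, 9 tillers): 0.1 g
per grain, 1.0 g per g, 1.9 g per tiller. Per-trait causal effects
default to 4 grains, 0.6 g and 0.5 tillers per dosage — each planted
locus explains a few percent of trait variance, detectable at
`P < 1e-6` with ~2000 lines. A `residual_sd` override bypasses the
h²-based noise tuning to express global-null studies (pure-noise
traits). Degenerate configurations are honoured exactly: all effects
and noise zero yields constant traits at the intercept.

Environments differ by additive trait shifts and independent noise only
— no genotype-by-environment interaction — matching the
per-environment-GWAS-then-meta design without adding unidentified
structure. One caveat is inherited from the real design: two
environments of the *same* population share lines, so their GWAS errors
are correlated and the meta-analysis's independence assumption is only
approximate. The simulation-based validation studies therefore use two
independent populations in one environment each ("2 datasets × 1000
lines × 5000 SNPs"), where independence is exact.

What the generator does **not** emulate: realistic rice LD maps and
recombination hotspots, the actual male-sterile × restorer crossing
scheme, dominance/heterosis (F1 dosages are additive), selection, and
genotype-by-environment interaction. Passing recovery tests therefore
show the chain is correct under its own assumptions, not that those
assumptions hold in any particular real panel.

## Pyramiding

Superior alleles are genotype *classes* (hom-ref / het / hom-alt), not
dosage slopes: per locus the class with the highest trait mean among
non-empty classes wins, ties broken towards the lower dosage class —
heterozygote superiority is representable, which matters in F1 hybrids.
Each locus is classified on the trait it was detected for (component
trait for indirect loci, yield for direct loci); all group summaries
are then on yield. Lines are grouped by how many superior classes they
carry; groups under `min_lines = 3` are omitted but stay accounted for.
Group comparisons use the least-significant-difference procedure: pooled
one-way-ANOVA error mean square, pairwise t on $N-k$ degrees of
freedom. In the pipeline, class means pool all datasets (line-level
yield averaged over environments), the default reading of a
multi-environment analysis; zero within-group variance (toy data) simply
yields no LSD table.

## Candidate-gene annotation

Genes within ±200 kb of a significant SNP are reported nearest-first
(distance 0 inside a gene body, else distance to the nearer end), with
user-supplied curated ids — cloned yield genes — ranked ahead of
proximity. "200 kb around" is ambiguous between a ±100 kb and a ±200 kb
reading; the package exposes `window_bp` (default 200000, i.e. ±200 kb)
so either is available.

## Validation problem sizes

The shipped test-suite exercises the chain at sizes chosen to make the
statistical assertions sharp yet quick on a single CPU: module checks on
panels of 100–2000 lines; whole-chain instrument recovery on 10 studies
of 2 × 1000 lines × 5000 SNPs; IVW coverage of the true yield weights
on 50 such studies (planted-locus scans with the full-panel GRM);
global-null calibration on 2 × 1000 lines × 1000 independent SNPs;
pyramiding trends on 10 studies of 800 lines with 5 direct-effect loci.
The published-table computations are exact and take milliseconds.

## Known limitations

* Exposure-side uncertainty is ignored in the Wald-ratio SE (first-order
  two-sample convention); adequate for strong instruments, optimistic
  for weak ones.
* The weighted-median SE is a parametric bootstrap, not the original
  quantile-based formula; its point estimate is unaffected.
* One-sample overlap (exposure and outcome GWAS on the same lines) is
  present by design in multi-environment studies of a single population;
  the validation studies avoid it with independent populations.
* The LD pruning threshold `r² > 0.01` is strict enough that, on an
  LD-structured panel, a borderline tagging SNP can occasionally pass as
  an ostensibly independent instrument (sample r² below threshold while
  its source signal is genome-wide significant).
* No multivariable or bidirectional MR; no outlier-removal (MR-PRESSO
  style) sensitivity analysis.
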