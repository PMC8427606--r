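---
title: "Methods: SMR-HEIDI association testing for miRNA expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SMR-HEIDI association testing for miRNA expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsmr)
```

## The problem

Genome-wide association studies (GWAS) locate risk variants but not the
genes — or, here, the microRNAs — whose expression mediates the risk.
Expression quantitative trait locus (eQTL) studies, conversely, tell us
which SNPs regulate which miRNAs. `mirsmr` joins the two at the summary-
statistic level: for each miRNA probe it asks whether the genetic signal
for the disease and the genetic signal for the miRNA's expression point at
a *shared* causal variant, and if so, in which direction expression pushes
risk. No individual-level genotypes are needed, only per-SNP effect sizes,
standard errors and alleles from each study plus an LD reference panel.

## The SMR model

Let $b_{zx}$ be the effect of a SNP $Z$ on miRNA expression $X$ (from the
eQTL study, per genotype SD, in expression-SD units) and $b_{zy}$ its
effect on the trait $Y$ (from the GWAS). Treating the top cis-eQTL as an
instrumental variable, the effect of expression on the trait is the ratio

$$\hat b_{xy} = \hat b_{zy} / \hat b_{zx},$$

with first-order delta-method variance
$\mathrm{se}^2_{xy} = \mathrm{se}^2_{zy}/b_{zx}^2 +
b_{zy}^2\,\mathrm{se}^2_{zx}/b_{zx}^4$
(`estimate_bxy()`). The test statistic combines the two z-statistics,

$$T_{SMR} = \frac{z_{zy}^2\, z_{zx}^2}{z_{zy}^2 + z_{zx}^2},$$

referred to $\chi^2_1$ (`smr_statistic()`, `smr_pvalue()`). $T_{SMR}$ is
symmetric in its arguments, bounded by $\min(z_{zx}^2, z_{zy}^2)$, and as
the instrument becomes noiseless it converges to the GWAS Wald statistic
$z_{zy}^2$. P-values are computed in log space so very strong signals
($|z| \gtrsim 40$) never collapse to an exact zero.

The sign of $\hat b_{xy}$ is biologically meaningful: among significant
associations a negative effect (more expression, less risk) calls the
miRNA tumor-suppressive, a positive one oncogenic (`classify_role()`).

### Instruments and probe eligibility

The instrument is the cis SNP with the strongest eQTL association, required
to pass $P_{eQTL} < 5\times10^{-8}$; probes without such a SNP are
excluded, as are probes whose transcription start site falls inside the
extended MHC region (chr6:28,477,797–33,448,354, GRCh37), whose extreme
long-range LD breaks the single-causal-variant assumption. The cis window
is the closed interval $\pm 1$ Mb around the probe TSS. z-scores are
recomputed from `beta/se` rather than trusted from the `p` column (the
reader warns when the two disagree), because rounded p-values are the most
common corruption in published summary files; a switch restores ranking by
the reported column.

## HEIDI: separating one causal variant from two

A significant $T_{SMR}$ is compatible with three generative models:
pleiotropy ($Z$ affects both $X$ and $Y$), causality
($Z \to X \to Y$) — both of which share one causal variant — and linkage,
where two *different* variants in LD drive $X$ and $Y$ separately. Under a
single shared variant, every SNP $i$ in the cis region estimates the same
ratio: $b_{xy}(i) = r_{ic}b_{zy}/(r_{ic}b_{zx}) = b_{xy}$ regardless of its
LD $r_{ic}$ with the causal variant. Under linkage the per-SNP ratios
disagree. HEIDI tests exactly this homogeneity: with $d_i = \hat
b_{xy}(i) - \hat b_{xy}(\mathrm{top})$ and $z_{d,i} =
d_i/\sqrt{\mathrm{Var}(d_i)}$,

$$T_{HEIDI} = \sum_i z_{d,i}^2 .$$

Contrast variances and correlations come from a delta-method covariance of
the per-SNP ratios (`bxy_covariance()`), which assumes the GWAS and eQTL
cohorts do not overlap (zero cross-study covariance) — appropriate when
expression and disease data come from disjoint studies. Because the
$z_{d,i}$ are LD-correlated, $T_{HEIDI}$ follows a weighted chi-square
mixture $\sum_k \lambda_k \chi^2_1$ under the null, with $\lambda_k$ the
eigenvalues of the contrast correlation matrix (negative numerical
eigenvalues clipped at zero). The default p-value uses the two-moment
Satterthwaite approximation — a scaled $\chi^2$ with scale $\sum\lambda^2 /
\sum\lambda$ and df $(\sum\lambda)^2/\sum\lambda^2$, exact for identity
correlation and for the duplicated-contrast case — with an Imhof-type
numerical inversion of the characteristic function available via
`heidi_config(method = "imhof")` for tail accuracy. The two agree closely
in the $p > 10^{-4}$ regime exercised by the tests; the retention decision
happens at $p = 0.01$, well inside that regime.

SNPs enter the test when they show real eQTL signal
($P_{eQTL} < 1.57\times10^{-3}$, i.e. $\chi^2_1 > 10$ — weaker SNPs make
unstable ratios) and are informatively linked to the top SNP
($r^2 \in [0.05, 0.9]$ — near-perfect LD duplicates the top SNP, near-zero
LD carries no heterogeneity information). At most 20 SNPs are used (the
smallest eQTL p-values); at least 3 (including the top) are required,
otherwise the probe is reported `too_few_snps` with no HEIDI p-value —
single- or two-SNP cis regions simply cannot support a heterogeneity test.
These thresholds follow the published practice of the SMR-HEIDI method and
are all configuration keys.

A probe is retained as pleiotropy/causality when $P_{HEIDI} > 0.01$
(`classify_model()`); the test deliberately does not attempt to
distinguish pleiotropy from causality, which summary data cannot separate.

## The pipeline and its decisions

`smr()` orchestrates harmonization → instrument selection → SMR →
Benjamini–Hochberg FDR → HEIDI and returns a classed fit with `print`,
`summary`, `coef` and `plot` methods. Decisions worth stating explicitly:

* **FDR scope.** FDR is computed within one analysis run (one cancer, one
  GWAS table), over exactly the probes tested in that run — not pooled
  across runs. Subtype analyses (e.g. ER+ and ER− breast cancer) are
  separate runs distinguished by `cancer_label`; overlap across runs is
  reported by `smr_overlap()`, never special-cased.
* **HEIDI ordering.** HEIDI runs only for FDR-significant probes — it is a
  filter on discoveries, not an independent screen
  (`heidi_everywhere = TRUE` forces it everywhere).
* **Allele harmonization.** All effects are aligned to the eQTL effect
  allele; swapped or opposite-strand-swapped GWAS rows have beta negated
  and frequency complemented. Strand-ambiguous SNPs (A/T, C/G) are dropped
  by default: alleles alone cannot orient them. `eaf_resolve = TRUE`
  instead keeps those whose allele frequencies are informative on both
  sides (`|f - 0.5| > 0.08`), a standard but riskier convention — hence
  opt-in. Indels are rejected. Output SNP order is ascending position with
  lexicographic tie-breaks, making every run byte-reproducible.
* **Ties.** Instrument ties on p-value break by larger $|z|$ then smaller
  position.
* **Multi-tissue eQTL input.** When one analysis combines eQTL tables from
  related tissues (colon and rectal into colorectal, say),
  `merge_eqtl_tables()` concatenates them and de-duplicates shared
  probe/SNP pairs, keeping by default the more significant record; how the
  upstream studies combined such tables is rarely documented, so the rule
  is explicit and switchable rather than implicit.

## What the simulator generates — and what it does not

`simulate_scenario()` is the test bed for the whole stack. Haplotypes are
latent AR(1) Gaussian vectors thresholded at $\Phi^{-1}(\mathrm{maf})$;
dosages are sums of two haplotypes, so each SNP is Binomial(2, maf) with
LD decaying along the 30-SNP, 1-kb-spaced block (probe TSS at the center).
Three cohorts are drawn independently: eQTL, GWAS and a 5,000-sample LD
reference — large enough that LD estimation error is negligible against
the summary-statistic noise, as with typical reference panels. Phenotypes
follow the configured model on the standardized-genotype scale, and
per-SNP marginal least-squares regressions produce `beta/se/p` exactly as
a study would publish them. Half the GWAS rows are emitted with swapped
alleles so harmonization is exercised in every simulated analysis.

Default effect sizes ($b_{zx} = 0.3$, $b_{zy} = 0.1$, $n = 20{,}000$)
give a strong instrument ($z_{zx} \approx 42$) with realistic GWAS-side
signal; the null-calibration experiments use `rho = 0.8`, while linkage
experiments use `rho = 0.9` so the LD decay grid is fine enough that a
SNP pair near the target $r = 0.3$ essentially always exists within the
generator's $\pm 0.05$ tolerance (an unreachable target is an error, not
a silent fallback).

The simulator is deliberately unrealistic in ways that matter for
interpreting green tests: LD is AR(1), not coalescent; traits are
quantitative, whereas cancer GWAS are case-control on the liability scale;
there is one causal variant (two under linkage), no allelic
heterogeneity; and effect sizes are chosen for statistical testability,
not to mimic any real tumor cohort. Passing tests certify the statistics,
not realism of the genetics.

## The differential-expression stage

`nb_wald_test()` is a simplified negative-binomial tumor-vs-normal test:
median-of-ratios size factors (identical to the standard implementation on
shared inputs), per-gene method-of-moments dispersion pooled across
groups with a $10^{-8}$ floor, and a Wald test of the log2 fold change of
normalized group means, referred to a t distribution on $n - 2$ df — the
moment dispersion estimate is noisy at typical cohort sizes and a normal
reference would be anti-conservative. There is no empirical-Bayes
shrinkage, by design: every estimator here has a closed form that an
independent oracle can transcribe, which is the property the tests
certify. It will therefore not reproduce the exact p-values of the
shrunken-GLM tools, and its contract is calibration (type-I
$0.05 \pm 0.015$ under permuted labels) and recovery (a 4-fold spike at
mean 500, dispersion 0.05, 20 vs 20 samples is detected with
$\log_2$FC in $[1.6, 2.4]$ in $\ge 95\%$ of replicates). Genes silent in
one condition receive a 0.5 pseudocount; all-zero genes are reported
untested. MA classification is strict: `up`/`down` require FDR strictly
below the level *and* a strictly signed fold change.

One algebraic caveat: multiplying one sample's counts by $c$ rescales
*every* median-of-ratios size factor (by $c^{1-1/n}$ for that sample and
$c^{-1/n}$ for the rest) and hence the absolute `base_mean` scale by
$c^{1/n}$ — this is a property of the estimator itself, shared by the
standard tools. Fold changes and classifications are invariant; the tests
assert the exact equivariance rather than a false invariance.

## Target-consensus filter

`consensus_targets()` keeps a gene as a target of a miRNA when it
survives all three sources: miRDB score in $(80, 100]$ (strict lower
bound), TargetScan cumulative weighted context++ score $\le -0.2$ (no
lower bound), and presence in miRTarBase (experimental support; all
evidence tiers accepted by default, with the column preserved so callers
can filter). Matching is exact on upper-cased symbols: alias resolution is
out of scope and a documented limitation, since silent aliasing would be
worse than a visible miss. Empty intersections are valid results.

## Problem sizes and numerical choices

The simulation suites run at the sizes the statistics need, chosen once:
500 replicates at $n = 20{,}000$ for HEIDI null calibration, 500 at
$n = 50{,}000$ for linkage power, 200 at $n = 50{,}000$ for effect
recovery, $10^6$-draw Monte Carlo oracles for the delta-method covariance
and the mixture p-value, and 100 seeded replicates for the DE spike
recovery. Seeds are fixed in the tests; the generator takes a mandatory
seed and touches no hidden RNG state. Degenerate inputs are defined, not
crashed on: empty loci and empty intersections are valid empty results,
both-zero z-statistics give $T_{SMR} = 0$ with a warning, non-positive
contrast variances drop the contrast, and an all-zero eigenvalue spectrum
returns $p = 1$ with a warning.

## Known limitations

* Single-instrument MR only; no multi-SNP (GSMR-style) estimation, which
  needs LD-aware joint modeling beyond the summary statistics used here.
* HEIDI's delta-method null is approximate for weak instruments; the
  $\chi^2_1 > 10$ selection floor is what keeps it calibrated.
* Cohort overlap between GWAS and eQTL studies would induce cross-study
  covariance the HEIDI covariance ignores.
* The DE stage is a calibrated simplification, not a drop-in replacement
  for the shrunken-GLM tools on small cohorts.
* Gene-symbol aliasing in target tables is not resolved.

## A worked example

```{r example}
scen <- simulate_scenario(sim_config(model = "causality", seed = 11,
                                     n_gwas = 10000, n_eqtl = 10000,
                                     n_ld = 2000, m_snps = 20,
                                     b_zx = 0.3, b_xy = 0.3))
fit <- smr(scen$gwas, scen$eqtl, scen$ld, scen$probes,
           cancer_label = "simulated")
summary(fit)
```

The estimated effect `coef(fit)` targets the generating
`b_xy = 0.3`, and the HEIDI p-value stays above 0.01 because a single
causal variant generated both signals.
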