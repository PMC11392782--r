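---
title: "Multi-omics summary-data MR and colocalization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics summary-data MR and colocalization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(momicsmr)
```

## The model

`momicsmr` estimates the causal effect of a molecular trait (CpG
methylation, gene expression, or protein abundance) on a disease using a
single cis-SNP as instrument. For instrument $z$, exposure $x$, outcome
$y$, with marginal effects $b_{zx}$ and $b_{zy}$:

$$\hat b_{xy} = \frac{\hat b_{zy}}{\hat b_{zx}}, \qquad
T_{\mathrm{SMR}} = \frac{z_{zx}^2\, z_{zy}^2}{z_{zx}^2 + z_{zy}^2}
\sim \chi^2_1,$$

with the first-order delta-method variance
$\mathrm{var}(\hat b_{xy}) = se_{zy}^2/b_{zx}^2 + b_{zy}^2 se_{zx}^2 / b_{zx}^4$.
The estimator is consistent when the instrument affects the outcome only
through the exposure. Its two failure modes — linkage (two causal
variants in LD) and horizontal pleiotropy — are what the HEIDI test and
colocalization each probe from a different angle.

**HEIDI.** Under a single shared causal variant, $b_{xy}$ estimated at
*any* SNP in LD with it converges to the same value, so the contrasts
$d_i = \hat b_{xy}(i) - \hat b_{xy}(\mathrm{top})$ are jointly zero-mean.
Their covariance follows from the delta method with
$\mathrm{cov}(\hat b_{z\cdot,i}, \hat b_{z\cdot,j}) = r_{ij}\,se_i\,se_j$
within each trait (shared-sample marginal statistics on standardized
genotypes) and independence across the exposure and outcome cohorts.
$T = \sum_i (d_i/\mathrm{sd}(d_i))^2$ is a quadratic form in correlated
normals; we match its first two moments to a scaled
$\chi^2$ (Satterthwaite: scale $\sum\lambda_k^2/\sum\lambda_k$, df
$(\sum\lambda_k)^2/\sum\lambda_k^2$, $\lambda$ the eigenvalues of the
correlation matrix of the standardized contrasts). The test suite
cross-validates this tail against a Monte-Carlo eigenvalue-sum oracle;
agreement is within 0.03 absolute over the eigenvalue shapes HEIDI
encounters. We chose the two-moment match over numerical inversion of
the characteristic function because the inversion integrand decays only
polynomially while oscillating and generic quadrature fails on it
unpredictably — calibration-level accuracy, which is what a 0.05
screening threshold needs, does not require the exact tail.

**Colocalization.** Per-SNP evidence is the Wakefield approximate Bayes
factor $\mathrm{lABF} = \tfrac12\{\log(1-r) + r z^2\}$, $r = W/(V+W)$,
$V = se^2$. Five regional hypotheses (H0 no association; H1/H2 one
trait; H3 both, distinct variants; H4 both, shared variant) are scored
by summing configuration likelihoods in log space; the H3 off-diagonal
double sum uses the guarded identity
$\log\{\exp(S_1+S_2) - \exp(S_{12})\}$ with negative round-off clamped
to $-\infty$. An exhaustive $(m+1)^2$ enumeration oracle
(`coloc_enumerate`, $m \le 12$) agrees with the production path to
$10^{-10}$ per posterior. The framework assumes at most one causal
variant per trait per region; with allelic heterogeneity PP.H3 can be
inflated at the expense of PP.H4, and no SuSiE-style decomposition is
attempted.

## Thresholds and defaults

| Parameter | Default | Units / scale | Rationale |
|---|---|---|---|
| instrument p | 5×10⁻⁸ | — | genome-wide significance |
| cis-window | ±1 Mb gene body | bp | QTL-catalog convention |
| coloc window, mQTL | ±500 kb of top cis-SNP | bp | CpG signals are narrow; anchored at the instrument |
| coloc window, eQTL/pQTL | ±1 Mb of gene body | bp | matches the instrument search window |
| eaf discrepancy | 0.2 | allele frequency | excludes mismatched strand/population SNPs across *all* dataset pairs including the LD reference |
| HEIDI eligibility | r² ∈ [0.05, 0.9], \|z\| > 3.16, ≤ 20 SNPs | — | published SMR tool defaults; r² < 0.05 contrasts carry no information, r² > 0.9 are numerically degenerate duplicates |
| FDR (discovery) | q < 0.05, per layer × outcome | — | one family per omics layer against one outcome; pooling layers would mix very different probe counts (thousands of CpGs vs ~100 proteins) |
| HEIDI exclusion | p < 0.05 | — | heterogeneity flags linkage/pleiotropy |
| coloc priors | 1e-4, 1e-4, 1e-5 | per SNP | conventional |
| coloc prior SD W | 0.15 / 0.2 | per-SD / log-odds | conventional defaults; exposed in `wakefield_labf()` |
| PP.H4 labels | strong > 0.7, moderate > 0.5 | — | reporting convention |
| Phe-MR | ≥ 500 cases, q < 0.1 pooled | — | power floor; one BH family over all gene×phenotype tests |
| ORA | q < 0.1, top 10 by q | — | relaxed threshold usual for pathway screens |

All of these are arguments, not constants. Complication-style outcomes
with few cases can be flagged on nominal p instead of q
(`run_layer(..., significance = "nominal")`), mirroring the common
practice of relaxing multiplicity for underpowered secondary outcomes.

## Evidence tiers

A layer is *causal* for a gene when any probe has q < 0.05 and HEIDI
p > 0.05; it is *coloc-supported* when a causal probe also has
PP.H4 > 0.5. Counted over the layers a gene has data for: Tier 1 needs
≥ 2 causal and ≥ 2 coloc-supported layers; Tier 2 exactly one
coloc-supported layer; Tier 3 none; genes causal at < 2 layers are not
reported. Two readings of "concurrently supported by colocalization"
exist (≥ 1 vs ≥ 2 layers for Tier 1); only the ≥ 2 reading is
consistent with the bundled 18-gene worked example (a gene with one
strong PP.H4 and one near-zero PP.H4 is Tier 2 there), so that reading
is implemented and locked in by a fixture test. Probes within a layer
aggregate by "any passes" because CpGs of one gene can have opposite
directions; direction is reported per probe and never averaged.

## The simulator: what it emulates, what it does not

Summary statistics are generated directly at the summary level: for a
region with LD correlation $R$ and joint causal effects $b$ on
standardized genotypes, $\hat z \sim \mathcal N(\sqrt{nv}\,R b,\; R)$,
converted to per-allele betas with $se_j = 1/\sqrt{nv\cdot 2\,\mathrm{maf}_j(1-\mathrm{maf}_j)}$,
where $v = 1$ for quantitative traits and $v = \phi(1-\phi)$-style
case-fraction product $(n_\mathrm{case}/n)(n_\mathrm{ctrl}/n)$ for
case-control traits (a small-effect log-odds approximation). This is
the distribution SMR/HEIDI/coloc actually consume, so nothing is lost
relative to individual-level simulation for these methods, and it is
orders of magnitude faster.

The causal chain generator shares one causal SNP across layers with
methylation → expression → protein → disease effects
$\theta_{me}, \theta_{ep}, \theta_{ed}$; downstream molecular traits
are rescaled to unit variance (requiring $|\theta| < 1$), which makes
the true SMR ratios exactly the $\theta$s — the parameter-recovery
tests rely on this identity.

Stated-world choices, fixed once:

* **Region**: 30 SNPs, AR(1) ρ = 0.9, MAF ~ U(0.05, 0.5), 2 kb spacing —
  a dense cis-block with realistic neighbor LD; the HEIDI linkage-power
  scenario instead uses ρ = 0.6 with adjacent causal SNPs so the two
  causal variants sit at r² = 0.36 as that scenario stipulates.
* **Sample sizes**: desk-scale defaults (10⁴–5×10⁴) with the real
  cohort sizes available as `cohort_presets()` (blood mQTL 1,980;
  eQTLGen 31,684; deCODE 35,559; T2DM GWAS 242,283 cases).
* **Effects**: causal SNP explains 5% of the molecular trait (a typical
  strong cis-QTL; instrument z ≈ 22 at n = 10⁴) and 1% in the
  two-trait H0–H4 scenarios (z ≈ 22 at n = 5×10⁴, the regime the
  behavioral acceptance criteria stipulate). The demo pipeline uses
  $\theta_{me} = -0.5$, $\theta_{ep} = 0.5$, $\theta_{ed} = 0.5$: the
  disease z at the causal SNP is then ≈ 5, i.e. a gene whose effect is
  detectable by design — a demonstration of the machinery, not a power
  study.

Not emulated: haplotype-level LD from real panels, MAF–LD coupling,
population stratification, sample overlap between exposure and outcome
cohorts, trans effects, and multi-causal-variant architectures. A green
simulation test therefore establishes internal statistical correctness
(calibration, power, parameter recovery under the stated model), not
robustness to those real-data complications.

## Numerical choices and degenerate inputs

* Instrument ties on p break by distance to the probe midpoint, then
  lexicographic SNP id — deterministic across platforms.
* `b_zy = 0` gives $T_{\mathrm{SMR}} = 0$, p = 1 rather than 0/0;
  `b_zx = 0` is an error (no instrument).
* HEIDI contrasts with zero variance are perfect-LD duplicates of the
  top SNP: dropped when $d = 0$ (no information), definitive
  heterogeneity (p = 0) otherwise; no eligible SNPs returns `NA` and
  the probe is *retained* flagged "HEIDI not evaluable", because the
  exclusion rule is conditional on a computed p.
* SMR p-values can underflow to exactly 0 at very strong instruments;
  the FDR step clamps them to the smallest positive double.
* Palindromic (A/T, C/G) SNPs are dropped outright during
  harmonization rather than frequency-resolved — conservative and
  deterministic where the upstream convention is unstated.
* LD matrices are accepted down to eigenvalues of −10⁻⁶ (warned), and
  factorized with an eigenvalue-clipping fallback when Cholesky fails.
* The round-trip writers emit 17 significant digits so written files
  reload bit-identically.

## Reproducibility

Every simulation consumes an explicit integer seed through an isolated
RNG stream that neither reads nor perturbs the session's `.Random.seed`.
`run_pipeline()` snapshots its full configuration and hashes every
output TSV into a JSON manifest; identical config + seed reproduce
byte-identical outputs. The pipeline configuration is JSON rather than
YAML solely because the target environment ships no YAML parser for R.

## Known limitations

Single-instrument estimators only (no IVW/Egger), cis instruments only,
one causal variant per trait per region in colocalization, no genotype
handling (LD is consumed precomputed), no liftover, and the Satterthwaite
tail is approximate in the far tail (fine at the 0.05 screening level;
do not reuse it to quote p ≈ 10⁻⁸ heterogeneity p-values).
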