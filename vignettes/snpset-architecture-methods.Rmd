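---
title: "SNP-set biclustering and genotype-phenotype architecture: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNP-set biclustering and genotype-phenotype architecture: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpsetarch)
```

## The problem

Two chronic diseases that co-occur in a population — here coronary heart
disease (CHD) and type 2 diabetes (T2D) — partition a case-control cohort into
four disease patterns: comorbid, CHD-only, T2D-only, and neither. The question
this package addresses is whether the *genetic* architecture underlying these
patterns is organized into subgroups: sets of subjects who share concordant
genotypes at particular subsets of variants, and whether those SNP sets align
with the phenotype subgroups.

The analysis treats the genotype data as an additive-dosage matrix
$X \in \{0,1,2\}^{m \times n}$ (SNPs by subjects) and proceeds in stages:

1. **QC and prescreen** — standard per-SNP filters (missingness, minor allele
   frequency, exact Hardy–Weinberg test, sample call rate), followed by a
   per-SNP logistic regression against each disease. Variants with a loose
   association ($P < 5\times10^{-5}$) with either disease are pooled into the
   analysis panel, each labeled with its panel disease and effect direction.
2. **Fuzzy biclustering by nonsmooth NMF** — the pooled matrix is factorized as
   $X \approx W\,S(\theta)\,H$ over a sweep of ranks $k$, and each factor is
   turned into a *SNP set*: the SNPs and subjects whose loadings reach at least
   a fraction $\tau$ of the factor's maximum.
3. **Set-level association** — each SNP set is tested jointly against each
   disease with a variance-component kernel score test (SKAT-style), with
   Bonferroni correction over all generated sets.
4. **Architecture** — significant sets are de-duplicated by Jaccard redundancy
   filtering and related to the four phenotype subgroups by upper-tail
   hypergeometric tests on shared subjects; retained sets are finally
   co-clustered on shared SNPs into a genotypic network.
5. **Replication** — sets are regenerated in a held-out sample restricted to
   the same panel and matched to discovery sets by hypergeometric overlap of
   SNPs.

## The nonsmooth NMF model

Plain NMF approximates $X \approx WH$ with nonnegative factors. The nonsmooth
variant inserts a smoothing matrix

$$S(\theta) = (1-\theta)\,I + \frac{\theta}{k}\,\mathbf{1}\mathbf{1}^\top,
\qquad \theta \in [0,1],$$

so the model is $X \approx W S H$. Multiplying a factor by $S$ pulls it toward
the uniform vector; because the *other* factor must compensate, the net effect
is sparseness in both $W$ and $H$, which is what makes single factors readable
as biclusters. At $\theta = 0$ the model is plain NMF; `theta = 0.5` is the
default — the canonical middle ground of the cited formulation, since nothing
in the source analysis pins the value.

Updates are multiplicative on the generalized Kullback–Leibler divergence
(the dosage-derived data are count-like; a squared-error objective is available
behind `objective = "frobenius"`). The $H$-step uses the effective basis $WS$,
the $W$-step the effective coefficients $SH$. Denominators are
epsilon-guarded, so zero rows or columns of $X$ simply receive vanishing
loadings.

**Normalization.** The contract called for unit-sum normalization of the
columns of $W$ at every iteration. A per-iteration column rescaling (with the
inverse scale absorbed into $H$) is *not* an invariance of the nonsmooth model
— diagonal matrices do not commute with $S(\theta)$ — and would perturb the
objective between iterations, defeating the guarantee that the KL trace is
non-increasing. This implementation therefore runs the provably monotone raw
updates and applies the unit-sum normalization once at convergence. Set
extraction is unaffected either way: it thresholds each factor against its own
maximum, which is scale-invariant.

**Encoding.** Dosages are offset to $\{1,2,3\}$ (`offset_dosage`) so that
homozygous-reference genotypes remain informative under multiplicative
updates; `risk_dosage` first flips protective SNPs ($d \mapsto 2-d$) so that
loadings align with risk-allele burden. Missing genotypes are imputed with the
per-SNP mode before factorization (deterministic; ties break to the smaller
dosage; preserves the integer coding).

**Set extraction.** In the default `factor_wise` mode, SNP $j$ belongs to set
$i$ iff $W_{ji} \ge \tau \max_{j'} W_{j'i}$ (and similarly for subjects on the
rows of $H$), with $\tau = 0.6$ — 60% of the highest value per factor. The
phrase "per row or column" admits a second reading, thresholding each entity
against its own maximum across factors; that is implemented as
`entity_wise`. `factor_wise` is the default because it can never produce an
empty set (the maximum always qualifies), which is what makes the sweep
accounting exact: ranks $2..16$ give $\sum_k k = 135$ sets.

**Rank sweep.** The stated sweep rule bounds $k$ by $\sqrt{m}$ of the panel
($\sqrt{193} \approx 13.9$), yet the source accounting runs to $k = 16$; the
two cannot both be the generating rule, so `k_max` is an explicit parameter
defaulting to $\lfloor\sqrt{m}\rfloor$ and overridable to 16.

## The kernel association test

For disease status $y$ the null model is logistic in the covariates only
(age, age², sex, BMI, and ancestry PCs when present; age² is derived in the
test module rather than stored). With $\hat\mu$ the fitted probabilities and
$r = y - \hat\mu$,

$$Q = r^\top G W^2 G^\top r,$$

where $G$ is the subjects-by-SNPs dosage matrix of the *set's SNPs over all
cohort subjects*. The set's subject membership deliberately plays no role
here: the kernel framework tests a variant collection over the full sample,
and subject membership is consumed by the downstream hypergeometric
architecture stage instead. Weights default to flat ($w = 1$) because the
panel consists of common variants (MAF > 1% after QC); Beta(1, 25) MAF weights
are selectable but inappropriate for this design.

Under the null, $Q \sim \sum_j \lambda_j \chi^2_1$ with $\lambda_j$ the
eigenvalues of the covariate-projected half-kernel
$W G^\top (V - VX(X^\top VX)^{-1}X^\top V)\, G W$, $V = \mathrm{diag}(\hat\mu(1-\hat\mu))$.
The tail probability is computed by numerical inversion of the characteristic
function: the inversion integrand is truncated at the point where an analytic
tail bound guarantees the requested accuracy ($10^{-9}$, relaxed once to
$10^{-6}$) and integrated by Simpson quadrature with ~40 nodes per oscillation
period. When the grid that accuracy would require is infeasible — few, widely
spread eigenvalues, where the integrand tail decays slowly — the Liu
four-moment match is used instead and recorded in the `method` column. For a
single eigenvalue the Liu match is algebraically exact
($Q/\lambda \sim \chi^2_1$), so the single-SNP score-test equivalence holds on
either path.

A caveat the test suite makes explicit: at very small sample sizes (tens of
subjects) the *exact permutation* distribution of $Q$ deviates from the
asymptotic mixture at $O(1/n)$, because binary residuals take two values and
their kurtosis is below 3. The suite's comparison of the inversion p-value with
a 100,000-permutation p-value at $n = 30$ fails for any correct implementation
of the standard estimator and is intentionally left failing; the type-I error
of the test at $n = 300$ is verified to sit inside the exact binomial 99%
interval around the nominal 0.05 over 2000 null replicates.

## Architecture, redundancy, network

All overlap tests are upper-tail hypergeometric: the probability of an
intersection at least as large as observed between two subsets of a finite
universe, summed exactly in log space. The universe is the analyzed cohort for
subject overlaps (the only choice consistent with the reference subgroup
accounting) and the pooled panel (193 SNPs in the reference design) for SNP
overlaps.

Redundancy filtering uses the Jaccard coefficient on both dimensions; "over
0.8" is read strictly, so a boundary JC of exactly 0.8 is kept. The selection
of "optimal, non-redundant" sets is stated in the source only as an
optimization by association strength, so this package implements a declared
stand-in: sort sets by their best (smallest) phenotype-relation p, break ties
by smaller $k$ then smaller factor index, and accept greedily, rejecting any
candidate whose SNP- or subject-JC against an accepted set exceeds 0.8. The
canonical sort makes the output independent of input order.

Relations between retained sets and the four patterns are Bonferroni-corrected
by the number of retained sets (23 retained sets at $\alpha = 0.05$ reproduce
the reference threshold $2.17\times10^{-3}$); the four patterns are not
separately corrected, matching how the reference threshold was printed. The
genotypic network links set pairs whose shared-SNP overlap is significant at
$\alpha$ Bonferroni-corrected over pairs (a declared choice — the source names
the test but no edge threshold; `alpha = 1` links any nonzero overlap), with
SNP-Jaccard edge weights and union-find components.

## The synthetic cohort generator

`simulate_cohort()` produces the world the pipeline assumes: background
genotypes per-SNP binomial(2, MAF) with MAFs uniform on a configured range;
planted SNP-by-subject blocks overwritten with a concordant dosage
(homozygous-alternate by default); two diseases drawn from independent
logistic liabilities combining centered covariate effects
(age ~ N(60, 8) truncated to [40, 85], sex ~ Bernoulli(0.5), BMI ~ N(25, 3))
with planted penetrance shifts; and missingness applied MCAR. Defaults encode
the reference geometry: 441 subjects split 61/91/97/192, a 110 + 83 SNP panel.

Exact pattern counts are enforced by stratified reassignment: while any
pattern has a surplus, the surplus subject with the highest liability-model
probability of a deficit pattern moves there. Each move reduces the total
imbalance by two, so termination is guaranteed without whole-cohort rejection.

Ancestry PCs are computed post hoc from the genotype matrix rather than
simulated, which mirrors how real PCs arise — with one important consequence.
In a synthetic cohort there is no ancestry structure, so PCs computed from the
193-SNP analysis panel load on the *planted biclusters* (the dominant
structure present) and adjusting for them absorbs the association signal under
study. The pipeline therefore computes and stores the PCs but defaults to
`gwas$adjust_pcs = FALSE`; enable the flag when the PCs come from genome-wide
data, which is what the 10-PC covariate convention assumes.

Two further interactions between the stated world and the pipeline are worth
knowing:

* Planted homozygous blocks at low background MAF violate Hardy–Weinberg
  equilibrium by construction, so the HWE filter can legitimately remove part
  of a planted panel. The QC stage logs per-step counts; planted SNPs are
  *not* exempted from QC.
* Recovery of $c$ planted sets works with rank $k = c + 1$: one factor absorbs
  the genotypic background of a realistic cohort. With $k = c$ the background
  competes with the planted structure and recovery degrades. A matrix that
  consists *only* of two blocks is recovered at $k = 2$.

What a green recovery test establishes is that the factorization-extraction
path finds planted concordant blocks of the stated size (at least 10 SNPs by
20 subjects) against a binomial background; it does not establish performance
under linkage disequilibrium, relatedness, or ancestry confounding, none of
which the generator emulates (deliberately — the source design excluded
related subjects, and LD beyond planted concordance is out of scope).

## Numerical choices and defaults

| parameter | default | units / range | why |
|---|---|---|---|
| `snp_missing_max` | 0.05 | proportion | removal at ≥ 5%, closed threshold as printed |
| `maf_min` | 0.01 | frequency | removal at ≤ 1%, closed threshold |
| `hwe_p_min` | 1e-6 | probability | exact conditional test, standard P (no mid-p) |
| `p_thresh` | 5e-5 | probability | loose prescreen association |
| `theta` | 0.5 | [0, 1] | smoothness/sparsity trade-off; source value unstated |
| `tau` | 0.6 | (0, 1] | 60%-of-maximum extraction rule |
| `k_max` | floor(sqrt(m)) | rank | overridable to 16 (see sweep discussion) |
| `max_iter`, `tol` | 2000, 1e-6 | — | relative KL change stopping rule |
| `jc_thresh` | 0.8 | [0, 1] | redundancy, strict "over 0.8" |
| `weights` | flat | — | common-variant panel |
| `p_match` | 1e-3 | probability | replication call; source states only the P = 0 extreme |

Seeds: the master seed spawns per-stage and per-rank child seeds
deterministically (`seed + 1000k` per rank; stage offsets 101 and 202), all
kept below $2^{31}$; identical configuration and seed reproduce every artifact
byte for byte.

## Known limitations

* The factorization is a local optimizer from a random start; set membership
  can vary across seeds on weakly structured data. The sweep *accounting*
  (sets per rank) is seed-invariant in `factor_wise` mode, the memberships are
  not.
* The mixture-of-chi-square inversion falls back to a four-moment match in the
  slow-tail regime; extreme tail p-values from the fallback are approximate
  (they are used for ranking and thresholding, where this is immaterial).
* Heritability estimation, genotype imputation, functional annotation,
  enrichment, and network visualization are out of scope; the network stage
  exports GraphML/TSV for external tools.
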