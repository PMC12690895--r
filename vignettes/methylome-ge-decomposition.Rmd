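---
title: "Dissecting genetic and environmental contributions to DNA methylome variability"
author: "gemvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting genetic and environmental contributions to DNA methylome variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemvar)
```

## The problem

Inter-individual variability in DNA methylation (DNAme) arises from genetic
variation, environmental exposure, and their joint action. Given matched
microarray methylation, genotype, and exposome data from a single cohort,
`gemvar` asks, for every variably methylated locus: which of five
explanations best accounts for its methylation levels?

| Model | Form |
|-------|------|
| B  | DNAme ~ covars |
| G  | DNAme ~ SNP + covars |
| E  | DNAme ~ exposure + covars |
| G+E | DNAme ~ SNP + exposure + covars |
| GxE | DNAme ~ SNP + exposure + SNP*exposure + covars |

DNAme is always the per-sample summary of a locus on the M-value scale
(`log2(beta/(1-beta))`), whose approximate homoscedasticity suits linear
modelling better than beta values. `covars` are the concomitant variables
(sex, gestational age, cell-type composition, genetic-ancestry components,
...) supplied by the user; they appear in every model and are never treated
as signal.

## Pipeline stages and their parameters

**1. Highly variable probes (HVPs).** M values are residualized per probe on
the concomitant variables (ordinary least squares with intercept — no
shrinkage, since only the linear effect is removed), and the sample variance
(denominator n−1) of the residuals ranks the probes. Probes whose variance
strictly exceeds the 90th percentile of the variance distribution (linear
interpolation, R type-7) are HVPs — the top decile of probes. Variance is
used rather than the median absolute deviation because it still detects
probes whose methylation varies strongly in a minority of individuals.
Residuals are used *only* here; every later stage consumes unadjusted M
values, with covariates handled inside the models instead.

The strict inequality at the threshold is a deterministic tie rule
(`inclusive = FALSE` flips it); with continuous variances ties essentially
never occur.

**2. Variably methylated loci (VMLs).** HVPs on the same chromosome are
chained while consecutive probes are < 1 kb apart (`max_gap = 1000`,
strict). Within a chain, each adjacent pair must also share a methylation
profile — Pearson r of their unadjusted M values > 0.15, a regional
co-methylation threshold established empirically in the literature; chains
split at uncorrelated pairs, and surviving runs of ≥ 2 probes become VMRs.
Correlation is evaluated between adjacent pairs rather than all pairs
because chaining is a sequential construction along the genome and the
adjacent rule is order-deterministic; an all-pairs-mean mode
(`cor_mode = "allpairs"`) is available. A VMR's methylation is summarized
per sample as the median M value across its member probes — a regional
summary rather than a most-variable-probe representative.

HVPs that end up alone are kept as sparse VMPs (sVMPs) only when the array
itself is sparse there: no manifest probe at all (variable or not) lies
within `max_gap`. An HVP with a near but unlinked neighbour is discarded —
proximity without co-methylation is evidence against a coherent region,
whereas array sparsity is not evidence of anything. `svmp_mode = "hvp"`
restricts the neighbour pool to HVPs for users who prefer the laxer rule.

**3. cis SNP mapping.** A SNP is cis to a VML if it lies on the same
chromosome within 1 Mb of the locus span (boundary inclusive; the window is
anchored at the span's start and end, not its midpoint). Loci with no cis
SNPs remain in the analysis — they can only ever be explained by E or B.

**4. Variable screening.** With hundreds to thousands of cis SNPs against
~10² exposures, exhaustively fitting all pairwise models is both expensive
and biased towards the larger candidate pool. Each VML is therefore screened
with an L1-penalized (LASSO) regression in three scenarios — cis SNPs only,
exposures only, both — with the concomitant variables included unpenalized
(penalty factor 0) in every scenario. Variables with a nonzero coefficient
in any scenario are pooled. ("Nonzero" rather than "positive": the sign of a
LASSO coefficient is arbitrary with respect to allele and exposure coding.)

The penalty is tuned by 10-fold cross-validation with seeded fold
assignment. The package default is the one-standard-error rule
(`lambda_rule = "1se"`): the screen's job is to hand the model competition a
small set of plausible candidates, and the CV-minimum rule measurably admits
chance-correlated candidates (at n = 500, on the order of one or two per
screen), which then survive the AIC comparison — adding a variable with
chance partial R² of r² beats the AIC penalty whenever n·r² > 2 — and
systematically inflate G+E calls at loci with a purely genetic architecture.
The 1se rule is the standard parsimonious choice for screening and removes
this failure mode; `lambda_rule = "min"` remains available. Candidates are
standardized internally for penalization; covariates are not (they are
unpenalized, so their scale is irrelevant). The lambda path is capped at 50
values, which reproduces the default path's selections at half the cost.

Each VML draws its RNG stream from a stable hash of (global seed, VML id),
so results are independent of processing order and safe to parallelize.

**5. Model competition and variance decomposition.** Every selected SNP
yields a G model, every selected exposure an E model, and every SNP ×
exposure pair one additive and one interaction model (interactions always
include both main effects). The winner minimizes AIC under the Gaussian
convention `AIC = n log(2π RSS/n) + n + 2(k+1)` — identical to R's
`AIC(lm(...))`, pinned so that independent implementations agree to
rounding. Exact ties break towards fewer coefficients, then the class order
G < E < G+E < GxE, then lexicographic variable ids. A residual sum of
squares of exactly zero is floored at 1e−12 so a perfect fit keeps a finite
AIC. Singular designs (e.g. a SNP monomorphic in the analyzed samples) drop
out of the competition with a warning; if nothing remains, the locus falls
back to B. VMLs where the screen selected nothing skip the competition and
are labelled B directly.

The winner's R² is decomposed with the LMG (Lindeman–Merenda–Gold) method:
the average, over all orderings of the model's G/E/GxE terms, of each term's
sequential R² increment, with the covariate block forced first in every
ordering so that shares are defined net of the concomitant variables. With
at most three terms the 3! orderings are enumerated exactly — no sampling.
Shares are non-negative and sum to R²_model − R²_baseline to numerical
precision.

**6. Permutation null filter.** A winning model can have the lowest AIC yet
explain no more than chance. To calibrate this, the genotype and exposome
tables are shuffled by a single shared row permutation — breaking every
association with methylation while preserving all G–E correlations — and
screening plus competition are re-run (10 permutations by default, reusing
the observed run's per-VML fold seeds so that shuffling is the only
difference). The ΔR² = R²_winner − R²_baseline values of informative
permuted winners pool across VMLs and permutations into a null distribution
that is distinctly bimodal: two-variable winners (G+E, GxE) absorb more
chance variance than one-variable winners (G, E). The two strata therefore
get separate 95th-percentile cutoffs. Observed winners below their stratum's
cutoff are demoted to B (equality keeps the winner; the pre-filter class is
retained for audit). Cutoffs are pooled across VMLs, not computed per locus.
With few VMLs, 10 permutations give a coarse percentile; ≥ 20 are advisable
for sets under a few hundred loci. An empty null stratum leaves its cutoff
at 0 (nothing demoted) with a warning, since there is then no evidence that
such winners arise by chance.

## The synthetic-data generator

Because the cohort data this kind of analysis targets is access-restricted,
`gemvar` ships a generator whose outputs exercise every stage end to end.
Its defaults are the package's reference study conditions: n = 500 samples,
20 planted loci per class (B, G, E, G+E, GxE), per-term target partial
R² = 0.2, within-region correlation ρ = 0.5, covariate share 0.15 of probe
variance, dosages Binomial(2, maf) with maf ~ U(0.05, 0.5), 15 exposures of
which 40% are binary with prevalence U(0.1, 0.5), 8 decoy cis SNPs per
locus, probe clusters of 2–5 probes with gaps U[50, 800] bp, 25% of loci
laid out as isolated single probes, and 9 low-variance filler probes per
planted probe so that planted probes sit just inside the top variance
decile. Loci are spaced 2.5 Mb apart so cis sets do not bleed into each
other; filler probes live on separate chromosomes, ≥ 2 kb apart, so they can
only surface as sVMPs.

Effect sizes are parameterized as target partial R² (portable across sample
sizes) and solved from the empirical variance of each generated term at the
probe level, where total planted-probe variance is 1. The interaction
column is orthogonalized against (1, SNP, E) before scaling, so its target
is not absorbed by the main effects; the fitted model space is unchanged by
this, since the orthogonalized product spans the same design space as the
raw product. The shared (regional) variance fraction is max(ρ, Σ targets):
for null loci it is exactly ρ, making ρ the plain within-region
correlation there; strong-signal loci are necessarily more correlated,
because the signal itself is shared across member probes. Covariate effects
are probe-specific so they contribute to probe variance but not to
between-probe correlation.

What the generator does *not* emulate: linkage disequilibrium among SNPs,
population stratification, beta-value heteroscedasticity, missingness, or
batch structure. Passing recovery tests on this generator demonstrates that
the machinery identifies the architectures it models, under clean additive
Gaussian noise — not that real cohort data meets those assumptions.

A note on summarization: targets are defined at probe level, and the median
summary of a VMR averages away part of the probe-unique noise, so realized
partial R² at VMR level runs slightly above target. The recovery criteria
are one-sided (sensitivity thresholds), so this bias is visible and benign.

## Validation results computed by this package

The test suite and `scripts/acceptance.R` recompute, from scratch:

- exact agreement of the AIC winner with brute-force enumeration, and of
  LMG shares with the all-orderings average (tolerance 1e−10);
- null calibration: on global-null data (no planted G/E effects,
  n = 300, 10 permutations, 20 seed replicates pooling ~200 VMLs) the
  post-filter informative fraction stays within the nominal level of the
  95th-percentile rule;
- parameter recovery at the default conditions, pooled over three seeds
  (60 loci per class): class sensitivity for G, G+E and GxE and
  causal-variable recovery among correctly classified loci;
- pooling consistency: when the screen selects both G and E variables at
  loci with real joint signal, the winning model contains both factors;
- robustness of the screen to a 1000-vs-10 candidate imbalance under pure
  noise (median selected count 0 on both sides).

One intrinsic limitation surfaces in these numbers: among loci whose true
architecture is additive (G+E), a fraction ≈ P(χ²₁ > 2) ≈ 0.16 is called
GxE, because AIC admits one extra parameter whenever the chance interaction
improves 2·log-likelihood by more than 2. This is a property of AIC model
competition itself, not of the implementation; the interaction's LMG share
at such loci is correspondingly near zero, which is the designed way to read
them.

## Worked example

```{r example, eval = FALSE}
library(gemvar)

sim <- simulate_ge_dataset(sim_config(), seed = 1)
pl <- run_ge_pipeline(sim$dataset, seed = 1, n_perm = 10)
pl$summary                      # class proportions by VML kind
head(pl$results)                # per-VML winner, AIC, delta R2, LMG shares
evaluate_recovery(pl$results, pl$vml, sim$truth)
```

Problem sizes throughout the shipped tests (hundreds of probes, tens of
loci, n of a few hundred) are the package's chosen desk-scale reference
conditions; all thresholds are defined as rates so they transfer to larger
inputs unchanged.

## Known limitations

- One G and one E variable per model: multi-variant or multi-exposure
  architectures are approximated by their best single pair, as in the
  framework this package implements.
- LASSO keeps an arbitrary representative of a correlated candidate block;
  selected variables should be read as tagging their block, not as causal
  calls.
- Complete cases are required; imputation is upstream work, and the loaders
  fail fast on missing values rather than dropping silently.
- The permutation null assumes exchangeability of (G, E) rows against
  methylation under the null; structured confounding not captured by the
  covariates violates this.
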