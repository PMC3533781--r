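---
title: "Population genetics of HLA samples with typing ambiguities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population genetics of HLA samples with typing ambiguities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlapop)
```

## The problem

HLA loci are the most polymorphic genes in the human genome, and most
laboratories type them at intermediate resolution: the typing result is
consistent with more than one allele pair.  Dropping that ambiguity — by
picking the most likely pair, or by expanding registry abbreviation codes
into inflated pair lists — biases every downstream population-genetic
statistic.  `hlapop` keeps the ambiguity explicit from input to report: a
genotype is always the full list of candidate allele pairs required to
explain the typing, and every estimator and test sums over that list.

## Genotype representation

The canonical text dialect uses the genotype-list delimiters: `/` separates
allele-level alternatives, `+` the two alleles of a genotype, `|`
alternative whole-genotype explanations, `^` loci.  `A*01:01/A*01:02+A*02:01`
expands to two candidate pairs; `A*01:01+A*02:01|A*01:02+A*02:02` is exactly
those two pairs — the `|` form states the pair list and is never re-factored
into the four-pair cross-product.  Homozygotes are written with the allele
duplicated, which removes the homozygote-versus-blank reading of a
single-allele record.  Candidate pairs are unordered and canonicalized
(locus, then numeric field sequence, then expression suffix), so parsing,
serialization and file conversion are closed over candidate sets.

Multiple-allele codes (e.g. `A*01:XX`) are expanded faithfully as the full
cross-product of the two sides, and `count_spurious_pairs()` measures the
pairs this adds beyond the laboratory's true pair list — the reason such
codes are discouraged for population data.

## Allele frequencies by EM

At one locus with candidate sets $C_i$, the likelihood under
Hardy–Weinberg proportions is

$$L(p) = \prod_i \sum_{(a,b)\in C_i} g_{ab}(p),\qquad
  g_{aa}=p_a^2,\; g_{ab}=2p_ap_b .$$

The E-step gives each candidate pair the posterior weight
$g_{ab}(p)/\sum_{C_i} g(p)$; the M-step sets $p_a$ to the expected count of
$a$ over $2N$ gene copies.  On unambiguous data one iteration reproduces the
counting estimator exactly.  Defaults: 5 starts (first uniform, the rest
Dirichlet(1) draws under the user's seed), convergence when the
log-likelihood change is below $10^{-8}$ or the sup-norm frequency change
below $10^{-9}$, at most 5000 iterations.  The fit reports the number of
starting points, the number of distinct solutions found (two optima count as
one when their log-likelihoods differ by at most 0.01 and their frequency
vectors by at most $10^{-4}$ in sup norm — artifact choices, surfaced in the
diagnostics), the criterion met, the iteration count and the seed, because a
frequency estimate without its estimation conditions is not reproducible.

Haplotype frequencies use the same EM over phased diplotypes: each
multi-locus candidate expands to its $2^{h-1}$ compatible haplotype pairs
($h$ heterozygous loci), weighted $h_jh_k$ (doubled off the diagonal).
Haplotypes below `prune_threshold` (default $1/(10\cdot 2N)$) are dropped
between iterations unless that would leave an individual unexplained; the
expansion is capped at $10^6$ diplotypes per individual, beyond which the
advice is to reduce typing resolution first.  With one locus the procedure
reduces exactly to the allele EM.  Pairwise linkage disequilibrium reports
$D_{jk}=h_{jk}-p_jq_k$, the conventionally normalized $D'$, and
$W_n=\sqrt{\sum D_{jk}^2/(p_jq_k)\,/\,(\min(k_1,k_2)-1)}$.

## Hardy–Weinberg testing under ambiguity

Contingency-table tests (chi-square, G, exact) require unambiguous
genotype counts.  `hwe_test()` instead compares nested likelihoods computed
by summing over each individual's candidate set.  The default alternative is
the one-parameter inbreeding model
$P(aa)=p_a^2+fp_a(1-p_a)$, $P(ab)=2p_ap_b(1-f)$ (df = 1), the canonical
nested departure from equilibrium; the saturated genotype-frequency model
(df $=k(k+1)/2-k$) is available and equals the classical G statistic on
unambiguous data.  $f$ is profiled: for each $f$ on a 0.05-step grid over
$(-0.95, 0.95)$ the frequencies are re-optimized (softmax parametrization,
warm-started along the profile), then the profile is refined by
golden-section search around the grid maximum.  $f = 0$ is always a profile
point, so the likelihood ratio is non-negative by construction; the
admissible range of $f$ is bounded below by
$-\min_a p_a/(1-p_a)$ to keep all genotype probabilities non-negative.  One
numerical detail matters: the grid is built from integer multiples of 0.05
so that 0 appears exactly once — a floating-point near-duplicate of zero
would silently truncate the refinement bracket and collapse the statistic to
zero whenever the maximum lies just beside the null.

## Selective neutrality

`ewens_watterson_test()` compares the observed homozygosity
$F=\sum\hat p_a^2$ with its neutral sampling distribution conditional on
$n=2N$ gene copies and $k$ alleles.  $\hat\theta$ solves
$E[K\mid\theta,n]=\sum_{i=0}^{n-1}\theta/(\theta+i)=k$ by monotone
root-finding; null configurations are drawn by the sequential urn
construction of the Ewens sampling formula and rejection-conditioned on
$K=k$ (an error advises exact enumeration when acceptance falls below
0.1%).  Tail probabilities use the mid-p convention — ties at $F_{obs}$
count half in each tail — so `p_low + p_high = 1`.  For $n\le 30$,
`exact_ewens_null()` enumerates all partitions of $n$ into $k$ parts with
conditional probabilities $\propto\prod_j (1/j)^{a_j}/a_j!$ and serves as
the independent oracle for the sampler; at $n=4,k=2$ the null support is
$\{0.625, 0.5\}$ with probabilities $8/11$ and $3/11$.  By default $k$
counts all estimated alleles; an option restricts it to alleles whose
frequency is significant for the sample size, because allele counts are
strongly sample-size dependent.  $F_{obs}$ is computed from the point EM
frequencies; ambiguity uncertainty is not propagated into the null, and the
result says so.

## Sample-size thresholds

A frequency estimate can be "nonsignificant" — not distinguishable from
zero — purely because the sample is small.  Model I solves
$p = z\sqrt{p(1-p)/2N}$ with $z=2$ ("two standard deviations"), giving
$p^* = z^2/(2N+z^2)$; $z=2$ rather than 1.96 because only $z=2$ reproduces
every published cell of that column (e.g. $6.25\% = 4/64$ at $N=30$).
Model III solves $(1-p)^{2N}=0.05$: the frequency at which the sample
misses the allele entirely with 5% probability.  Model II (one-tail normal)
is provided as the $z_1=1.645$ analogue but flagged approximate: the
published one-tail column follows no documented formula and is not
reproduced by it.  Two further published cells disagree slightly with their
own formulas (model I at $N=500$ prints 0.39 where $4/2004$ rounds to 0.40;
model III deviates by up to 0.02 at $N\in\{30,100,150\}$) — the packaged
printed table is kept verbatim so the discrepancies are visible, and the
computed values follow the formulas.  Display rounding is half away from
zero to two decimals, with the unrounded value retained as an attribute.

## The synthetic-data generator

`generate_genotypes()` draws $N$ independent individuals with
$P(aa)=p_a^2+fp_a(1-p_a)$, $P(ab)=2p_ap_b(1-f)$ — Hardy–Weinberg at $f=0$ —
from explicit frequencies or a symmetric Dirichlet draw; independence
matches the sampling guideline that first-degree relatives be excluded.
`generate_kit()` builds random probe panels (each allele reacts with each
probe with probability 0.5, re-drawn until signatures are distinct or a cap
is hit), and `mask_with_kit()` pushes a clean sample through forward probe
prediction and reverse interpretation, reproducing exactly the mechanism by
which reverse-SSO typing creates ambiguity — the true genotype is always
among the candidates.  Attached metadata is deliberately fictional
("Simulandia", mid-ocean coordinates): fixtures must not imitate real
populations.

What the generator does *not* emulate: probe noise or failed reactions,
blank-like alleles invisible to a kit, genotyping error, related
individuals, or population structure.  Passing recovery tests therefore
show that the estimators invert the ambiguity mechanism they model, not
that they are robust to artifacts outside that model.

Problem sizes used in the packaged checks are chosen as the smallest that
make the statistical assertions sharp: frequency recovery at $k=8$,
$N=500$ through a 5-probe kit (over 90% of individuals ambiguous);
HWE calibration over 1000 samples at $k=5$, $N=200$ with equifrequent
alleles — equifrequency is used so the nominal allele count is actually
realized in every sample, which a Dirichlet draw does not guarantee — and
power against $f=0.15$ at the same size; neutrality-null agreement with the
exact distribution for all $n\le 12$.

## Known limitations

Serology-era names and G/P groups are not parsed.  Blank-like alleles are
not modeled in the likelihood; validation warns when a kit universe is
smaller than the allele pool.  The common-pool construction treats
within-typing alternatives and name-prefix nesting as indistinguishability
evidence and takes the transitive closure; other readings of "setting the
common allele pool" are possible.  Multi-locus candidates are stored
unphased, and phase enters only in the haplotype EM.  Registry-scale
performance engineering is out of scope.
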