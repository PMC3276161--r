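---
title: "Mutation rarefaction for microsatellite panels: models, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutation rarefaction for microsatellite panels: models, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msatrare)
```

## The model

Microsatellite alleles are characterised by their repeat count; under the
stepwise mutation model (SMM) each mutation adds or removes exactly one
repeat unit, with equal probability, at rate $\mu$ per generation per
lineage. For a pair of alleles whose lineages coalesced $t$ generations
ago, the signed difference in repeat count is a sum of $2t$ independent
steps taking $-1, 0, +1$ with probabilities $\mu/2$, $1-\mu$, $\mu/2$, so
its characteristic function is $(1 - \mu + \mu\cos\omega)^{2t}$. In a
sample, $t$ varies across pairs according to the (unknown) genealogy, and

$$\hat p(\omega, \mu) \;=\; \sum_t g_t\,(1-\mu+\mu\cos\omega)^{2t}
  \;=\; \tilde g\!\left(1 - \mu(1-\cos\omega)\right),$$

where $g_t$ is the distribution of pairwise TMRCA and $\tilde g$ its
generating function. The key observation is that $\tilde g$ is a property
of the genealogy alone: under neutrality it does not depend on $\mu$.
Substituting frequencies therefore maps one mutation rate onto another,

$$\hat p(\omega, \mu') = \hat p\!\left(\arccos\left[1 -
  \tfrac{\mu'}{\mu}(1-\cos\omega)\right],\, \mu\right),
  \qquad r = \mu'/\mu \le 1,$$

which is exactly what one would obtain by randomly deleting a fraction
$1-r$ of the mutations on the genealogy — a *rarefaction* of the
mutations. Inverting the cosine transform gives a linear kernel acting on
the observed distribution $p(\Delta)$ of absolute repeat differences;
rarefied heterozygosity is $H_{\text{rar}} = 1 - p_{\text{rar}}(0)$ and
the repeat-count variance obeys $V_{\text{rar}} = r\,V$ (a Taylor
expansion of the characteristic function at $\omega = 0$).

Assumptions worth keeping in view:

* **Neutrality** — the genealogy is independent of the mutation process;
  this is what lets $\tilde g$ cancel between rates.
* **Single-step, rate-homogeneous SMM within a class** — markers grouped
  into a class are treated as sharing one rate. Directional mutation bias
  is harmless: the method uses only $|\Delta|$ and the cosine series, so
  any constant drift in repeat count cancels.
* **Downward only** — $r \le 1$. Rarefaction removes information;
  inverting it would amplify sampling noise without bound, so `r > 1` is
  a hard error rather than an attempted extrapolation.

Because the transform is linear in $p(\Delta)$, it commutes with
averaging: rarefying the locus-averaged distribution equals averaging the
per-locus rarefied distributions, and the identity
$\text{rarefy}(p(\mu), \mu'/\mu) = p(\mu')$ holds for any mixture over
TMRCA — this is tested both for fixed-$t$ distributions and explicit
mixtures.

## Estimating relative mutation rates

`fit_rarefaction_factor()` finds the $k = \mu_{\text{ref}}/\mu_{\text{src}}$
that brings the source class's diversity closest to the reference class's:

* `full_distribution` — least squares on the full per-population-pair
  difference distributions (all pairs weighted equally, all $\Delta$ up to
  the common truncation bound);
* `heterozygosity` — least squares on the within/between heterozygosity
  matrices only;
* `variance` — the classical closed form
  $k = \bar V_{\text{ref}} / \bar V_{\text{src}}$ with $\bar V$ the mean
  across loci of the pooled-sample allele repeat-count variance.

The scalar objective is minimised by `stats::optimize()` on $(10^{-3}, 1]$
with tolerance $10^{-5}$; on clean SMM data the objective is unimodal, so
a bounded golden-section search is sufficient and deterministic. When the
*reference* is the more diverse class no $k \le 1$ exists; the optimum
then pushes against $k = 1$ while the reference stays more heterozygous,
and the fit is reported as infeasible (`NA`, the analogue of a dash in a
rate table) rather than returning the boundary. With an anchor rate for
one class (for di-nucleotides a pedigree estimate,
$\mu_2 = 1.52\times10^{-3}$, is the conventional choice), fitted factors
convert to absolute rates, and `composite_rate()` chains two factors
through a common reference ($\mu_B = \mu_A k_{AR} / k_{BR}$), which is
useful when $A$ and $B$ cannot be scaled onto each other directly.

## Fragment-length cleaning

Raw genotypes arrive as fragment lengths in bp, $L = L_m n + \gamma$.
Per locus, pooled across populations (one $L_m$ per locus is wanted, and
pooling maximises spectrum density):

1. $L_m$ maximises the relative overlap
   $\sum_i f_i f_{i+L_m} / \sum_i f_i^2$ over shifts of 2–5 bp;
2. $\gamma$ is the modal remainder $L \bmod L_m$, counted per allele copy;
3. if the modal $\gamma$ covers $\ge 95\%$ of allele copies, individuals
   carrying any off-offset allele are recoded missing at that locus and
   the rest converted to repeat counts; otherwise the locus is rejected.

Numerical/design choices where the procedure is underdetermined: ties in
the overlap score go to the smallest candidate $L_m$ (a di-nucleotide
ladder is always self-consistent; larger motifs need positive evidence)
and ties in $\gamma$ to the smallest offset, both flagged in the QC table;
the threshold comparison is $\ge 0.95$, so the retain/reject rule
partitions all cases; loci with fewer than two distinct lengths are
degenerate (no informative shift) and rejected; penta-nucleotides are
cleaned but flagged so callers can drop sparse classes.

The overlap statistic is an empirical heuristic, not a theorem: on sparse,
ragged spectra a harmonic shift can outscore the true motif (a true
di-ladder occupying every second length can score marginally higher at a
4 bp shift). When that happens the offset filter catches it — the
misclassified ladder splits its remainders across offsets and the locus is
rejected. The guarantee that is property-tested is therefore *recovery or
rejection, never a silently wrong conversion*; exact recovery is asserted
on spectra dense enough (on the order of a hundred allele copies per
locus) for the statistic to be reliable.

## Heterozygosity, F_ST and regressions

Within-population expected heterozygosity uses Nei's unbiased estimator
$\frac{n}{n-1}\left(1-\sum_i \hat p_i^2\right)$ with $n$ the number of
typed allele copies (equivalently: the fraction of *distinct* allele
pairs that differ — which is exactly how the within-population difference
distribution is built, so $1 - p(0)$ and the estimator agree by
construction). Between-population heterozygosity is the plug-in
cross-product $1-\sum_i \hat p_{i,a}\hat p_{i,b}$; sampling never pairs
an allele with itself across populations, so no correction is needed.
Loci are averaged with equal weight; a locus is skipped (not imputed) for
entries where a population has fewer than two typed alleles. A
`plugin` flag switches the within estimator to uncorrected frequencies
for sensitivity analyses. Pairwise differentiation is
$F_{ST}(a,b) = 1 - \tfrac{1}{2}(H_{aa}+H_{bb})/H_{ab}$, clamped to
$[0,1]$ with clamping counted.

`regress_h_on_covariate()` fits OLS of per-population diversity on a
covariate and attaches percentile bootstrap intervals (default
$B = 10{,}000$). The default resampling unit is **loci**: the uncertainty
of interest is usually "would a different draw of markers give the same
cline?", and loci are the exchangeable unit for that question; resampling
populations instead is available for spatial-sampling uncertainty.
`compare_slopes()` tests slope equality by the extra-sum-of-squares F
statistic on $(1, n_a+n_b-4)$ degrees of freedom, computed directly from
the residual sums of squares of the pooled-slope and separate-slope
models. `combined_heterozygosity()` rarefies every class to a target
class's rate before averaging with weight proportional to locus count, so
each locus carries equal weight in the combined metric; pooling without
rarefaction mixes mutation-rate scales and inflates the result.

## Numerics

* **Quadrature** — all inverse cosine transforms use the composite
  trapezoid rule on a uniform $\omega$ grid over $[0,\pi]$, 4096 nodes by
  default (2048 inside the optimiser loop). The integrands have smooth,
  even periodic extensions, so the trapezoid rule converges spectrally;
  the fixed-TMRCA oracle and the $r=1$ identity hold to $\sim 10^{-14}$
  at these defaults.
* **Folding** — $\Delta$ is folded to $|\Delta|$ before all transforms;
  the inverse transform carries the folding factor $c_\Delta$ (1 at
  $\Delta=0$, 2 otherwise), without which the kernel would neither be the
  identity at $r=1$ nor conserve probability.
* **Truncation** — pmf supports default to the largest observed
  difference plus 20; kernel columns then sum to one within $10^{-8}$.
  Tiny negative entries from truncation are clipped and the pmf
  renormalised; clipped mass is recorded and warned about above
  $10^{-6}$. The variance-scaling check warns when the input carries
  mass beyond half its truncation bound.
* **Determinism** — simulation panels are fully determined by their seed;
  bootstrap intervals are bit-reproducible given theirs.

## What the simulator emulates — and what it does not

`simulate_panel()` generates diploid multi-population panels from a
structured coalescent (island model with symmetric migration, a
serial-founder chain with post-founding bottlenecks, or a star genealogy
with fixed TMRCA), drops SMM mutations as a Poisson process along
branches (a discrete per-generation mode exists for exact agreement with
the $(1-\mu+\mu\cos\omega)^{2t}$ form), encodes repeat counts as fragment
lengths $L = L_m n + \gamma$, and optionally contaminates a fraction of
allele copies with off-ladder shifts. Ground truth (motif structure,
rates, contamination, realised TMRCAs) is retained for every assertion.

It deliberately does **not** model recombination, selection,
length-dependent or multi-step mutation, allele-calling stutter beyond
the simple off-ladder shift, or realistic human history; demographies are
kept schematic because the tests need statistical structure, not
historical realism. Passing tests therefore show that the estimators
recover truth *under the SMM and neutral-genealogy assumptions*, not that
real panels satisfy those assumptions — on real data the cleaning step
and cross-class consistency checks are precisely the tools for probing
the latter.

Default study conditions and the reasoning behind them:

* Rate-recovery experiments use two classes of 60 loci with true ratio
  0.5 ($\mu_2 = 1.5\times10^{-3}$, the pedigree scale for human
  di-nucleotides) on **shared star genealogies**
  (`demography = "star"`, `share_genealogies = TRUE`). Two choices need
  justifying. Sharing genealogies between classes is a matched-loci
  design: the contrast of interest is the rate ratio, and pairing removes
  genealogical variance from the comparison. The star genealogy
  (instantaneous expansion, every pair coalescing at
  `expansion_time = 2000` generations) is the fixed-TMRCA setting in
  which the rarefaction principle is usually illustrated; it is chosen
  here because under Kingman-coalescent demographies the pooled
  repeat-count variance of a locus is dominated by net mutational
  displacement on a few deep branches — effectively a one-degree-of-
  freedom chi-square — so the classical variance ratio has a sampling
  sd near 0.1 at 60 loci for *any* island/founder parameterisation,
  and no 60-locus experiment can hold all three fitting schemes to
  $\pm 0.05$. Under the star design the genealogical component is
  controlled, only mutational noise remains, and all three schemes
  concentrate (sd $\approx 0.012$ across replicate panels). The
  coalescent demographies remain the test bed for everything
  qualitative: founder-chain diversity clines, $F_{ST}$ behaviour,
  equilibrium heterozygosity.
* The founder-chain demonstration uses founding intervals much shorter
  than the deme size (150 generations vs $N = 2000$): a cline in
  within-population diversity persists only while demes have not
  re-equilibrated, which is the regime the serial-founder picture of a
  range expansion describes; with slow founding the cline flattens from
  the oldest demes onward.
* Equilibrium calibration uses a single deme ($N = 500$,
  $\mu = 10^{-3}$, 300 loci) against the closed form
  $H = 1 - 1/\sqrt{1+8N\mu}$; bootstrap coverage uses 500 replicates of
  a 52-point linear cline with $B = 1000$. These sizes keep each check to
  seconds while leaving Monte-Carlo error well below the tolerances
  asserted.

## Known limitations

* Rarefaction runs only toward lower rates; comparing a slow class to a
  fast one must rarefy the fast one (the infeasible direction is
  reported, not silently flipped).
* Classes with few loci give unstable fits — as a rule of thumb at least
  10, better 20+ loci per class; the package does not enforce this, it
  only exposes `n_loci`.
* The cleaning statistic needs dense allele-frequency spectra; sparse
  loci fall back to rejection rather than risking misclassification (see
  above), which on low-diversity panels preferentially removes the least
  diverse loci — an ascertainment effect of QC itself that matters when
  comparing marker classes near the rejection margin.
* The within-population estimator corrects for sample size, but the
  between-population plug-in does not correct allele-frequency noise;
  with very small samples $F_{ST}$ is accordingly noisy.
* Degrees of freedom in `compare_slopes()` are reported as
  $(1, n_a+n_b-4)$ from the stacked ANCOVA; analyses that pair the two
  responses population-by-population would use a different bookkeeping.
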