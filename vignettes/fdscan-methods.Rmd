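---
title: "Window-based ABBA-BABA statistics: models, simulator and evaluation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based ABBA-BABA statistics: models, simulator and evaluation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdscan)
```

## The four-taxon setting

Given three populations and an outgroup related as (((P1, P2), P3), O),
biallelic sites where the derived allele B is shared by P2 and P3 ("ABBA")
or by P1 and P3 ("BABA") are equally likely under incomplete lineage
sorting without gene flow. With population samples, each site contributes
frequency weights rather than binary counts:

$$C_{ABBA}(i) = (1-\hat p_{i1})\,\hat p_{i2}\,\hat p_{i3}\,(1-\hat p_{i4}),
\qquad
C_{BABA}(i) = \hat p_{i1}\,(1-\hat p_{i2})\,\hat p_{i3}\,(1-\hat p_{i4}),$$

where $\hat p_{ij}$ is the derived-allele frequency at site $i$ in
population $j$. Patterson's $D$ is the normalized difference
$\sum(C_{ABBA}-C_{BABA}) / \sum(C_{ABBA}+C_{BABA})$; the numerator sum is
called $S$. The three estimators of the introgression proportion $f$
divide the observed $S$ by the $S$ expected under complete introgression:
$\hat f_G$ replaces P2 by one half of a split P3 sample
($S(P_1, P_{3a}, P_{3b}, O)$), $\hat f_{hom}$ assumes complete
homogenization ($S(P_1, P_3, P_3, O)$), and the dynamic estimator
$\hat f_d$ substitutes, site by site, whichever of P2/P3 carries the
higher derived frequency ($S(P_1, P_D, P_D, O)$).

Useful algebraic facts that the test-suite exploits: per site,
$C_{ABBA}-C_{BABA} = \hat p_3 (1-\hat p_4)(\hat p_2-\hat p_1)$; $D$ is
exactly antisymmetric under swapping P1 and P2; $\hat f_d = \hat f_{hom}$
whenever $\hat p_3 \ge \hat p_2$ at every site; and $\hat f_d = 1$ when
P2 and P3 frequencies coincide everywhere. The often-quoted bound
$\hat f_d \in [0,1]$ on windows with $D \ge 0$ is a *per-site* theorem
and an empirical property of genealogically generated data, not an
identity for arbitrary frequency tables; adversarial tables mixing
ABBA-leaning sites with sites where $\hat p_1 > \hat p_2 > \hat p_3$ can
exceed it. We therefore assert the bound on single sites and on simulated
windows, where it held in every window we generated.

## Polarization and site filtering

Sites are used only if they are biallelic over all called haplotypes and
every group has at least one called haplotype (frequencies are undefined
otherwise; the original description gives only a window-level filter, so
this per-site rule is the package's choice). The ancestral allele is the
allele fixed among called outgroup haplotypes; if the outgroup is
polymorphic, the overall majority allele is ancestral, with ties broken
deterministically towards the alphabetically first base. Because of the
majority rule the outgroup derived frequency $\hat p_4$ can be nonzero;
we keep it (the $(1-\hat p_4)$ factor is retained in the weights) and
expose `force_p4_zero` for the stricter convention — the source analyses
do not state which was used.

For $\hat f_G$, the P3 sample is split into halves interleaved by sample
order (odd indices form the larger half when the count is odd), with a
seedable random split as an option. A contiguous first/second-half split
is deliberately not offered: when nearby haplotypes are locally identical
— precisely the situation in low-recombination windows — it makes the
denominator degenerate at every site, while the interleaved split keeps
the halves exchangeable.

$\hat f$ values are computed and stored for all windows, including
$D < 0$ windows where they are negative; consumers are expected to
interpret them only where $D \ge 0$, and the outlier machinery enforces
that eligibility rule.

## Windows, $\pi$ and $d_{XY}$

Scans use nonoverlapping 5-kb windows by default, never spanning scaffold
boundaries; trailing partial windows are emitted but flagged rather than
dropped (the original treatment is unstated). Windows are discarded when
fewer than 3,000 sites have genotype calls for at least half of the
individuals — "half" rounds up for odd sample sizes. Coordinates are
0-based half-open internally and 1-based inclusive in written tables.

$\pi$ and $d_{XY}$ are means over haplotype pairs of (differences /
jointly called sites): missing data are excluded pairwise, each pair
contributes equally, and pairs with no jointly called site are excluded.
Whether the original $\pi$ included within-individual haplotype pairs is
ambiguous ("each pair of individuals"); the package excludes them by
default for diploid input and treats every haplotype as its own
individual for simulated (haploid) data, with a switch
(`exclude_same_individual`).

## The coalescent simulator

No installed R package simulates the coalescent with recombination, so
the engine is implemented natively (in C++): Hudson's ancestral
recombination graph with time in units of $4N$ generations ($k$ lineages
in a population coalesce at rate $k(k-1)$; a lineage whose ancestral
material spans $g$ bp recombines at rate $4Nr \cdot g$), stepwise
demography as population joins, and instantaneous admixture as a pulse in
which each recipient lineage independently traces its ancestry through
the donor with probability $f$ — the classic `-es/-ej` idiom of
coalescent simulators, whose printed form for a 5-kb window with
$f = 0.2$, $t_{GF} = 0.1$ and $4Nr = 0.01$/bp corresponds to a retention
parameter of 0.8 and a whole-window recombination rate of 50.

Sequences evolve along the marginal tree of each recombination segment
under finite-site HKY mutation with branch lengths scaled by 0.01
substitutions per site per $4N$ generations. Base frequencies default to
equal and the transition/transversion rate ratio to $\kappa = 1$
(equivalently a transition:transversion ratio of 0.5, the conventional
simulator default; the original runs do not state it), both exposed as
configuration. Mutation uses uniformization of the normalized HKY rate
matrix — Poisson-many jump-chain events per branch — which is exact and
avoids a per-site, per-branch draw; the closed-form HKY transition matrix
is kept as `hky_transition()` and cross-checked against a matrix
exponential in the tests. Correctness of the engine is pinned by analytic
oracles: within-population diversity $\approx 2 \times 0.5 \times 0.01$,
between-population divergence $\approx 2(t_{split}+0.5) \times 0.01$
after Jukes-Cantor-style saturation, a null distribution of $D$ centred
on zero, $f = 0$ pulses being distributional no-ops, and complete
introgression driving $\hat f_{hom}$ towards 1.

Study designs built on the engine:

* **Estimator grid** — both gene-flow directions, $f = 0,0.1,\dots,1$,
  $t_{GF} \in \{0.1, 0.5\}$, window lengths 1/5/10 kb and per-bp $4Nr \in
  \{0.001, 0.01, 0.1\}$, with splits fixed at $t_{12}=1$, $t_{23}=2$,
  root 3; 100 windows per setting by default.
* **Combined datasets** — 9,000 Background windows (species topology,
  no sharing) plus 1,000 Alternate windows with complete P2-P3 sharing:
  under gene flow the P2/P3 join moves to $t_{GF} < t_{12}$ (P1 joins at
  $t_{23}$); under ancestral structure the P2/P3 join stays at $t_{23}$
  and P1 joins at $t_{STR} > t_{23}$, so P2-P3 divergence is unchanged
  while ABBA sharing is inflated. At $f = 1$ the two gene-flow directions
  define the same genealogical process; the direction is kept as
  metadata.
* **Model grids** — split times on $\{0.2, 0.4, \dots, 2.0\}$ with the
  root at 3.0: ordered pairs $t_{12} < t_{23}$ give 45 null models, and
  ordered triples give 120 models per gene-flow direction
  ($t_{GF} < t_{12} < t_{23}$) and 120 structure models
  ($t_{12} < t_{23} < t_{STR}$), 405 in total. The exact published
  per-model parameter lists are in supplementary material we do not
  carry; this enumeration reproduces the counts and the stated
  constraints, though possibly not the identical orderings.

What the generator does *not* emulate: heterogeneity in mutation and
recombination rate along real chromosomes, selection, varying $N_e$,
continuous migration, genotyping error and missing data. Passing tests
therefore demonstrate the statistical behaviour of the estimators under
the idealized histories, not robustness to those real-data complications
— indeed the package's own diversity-bias diagnostics exist precisely
because real genomes violate these assumptions.

## Outlier evaluation

Outliers are the top `round(0.1 * n)` windows by a statistic among
eligible candidates ($D > 0$ for $D$; $D \ge 0$ and non-missing for the
$\hat f$ family), with ties broken by window order so partitions are
deterministic. P2-P3 $d_{XY}$ is compared between outlier and nonoutlier
(or Alternate and Background) windows with a one-sided Wilcoxon rank-sum
test — exact by enumeration up to a combined $n$ of 20 without ties,
normal approximation with tie correction otherwise; whether the original
test was one-sided is unstated, so the direction is configurable —
followed by Bonferroni correction over the number of models actually
evaluated in the run, at a 99% threshold. Significance additionally
requires the outlier mean to be below the nonoutlier mean. Normality
screening is deliberately not used to switch tests; the rank test is
unconditional.

## Problem sizes and numerical choices

The full published study (405 models x 10,000 windows x 2 recombination
rates) is far larger than a desk run. The package's reduced reproduction
uses 10 evenly spaced models per scenario grid; 1,000 windows per model
(900 + 100) for the labelled gene-flow comparisons, whose effect is
large; and 5,000 windows per model for the outlier-bias comparisons at
$4Nr = 0.001$, where the $d_{XY}$ reduction is a few percent and rank-test
power at a 10%/90% split needs a sample close to the full design's
10,000 windows; the outlier cells therefore run at half the published
window count rather than a fifth. Counts are scaled proportionally to
the full grid (120 or 45) when reported.
Bonferroni uses $m = 10$, the family actually tested.

Other numerical conventions: oracle comparisons in tests use relative
tolerances of $10^{-9}$ (exact algebra) and $10^{-12}$ (hand-enumerated
divergence examples); statistics carry explicit missing values whenever a
denominator is zero (or nonpositive for the $\hat f$ family) rather than
NaN; polarization ties go to the alphabetically first base; and every
stochastic routine takes a single integer seed from which per-window
seeds are drawn, so any window in any manifest can be regenerated in
isolation.

## Known limitations

$\hat f_G$ is reported as-is even when it exceeds 1 (that instability is
part of what the window statistics are meant to reveal). The VCF path
applies the call filter to the records present in the file, which for a
variant-only VCF undercounts callable sites; supply all-sites input or
lower the threshold accordingly. The closed-form expectation of $D$
under admixture, single-SNP $D$ scans, block-jackknife genome-wide tests
and model-fitting on the joint $(\hat f_d, d_{XY})$ distribution are out
of scope.
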