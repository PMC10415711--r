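---
title: "Diversity, null models and drift: the methods behind hilldrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity, null models and drift: the methods behind hilldrift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hilldrift)
```

## The problem

Replicated bioreactor experiments follow the microbial community of two (or
more) reactors seeded from a common inoculum through a series of
disturbances — here, the periodic removal of half of the settled biomass of
a granular-sludge reactor. The analysis has to separate three things that
all look like "the community changed": sampling noise at finite read depth,
neutral turnover (ecological drift plus the random loss of whole granules),
and deterministic selection imposed by the reactor environment. `hilldrift`
provides the standard toolkit for that separation — Hill-number diversity at
several orders, bounded dissimilarity indices, Raup–Crick and nearest-taxon
null models, time-decay regression and PERMANOVA — plus a mechanistic
simulator that generates data *known* to be neutral or *known* to be
selected, so every statistic can be calibrated end to end.

## Hill-number diversity

For relative abundances $p_i$ the Hill number of order $q$ is
$$^qTD = \Big(\sum_{i\,:\,p_i>0} p_i^q\Big)^{1/(1-q)},\qquad
^1TD = \exp\Big(-\sum_i p_i \ln p_i\Big),$$
the *effective number of ASVs*: $q=0$ counts every ASV (richness), $q=1$
weights by abundance ("common" ASVs), $q=2$ emphasises dominants
("abundant" ASVs, the inverse Simpson index). The order-1 case is always
computed by its analytic limit, never by numerically approaching $q=1$.

Phylogenetic structure enters through pairwise patristic distances $d_{ij}$
(path sums of branch lengths, `patristic_distances()`). With Rao's
quadratic entropy $Q=\sum_{ij} d_{ij} p_i p_j$, the attribute diversity
$$^qD(Q) = \Big(\sum_{ij} \frac{d_{ij}}{Q} (p_i p_j)^q\Big)^{1/(2(1-q))}$$
is the effective number of equally-distinct ASVs, and
$$^qPD = \big(^qD(Q)\big)^2 \cdot Q$$
is the **total effective phylogenetic distance** between the ASVs of the
sample. For $S$ equally abundant, mutually equidistant ASVs at distance $d$
this equals $d\,S(S-1)$ at every order — the total distance over ordered
ASV pairs — which is the closed form the unit tests pin down. A single-ASV
sample has $Q=0$ and $^qPD$ is defined as 0.

By default the distances come from the input tree; a precomputed sequence
dissimilarity matrix can be supplied instead wherever a `distances` argument
is accepted (the choice is the user's; tree-derived distances are the
default because the tree is an explicit input of the pipeline).

## Pairwise dissimilarity

Beta-diversity of a sample pair is the multiplicative ratio
$\beta = \gamma/\alpha$ computed on the evenly pooled pair (each sample
contributes weight 1/2 — sensible because samples are first rarefied to
equal depth, making read weights and equal weights coincide). Taxonomic
$\beta$ lies in $[1, 2]$; the distance-based analogue uses the ratio of the
squared attribute diversities, $\beta_{FD} = (^qD_\gamma / {^qD_\alpha})^2
\in [1, 4]$, because the functional measure effectively counts ASV *pairs*.
Both are mapped onto $[0,1]$ by overlap transforms; with $N$ assemblages and
$M = N$ (taxonomic) or $M = N^2$ (distance-based),
$$\text{local: } 1 - C_{qN} = \frac{1-\beta^{1-q}}{1-M^{1-q}},\qquad
\text{regional: } 1 - U_{qN} = \frac{1-\beta^{q-1}}{1-M^{q-1}},$$
with the shared limit $\ln\beta/\ln M$ at $q=1$. Identical samples score 0
and samples sharing no ASVs score 1, at every order and for both kinds —
this is verified exactly in the tests. The **local** (Sørensen-type)
variant is the default, matching the common default of implementations of
this framework; the regional variant is a switch. At $q=0$ the local
taxonomic index reduces to the classical Sørensen dissimilarity.

Two conventions cover degenerate cases: ASVs absent from both samples are
dropped before the computation (they carry no information and avoid $0^0$
choices), and a pooled pair with $Q=0$ — two copies of the same single ASV —
has phylogenetic dissimilarity 0.

One property worth knowing: when all between-ASV distances are equal the
distance-based dissimilarity does *not* reduce to the taxonomic one (the
zero within-ASV diagonal prevents the collapse); it keeps the same 0/1
endpoints and ranks pairs the same way, but sits below the taxonomic value
at $q=0$ and above it at $q=2$. The test suite asserts the true behaviour
(rank agreement and shared endpoints) together with exact equality against
a literal brute-force evaluation of the defining sums.

## Raup–Crick null model (qRC)

For each sample pair the observed taxonomic dissimilarity is compared with
dissimilarities of `n_randomizations` (default 999) randomly assembled
sample pairs. Each null sample preserves the observed sample's richness and
read total; ASV identities are drawn without replacement from the regional
pool with probability proportional to **occurrence frequency**, each chosen
ASV receives one read, and the remaining reads are allocated by a
multinomial draw proportional to **regional mean relative abundance**
(`weighting = "frequency_x_abundance"`, the default; `"frequency"` and
`"abundance"` use one weight for both steps). The standardized effect size
$$SES = \frac{d_{obs} - \overline{d_{null}}}{sd(d_{null})}$$
is significant when $|SES| > 2$: below $-2$ the pair shares more taxa than
chance, above $+2$ fewer, and in between the turnover is indistinguishable
from stochastic assembly.

The regional pool defaults to *all* samples of the table (both reactors and
the inoculum) because between-reactor comparisons need a common pool; a
restricted pool can be passed explicitly.

Two practical properties of this null model matter for interpretation, and
the simulator makes both visible:

* **The SES floor is set by the null's coefficient of variation.** A pair
  can only reach $SES < -2$ if $\overline{d_{null}} > 2\,sd(d_{null})$.
  With small regional pools (tens of ASVs) or samples whose richness nearly
  exhausts the pool, the null support barely varies, the null distribution
  is skewed, and no pair — not even a duplicated sample — can score below
  $-2$ at $q \ge 1$. Concentration requires many ASVs whose inclusion
  varies between randomizations; the calibration fixtures therefore use
  300-ASV pools with sample richness well below pool size.
* **Abundance-weighted read allocation partially absorbs global
  convergence.** When every sample in the pool is dominated by the same
  ASVs (e.g. after strong selection has swept both reactors), the null
  samples inherit those dominances from the pool means, so null pairs
  resemble observed pairs and the deterministic signal in $SES$ is
  conservative. The `"frequency"` weighting spreads reads evenly and is
  *not* a fix: it inflates $\overline{d_{null}}$ for every pair and pushes
  even neutral data below $-2$, destroying the contrast between regimes.

## βMNTD and βNTI

The abundance-weighted beta mean nearest-taxon distance is
$$\beta MNTD = \tfrac12\Big[\sum_i p_i^A \min_{j \in B} d_{ij}
 + \sum_j p_j^B \min_{i \in A} d_{ij}\Big],$$
with ASVs present in both communities contributing distance 0 (self-matches
allowed, the standard nearest-taxon convention). βNTI is the standardized
effect size of βMNTD under random permutations of ASV labels across the
tips of the regional-pool phylogeny — the same permutation applied to both
samples, and only across tips actually present in the pool, so the distance
structure of unused tips cannot leak in. Negative βNTI means the two
communities are more phylogenetically close than chance; $|βNTI| < 2$ is
read as stochastic phylogenetic turnover.

Because tip shuffling preserves which ASVs are shared, a pair of samples
with identical support has observed and null βMNTD all exactly 0. Such
pairs (and any null distribution with zero spread, e.g. on a star-like
distance matrix) are flagged `degenerate`, with `ses = NA` and
`significant = FALSE` — never as ±infinity. Downstream summaries count
degenerate pairs as indistinguishable from the null expectation, which is
what they are.

## Succession, time decay and PERMANOVA

`build_series()` derives the three canonical comparison series from the
metadata: successive pairs (adjacent sampling days within a reactor),
between-reactor pairs (equal days across reactors) and versus-inoculum
pairs. It is a pure function of the metadata.

The time-decay rate converts dissimilarities to similarities $s = 1 - d$
and fits $\ln s$ against the day difference by ordinary least squares over
*all* within-reactor pairs (not only successive ones), optionally windowed
to one disturbance period via `day_range`. Natural logarithm is used, so
the slope is a per-day e-folding rate; any other base rescales the slope by
a constant. Pairs with $s \le 0$ cannot be log-transformed and are dropped
and counted (`n_dropped`) rather than floored at an epsilon, which would
bias the slope. Fits with exactly zero residuals are reported with p-value
0 (an exact trend) or 1 (an exact constant).

PERMANOVA is delegated to `vegan::adonis2` (Gower-centred partitioning of
squared dissimilarities, permutation p-value $(\#\{F_{perm} \ge F_{obs}\} +
1)/(n_{perm}+1)$) behind a thin wrapper that validates the matrix, aligns
group labels, seeds the permutations and returns a tidy one-row record;
`pairwise_permanova()` runs all group pairs with raw p-values by default
and optional Benjamini–Hochberg adjustment.

## The simulator

`simulate_study()` generates data with the statistical structure the
analysis assumes, not a mechanistic reactor model:

* An inoculum of `n_granules` granules; each granule is founded by
  `founders_per_granule` individuals drawn from a lognormal rank-abundance
  pool and grown to `individuals_per_granule`. Small founder counts give
  the large within-granule variability that makes granule loss an
  effective driver of community jumps.
* The granules are split at random between two reactors (R2, R3), each of
  which regrows to capacity and then evolves one Wright–Fisher generation
  per day: every granule's next composition is a multinomial draw with
  probabilities $\propto$ counts $\times\, e^{s_i}$. All $s_i = 0$ is pure
  drift; `tree_selection_coefficients()` draws coefficients from a
  Brownian walk down the tree so selection carries a phylogenetic signal.
* On each disturbance day (default 0/50/100) a disturbance removes
  `removal_fraction` (default 0.5) of the biomass: whole uniformly-random
  granules (`"granule"` mode, the default) or a hypergeometric thinning of
  every granule (`"uniform"` mode). The reactor regrows to carrying
  capacity in one composite step — surviving granules are duplicated with
  multinomial resampling and regrown — a deliberate simplification that
  preserves the compositional consequences of the disturbance without
  modelling day-scale biomass accumulation.
* On each sampling day (default 27 days spread over 149) a multinomial
  read sample of `read_depth` (default 70492) is drawn from the pooled
  reactor composition, emulating homogenized biomass sampling. New
  granules are never nucleated; granulation dynamics, substrate gradients
  and taxon identities are out of scope.

Default sizes: 200 ASVs with lognormal `abundance_sdlog = 3`, chosen so the
top ASV typically holds tens of percent of the community (median ≈ 0.4,
90% range ≈ 0.16–0.83) over a long tail — the dominance structure typical
of acetate-fed granular sludge; 200 granules of 2000 individuals, an
*effective* population far below a real reactor's census size, which makes
drift faster than reality — conservative in the sense that neutral
calibration passes despite exaggerated drift. The abundance ranks are
assigned to tree tips *unsorted*: tip labels of random trees are
topologically ordered, and sorting abundances onto them would correlate
abundance with phylogeny and bias βNTI.

Seeding is hierarchical: every stochastic operation derives a child seed
from the master seed and a tag (operation name, sample id or pair), so
results are independent of execution order and a fixed master seed
reproduces the full table–metadata–tree triple bit for bit.

## Calibration: what the tests show, and on what problem sizes

The test suite calibrates the pipeline on three simulated regimes (sizes
are the package's choices, stated here so the numbers can be read):

* **Neutral study** — 100 ASVs, default granule structure, read depth 5000,
  disturbances at days 0/50/100, 99 randomizations: ≥ 90% of successive and
  between-reactor comparisons fall in $|{}^1RC| < 2$ and $|βNTI| < 2$
  (observed: 97–100% across seeds), while PERMANOVA still separates the
  reactors and the time-decay slope is negative with $p < 0.05$ — drift
  changes communities without making their assembly deterministic. $^0RC$
  sits below $-2$ for most pairs, as richness-level overlap between samples
  from a closed system always exceeds random assembly.
* **Duplicated sample** in a diverse 20-sample, 300-ASV pool at depth 4000:
  $^qRC < -2$ for $q = 0, 1, 2$ in ≥ 95 of 100 seeded repeats with 999
  randomizations (typical SES ≈ −17/−10/−4).
* **Selection regime** — 300 ASVs, even inoculum (`abundance_sdlog = 1`),
  2000 granules, strong tree-correlated selection (sd 0.05 per generation)
  applied identically in both reactors from different random splits, depth
  20000: the majority of matched-day between-reactor $^1RC$ fall below
  $-2$. The even, larger pool keeps selection's losers in the regional pool
  (concentrating the null), and the larger granule count keeps drift below
  the deterministic signal; the earliest days stay above $-2$ because the
  random inoculum split dominates before selection has converged the
  reactors. A neutral twin at identical sizes yields no pair below $-2$.

These simulations emulate the *statistical* regime of a disturbed-reactor
study — dominance structure, granule-clustered biomass loss, common-origin
replicates, finite read depth. They do not emulate real amplicon error,
compositional biases of PCR, time-varying environments, immigration, or
pool sizes of thousands of ASVs; passing calibration here shows the
machinery is sound at these scales, not that any particular real dataset is
neutral.

## Numerical choices and limitations

* Rarefaction is a true without-replacement (multivariate hypergeometric)
  subsample; samples below the target depth are dropped with a warning, and
  each sample's draw is seeded independently of sample order. Default depth
  70492.
* Continuity of $^qTD$ at $q = 1$ is tested at $q = 1 \pm 10^{-5}$; a wider
  probe measures the slope of the diversity profile rather than the limit
  implementation.
* Negative branch lengths (a known artifact of some tree builders) are
  clamped to zero with a warning by default; strict rejection is a switch.
* Dissimilarities are clamped to the theoretical $[0,1]$/$[1,M]$ ranges to
  absorb floating-point rounding at the endpoints.
* The inoculum's replicate DNA extractions, when present, are treated like
  any other sample by rarefaction and pooling; nothing in the pipeline
  gives the inoculum special weight beyond its role in the versus-inoculum
  series.
* `null_sd = 0` (degenerate nulls) yields `ses = NA`, never ±Inf; with few
  randomizations SES estimates are themselves noisy, and 999 randomizations
  are recommended for final analyses (the reduced profile uses 99 for
  speed).
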