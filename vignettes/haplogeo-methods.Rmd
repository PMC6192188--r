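---
title: "HaploGeo: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HaploGeo: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HaploGeo)
```

HaploGeo implements the analysis battery of classic single-locus
phylogeographic surveys: haplotype collapsing, diversity and
differentiation statistics with permutation inference, spatial AMOVA,
isolation by distance, haplotype networks, and demographic-expansion
inference. This vignette records the statistical models, the
conventions and tunable parameters, and the design decisions that were
genuinely open, so that results are interpretable and reproducible.

## Haplotype definition and distances

Sequences must arrive pre-aligned (one locus per run; concatenated
plastid regions are treated as a single sequence because the plastid
genome is effectively one linkage unit). Under the default gap policy
(`exclude_columns`) every alignment column containing `-`, `N` or an
IUPAC ambiguity in *any* record is removed before anything else. Two
sequences share a haplotype iff they are identical at all retained
columns; haplotypes are numbered in order of first appearance. The
inter-haplotype distance $d_{ij}$ is the substitution count between
representatives over retained columns, which is a Hamming metric and
therefore always yields a connected minimum spanning network. This
matches the substitutions-only haplotype definitions of DnaSP-style
workflows, where ITS alignments with small indels still yield
ribotypes "determined by substitutions". The alternative
`pairwise_complete` policy retains all columns and ignores, per pair,
only positions where either sequence is unresolved; distances are then
not guaranteed metric, and it is off by default for that reason.

Population maps accept decimal degrees or degree–minute–second
strings. Printed field tables occasionally carry seconds $\ge 60$;
these are converted arithmetically with a warning rather than
rejected, because rejecting them would make published tables
unusable as-is.

## Diversity

Unbiased gene diversity and its sampling standard deviation follow
Nei (1987):
$$\hat h = \frac{n}{n-1}\Bigl(1 - \sum_i p_i^2\Bigr),$$
with the eq. 8.12 variance. Nucleotide diversity is the unbiased mean
pairwise difference per site,
$\hat\pi = \frac{n}{n-1}\sum_{i\ne j} p_i p_j d_{ij} / L$, with the
no-recombination variance approximation (Nei 1987, eq. 10.7) for its
SD. $L$ is the full alignment length in bp, so $\pi$ is comparable to
published per-site values.

## Differentiation (Pons–Petit $G_{ST}$ / $N_{ST}$)

$H_S$ is the *unweighted* mean over populations of the per-population
unbiased gene diversity; weighting by sample size is available but off
by default because the unweighted form is what the classic PERMUT
workflow reports. For $H_T$ two estimators are computed and both are
reported:

- `nei_chesser` (default): $H_T = 1 - \sum_i \bar p_i^2 + H_S/(\tilde n P)$,
  with $\bar p_i$ the unweighted mean haplotype frequency across the
  $P$ populations and $\tilde n$ the harmonic mean sample size;
- `uncorrected`: $1 - \sum_i \bar p_i^2$.

The ordered (distance-weighted) analogues replace identity/
non-identity with $d_{ij}$: $v_k = \frac{n_k}{n_k-1}\sum_{ij}
p_{ki}p_{kj}d_{ij}$, $v_S = \text{mean}_k\, v_k$, and $v_T$ built with
the same correction structure as $H_T$. Using the same functional form
on both sides guarantees the identity $N_{ST} = G_{ST}$ *exactly*
(to machine precision) whenever all off-diagonal $d_{ij}$ are equal,
which the test suite asserts; $N_{ST} > G_{ST}$ then isolates the
contribution of haplotype relatedness to spatial structure.

The permutation test relabels haplotype identities on the distance
matrix (a joint row/column permutation of $d_{ij}$), which holds the
frequency table — and hence $G_{ST}$ — fixed while destroying any
association between relatedness and location. The one-sided p-value
uses the add-one convention $p = (1 + \#\{\text{perm} \ge
\text{obs}\})/(B+1)$, so $p \in [1/(B+1), 1]$ and is never zero.
$B = 1000$ by default; the seed is an explicit argument everywhere and
every stochastic operation is bit-reproducible given it. Note that
with $k$ haplotypes the null has at most $k!$ distinct relabellings,
so with few haplotypes the attainable p-values are coarse; this is a
property of the test, not of the implementation.

## AMOVA and SAMOVA

AMOVA decomposes squared molecular distances
($\delta^2_{xy} = d_{ij}$ for individuals carrying haplotypes $i,j$)
among groups, among populations within groups, and within populations,
using the pairwise-distance identity
$SS(\text{set}) = \sum_{x<y}\delta^2_{xy}/|\text{set}|$ and the
standard nested moment equations with unequal-sample-size
coefficients. Φ-statistics are tested by the Arlequin permutation
schemes: individuals among populations for $F_{ST}$, individuals
among populations within groups for $F_{SC}$, whole populations among
groups for $F_{CT}$; $B = 1000$ by default with the add-one
convention. Degenerate cases are flagged rather than silently
dropped: zero total variance leaves Φ undefined, and a partition of
all-singleton groups leaves $F_{SC}$ undefined (then
$F_{CT} = F_{ST}$ of the ungrouped design, which the tests assert).
The implementation is validated against an independent brute-force
oracle that sums individual-level distances explicitly.

SAMOVA searches partitions of populations into $K$ groups maximizing
$F_{CT}$. The original algorithm seeds groups from a Delaunay
triangulation of population coordinates; we approximate the same
intent with nearest-seed geographic seeding ($K$ random seed
populations, every other population joining the nearest seed by
great-circle distance). Contiguity is encouraged by initialization
but not enforced during the search. The search is simulated
annealing over single-population moves (a donor group must stay
non-empty), Metropolis acceptance on $\Delta F_{CT}$, geometric
cooling (factor 0.95 per 100 proposals), and an initial temperature
calibrated from the median early $|\Delta F_{CT}|$ so that roughly
half of early proposals accept. Defaults are 100 restarts of 10,000
proposals — deliberately generous for up to a few dozen populations;
the tests use smaller but sufficient budgets (4–8 restarts of
500–1500 proposals), at which the annealer recovers the exhaustive
optimum on all 6-population bipartition instances. `fctPlateau`
selects the smallest $K$ whose $F_{CT}$ is within a relative
tolerance (default 1%) of the maximum attained at that or any larger
$K$; a strictly increasing trajectory returns the largest $K$ with a
warning.

Great-circle distances use the haversine formula with Earth radius
6371.0 km. The Mantel test correlates off-diagonal genetic and
geographic distances (Pearson), with one-sided significance from
simultaneous row/column permutations (delegated to `vegan::mantel`).
The default genetic distance is linearized pairwise
$\Phi_{ST}/(1-\Phi_{ST})$; plain $\Phi_{ST}$ is available and is the
sensible choice when fixed population pairs push $\Phi_{ST}$ to 1
(the linearized value is then infinite). For a pair of populations
both monomorphic for the same haplotype the pairwise $\Phi_{ST}$ is
0/0; we define it as 0 (no molecular variance, no differentiation).

## Haplotype network

A Kruskal MST with deterministic tie-breaking (weight, then
lexicographic haplotype ids), augmented with every non-tree edge whose
weight ties the maximum edge weight on the tree path between its
endpoints. This is the $\varepsilon = 0$ minimum spanning network; it
is adequate for the shallow divergences typical of intraspecific data
(here $\le 10$ observed haplotypes). Median-joining's inferred median
(Steiner) nodes are deliberately not implemented: they require
sequence-level median computation and an $\varepsilon$ parameter with
no principled default at this scale.

## Demography

The mismatch distribution pools all (or a clade's) individuals and
tabulates pairwise difference counts. Under the stepwise
("sudden") expansion model a population of mutation-scaled size
$\theta_0$ jumps to $\theta_1$ at $\tau$ mutational units before the
present; with $\hat F_i(\theta) = \theta^i/(1+\theta)^{i+1}$ and
$a_m = 1 + 1/\theta_m$, the class probabilities are
$$F_i = \hat F_i(\theta_1)\,\bigl[1 - P(\text{Pois}(a_1\tau)\le i)\bigr]
      + \hat F_i(\theta_0)\, e^{-a_1\tau} \sum_{j=0}^{i}
        \frac{(a_0\tau)^j}{j!},$$
an exact closed form of the piecewise-exponential coalescence mixture
(the tests verify it against numerical integration to $10^{-9}$ and
that it sums to one). $\theta_0 \to 0$ is handled in log space.
Parameters minimize $SSD = \sum_i (\text{obs}_i - F_i)^2$ by a coarse
grid refined with `nlminb` plus a Nelder–Mead polish; bounds are
$\tau \in [0, 2\cdot\text{max class}]$, $\theta_0 \ge 0$, and
$\theta_1 \in [0, 10^6]$ — beyond $10^6$ the expected histogram is
flat in $\theta_1$ and the parameter is unidentifiable. $\theta_1$ is
estimated rather than fixed at infinity; `profileTheta1Inf = TRUE`
gives the original two-parameter Rogers–Harpending form. Only the
sudden (stepwise) model is implemented; the spatial-expansion
likelihood is a different model and out of scope.

Goodness of fit uses a parametric bootstrap: $B$ coalescent samples of
the same size are simulated under the fitted parameters, each is
refitted, and $SSD$ and Harpending's raggedness get add-one p-values
$P(\text{boot} \ge \text{obs})$. Raggedness is
$r = \sum_{i=1}^{d+1} (F_i - F_{i-1})^2$ over classes $0..d$ with
$F_{d+1} = 0$.

Tajima's $D$ uses the 1989 coefficients, with a two-sided p-value from
the beta-distribution approximation of its bounded null; the
approximation is known to be slightly conservative (the calibration
test brackets the empirical 5% rejection rate at 2–8% over neutral
coalescent replicates). Fu's $F_s = \ln(S'/(1-S'))$ with
$S' = P(K \ge k_0 \mid \hat\theta_\pi, n)$ computed from the Ewens
sampling distribution via a log-space recursion over unsigned Stirling
numbers of the first kind (stable to $n$ in the hundreds; validated
against exactly tabulated Stirling numbers at small $n$). Its p-value,
when requested, comes from coalescent simulation at the observed
$\hat\theta_\pi$; following Fu (1997), the 5% significance level
corresponds to $p < 0.02$, and the raw p is always reported.

Expansion time is $t = \tau/(2u)$ with $u = \mu k g$
(substitutions/locus/generation; $\mu$ in substitutions/site/year,
$k$ the aligned length in bp, $g$ the generation time in years). The
formula yields generations; both generations and years are reported
because reading the generations figure as years silently inflates the
date by a factor $g$ — an easy mistake when comparing published
expansion times. A strict-clock divergence estimate
$T = d_{net}/(2\mu)$ with
$d_{net} = \bar d_{between} - (\bar d_{within,1}+\bar d_{within,2})/2$
is provided as a closed-form cross-check on Bayesian dating; it
assumes rate constancy and no ancestral polymorphism beyond the
within-lineage correction.

## The synthetic-data generator

`simulateDataset` and `simulateSuddenExpansion` implement a Kingman
coalescent with island-model migration, piecewise-constant size and
infinite-sites mutation. Scaling: $\theta$ is the expected
within-deme pairwise difference; time is measured so that a size
change $\tau$ units before the present corresponds exactly to the
$\tau$ of the mismatch model, making the simulator usable as the
parametric bootstrap engine without unit conversion. Calibration
tests check the closed forms $E[S] = \theta a_1$ (Watterson), mean
Tajima's $D \approx 0$ under neutrality, and that differentiation
decreases with migration.

The generator emulates the statistical structure the analyses assume —
neutral, non-recombining, infinite-sites variation in discrete demes —
and deliberately omits features of real data: recombination (relevant
for nuclear ITS), concerted evolution, homoplasy, selection,
sequencing error, and realistic spatial geometry (coordinates are laid
on a grid). Passing tests therefore demonstrate correctness of the
estimators under their own assumptions, not robustness to violations
of them.

`makePaperFixture` reproduces a published 16-population,
253-individual survey: the per-population haplotype counts,
coordinates and elevations are the published ones, and the
constructed haplotype sequences realize exactly 7 substitution sites
for the 6 chlorotypes (1531 bp) and 4 substitution sites plus two
indel columns for the 6 ribotypes (604–606 bp within 606 columns),
with a topology satisfying the published clade statements (H3–H6
adjacent; R2 most divergent). The true haplotype sequences are
unpublished, so every distance-dependent statistic on the fixture
(nucleotide diversity, $N_{ST}$, AMOVA percentages, $\tau$) is
fixture-conditional: count-only statistics are reproduced exactly,
distance-dependent ones only qualitatively.

## Problem sizes and numerical conventions

The test suite runs in about a minute on one core with the following
choices, stated here as the package's own calibration-scale
conventions: parameter-recovery for $\tau$ uses 51 replicates of
$n = 200$ at $\tau \in \{2, 5, 10\}$ (median relative error $\le
25\%$); neutrality-test calibration uses 500 (Tajima) and 200 (Fs)
neutral replicates; permutation-null calibration uses 400 datasets at
$B = 99$; brute-force AMOVA oracles run on instances of $\le 20$
individuals; SAMOVA exhaustive checks enumerate all 31 bipartitions of
6 populations. All add-one p-values, all seeds explicit.

## Known limitations

- $H_T$ estimation from a haplotype count table is estimator-variant
  sensitive in the second or third decimal; both variants are
  reported and neither is privileged when comparing to published
  values computed with legacy software whose exact variant is
  undocumented.
- The $N_{ST}$ permutation null is coarse for few haplotypes (at most
  $k!$ relabellings).
- SAMOVA does not enforce group contiguity during search; with weak
  structure the best-$F_{CT}$ partition need not be geographically
  contiguous.
- The beta approximation for Tajima's $D$ is approximate in the tails;
  simulation p-values are available where that matters.
- Mismatch-model fitting is by SSD, not likelihood; with
  $\theta_1$ near the boundary the fitted $\theta_1$ is reported at
  its cap rather than as infinity.
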