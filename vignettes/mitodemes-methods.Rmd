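---
title: "Models and methods in mitodemes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mitodemes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mitodemes)
```

`mitodemes` reconstructs regional maternal demographic history from serially
sampled complete mitochondrial genomes: ancient individuals excavated from
dated archaeological contexts alongside a modern sample. This vignette is
the package's own account of its models, the choices behind them, and what
the shipped experiments do and do not demonstrate.

## The coalescent model

Everything is haploid. The simulator realises the structured coalescent
backward in time: within a deme holding $k$ lineages of haploid effective
size $N_e$, a pair coalesces at rate $k(k-1)/(2N_e)$ per generation, so two
lineages in a constant deme find their ancestor after $N_e$ generations on
average. Single lineages migrate from deme $i$ to deme $j$ at rate $M_{ij}$,
the per-generation probability (backward in time) that a lineage moves; a
migration matrix applies over a stated epoch and is zero outside it.
Demographic events are processed at fixed times: size changes, and "move"
events that transfer every lineage of one deme into another at once. Moves
encode both ordinary backward merges (population splits, read forward) and
population replacement: a deme founded at time $t$ by incomers has all its
lineages transferred to the source deme at $t$, so the local lineage that
preceded it never feeds it. Tips enter the genealogy at their sampling
times. The continuous-time exponential-rates approximation of the discrete
model is used throughout; it is accurate whenever $N_e \gg k$, which holds
across the parameter ranges the package ships.

Two robustness details matter in practice. First, a sampled radiocarbon age
is drawn from a normal prior (mean, sd from the 95% range) truncated at
zero, and can occasionally exceed the founding time of the deme the sample
is assigned to; the simulator then places the lineage in the deme's source,
which is where its ancestor resided at that time. Second, simulation is
guarded by a time cap and an explicit non-coalescence error for structurally
disconnected demes.

Mutations are overlaid on the realised genealogy as a finite-sites Poisson
process: each branch of length $b$ receives $\mathrm{Poisson}(b\,\mu L)$
mutations placed uniformly over $L$ sites, with repeat hits allowed and the
replacement base drawn with a transition/transversion weight (default 1).
The default per-site rate, $\mu = 25/(3624 \times 16569)$ per generation,
is the whole-molecule substitution clock of one mutation per 3,624 years at
a 25-year generation time. Because all summary statistics scale linearly
with $L$ under low per-site diversity, simulation studies use a reduced
locus of $L = 2000$ sites at the same per-site rate; the full 16,569 is
available by passing `mutationModel()`.

## The model library

The eleven named models describe one ancient-plus-modern design with eleven
sampling groups (sizes 8, 8, 4, 3, 14, 55, 3, 3, 5, 6, 236 from the Late
Mesolithic to the present). Model A is complete continuity: a single deme
through time. Models B–E separate the Phoenician/Punic, Greek and
Islamic-period groups into their own demes, split from a deep ancestral deme
(default 50,000 years); B keeps the local lineage continuous while C, D and
E insert a replacement at the Mesolithic/Neolithic, pre-Bronze/Bronze and
pre-Iron/Iron boundaries respectively, with event times fixed at the group
age boundaries. Models F–I add continuous two-way migration between the
Sicilian, Phoenician/Punic and Greek demes during the Iron Age epoch
(default 3,000–2,200 yr B.P.) and between the Sicilian and Islamic demes
during the Medieval epoch (1,400–458 yr B.P.); G is C plus migration. Gpan
and Gst restructure the modern sample into nine geographic demes that merge
into the main deme a default 1,500 years back: Gpan exchanges migrants
between all nine at one rate, Gst partitions them into two isolated blocks.
The two block memberships are {Caltanissetta-Enna, Catania-Siracusa, Gela,
Messina, Ragusa} and {Palermo city, Palermo outer, Trapani, Agrigento}; the
package labels them east and west by geography, and nothing downstream
depends on the labels.

Shipped priors are deliberately wide and simple: log-uniform haploid
$N_e \in [10^2, 10^5]$ per deme, uniform migration rates in $[0, 0.01]$
(the panmixia-scale geogroup exchange uses $[0.005, 0.05]$), and fixed event
times. All priors are overridable per model through
`modelLibrary(name, config = list(priors = ...))`, and
`fixedParameterTemplate()` collapses them to point masses when a known
generating history is wanted.

## Summary statistics and their conventions

Per population: the haplotype count $K$, the unbiased gene diversity
$H = \frac{n}{n-1}(1 - \sum_i p_i^2)$ computed on collapsed haplotypes, the
number of segregating sites $S$ (columns with at least two distinct
non-missing residues), and Tajima's $D$ with the standard constants. Per
pair: Hudson-type sequence $F_{ST} = 1 - H_w/H_b$ ($H_w$ = average of the
two within-population mean pairwise differences, $H_b$ = mean
between-population difference) and $H_b$ itself as Pi. "H" here is
haplotype-level gene diversity, not per-site heterozygosity — the natural
reading for non-recombining haploid sequences; a per-site variant can be
obtained by dividing by the number of compared columns.

Missing-data conventions are chosen for transitivity and fixed geometry:
distances use pairwise-complete columns; haplotype collapsing drops columns
with an N anywhere in the population (complete case), so haplotype identity
is transitive; indel columns are dropped alignment-wide by the default mask
rather than per pair, for the same reason. One mask policy is applied
uniformly to all analyses rather than per analysis stage; it is exposed in
`maskPolicy()` if a user wants otherwise. Negative $F_{ST}$ estimates are
reported as computed, with flooring at zero available where a distance
matrix is required. Tajima's $D$ is undefined at $S = 0$; reference tables
impute 0 and append one indicator column per population so the ABC geometry
never varies. $F_{ST}$ between a population and itself is defined as
exactly zero by excluding same-sample pairs from the between-population
mean.

## ABC model choice

The reference table holds equal numbers of simulations per model (uniform
prior model probabilities), each summarised by the fixed-order statistic
vector. Linear discriminant axes — min(models − 1, statistics) of them —
are *appended* to the raw statistics rather than replacing them, and the
projection is stored so the observed vector is augmented identically; the
within-class covariance is ridge-regularised ($\varepsilon = 10^{-8}$ on
standardised inputs) so nearly collinear statistics never abort a run. The
classifier is a 500-tree random forest; the selected model takes the
majority of tree votes at the observed point. Its posterior probability is
estimated by a second, regression forest trained on the out-of-bag
misclassification indicator and evaluated at the observed point (one minus
the predicted local error rate) — the regression-forest estimator, not the
naive vote fraction. Out-of-bag prior error, the confusion matrix and
per-model classification errors are reported with every comparison.
Hierarchical comparisons run stages in order, with `"winner:k"` tokens
carrying earlier winners forward. Per-simulation seeds derive
deterministically from the master seed, model index and simulation index,
so tables are reproducible and rebuildable in a streaming fashion.

## Rho dating and recalibration

For a clade with a known root haplotype, $\rho$ is the mean number of
mutations from root to tip, and the genealogy-based standard error is
$\sigma^2 = \sum_b (n_b/n)^2 l_b$ over branches ($n_b$ descendant tips,
$l_b$ mutations), which reduces to $\rho/n$ on star trees. Conversion to
years is linear: age $= \rho/r$ with a default $r = 1/3624$ mutations per
year on the complete molecule; the 95% interval is
$(\rho \pm 1.96\sigma)/r$, floored at zero. The purifying-selection
polynomial correction sometimes applied to this clock is deliberately not
implemented; the rate is a plain constant.

Ancient tips bias classic $\rho$ downward: a tip sampled $a$ years ago is
missing the $a \cdot r$ mutations it would have accumulated to the present,
so a clade dated from ancient tips looks about $a$ years too young.
Recalibration adds that expected count to each ancient terminal branch
(real-valued; a stochastic Poisson mode exists for recovery experiments)
before $\rho$ and $\sigma$ are recomputed — $\sigma$ is recalibrated
consistently with $\rho$ rather than left on the original counts, and both
classic and recalibrated estimates are always reported side by side.
Recalibration is linear: scaling ages by $c$ is the same as scaling the
rate by $c$. Tip ages are point estimates; a sensitivity analysis can
resample them from their normal priors. The recovery experiment in the test
suite quantifies the behaviour: on simulated star clades with all tips at
age $a$, the classic estimator is biased by almost exactly $-a$ while the
recalibrated one is unbiased.

## Exploratory analyses

$F_{ST}$ matrices exclude groups below three individuals (the hard floor is
two, where the statistic stops existing). Classical multidimensional
scaling is Torgerson double-centering via `stats::cmdscale`; negative
eigenvalues are reported, and distances from non-Euclidean matrices (e.g.
raw $F_{ST}$) are floored at zero first. Correspondence analysis is the
SVD of the standardised residuals $(P - rc^\top)/\sqrt{rc^\top}$ with
row-principal normalisation (rows in principal coordinates, columns in
standard coordinates) — chosen so row profiles plot at their barycentric
positions; total inertia equals $\chi^2/n$ to numerical precision, which is
also the package's main correctness check. No continuity correction is
applied anywhere; for the sparse haplogroup tables this package produces,
the Monte-Carlo chi-square (margins fixed, $p = (1 + \#\{\chi^2_{perm} \ge
\chi^2_{obs}\})/(B+1)$) is the recommended default over the asymptotic
test.

## The synthetic study generator

`generateStudy()` emulates the shape of a real diachronic mitogenome study:
eleven groups with the design's sizes and group-level ages (means placed
inside the conventional period boundaries, e.g. the Mesolithic group at
9,500 yr B.P. with a ±700-year 95% range, the Neolithic at 7,000 ± 600),
nine modern geogroups of sizes 36, 21, 17, 21, 17, 65, 27, 12, 20, and
synthetic haplogroup labels. The generating demography defaults to the
replacement-plus-migration model G at one fixed, realistic parameter set
(`studyParameters()`): haploid female effective sizes of 2,000 (main deme),
1,000 (Mediterranean demes), 5,000 (deep ancestry) and 500 for the
hunter-gatherer deme — the small value produces the strong differentiation
of the oldest group that real ancient samples show — with migration rates
of 0.002 during contact epochs. These are generator conditions, chosen once
for realism, not tuned quantities.

Haplogroup labels are single-linkage clusters of haplotypes at a one-mutation
threshold; at the default locus length this yields label counts on the scale
of real macrohaplogroup tables (tens of labels over hundreds of samples,
most cells sparse), which is what the correspondence-analysis and chi-square
stages need to be exercised realistically. The labels are arbitrary cluster
ids: they carry no phylogenetic meaning, and nothing in the package treats
them as more than categories.

What the generator does not emulate: post-mortem ancient-DNA damage,
sequencing error, contamination, reference bias, within-group age spread
(one age draw per group), recombination (absent in mtDNA) and selection.
Tests passing on synthetic data therefore demonstrate the correctness and
calibration of the algorithms, not robustness to the artefacts of real
ancient-DNA data production.

## Numerical choices and experiment sizes

Test-suite experiment scales are package choices balancing precision
against runtime: the model-recovery experiment uses 1,000 simulations per
model with group sizes divided by four (floor two) at $L = 2000$ and twenty
replicate observed datasets; simulator calibration uses 5,000 constant-size
datasets ($N_e = 1000$, $n = 20$, $\theta = 20$); rho recovery uses 2,000
star clades; oracle equivalences use 1,000 randomised instances per
statistic at tolerance $10^{-9}$.

Degenerate inputs are defined rather than left to chance: empty masks are
the identity; an all-zero distance matrix embeds at the origin; ties in
model votes resolve to the first model name alphabetically; haplotype
tables sort by descending count then id; a monomorphic pair of populations
has $F_{ST} = 0$ (0/0 between *different* monomorphic populations is NA).

## Known limitations

Tajima's $D$ has a small negative neutral expectation at finite sample size
and diversity (roughly −0.05 at $n = 20$, $\theta = 20$), with finite-sites
saturation pushing the other way at high per-site diversity. The
calibration suite resolves this offset at 5,000-replicate precision; it is
a property of the statistic, reproduced by an independent coalescent
implementation, not a simulator artefact. Mean pairwise diversity, by
contrast, calibrates to $\theta = 2N_e\mu L$ within Monte-Carlo error.

The rho clock treats the mutation rate as exactly known; clock uncertainty
is not propagated into the confidence interval. A clock prior expressed as
a rate with mean $2.45\times10^{-5}$ (sd $3.5\times10^{-6}$) is stored for
reference in Bayesian workflows but is unit-ambiguous and unused by
default. Reference tables for many models at full locus length are
cluster-scale jobs; the package logs sizes and encourages the reduced-locus
route for interactive use.
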