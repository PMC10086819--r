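---
title: "Dating recombination cessation between gametologs: models and methods"
author: "trcest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating recombination cessation between gametologs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Once recombination between a Z and a W chromosome (or X and Y) stops in a
genomic region, the two copies of each gene in that region — the
*gametologs* — begin to diverge independently. The time of recombination
cessation, `t_RC`, is therefore the divergence time of the Z and W copies,
and groups of genes with a shared `t_RC` delimit *evolutionary strata*.
`trcest` implements four estimators of `t_RC` for a focal species embedded
in a dated reference species tree, an evaluation layer (clustering and
nonparametric tests), and a simulator that generates gametolog alignments
with known cessation times.

All four estimators express `t_RC` in the coordinate system of a rooted,
binary, time-calibrated reference species tree with a designated focal
species (`species_tree()`). The bundled
`sylvioidea_reference_tree()` encodes the 13-species songbird system
(six Sylvioidea species with the great reed warbler as focal, five further
Neognaths, an emu and a green anole); its node ages are literature-scale
approximations in Myr and are meant for simulation and examples, not as a
source of biological dates.

## Scenario enumeration and the discrete time scale

The internal nodes on the path from the focal tip to the root (the *focal
path*, `P` nodes) partition time before present into `P` intervals. A
cessation time inside interval `k` produces a characteristic gametolog
topology: the focal W lineage attaches to the focal path between path
nodes `k-1` and `k`. `enumerate_single_w()` builds one rooted topology per
interval, indexed from recent (1) to ancient (`P`); attachments above the
root are excluded by default, mirroring the usual practice of not
considering cessation older than the root calibration (for the bundled
system, the bird–reptile split). On the 13-species reference this yields
exactly 12 hypothetical topologies.

With W gametologs from several species (`enumerate_multi_w()`), scenario
`k` places the W tips of all W-bearing species that diverged from the
focal path below attachment point `k` in a clade mirroring the species
topology; species that diverged earlier keep their W sister to their own
Z. Where the published figure series for intermediate multi-W scenarios
was not available, this emission rule was fixed as the natural
generalization consistent with the documented endpoints (scenario 1 =
every W sister to its own Z; late scenarios = one W clade mirroring the
full species topology); the simulator implements the biologically
equivalent rule of cutting the W genealogy at `t_RC`, and the test suite
verifies that the two constructions agree on the reference system.

`scenario_to_time_interval()` converts index `k` to the half-open
normalized interval `(h[k-1], h[k]]/h_root`; the interval boundaries over
all scenarios form `S + 1` distinct values (13 on the reference), which is
the conversion scale between the discrete ELW index and the continuous
0–1 dating scale.

## Likelihood engine

All likelihood computations use Felsenstein's pruning algorithm under the
reversible families JC69, K80, HKY85, TN93 and GTR, with discrete-gamma
rate variation (Yang's equal-probability category means) and an optional
proportion of invariant sites (`subst_model()`). The rate matrix is scaled
to one expected substitution per site at equilibrium, and the gamma
category rates are rescaled by `1/(1 - pinv)` so that branch lengths stay
on the substitutions-per-site scale under the full mixture. Gaps and IUPAC
ambiguity codes are treated as missing data (partial likelihood 1 for
every compatible state), never as a fifth state. The kernels are written
in C++ (site-pattern compression, per-node underflow rescaling, a
column-lookup fast path for unambiguous tip states) because the dating
MCMC and the per-topology fits evaluate the likelihood 10^5–10^6 times;
the test suite checks the kernels against closed forms, an
exhaustive-state oracle on small trees (tolerance 1e-9) and an independent
likelihood implementation.

Branch lengths on a fixed topology are optimized coordinate-wise
(`optimize_branch_lengths()`): golden-section search on the log-length
scale per branch, with the rest of the tree folded into a per-edge
"above/below" partial cache, swept until the relative log-likelihood gain
falls below 1e-8. The derivative-free search was chosen for robustness;
the minimum branch length is 1e-9 to keep logarithms finite. `fit_model()`
alternates these sweeps with one-dimensional searches over the model's
free parameters (exchangeabilities and gamma shape on the log scale,
invariant proportion on [0, 0.95]); base frequencies are fixed at their
ambiguity-aware empirical values.

## The ELW estimator

For a gene alignment, each scenario topology is fitted (shared model,
per-topology branch lengths — the substitution model is estimated once on
the first topology unless `fit_shared_model = FALSE` supplies a default)
and the per-site log-likelihoods are stacked into an S x L matrix. The
expected likelihood weight of scenario `i` is the bootstrap average of the
softmax of resampled total log-likelihoods (RELL: sites are resampled,
parameters are not re-fitted). The estimate of `t_RC` is the argmax
index; uncertainty is the contiguous index hull of the greedy
95%-accumulated-weight set (ties broken toward the lower index), matching
the way accumulated-ELW ranges are reported on the conversion scale. The
RELL replicate count defaults to 100,000; tests and the worked examples
use far fewer replicates with fixed seeds, since the weights stabilise
quickly at the alignment lengths involved. The AU test is deliberately
out of scope: the ELW vector is the decision statistic.

## The dating estimator

`run_dating_mcmc()` is a deliberately small Bayesian node-dating sampler
on a *fixed* gametolog topology (reference topology plus the focal W
tip): Metropolis-within-Gibbs over internal node ages, the clock rate,
and the substitution parameters, with calibration priors (normal,
lognormal or uniform on the age scale) on every internal node except the
focal Z–W divergence node, whose marginal posterior is the `t_RC`
estimate. Design choices:

* **No tree prior beyond ordering.** With the topology fixed and every
  species node calibrated, a Yule/coalescent prior adds little;
  uncalibrated node ages are uniform subject to parent-older-than-child.
  An uncalibrated root receives a uniform prior on `(0, root_max]`.
* **Proposals.** Uniform slides within the parent/children age bracket
  (symmetric because the bracket does not depend on the node's own age),
  multiplier (scale) moves for the root, the clock rate, the model
  parameters and the relaxed-clock quantities; multiplier step sizes are
  adaptively tuned toward 20–50% acceptance during the pre-burn-in phase
  only, so the recorded chain is a fixed-kernel Markov chain.
* **Clocks.** `strict` (one rate, diffuse lognormal prior centred on a
  crude distance-based guess) or `ucln` (uncorrelated lognormal
  per-branch multipliers with mean 1 and an exponentially distributed
  spread). Recovery and coverage tests use the strict clock; the relaxed
  clock is exercised for correctness of bookkeeping.
* **Summaries.** `dating_result()` drops a tracer-style additional
  burn-in fraction (default 10% of the recorded samples — the
  pre-burn-in handling of the summarising tool in the original workflow
  is not documented, so it is a knob), then reports the posterior median,
  the 95% HPD (shortest window over order statistics) and the ESS
  (`n / (1 + 2 sum rho_k)`, autocorrelations summed to the first
  non-positive term). Normalized results divide each focal-age sample by
  the same iteration's root age.

Chain defaults are desk-scale (2e5 states, sampling every 100, 1e4
pre-burn-in); the production-scale settings of the original workflow
(2e8 states, sampling every 1e4) are reachable through `dating_config()`
but are not test defaults.

`reduce_outgroups()` prunes the dating problem to the `keep` outgroup
species closest to the focal tip, the setup used to study how outgroup
number affects precision. When a cessation time predates the pruned root,
the W tip attaches above the root of the pruned topology, and the Z–W
node is then bounded only by `root_max` — which is exactly why few-outgroup
datasets produce wide HPDs for old genes.

## The dS estimator

`ng86_ds()` implements the Nei–Gojobori (1986) counting estimator between
the focal Z and W coding sequences: synonymous/nonsynonymous site counts
per codon averaged over the two sequences, differences averaged over all
minimal substitution pathways (pathways through stop codons excluded
unless all are blocked; mutations to stops count as nonsynonymous), and
the Jukes–Cantor correction `d = -3/4 log(1 - 4p/3)`. A synonymous
proportion at or above 3/4 is reported as saturated with `dS = NA`.
Codons containing gaps or ambiguity codes are excluded entirely
(`extract_focal_pair()` drops such codon columns while preserving frame).
The counting estimator was chosen over a codon-model ML estimator because
it is self-contained and oracle-verifiable; the conclusions it supports
in the evaluation layer (cluster overlap between strata) are qualitative.

## The collapsed-ML-tree estimator

`ml_search()` is a lightweight ML tree search (neighbour-joining start,
NNI hill climbing with branch-length and model optimization — this is
where the package reuses phangorn's optimizer rather than re-deriving a
tree searcher). `bootstrap_supports()` resamples alignment columns,
re-runs the search per replicate, and scores each internal branch by the
fraction of replicate trees containing its bipartition (fixed replicate
count; no bootstopping heuristic). `collapse_low_support()` contracts
internal branches with support strictly below 0.70 (equal-to-threshold
branches are kept; a 0–100 support scale is auto-detected). The collapsed
tree's position range (`w_position_range()`) is the span of scenario
indices whose topology refines the collapsed tree — every gene-tree
bipartition must be a bipartition of the scenario tree on the shared
taxa. This formalizes what is otherwise a manual assignment; a collapsed
tree incompatible with every scenario (for example, W resolved inside a
non-focal clade) raises an error naming the conflicting bipartition
rather than guessing.

## Evaluation statistics

The two-strata evaluation assumes two clusters a priori and asks whether
an estimator's per-gene output separates them. Lloyd's K-means needs
coordinates, so the per-approach feature representations are: dS as a
scalar, collapsed-tree ranges as (lo, hi) pairs, ELW as the full
12-component weight vector (all clustered by restarted Lloyd,
`kmeans_lloyd()`), and dating posteriors as empirical distributions
compared by the 1-D second-order Wasserstein distance
(`wasserstein2_1d()`, exact via quantile functions, including unequal
sample sizes) and clustered by PAM (`kmedoids()`), since Euclidean
distance is not defined on distributions. Spearman correlations use
mid-ranks with the t approximation; the Kruskal–Wallis/paired-Wilcoxon
battery applies the exact signed-rank null for n <= 25 (without ties or
zero differences) and Bonferroni correction over each pairwise family.

## The simulator and what the tests do (and do not) show

`gametolog_tree()` constructs the gene tree implied by a cessation time:
Z genealogy identical to the species tree, W lineages following the
species tree until `t_RC` and splitting from their Z lineage exactly
then. There is no coalescent variation, no incomplete lineage sorting, no
gene conversion and no indel process — the same idealization underlying
the hypothetical-topology construction — so recovery results quantify
estimator behaviour under the model, not robustness to gene-tree
discordance. The default W-branch rate multiplier of 1.5 emulates the
faster, more idiosyncratic evolution of W-linked sequences that drives
the long-branch-attraction-like overestimation seen with single-W data;
setting it to 1 gives clean clock-like data for coverage tests.
`simulate_two_strata()` reproduces the 22 ancestral-part + 29 added-part
gene design: per-gene cessation times are drawn uniformly from an
old-stratum range (default 55–160 Myr on the bundled tree, predating the
W-clade crown) and a young range (default 1.5–21 Myr, inside the
Sylvioidea-analog clade), with the truth table recording times, scenario
indices and strata.

Problem sizes in the test suite were chosen to keep the whole suite at
desk scale while leaving each effect comfortably detectable: per-topology
ELW fits use alignments of 500–2000 sites with 500 RELL replicates;
dating coverage uses 20 strict-clock replicates of 2e5 states on a
four-species fixture, recorded every 20 states so that the Monte Carlo
error of the HPD endpoints stays well below the interval widths; the
outgroup comparison uses 20 genes at 2e4 states per run; the clustering evaluation uses the full 51-gene design at
1002 coding sites with tight, well-separated stratum ranges (old times
drawn within the oldest scenario interval, young within one young
interval), because the cluster-recovery claim is about separability of
the representations, not about boundary cases. The calibration fixtures
are normal priors centred on the true node ages with 5% standard
deviation — synthetic stand-ins for published calibrations, not published
values.

## Known limitations

* The reference tree must be binary and time-ultrametric; age ties
  produce zero-width conversion intervals (warned, not rejected).
* The dating sampler fixes the gametolog topology; the scenario must be
  supplied (for example, from the ELW argmax or a simulation truth),
  and the posterior for `t_RC` is accordingly conditional on it.
* The multi-W emission rule for species that diverged before cessation
  is the "W sister to own Z" idealization; lineages whose cessation
  history differs from the focal path's are out of scope.
* NG86 uses the standard genetic code only, without gamma-corrected
  distances or codon-usage diagnostics.
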