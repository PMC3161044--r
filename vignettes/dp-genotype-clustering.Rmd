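---
title: "Dirichlet-process clustering of multilocus genotypes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dirichlet-process clustering of multilocus genotypes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The inference problem

Given multilocus genotypes of `n` diploid (or haploid) individuals sampled
from an unknown number of randomly mating populations, we want the joint
posterior of (i) the number of populations `K` and (ii) the assignment of
individuals to populations. Populations are identified with unique allele
frequency vectors; admixture proportions are not modelled.

`dpmixpop` treats the partition `eta = {S_1, ..., S_K}` of the individuals
as the parameter of interest and places a Dirichlet process prior on it.
Marginalising the DP's random measure leaves the Chinese restaurant process
(CRP): when an individual is added to a configuration with clusters of
sizes `|S_j|`, it joins cluster `j` with prior probability proportional to
`|S_j|` and opens a new cluster with probability proportional to the
concentration parameter `alpha`. Multiplying these sequential weights gives
the partition prior

    P(eta) = alpha^K * Gamma(alpha) / Gamma(alpha + n) * prod_j Gamma(|S_j|),

which is exchangeable: it does not depend on the insertion order (a property
the test suite checks directly). The prior mean of `K` is
`sum_{i=1..n} alpha / (alpha + i - 1)`; `crp_alpha_for_k()` inverts this so
users can express the prior as "I expect about two populations". The
`rich-get-richer` character of the CRP is not a nuisance here — it is the
reason the method tolerates strongly unbalanced sample sizes, where fixed-K
samplers with a uniform 1/K assignment prior tend to equalise cluster sizes.

# Integrated genotype likelihood

Population allele frequencies get a symmetric `Dirichlet(lambda_l)` prior at
each locus `l` and are integrated out analytically. The predictive
probability of one genotype given the allele-copy counts `y_jlh` of cluster
`j` is, per locus,

    2^het * Gamma(y_jl. + J_l lambda_l) / Gamma(y_jl. + J_l lambda_l + m) *
    prod_h Gamma(y_jlh + lambda_l + c_h) / Gamma(y_jlh + lambda_l)

with `c_h` the individual's copies of allele `h`, `m = sum_h c_h`, and the
factor 2 for observed heterozygotes. The marginal likelihood of a whole
cluster is the chain of these predictives, again order-invariant. All
probability arithmetic is done in log space through `lgamma`; the compiled
sampler caches `lgamma(k + lambda_l)` and `lgamma(k + J_l lambda_l)` tables
per locus so that one predictive evaluation is a handful of lookups.

Missing data follow the standard Dirichlet-multinomial treatment: a missing
allele copy contributes nothing to any count or likelihood, and a fully
missing locus contributes a factor of one. `J_l` is the number of alleles
observed in the data set; with real data the unobserved allele space is
unknowable, and the simulators go through the same observed-allele recoding
as file input so simulated and real data are treated identically.

# The Markov chain

One iteration is either a **Gibbs scan** — every individual is removed from
the partition and reassigned to cluster `j` with probability proportional
to `|S_j| * P(x_i | counts of S_j)`, or to a new cluster proportional to
`alpha * P(x_i | empty)` — or a **sequentially-allocated merge-split (SAMS)
proposal**: two distinct individuals are drawn uniformly; if they share a
cluster, that cluster is split by allocating the remaining members one at a
time (in a uniformly random order) to the two seeds with probability
proportional to current size times predictive; if they sit in different
clusters, merging the two clusters is proposed. Proposals are accepted by
Metropolis-Hastings with the exact prior and integrated-likelihood ratios;
the reverse transition probability of a merge is obtained by replaying the
corresponding split with a freshly randomised order. Single-individual
Gibbs moves cannot cross the valley between "one merged cluster" and "two
separated clusters" on realistic data — in our island-model experiments a
pure Gibbs chain started from one cluster stays at `K = 1` for thousands of
scans, while the mixed schedule finds the true partition within tens of
iterations. The default schedule repeats four SAMS iterations followed by
one Gibbs scan; the ratio is configurable (`sams = 0` gives a pure Gibbs
sampler, used for baseline comparisons), and nearby ratios behave almost
identically.

Defaults follow the scale of the original analyses: 20,000 iterations, the
first half discarded as burn-in, sampling every 10 iterations. The chain is
initialised with all individuals in one cluster (a random CRP draw is
available); with the SAMS moves in the schedule the initial state is
forgotten within tens of iterations, and the single-cluster start is
deterministic. SAMS acceptance rates on realistic data are low (order
1e-2 to 1e-3) — that is expected for this move family, and the accepted
moves are precisely the large jumps Gibbs cannot make.

# The allele-frequency hyperparameter

`lambda` controls how uniform the prior thinks allele frequencies are:
large values favour near-equal frequencies, values near `1/J_l` favour
skewed ones. The practical consequence, reproduced by the acceptance
checks, is that a mismatched fixed `lambda` can be catastrophic: with
strongly skewed frequencies and `lambda = 3` the sampler collapses
everything into one cluster (normalised partition distance 0.5 from a
two-population truth), while `lambda = 1/J` recovers the structure almost
perfectly.

Instead of fixing it, `lambda` can be sampled by Metropolis-Hastings under
a flat `U(0, 10)` prior with a `N(lambda, delta^2)` random-walk proposal
(`delta = 0.02` by default), either as one shared value for all loci
(`"single"`) or one value per locus (`"unique"`). Because the prior is flat
and the proposal symmetric, the acceptance ratio is just the integrated
likelihood ratio, which at a single locus involves only that locus's
cluster counts. Proposals outside the support are rejected outright. We
update `lambda` once per iteration, after the partition move, and also
during burn-in (the chain has no adaptive components, so early updates are
harmless and speed up convergence of the hyperparameter).

# Summaries of the sampled partitions

* **Partition distance** — the minimum number of individuals whose removal
  makes two partitions identical; computed as `n` minus the maximal total
  cluster overlap over one-to-one cluster matchings, a linear sum
  assignment problem solved by a Hungarian algorithm written for this
  package (and verified against brute-force matching and minimal-removal
  searches in the tests). Distances are reported normalised by `n`.
* **Weighted distance** — with unbalanced designs the plain distance hides
  failures (absorbing a 10-individual population into a 300-individual one
  costs only 10/310). The weighted variant gives every true population
  equal total weight, so that failure costs 0.5; with sizes 10 and 300 one
  misassigned small-population individual costs 30/600.
* **Mean partition** — the partition minimising the total distance to all
  samples, found by greedy single-individual coordinate descent sweeping
  individuals in index order and accepting only strict improvements (ties
  are rejected so the search terminates). The search starts from the
  best-scoring partition among the most frequent distinct samples, which
  makes it deterministic; on tiny instances it attains the exhaustive
  optimum in ≥95% of random trials, and the tests tolerate the rare local
  minimum rather than hide it.
* **Co-assignment matrix and dendrogram** — pairwise co-assignment
  probabilities across samples, clustered by complete linkage on
  `1 - coassignment` (via `hclust`) and exported as a Newick tree. Both
  summaries are label-free, so the label-switching ambiguity of mixture
  samplers never reaches the user.

# Fixed-K baselines

Two no-admixture fixed-K Gibbs samplers serve as comparison points, with a
1/K assignment prior and explicit allele frequencies. FUM resamples
frequencies from `Dirichlet(y + 1)` (uncorrelated, flat prior); FCM uses the
correlated-frequency model `Dirichlet(y_jlh + Pa_lh f_j)` around sampled
ancestral frequencies `Pa` with per-cluster drift `F_j ~ U(0,1)`,
`f_j = (1 - F_j)/F_j`. `Pa` is updated per locus by a Dirichlet
neighbourhood proposal (concentration 2000, chosen for a 20-50% acceptance
rate on typical microsatellite data) with the exact Hastings correction,
and `F_j` by a logit-scale random walk. During the first half of burn-in
the two allele copies of an individual may be assigned to different
clusters under flat per-individual mixture weights; this warm-up keeps
early sweeps from collapsing clusters to emptiness and is discarded at the
switch. Stored samples are aligned to a running reference by greedy maximal
shared membership before assignment probabilities are averaged.

When `Pa` is fixed uniform and `F_j` is fixed so that `Pa_lh f_j = 1`, the
FCM update reduces exactly to FUM — the test suite pins this equivalence.
(Note the limit `F -> 1` alone gives `Dirichlet(y)`, not FUM's
`Dirichlet(y+1)`; equality requires the prior weight one per allele.)

# Simulators

**Correlated-Dirichlet model.** Population frequencies are drawn from
`Dirichlet(Pa (1-F)/F)` around chosen ancestral frequencies — mean `Pa`,
variance `Pa(1-Pa)F`, so `F` plays the role of Wright's Fst — and genotypes
are two independent allele draws. Loci observed monomorphic are excluded.
The canonical scenarios are two populations of 25 with microsatellite-like
(`J = 5`) or SNP (`J = 2`) loci, uniform or skewed ancestral frequencies
(`{0.2 x 5}` / `{0.8, 0.05 x 4}`; `{0.5, 0.5}` / `{0.8, 0.2}`), `F = 0.05`
(microsatellites) or `0.07` (SNPs).

**Island Wright-Fisher model.** Eight demes of 1000 diploids by default;
each generation applies migration (fraction `m` of each deme's pool
replaced by the average of the other demes), K-allele mutation (rate `mu`,
uniform target state), and multinomial resampling of the `2N` copies.
Because loci are unlinked and mating is random, the model is simulated at
allele-frequency resolution rather than as individual pedigrees — for the
statistics used here the two are distributionally equivalent, and this
makes long scenarios desk-feasible. Samples of individuals are genotyped by
two independent draws from their deme's final frequencies. With the
microsatellite scenario (50 loci, 10 states, `mu = 5e-4`, `m = 0.003`) the
simulator reproduces the reference calibrations: mean pairwise
Weir-Cockerham Fst ≈ 0.061 among demes and observed heterozygosity ≈ 0.81.
We run 5,000 generations rather than 20,000: the summaries above are at
mutation-migration-drift equilibrium well before that point, and only
near-equilibrium summaries enter any analysis.

Fst is estimated by Weir and Cockerham's (1984) theta as the ratio of
summed variance components over loci and alleles; small numerical
differences from other estimators are expected and documented.

# Problem sizes used in the checks

The automated checks scale the original designs down to keep a full run in
minutes: 10 replicates (5 in the test suite) instead of 100 for the
scenario means, 5,000-10,000 MCMC iterations instead of 20,000-100,000 for
the DP sampler, 30,000 instead of 100,000 for FCM, three island replicates
for the simulator calibration, and exact-posterior comparisons on n ≤ 6
where all set partitions can be enumerated. These sizes are the package's
own choice of a desk-scale experiment; the scenario parameters themselves
(sample sizes, locus counts, mutation and migration rates, ancestral
frequencies) are never altered.

# Known limitations

* `alpha` is fixed, not sampled; choose it through the prior mean of `K`.
* No admixture model: individuals belong to exactly one population
  (the fixed-K warm-up uses copy-level assignment only as a device).
* The mean-partition search is a greedy local optimiser; it can in
  principle return a local minimum (observed in roughly 1 in 20 tiny
  random instances, and mitigated by the multi-candidate start).
* The island simulator omits linkage, selection, bottlenecks and unequal
  deme sizes; it emulates neutral equilibrium differentiation only. The
  correlated-Dirichlet simulator matches the correlated-frequency prior of
  FCM, not a demographic history.
* Genotype input is the whitespace table dialect described in
  `?read_genotype_table` (one or two rows per individual); VCF/PLINK
  ingestion and linked-loci models are out of scope.
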