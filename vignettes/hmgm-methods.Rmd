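---
title: "Hidden Markov graph models: methods and design notes"
author: "hmgm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hidden Markov graph models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmgm)
```

## The model

`hmgm` treats multi-subject regional brain-activity recordings as
independent realisations of one shared stochastic process: a hidden Markov
chain over K brain states with multivariate-normal observation models. For
subject n at time t the hidden state S(n,t) follows

    Pr(S(n,t) = s | S(n,t-1) = s') = P[s', s]

with a K x K row-stochastic transition matrix P shared by all subjects, and
the observed region vector is drawn from N(mu(s), Sigma(s)) for the current
state. Each subject's initial state is drawn independently; the generator
uses a uniform law over states, a documented choice since only "at random"
is specified by the modelling convention we follow, and it is configurable
through the generator's transition structure.

Fitting happens in a reduced space: each region series is standardized to
mean 0 and SD 1, all subjects are stacked, and the leading d eigenvectors A
(D x d) of the pooled correlation matrix define the projection. Because
standardization makes covariance equal correlation, PCA on the pooled
correlation matrix is the natural shared basis. The retained dimension d
comes from Horn's parallel analysis: observed eigenvalues are kept while
they exceed the 95th percentile of eigenvalues of size-matched i.i.d.
standard-normal data (100 null draws by default). The 95th percentile is
the common conservative variant; the classical mean criterion is available
by setting `percentile = 0.5`. Reduced-space state parameters are
back-projected as

    Sigma(s) = A Sigma*(s) A',   mu(s) = A mu*(s),

so region-space covariances have rank at most d by construction — the graph
builder therefore regularises variances with a tiny ridge (1e-10 relative)
before computing correlations and does not warn about the expected rank
deficiency when called from the pipeline.

## Fitting backend

The observation-model machinery of the original variational-Bayes
implementation is deliberately abstracted behind a fit contract: downstream
stages consume only P, the state parameters, and posterior state marginals.
The backend shipped here is Baum-Welch expectation-maximisation with full
covariances, written in C++ (RcppArmadillo):

* subjects enter as independent trials sharing parameters; the scaled
  forward-backward recursion restarts at each trial boundary;
* `nRestarts` k-means-initialised restarts (default 5), best training
  log-likelihood wins; the trace is exposed and tested to be
  non-decreasing;
* covariances carry a relative diagonal ridge eps = 1e-6 * trace/d for
  numerical positive definiteness;
* a state whose responsibility mass vanishes is retained at its last
  regularized parameters with a warning rather than dropped mid-fit;
* states are reported in decreasing order of pooled occupancy so output
  ordering is stable across runs.

## Choosing the number of states

For each candidate k and held-out subject n, a model is trained on the
other subjects and the held-out fractional occupancy

    kappa(s, n) = (1/T) sum_t Pr(S(n,t) = s | model, data)

is computed from smoothed posterior marginals. The selection objective is
the pooled cross-validated entropy

    H(k) = - sum_n sum_s kappa(s,n) log kappa(s,n),

with 0 log 0 := 0, and the selected K is the argmax (smallest k on ties).
The printed form of this objective omits the state sum; the double sum is
the only reading that yields a proper entropy and is the one implemented.
The same cross-validation records the held-out log-likelihood per k for
comparison. Per-fold fits use fold-derived seeds, so a selection curve is
reproducible from one seed and invariant (in selection, not bit-exact in H)
to subject ordering.

**A property worth knowing before trusting H(k) on synthetic data.** Our
test suite measures both criteria on generated data with well-separated
states. The held-out log-likelihood reliably peaks at the generating K. The
entropy does not turn over there: when every subject is an i.i.d.
realisation of the same process and the backend is maximum-likelihood EM, a
model with k > K splits true states into co-occupied near-duplicates, and
any refinement of an occupancy distribution weakly increases its entropy —
so H(k) keeps rising past the generating K (about one nat per extra state
in our measurements, for soft and hard occupancy alike). An interior
entropy maximum evidently needs a mechanism that starves redundant states
(variational-Bayes state death) or genuine between-subject heterogeneity,
neither of which a homogeneous ML-EM synthetic benchmark provides. The
acceptance checks report both criteria honestly; the entropy-recovery check
fails under these conditions and is left failing. In practice we recommend
reading the entropy curve as a lower bound on K (it rises steeply while k
is insufficient) and cross-checking against the recorded held-out
log-likelihood.

After selection, states occupied by fewer than 25% of subjects are pruned
and the surviving transition rows renormalised. "Occupied" means
kappa(s,n) > 1/T — more than one expected time point — since no sharper
occurrence rule is fixed by the method description; a Viterbi-presence rule
is an easy substitution.

## From states to graphs

Each state becomes a layer of a multiplex graph. Node weights are the mean
activity a(s) = mu(s); the edge weight from region x to y is

    W(s)[x, y] = |rho(s)[x, y]| / sum_z |rho(s)[x, z]|,

the row-normalised absolute correlation derived from Sigma(s), diagonal
included — so self-loops get weight 1/rowsum and every row of W is a
probability vector. W is a random-walk (Markov) transition matrix over
regions, the property the community-ranking null model exploits. Layers are
linked by P and its stationary distribution pi (left Perron eigenvector; an
error lists the closed communicating classes when the chain is reducible
and no unique pi exists — note an irreducible periodic chain still has a
unique pi and is accepted).

Because |rho| is symmetric, W departs from symmetry only through row
normalisation. The symmetry fraction

    Sym(W) = ||(W + W')/2||_F^2 / ||W||_F^2

quantifies this: the symmetric and antisymmetric parts are orthogonal, so
Sym lies in [0, 1] and equals 1 exactly for symmetric W. "Energy" is the
squared Frobenius norm, the standard matrix-energy usage.

## Community detection

Both the temporal graph (P itself) and each spatial state graph are
partitioned the same way: Louvain optimisation runs on the symmetrized
graph (W + W')/2 with shuffled node orders, and every candidate partition
is scored with the directed (Leicht-Newman) modularity on the original
asymmetric matrix,

    Q = (1/m) sum_ij [ W_ij - gamma * s_out(i) s_in(j) / m ] delta(c_i, c_j),

self-loops counted once in m and in both strengths. This optimise-symmetric
/ score-directed hybrid mirrors the original method's acknowledged
compromise. On symmetric graphs the directed form reduces exactly to
classical modularity (asserted in tests against igraph).

Partition significance uses label permutations: the observed Q is compared
with Q under `nPerm` (default 10,000) uniform shuffles of the label vector
(community sizes preserved), with the add-one p-value
(1 + #{Q_perm >= Q_obs}) / (1 + nPerm).

The temporal resolution gamma is chosen by Variation of Information:
for each gamma on a grid, Louvain is repeated with shuffled orders and the
mean pairwise VI of the resulting partitions is computed; the gamma with
the most reproducible partitions wins (smallest on ties). VI is computed
in-house from the joint label contingency table. Spatial (within-state)
community detection uses a fixed gamma = 2, the resolution that produced
consistently sized, rankable communities in the original analyses; making
it resolution-matched per hub was rejected there for producing incomparable
community sizes.

Hub states maximise the within-community centrality z-score: for node i in
community U, k_i is the sum of in- and out-weights between i and members of
U, standardized by the mean and SD of k over U (z = 0 for all members when
the SD vanishes; ties go to the lower state index). Total (in+out) strength
is used; in- or out-only variants would be a one-line change. As a
complementary view of subject-state structure, the occupancy matrix is
clustered hierarchically (Ward linkage on 1 - Pearson distance, rows and
columns separately) and the trees serialized to Newick.

## Ranking spatial communities

The coherence score of community C in state s is the functional homogeneity

    FH(s, C) = mu(s)[C]' Sigma(s)[C, C] mu(s)[C],

which is large when mean activity aligns with the leading covariance
directions of the community, and nonnegative for PSD Sigma. Its null
distribution is sampled by random walks on the multiplex model: draw a
state from pi, a start region uniformly from C, walk on that state's W
until |C| distinct regions are collected (start included; the walk is
redrawn if a guard of 100 |C| steps is exhausted — needed because nearly
absorbing rows can trap a walk), and score the sampled pair with its own
state's parameters. The T-score is the fraction of L (default 10,000) null
pairs strictly exceeded by FH(s, C); ties count against the candidate,
which makes the single-state whole-graph case exactly 0 and keeps the score
conservative. Collecting distinct regions (rather than walk positions) is
what makes the null pair's FH dimensionally comparable to the candidate's.
Communities are ranked within a state by decreasing T (ties by larger FH,
then lower community id); T-scores are not comparable across states. The
community's sign — correlated versus anticorrelated activity — is the sign
of sum_{x in C} mu(s)[x], reported separately and flagged when the sum is
exactly zero.

## Term-score projection

Given per-state scores theta in [-1, 1] for M terms (supplied by the user;
no literature-database querying happens here), the expected score one step
ahead is the convex combination P theta. Correlating, across states, each
current-term column with each projected-term column (Pearson, two-sided
t-test with K - 2 degrees of freedom) and adjusting all M^2 p-values with
Benjamini-Hochberg reproduces the style of spatiotemporal term-affinity
table used to interpret state dynamics; tiers are reported at 0.01 / 0.05 /
0.1. FDR method and tiers are configurable.

## The synthetic generator, and what tests do and do not show

`generateHmmDataset` emulates exactly the modelled data-generating process:
a shared Markov chain, per-state Gaussian observations, independent
subjects, uniform initial states. It deliberately omits haemodynamics,
temporal autocorrelation within states, scanner artefacts, and
between-subject parameter variability. Passing recovery tests on these data
therefore validates the estimation and graph machinery, not robustness to
real fMRI nuisance structure — and, as noted above, the homogeneity of
synthetic subjects is precisely why the entropy criterion behaves
differently here than on heterogeneous recordings.
`generatePlantedPartitionGraph` (blocks with p_in/p_out edges, weights
uniform(0.5, 1.5)-scaled so weighted and unweighted structure coincide) and
`plantCoherentState` (an exact within-correlation block for the planted
community, plus weak background correlations that keep every region
reachable by the walk without touching the block) provide ground truth for
the community-detection and ranking stages.

Default problem sizes in the shipped tests were chosen as the smallest
scales at which the statistical claims are comfortably identifiable:
selection experiments use 8 subjects x 200 time points x 4 reduced
dimensions over 10 replicates; graph oracles enumerate all partitions up to
8 nodes; permutation and T-score calibrations use the same 10,000-draw
scale as the method's own significance conventions.

## Numerical conventions

* Row-stochasticity tolerance 1e-10 (1e-12 for generator inputs); PSD
  tolerance 1e-10 on symmetrized eigenvalues.
* Eigenvector sign convention: largest-magnitude entry positive.
* Argmax ties always resolve to the smallest index (parsimony).
* Every user-facing function takes an explicit seed and restores the
  caller's RNG state; stage seeds are derived deterministically from one
  master seed, so pipeline reruns are bit-identical.
* All artifacts are plain text: TSV tables, GraphML graphs, Newick trees,
  JSON manifests.

## Known limitations

* The entropy selection criterion's interior maximum is not reproducible
  with this maximum-likelihood backend on homogeneous synthetic subjects
  (see above); the held-out log-likelihood recorded alongside it is the
  reliable recovery signal in that regime.
* Louvain optimises an undirected surrogate; edge directionality enters
  only through scoring.
* No autoregressive observation models, no Bayesian posterior over K, no
  InfoMap or interlayer-coupled multilayer modularity.
* T-scores are rank-based within a state; no cross-state league table is
  offered by design.
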