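---
title: "Dissecting allosteric conformational change: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting allosteric conformational change: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allostate)
```

## The problem

Photosensory LOV-domain proteins such as the fungal circadian photoreceptor
Vivid couple a local chemical event — blue-light-driven formation of a
covalent cysteinyl–flavin adduct — to a global conformational change of the
N-terminal cap. Molecular-dynamics ensembles of such systems contain the
kinetic and structural signatures of that allosteric coupling, but
extracting them requires three things at once: a kinetic coarse-graining of
the trajectory (which conformational states exist, and how does the
perturbation shift the transition probabilities between them?), a
quantitative measure of which geometric features distinguish those states,
and a way to aggregate feature-level evidence into mechanistically
interpretable groups of residues. `allostate` implements that workflow as a
set of composable model-fitting functions plus a one-call pipeline.

## Kinetic layer: the Markov state model

Frames are projected onto two collective variables, the C$\alpha$ RMSD to a
"dark" and to a "light" reference structure (minimum over rigid motions,
Kabsch superposition via SVD with a determinant correction that excludes
reflections). This 2D-RMSD plane is discretized by k-means into $k$
microstates (`cluster_microstates()`, 10 restarts, seeded; the reference
configuration for a full-size protein uses $k = 300$, the test-scale
configuration $k = 30$–$50$). Lagged transitions are counted with a sliding
window of stride 1 strictly within trajectories, and the model is restricted
to the largest strongly connected component of the positive-count digraph
(largest by total internal transition count; ties broken by vertex count,
then lowest index), so that a stationary distribution exists.

`msm()` estimates the maximum-likelihood *reversible* transition matrix by
the standard self-consistent fixed-point iteration on the symmetric flow
matrix $x_{ij}$,
$$x_{ij} \leftarrow \frac{c_{ij} + c_{ji}}{c_i/x_i + c_j/x_j},$$
iterated until the log-likelihood changes by less than $10^{-10}$ *and* the
transition matrix itself settles below $10^{-11}$ per element (the
likelihood is flat near the optimum, so the likelihood criterion alone
under-resolves $T$; both criteria together give agreement with a direct
numerical likelihood maximization to better than $10^{-6}$), with a cap of
10,000 iterations. Detailed balance $\pi_i T_{ij} = \pi_j T_{ji}$ then holds
at the optimum; the stationary distribution is read off as the eigenvalue-1
left eigenvector, renormalized. Reversibility also makes the spectrum real
(computed through the $\pi$-symmetrized matrix), which the implied
timescales $t_i(\tau) = -\tau / \ln \lambda_i(\tau)$ and the macrostate
lumping rely on. Nonpositive or complex eigenvalues are reported as missing
timescales, never dropped.

Macrostates come from Perron-cluster lumping (`pcca()`): k-means (seeded,
100 restarts) on the rows of the leading $n$ right-eigenvector matrix gives
a crisp microstate-to-macrostate assignment; $n = k$ degenerates to the
identity lumping. The fuzzy simplex variant (PCCA+) is a possible extension
but the crisp spectral variant is deterministic and directly testable
against planted block structure, which is what the test suite does.

Model validity is checked two ways. Microstate dispersion — the mean RMSD of
member frames to the iteratively aligned microstate mean — must stay below
2.0 Å (the conventional kinetic-similarity threshold; flagged otherwise).
The Chapman–Kolmogorov test compares $[T(\tau)^k]_{ii}$ against the directly
estimated self-transition probability at lag $k\tau$; both sides use plain
row-normalized counts so the $k=1$ case is exact by construction. Two error
bars are attached: the standard multinomial $\sqrt{p(1-p)/N_i}$, and a
modified form in which the denominator is replaced by the ratio of the total
transition count to $N_i$, which weakens the error bar's dependence on the
frame-save frequency. The precise modified formula in the literature is not
fully specified, so both are emitted, labeled, and the violation flag uses
the standard form.

Condition-dependent kinetics (covalently bonded vs. non-bonded ensembles)
are obtained by recounting macrostate transitions over the selected
trajectory subset only (`condition_macro_T()`); macrostates never visited in
a subset yield explicitly undefined rows rather than silent zeros.

## Discrimination layer: one-vs-one forests

Every unordered residue pair contributes one feature, its C$\alpha$
distance ($P = N(N-1)/2$; 10,878 features for a 148-residue construct),
enumerated lexicographically over index pairs $(i, j)$, $i < j$. Distances
are invariant under rigid motion of each frame, so no alignment enters the
machine-learning layer.

For every pair of macrostates a separate random forest is trained on that
pair's frames only (`train_ovo()`; 28 classifiers for 8 states). Forests
split on Gini impurity; a feature's importance in one forest is its total
impurity decrease accumulated over all nodes, normalized to sum to one. The
overall importance is the arithmetic mean over the state pairs. Baseline
classifiers (single tree, single multiclass forest, a one-hidden-layer
neural network with L2 penalty, and a stratified random dummy) are provided
for the accuracy comparison with stratified 12-fold cross-validation; the
neural network's weights are never used downstream because only the
tree-based importances are interpretable at the feature level.

Defaults are 100 trees of unlimited depth, with the forest implementation's
default feature subsampling ($\sqrt{P}$ candidates per split). One
hyperparameter deserves comment: when the goal is the *community graph*
rather than raw ranking, strong feature subsampling (small `mtry`) is
preferable. C$\alpha$-distance features are heavily correlated, and with
large `mtry` the Gini criterion concentrates all importance on one winner
per correlated group, leaving many genuinely discriminative residue-pair
edges with zero weight; small `mtry` forces trees to spread importance
across the correlated group, which stabilizes the downstream partition.
The recovery experiments in the test suite use `mtry = 5` for exactly this
reason.

## The community layer

Residues form an undirected graph whose edge weights $E_{ij}$ are the
feature importance of the pair $(i, j)$. The intra-community objective
$$T = \sum_l \sum_{i<j \in C_l} E_{ij}$$
counts each unordered edge once; minimizing $T$ pushes the
state-discriminating signal onto *inter*-community pairs, so that community
geometry, not intra-community detail, explains the states. Insertions and
swaps change the objective by
$$\Delta T_{\text{ins}} = Ex_{i,C_k} - In_i, \qquad
  \Delta T_{\text{swap}} = (Ex_{i,C_k} + Ex_{j,C_m}) - (In_i + In_j) - 2E_{ij},$$
and a move's *benefit* is the objective reduction $-\Delta T$: moves are
accepted only when $T$ strictly decreases, which reconciles the
benefit-maximization description of the search with the minimization of
$T$. The search (`kl_search()`) is best-improvement: every insertion and
every cross-community swap is evaluated (as vectorized matrix products),
the single best move is applied, ties prefer insertion over swap and then
the lowest node index, and each restart descends from a fresh random
partition with every community seeded non-empty. The reference
configuration uses 10,000 restarts; the tests use 100, where the search
matches exhaustive partition enumeration on small graphs in at least 99 of
100 random instances and never reports an objective below the enumerated
optimum. Incremental $\Delta T$ bookkeeping is verified against full
objective recomputation to $10^{-12}$.

Because every $n$-partition can be refined, the best objective is
non-increasing in $n$ (within-community importance cannot grow as
communities are added; equivalently the among-community share grows toward
100%). The number of communities is chosen by an elbow on the
within-objective curve, automated as the maximum discrete second
difference, with a manual override for visual choices. Communities are
lettered A, B, C, … by descending external importance, and accumulation
tables report (i) the importance mass between each community pair (summing
to 100%) and (ii) per state pair, the mass carried by designated
community-group pairs, which is how "which communities move in this
transition?" is quantified.

## Mechanism layer: transition path theory

On the macrostate matrix, the forward committor solves
$-q_i^+ + \sum_{k \in I} T_{ik} q_k^+ = -\sum_{k \in B} T_{ik}$ with
$q^+ = 0$ on the source set and $1$ on the target set; the backward
committor is taken as $q^- = 1 - q^+$, exact for the reversible estimates
this package produces (a general backward solve is deliberately out of
scope). Effective fluxes $f_{ij} = \pi_i q_i^- T_{ij} q_j^+$, net fluxes
$f^+_{ij} = \max(0, f_{ij} - f_{ji})$, and the total flux
$F = \sum_{i \in A}\sum_{j \notin A} \pi_i T_{ij} q^+_j$ follow directly.
Pathways are extracted by repeatedly finding the widest (maximum-bottleneck)
source-to-target path — a Dijkstra-style search with ties broken by the
lexicographically smallest state sequence — assigning it its bottleneck
flux, and subtracting that flux along the path, until the residual drops
below $10^{-8} F$ or 10,000 paths have been extracted (both logged).
Identical state sequences aggregate into channels whose probabilities are
flux shares; they sum to one by construction, and the decomposition is
checked against the identity $\sum_p f_p = F$.

## The synthetic generator: what it emulates, and what it does not

Because the trajectories behind the reference application are not
deposited, every layer is validated against a seeded generator with planted
ground truth (`synthetic_spec()`, `make_dataset()`). The default
specification mirrors the reference sampling plan: 148 residues, 8
macrostates, 6 trajectories per bond condition, 1 μs per trajectory saved
every 100 ps — 10,000 frames per μs and 120,000 data points in total. The
hidden chain is sampled per trajectory from a condition-dependent generator
matrix (banded and ergodic: self-transition weight 0.7, nearest-neighbor
exchange 0.1 with a ±0.08 drift whose sign encodes the bond condition, and
a 0.02 uniform floor — values chosen once to give metastable,
clearly condition-separated kinetics at a realistic self-transition
probability). Geometry starts from an ideal α-helical C$\alpha$ trace
(radius 2.3 Å, rise 1.5 Å, 100° per residue — nondegenerate and
superposition-friendly); macrostate $s$ translates each planted residue
community rigidly by $(s-1)\,d\,\mathbf{u}_c$ with distinct unit directions
per community, and isotropic Gaussian noise of σ per coordinate is added.
Defaults $d = 3$ Å and σ = 0.5 Å put the planted signal at roughly 4–8
noise standard deviations in distance space — "high signal" in the sense of
the recovery experiments. The test-scale specification (20 residues in 3
communities, 4 macrostates, 4 × 2,000 frames) keeps the full pipeline
under ~10 s.

The generator is deliberately *not* physically realistic: rigid community
displacements rather than dihedral moves (this keeps the planted
pairwise-distance signal analytically known — with σ = 0 each
inter-community distance takes exactly $n_\text{macro}$ values and each
intra-community distance is constant), no solvent, no cofactor chemistry,
Markovian state dynamics by construction. Passing tests therefore
demonstrate that each algorithm recovers what it is defined to recover;
they do not demonstrate that real MD ensembles satisfy the Markov or
high-signal assumptions — that is what the dispersion, implied-timescale
and Chapman–Kolmogorov diagnostics are for on real data.

## Numerical and statistical choices

* Superposition requires $N \ge 3$; smaller or degenerate inputs raise an
  error, with an explicit translation-free mode available.
* RMSF alignment is ambiguous in general; both modes exist. The default
  iteratively aligns to the running mean (10 iterations or mean shift
  < $10^{-6}$ Å); the no-superposition mode supports closed-form tests.
* Stochastic recovery checks use CLT error bars. Where a bound is applied
  across many matrix entries simultaneously, the test is family-aware
  (all entries within 4 SE, at most a prescribed few beyond 3 SE):
  an all-entries 3σ rule over 64 entries would reject a correct
  implementation in roughly a fifth of runs.
* k-means stages are seeded with explicit restart counts (10 for
  microstates, 100 for the eigenvector lumping); the KL search draws all
  its randomness from one seed, and the pipeline derives per-stage seeds
  from a single root seed by fixed offsets, so a run is reproducible from
  its config alone.
* All-zero community graphs, single-community partitions, unvisited
  macrostates, absorbing unreached states in the pipeline's TPT matrix,
  and importance vectors that sum to zero (uniformized) are all handled
  explicitly.

## Limitations

The crisp PCCA variant can split genuinely fuzzy microstates arbitrarily;
the KL search guarantees only local optimality per restart (the global
statement rests on the multi-restart evidence); the backward committor
convention requires reversibility; channel counts from real data depend on
the residual tolerance and are not comparable across tolerances; and the
community letters (by external importance) can permute between runs whose
importance estimates differ. On desk-scale hardware the full-size sampling
plan (120,000 frames × 10,878 features) is supported for bookkeeping and
featurization, but forest training at that scale is a batch job, not an
interactive call.
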