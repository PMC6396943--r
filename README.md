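# allostate

Dissecting allosteric conformational change in protein molecular-dynamics
ensembles: Markov state models on 2D-RMSD collective variables, one-vs-one
random-forest feature importance over pairwise Cα distances, residue
community partitioning that minimizes intra-community importance, and
transition path theory on the macrostate network.

## Who this is for

Computational structural biologists who have (or can simulate) several MD
trajectories of a protein under two experimental conditions — the motivating
system is a LOV-domain photoreceptor with and without its light-driven
cysteinyl–flavin covalent bond — and want a quantitative, end-to-end answer
to: *which metastable conformational states exist, how does the perturbation
shift the kinetics between them, which residue-pair geometry distinguishes
the states, which residue communities move as units, and along which state
sequences does the dark-to-light transition flow?*

## The models at the core

**Kinetics.** Frames are projected onto (RMSD to dark reference, RMSD to
light reference), discretized by k-means into microstates, and a reversible
maximum-likelihood transition matrix is estimated at lag τ from
sliding-window counts restricted to the largest strongly connected
component. Detailed balance π<sub>i</sub>T<sub>ij</sub> = π<sub>j</sub>T<sub>ji</sub>
holds at the optimum; implied timescales t<sub>i</sub> = −τ/ln λ<sub>i</sub>
guide the lag choice; Perron-cluster lumping maps microstates onto
metastable macrostates; Chapman–Kolmogorov and microstate-dispersion
diagnostics check model validity; and macrostate matrices are re-estimated
per condition to expose the perturbation's kinetic effect.

**Discrimination.** For every macrostate pair, a random forest is trained on
that pair's frames with all N(N−1)/2 pairwise Cα distances as features. A
feature's importance per pair is its normalized total Gini impurity
decrease; the overall importance is the mean over pairs.

**Communities.** Residues form a graph weighted by feature importance. A
multi-restart Kernighan–Lin-style search minimizes the importance retained
*inside* communities, T = Σ<sub>l</sub> Σ<sub>i&lt;j∈C_l</sub> E<sub>ij</sub>,
so that inter-community geometry carries the state-discriminating signal;
an elbow criterion selects the community count.

**Mechanism.** On the macrostate matrix, committors solve the standard
linear system, fluxes follow f<sub>ij</sub> = π<sub>i</sub>q<sub>i</sub><sup>−</sup>T<sub>ij</sub>q<sub>j</sub><sup>+</sup>,
and the net flux is decomposed into pathways by repeated widest-path
extraction, aggregated into channels with flux-share probabilities.

A seeded synthetic trajectory generator with planted macrostates, planted
communities and condition-dependent kinetics makes every stage testable
with no external data.

## Worked example

The full pipeline on the test-scale synthetic system (20 residues in 3
planted communities, 4 macrostates, 4 trajectories × 1,000 frames):

```r
library(allostate)
cfg <- run_config(spec = test_spec(duration_us = 0.1), k_micro = 30L,
                  lag_frames = 2L, restarts = 30L, seed = 5L)
run <- run_pipeline(cfg, verbose = FALSE)
print(run)
#> allostate pipeline run (seed 5, config 026fa9f9)
#>   data points: 4000 | microstates: 30 | macrostates: 4
#>   stationary distribution (pooled):
#> [1] 0.4005 0.0970 0.3901 0.1125
#>   intra-community importance: 0.143% of total
#>   total A->B flux: 0.01922 per lag; 3 channels
```

The stationary distribution is the long-time macrostate population implied
by the pooled transition matrix. Only 0.143% of the feature-importance mass
falls inside communities — the partition has pushed essentially all
state-discriminating signal onto inter-community residue pairs, and it
exactly recovers the three planted residue blocks:

```r
print(run$partition)
#> ML communities: 3 communities over 20 residues
#> intra-community importance: 0.00142621 (30 restarts, seed 10)
#>   Commu. A: X43 X44 X45 X46 X47 X48 X49
#>   Commu. B: X50 X51 X52 X53 X54 X55 X56
#>   Commu. C: X37 X38 X39 X40 X41 X42
```

Feature-level detail and the transition mechanism:

```r
ranked_importance(run$ovo$importance, 3)
#>   feature    pair overall_pct         rank1        rank2        rank3
#> 1     148 X47-X50        5.10  S2-S4: 7.77% S1-S2: 7.34% S3-S4: 7.28%
#> 2     151 X47-X53        4.34 S1-S2: 10.36% S2-S4: 6.37% S3-S4: 4.17%
#> 3     156 X48-X50        4.10  S2-S4: 8.38% S1-S4: 5.07% S1-S2: 4.99%

print(run$tpt)
#> Transition path analysis: A = {1} -> B = {4}
#> total flux 0.01922 per lag time; 3 pathways in 3 channels
#> top channels:
#>       channel probability
#> 1 State 1–2–4     48.457%
#> 2   State 1–4     37.892%
#> 3 State 1–3–4     13.652%

cumulative_coverage(run$ovo$importance)   # features for 90% of importance
#> [1] 39
```

Every top-ranked feature spans two communities (e.g. X47–X50 bridges
Commu. A and B), the channel table reads as "48% of the reactive flux from
macrostate 1 to 4 passes through macrostate 2", and 39 of 190 features
carry 90% of the distinguishing signal.

A thin command-line wrapper is installed with the package for shell use:
`Rscript $(Rscript -e 'cat(system.file("cli/allostate.R", package="allostate"))') run --out out/ --seed 1`.

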