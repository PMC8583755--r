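# gagscape

Conformational-landscape analysis of short glycosaminoglycan (GAG) chains.

Glycosaminoglycans — hyaluronic acid (HA), heparan-6-sulphate (H6S),
chondroitin-4-sulphate (C4S), chondroitin-6-sulphate (C6S) — are unbranched
polysaccharides whose biological roles hinge on conformational flexibility:
the chains fluctuate between extended and kinked shapes driven by their
glycosidic torsions and modulated by sulphation and bound cations.
`gagscape` is for structural bioinformaticians who want to quantify that
heterogeneity from molecular-dynamics-style trajectories of short GAG
chains, and to validate every step of such an analysis on synthetic
ensembles with known ground truth.

## What it computes

Per frame, for each glycosidic linkage class (Linkage1: amino sugar
→ GlcUA; Linkage2: GlcUA → amino sugar), the collective dihedral-offset
descriptor

    D = (1/N) Σᵢ [ (1 + cos(φᵢ − φ_ref)) + (1 + cos(ψᵢ − ψ_ref)) ] / 2,

normalized so a chain at the reference (fully extended) torsions scores
exactly 2 and the range is [0, 2]; the end-to-end distance R_ee
(C1 of the reducing-end residue to C4 of the terminal residue); geometric
hydrogen bonds (donor–acceptor < 0.35 nm, angular deviation < 30°);
residue contact maps (any-atom distance ≤ 0.4 nm); cation radial
distribution functions g(r) averaged over the five carboxylate or sulphate
groups; and proximal-ion counts (≤ 0.5 nm).

On top of the features it implements neighbour-count RMSD clustering
(greedy extraction of the frame with the most neighbours within a cutoff,
with its cluster-count convergence curve) and a free-energy-landscape
heuristic: PCA of the state vector {D_L1, D_L2, R_ee, N_HB}, the surface
ΔG(PC) = −k_B·T·ln P(PC)/P_max over the first two components, k-means
state segregation with automatic elbow selection, and representative
(centroid) structure retrieval.

A rigid-chair chain builder and a von Mises mixture ensemble generator
provide deterministic, seed-reproducible synthetic trajectories (optionally
with bulk or shell-placed monovalent cations) so that every stage has an
analytic or brute-force oracle.

## Worked example

```r
library(gagscape)

top <- gag_topology("C6S", 5)
top
#> <gag_topology> C6S: 5 disaccharides, 156 atoms, 5 Linkage1 + 4 Linkage2 linkages, formal charge -10

traj <- sample_ensemble(two_state_spec(top, n_frames = 2000, seed = 42))
feats <- compute_features(traj)
feats
#> # A tibble: 2,000 × 6
#>   frame d_offset_l1 d_offset_l2  r_ee  n_hb  rmsd
#>   <int>       <dbl>       <dbl> <dbl> <int> <dbl>
#> 1     1        1.85        1.14 0.750     0 1.31
#> 2     2        1.84        1.23 2.20      0 0.984
#> 3     3        1.99        1.98 4.88      0 0.114
#> # ℹ 1,997 more rows

pca <- principal_components(assemble_state_matrix(feats))
pca
#> <gag_pca> 2000 frames, 2 components; explained variance: 96.5%, 2.8%

states <- kmeans_with_elbow(pca, k_range = 1:8, seed = 42)
states
#> <gag_states> k = 2 (largest relative second difference of inertia); populations: 69.8%, 30.2%

representative_frames(states, pca, traj, features = feats)[,
  c("state", "population", "centroid_frame", "r_ee", "phi_l2", "psi_l2")]
#> # A tibble: 2 × 6
#>   state population centroid_frame  r_ee phi_l2 psi_l2
#>   <int>      <dbl>          <int> <dbl>  <dbl>  <dbl>
#> 1     1      0.698            495  4.77  121.  -173.
#> 2     2      0.302            199  1.68   90.7   66.9
```

The generator mixed an extended and a compact torsion state 70/30; the
pipeline recovers k = 2 states with populations 69.8% / 30.2% and, on this
seed, reassigns every frame to its true generator state. State 1 is the
extended basin (R_ee ≈ 4.8 nm, Linkage2 torsions at the reference values);
state 2 is the compact basin (small R_ee, Linkage2 rotated away). The
per-frame dihedral offsets show the same split: ≈ 2 for extended frames,
well below 1.6 on Linkage2 for compact ones.

`autoplot()` methods draw the free-energy surface
(`autoplot(free_energy_surface(pca))`), the inertia/elbow curve
(`autoplot(states)`), contact maps, RDFs and cluster-count evolution
curves; `tidy()`/`glance()` give broom-style summaries.

`run_gag_pipeline(gag_pipeline_config("HA", output_dir = "out"))` runs
simulate → features → clustering → FES end to end and writes CSV/JSON
artifacts plus a provenance manifest; reruns of the same configuration are
byte-identical.

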