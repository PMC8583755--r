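---
title: "Methods: conformational landscapes of glycosaminoglycan chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational landscapes of glycosaminoglycan chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gagscape)
```

## The problem

Glycosaminoglycans (GAGs) are unbranched polysaccharides of repeating
disaccharide units — hyaluronic acid (HA), heparan-6-sulphate (H6S),
chondroitin-4-sulphate (C4S) and chondroitin-6-sulphate (C6S) in this
package — whose biological activity is tied to their conformational
flexibility. For short chains the dominant degrees of freedom are the
glycosidic torsions phi and psi on either side of each bridging oxygen.
`gagscape` computes the standard per-frame observables of such ensembles
(torsions and a collective dihedral-offset descriptor, end-to-end distance,
residue contacts, geometric hydrogen bonds, cation radial distribution
functions, proximal-ion counts), clusters conformations by neighbour-count
RMSD clustering, and condenses the ensemble into a two-dimensional
free-energy landscape over principal components, segregated into states by
k-means.

Because the package must be testable without access to microsecond
atomistic trajectories, it also contains an idealized chain builder and a
synthetic ensemble generator with known mixture structure. Every analysis
stage is validated against that ground truth or against independent
oracles.

## Chain model and the extended reference

Residues are rigid idealized pyranose chairs: the six ring atoms sit on a
symmetric chair (uniform ring bond 0.152 nm, out-of-plane amplitude
0.025 nm), substituents at tetrahedral angles, glycosidic C–O bonds of
0.142 nm and a C–O–C bridge angle of 117 degrees (`gag_geometry()`). Only
heavy atoms plus polar (hydroxyl/amine) hydrogens are represented; apolar
hydrogens and the acetyl tail add nothing to the implemented observables.
Ring puckering is deliberately out of scope: every ring stays in the chair.

A chain conformation is fully specified by the per-linkage (phi, psi):
residues are placed one after another by internal-coordinate (NeRF)
construction, with the bridge geometry consuming psi, phi and one
chirality convention per anomeric configuration (beta for all linkages
except Linkage1 of H6S, which is alpha). Torsions follow the IUPAC sign
convention and agree numerically with `bio3d::torsion.xyz` and with
MDAnalysis.

The *reference torsions* define "fully extended". The shipped defaults
(`reference_torsions(..., source = "idealized_extended")`) are the torsions
that maximize the end-to-end distance of this rigid-geometry model; they
were frozen once from a one-time optimization and give R~ee~ = 4.88 nm for
the HA/C4S/C6S penta-disaccharide and 4.76 nm for H6S — matching the
~4.8 nm expected for an extended five-disaccharide chain. Torsion sets
typical of extended starting structures built with an all-atom carbohydrate
force field are shipped as the `"force_field_start"` preset; under the
idealized geometry those values do *not* produce a maximally extended chain
(R~ee~ = 3.7 nm for HA), which is why they are not the default anchor of the
dihedral-offset descriptor.

## The dihedral-offset descriptor

For the N linkages of one class,

$$D = \frac{1}{N}\sum_{i=1}^{N}
  \frac{(1+\cos(\phi_i-\phi_\mathrm{ref})) + (1+\cos(\psi_i-\psi_\mathrm{ref}))}{2}.$$

The per-linkage sum of the two cosine terms is divided by two; without that
normalization a conformation at the reference would score 4, while the
descriptor is conventionally read on a [0, 2] scale with 2 = fully
extended and values below ~1.6 indicating significant deviation from
linearity. The halved form makes the reference score exactly 2 and bounds
the descriptor in [0, 2]; this is asserted on every computation.

## Feature conventions

* **RMSD** — non-mass-weighted, after least-squares (Kabsch) superposition
  over all chain atoms; validated against an independent quaternion
  (Kearsley) oracle.
* **Contacts** — residues a and b are in contact when any inter-atom
  distance is *at most* 0.4 nm (boundary inclusive). The diagonal and first
  off-diagonal are computed but flagged masked, the usual display
  convention for within-disaccharide contacts.
* **Hydrogen bonds** — donor–acceptor distance strictly below 0.35 nm and
  angular deviation of D→A from the D→H direction strictly below
  30 degrees. A literal "donor–H–acceptor angle below 30 degrees" would
  exclude near-linear hydrogen bonds, which is geometrically inconsistent
  with the distance criterion; the deviation-from-linearity reading is the
  convention used by standard trajectory-analysis tools. Both cutoffs are
  arguments.
* **RDF** — minimum-image distances in the cubic box, shell-volume
  normalization against the bulk ion density n/V (not a solvent-excluded
  volume). Per-group profiles are time-averaged first and then averaged
  over the five carboxylate (or sulphate) groups; the alternative order
  differs only when group occupancies differ, and the group-wise order
  matches how such profiles are usually reported.
* **Proximal ions** — ions within 0.5 nm (inclusive) of any chain atom,
  minimum-image.
* The chain itself is never wrapped: intra-chain features see a whole
  molecule, and only chain–ion distances are periodic.

## Neighbour-count clustering

Given the all-vs-all fitted RMSD matrix, the greedy procedure repeatedly
extracts the frame with the most remaining neighbours within the cutoff
(0.3 / 0.4 / 0.5 nm are the conventional values) together with those
neighbours. Two conventions the procedure itself does not pin down are
fixed here: a frame counts as its own neighbour (so the minimum cluster
size is 1), and ties on the neighbour count go to the lowest frame index.
Membership uses `<=` at the cutoff. The implementation is checked for
exact equality against a brute-force transcription on hundreds of random
matrices whose values are drawn from a coarse grid, so ties occur
frequently. The cluster-count-versus-time curve
(`cluster_count_evolution()`) reruns the clustering on leading submatrices;
a flattening curve is the usual sampling-convergence diagnostic.

## Free-energy landscape and state segregation

The four state-vector features (D for each linkage class, R~ee~, N~HB~) are
z-scored by default before PCA: they carry incommensurate units, and
without scaling whichever feature has the largest numeric variance
(typically the hydrogen-bond count) dominates the projection. A
configuration flag restores raw-covariance PCA. Zero-variance columns
(e.g. N~HB~ in a waterless synthetic ensemble) keep scale 1 and pass
through harmlessly.

The free energy over the first two principal components is
$\Delta G = -k_B T \ln(P/P_{max})$ on a 50x50 histogram spanning the score
extent padded by 5%; the most probable bin sits at exactly 0, occupied
bins are non-negative, probabilities sum to 1 (all asserted on every run),
and empty bins are *undefined* — written as missing values, never as 0 or
infinity. Energies are reported in both k~B~T and kJ/mol
(k~B~ x 300 K = 2.494 kJ/mol); the temperature defaults to 300 K.

K-means uses Hartigan–Wong with 10 seeded restarts per candidate k; in
addition, each k is warm-started from the (k-1) solution's centres plus the
worst-fit point, and the better solution is kept, which makes the inertia
curve non-increasing in practice. The elbow is selected automatically at
the largest second difference of the inertia curve *relative to the local
inertia* (ties to the smaller k). The raw second difference — the textbook
rule — fails on strongly separated states: the first big split can carry a
larger absolute curvature than the true elbow, selecting k = 2 on a clean
four-blob layout, whereas the scale-invariant form selects k = 4 there and
k = 2 on genuine two-state data. The full inertia curve is returned and
exported so the automatic choice can always be overridden.

Representative structures are the member frames nearest (Euclidean, in PC
space) to each k-means centre; state reports give populations from label
counts, mean R~ee~ and N~HB~ with standard errors, and circular means of
(phi, psi) per linkage class.

## The synthetic generator: what it does and does not emulate

`sample_ensemble()` draws each frame's state from mixture weights, then
every linkage's (phi, psi) independently from a von Mises distribution
around the state's class means, and rebuilds coordinates on the rigid
geometry. The stock two-state conditions (`two_state_spec()`) are an
extended state centred on the reference torsions and a compact state whose
Linkage2 psi is rotated by -120 degrees (Linkage1 psi by -40), mixed
70/30 with concentration kappa = 20 (circular s.d. roughly 13 degrees).
This emulates the qualitative structure of atomistic GAG ensembles —
Linkage1 wobbling near linearity while Linkage2 splits into an extended
and a kinked population — and provides per-frame ground-truth labels.

What it does **not** emulate: excluded volume (no steric checks between
distant residues), correlated kinking at individual linkages (a state
shifts all linkages of a class coherently, so the compact state is far
more collapsed than real kinked chains), explicit water (hydrogen-bond
counts need externally supplied acceptor probes,
`place_hbond_probes()`), ion–chain energetics (ions are placed uniformly
or on geometric shells with no Boltzmann weighting), and any kinetics —
frames are i.i.d. Passing tests therefore demonstrate the *correctness of
the computations*, not that the generator reproduces real GAG physics.

Ion placement supports a uniform-bulk mode (an ideal-gas field whose RDF
must converge to 1 — a property test) and a shell mode that plants a g(r)
peak at a chosen radius, mimicking the 0.2–0.3 nm contact-ion-pair peak of
cation–carboxylate RDFs. The default box edge of 6.8 nm corresponds to a
solvated penta-disaccharide setup with at least 1.2 nm clearance; shell
radii beyond half the box are rejected to avoid periodic-image ambiguity.
Neutralizing cation counts equal the formal charge: 5 for the HA 5-mer,
10 for the sulphated 5-mers.

## Numerical choices and degenerate inputs

* Colinear torsion quadruples yield `NA`, not an arbitrary angle.
* Angles are reported in (-180, 180]; all distances in nm, energies in
  k~B~T and kJ/mol.
* The pairwise RMSD matrix refuses more than 2000 frames unless chunked
  mode is requested explicitly (a memory guard: the matrix is O(frames^2)).
* Identical seeds give bit-identical trajectories, ion placements, k-means
  labels and pipeline artifacts; the pipeline manifest hashes the
  scientific configuration (excluding the output location).
* PDB files are written in Angstrom with 3 decimals (0.1 pm), the package
  works in nm throughout; residue codes are mapped to 3-character aliases
  at the PDB boundary because the resName column cannot hold 4 characters.

## Problem sizes used in the shipped tests

The test-suite sizes were chosen to make the statistical checks sharp at
interactive cost: mixture-recovery runs use 5,000 frames (binomial s.e. of
a 70/30 split ~0.006, against a +/-0.03 acceptance band), ideal-gas RDF
checks use 1,000 ions over 50 frames with 0.05 nm bins (per-bin relative
s.e. of a few percent against a 3-s.e. band), clustering oracles use 200
random matrices of up to 50 frames, and pairwise-RMSD stages subsample a
few hundred frames.

## Known limitations

Rigid ring geometry (no pucker-driven kinks); a reduced atom model (no
apolar hydrogens, no acetyl tail, so absolute contact and hydrogen-bond
counts are not comparable to all-atom numbers); hydrogen-bond analysis
requires explicit acceptor coordinates when solvent is absent; the
synthetic generator is a statistical stand-in, not a physical model; and
the published per-state numerical values of atomistic GAG studies are not
reproducible from synthetic ensembles — the package reproduces the
*method*, with its own ground truth.
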