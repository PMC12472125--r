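---
title: "Coarse-grained RNA structure generation with graph diffusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained RNA structure generation with graph diffusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnadiff)
```

## The modelling problem

RNA function follows from three-dimensional structure, but experimentally
solved RNA structures are scarce and heavily biased toward ribosomal and
transfer RNA. `rnadiff` approaches structure prediction at the level of
*local 3D descriptors* — small substructures around a central residue that
recur across non-homologous molecules — and generates their coordinates with
a denoising diffusion model over a per-atom interaction graph. The user
supplies a sequence and a canonical (Watson–Crick–Franklin, WCF) secondary
structure in dot-bracket notation; the model generates coordinates that
respect those constraints.

The pipeline has five stages, each an exported module:

1. **Structure I/O and coarse-graining** (`read_pdb`, `coarse_grain`,
   `parse_dotbracket`, `center_and_scale`).
2. **Descriptor extraction and curation** (`extract_descriptors`,
   `curate_dataset`, `partition_by_family`).
3. **Graph construction** (`build_static_edges`, `build_dynamic_edges`,
   `edge_geometry`, `basis_expand`, `assemble_graph`).
4. **Diffusion model** (`make_schedule`, `forward_sample`, `train_denoiser`,
   `sample_structure`) with the graph/transformer denoiser
   (`init_denoiser`, `predict_noise`).
5. **Evaluation** (`kabsch_rmsd`, `ermsd`, `annotate_wcf_pairs`,
   `inf_score`, `evaluate_structures`).

## Coarse-grained representation

Each residue is reduced to five atoms: the backbone P and C4′ plus a base
triangle — N9–C2–C6 for purines, N1–C2–C4 for pyrimidines. The triangle
fixes base orientation (and hence pairing geometry) while keeping the atom
count low. A 5′-terminal residue without a phosphate keeps four atoms.
Before diffusion, every structure is centered at the origin and its
coordinates are divided by 10, so typical atom positions fall in roughly
\[−5, 5\] — the range a unit-variance Gaussian prior covers. The divisor and
the centroid are recorded on the structure, making the transform exactly
invertible; files written with `write_pdb()` are always in plain Ångström.
(The direction of the factor-of-10 rescaling is a design decision: dividing,
rather than multiplying, is what matches a unit-variance prior.)

## Local 3D descriptors

For a chain of N residues, every residue from the 3rd to the (N−2)th in turn
becomes a *central residue* (N−4 per chain). All residues whose C5′ atom
lies within a threshold T of the central C5′ are *in contact*; the default
T = 16 Å covers the C5′–C5′ span of canonical and non-canonical base pairs.
Central and in-contact residues are extended by two flanking residues on
each side (truncated at chain termini) and overlapping extensions merge into
maximal contiguous *segments*, so an isolated contact interior to its chain
always produces a 5-residue segment. Extraction runs on full-atom input —
the coarse model deliberately lacks C5′.

Curation applies, in order: removal of unfolded single-strand fragments
(single-segment descriptors in which the geometric pair annotator finds no
canonical pair — our operationalisation of "unfolded"), removal of
descriptors with more than three segments, greedy sequence-identity
deduplication at 80% (global alignment, match 1 / mismatch 0 / gap −1,
identity normalised by alignment length), and greedy structural
deduplication. Two descriptors are structurally redundant when all four
criteria hold: central elements within 2.5 Å; some duplex (central element
plus one matched segment) within 4 Å — treated as vacuously satisfied for
single-segment descriptors; element coverage above 1/2 and residue coverage
above 2/3; overall alignment RMSD within 3.5 Å. Segment matching solves a
linear assignment problem (a Hungarian solver written for this package,
O(n³)) augmented with dummy rows and columns priced at the duplex threshold,
so segments may stay unmatched — a partial alignment. Greedy deduplication
keeps the first representative in input order; the scan order is
deterministic because no selection rule beyond "keep one representative" is
defined for this step.

Rfam family *assignment* is out of scope: `partition_by_family()` consumes
externally supplied labels and sends the ribosomal/transfer families to the
training split and everything else to the test split.

## Graph construction

Nodes are atoms, in structure order. Node features: a one-hot over the atom
element (C, P, N), a C4′ flag, a one-hot over the residue type, a
256-dimensional per-residue sequence embedding shared by all atoms of the
residue, and a 16-dimensional sinusoidal time embedding.

Edges come in four classes:

* **covalent** (static): the five intraresidue bonds (four at a 5′
  terminus) plus the backbone link C4′(i)–P(i+1);
* **pairing** (static): per WCF constraint, anchor–anchor and C2–C2 edges.
  Two edges pin both the distance and the relative twist of the pair; the
  choice of endpoints is ours, since only "base–base edges" are prescribed;
* **local** (dynamic): non-static atom pairs within 5 Å;
* **global** (dynamic): non-static pairs in (5, 16] Å.

The two dynamic classes are disjoint (avoiding duplicate messages), and
each atom keeps at most 20 dynamic neighbours per class: candidate edges
are accepted in increasing distance order (ties broken by atom index) while
both endpoints are below the cap, which bounds every degree by construction.
Dynamic edges are rebuilt from the *current* coordinates at every diffusion
step — during training these are the noisy coordinates, matching inference
where only noise exists at the start. With six message-passing blocks the
maximal signal-propagation distance is therefore 6 × 5 = 30 Å through local
edges and 6 × 16 = 96 Å through global ones.

Close-contact edges (covalent, pairing, local) carry geometric features:
the distance d, one-hop angles θ between the edge and each other edge at
its source, and two-hop angles ϕ against edges one step further out (a
planar-angle convention, chosen where a torsion-like alternative would also
be defensible; the featuriser consumes d and θ). Distances are expanded in
16 sine-Bessel radial basis functions under a smooth cosine envelope that
vanishes at the class cutoff; angles in 7 Legendre harmonics whose products
with the radial basis form the spherical feature block (mean-pooled over a
source's neighbours). Static close edges use the 16 Å envelope so that
their features stay informative when noise stretches them; dynamic local
edges use the 5 Å envelope. Geometry is always computed in unscaled
Ångström; the ÷10 scaling applies only to the coordinates entering the
denoiser.

## Sequence embeddings

An external RNA language model can be registered as an embedding provider
(`register_embedding_provider()`); the package itself ships a deterministic
fallback: four seeded base vectors pushed through the projection head
(bias-free linear to 1280 units, ReLU, linear to 256). Multi-segment inputs
are concatenated into one string with no separator before embedding — kept
deliberately, with the known caveat that junction positions see spurious
sequence neighbours. The fallback embedding of a position depends only on
its base identity; a contextual model would add positional information, and
this difference matters for the overfitting experiments discussed below.
Swapping providers changes feature values only, never shapes or topology.

## The diffusion model

The forward process is a standard DDPM: `x_t = √ᾱ_t x0 + √(1−ᾱ_t) ε` with a
linear β schedule. β endpoints are not fixed a priori; we take the classic
(1e-4, 0.02) pair rescaled by 1000/T, which preserves the schedule's total
corruption for any step count — T = 5000 (the full-scale setting) gives
(2e-5, 4e-3), the desk-scale T = 200 gives (5e-4, 0.1), and in both cases
ᾱ_T < 1e-3, so the terminal marginal is indistinguishable from white noise.
Only coordinates are noised; atom identities, features and the static graph
are preserved throughout.

The denoiser is trained with the ε-prediction objective,
`MSE(ε, ε̂(x_t, t))`, with t uniform per item, gradient clipping at global
norm 2, and Adam. The full-scale learning-rate schedule (0.003 decayed by
0.9 every 30 epochs) is the default `training_state()`; desk-scale overfit
runs use a constant or stepwise-halved rate around 2e-3, which we found
necessary for convergence at tiny batch sizes.

Internally, the noise head is parametrised through a clean-coordinate
estimate: the network emits x̂0 (a per-atom 3-vector head plus a time-gated
skip from the input coordinates) and ε̂ follows analytically as
`(x_t − √ᾱ x̂0)/√(1−ᾱ)`. The two parametrisations are mathematically
equivalent; the x̂0 form keeps the regression target bounded at every step
and implicitly up-weights the low-noise steps, which materially improves
desk-scale convergence.

Ancestral sampling uses the standard posterior mean with variance β̃_t and
no noise at t = 1. Sampling from a Vienna-format input builds the atom
template from sequence + secondary structure, draws coordinates from
N(0, I), and runs T reverse steps, rebuilding dynamic edges from the
current coordinates before every model call. The primary correctness oracle
is exact: substituting the true conditional noise for the model inverts any
forward trajectory to machine precision, because the t = 1 posterior
collapses onto x0.

## The denoiser network

Stages: (1) a coordinate encoder — linear, row layer-norm, sigmoid — to 256
dimensions (64 in the tiny config); (2) B message-passing blocks, each with
a local branch aggregating over covalent/pairing/local edges with
radial+spherical features and a global branch aggregating over global edges
with radial features, fused per node by a two-way softmax attention with a
residual connection; (3) a pre-norm transformer encoder with full
self-attention over all atoms (no masking, no positional encoding — an
intentional simplification where a point-attention design would also fit);
(4) per-atom heads for the noise and for atom/residue-type logits. The type
logits are produced but carry no weight in the default loss. There is no
pooling anywhere; the network is permutation-equivariant and deliberately
*not* SE(3)-equivariant — centering provides partial translation
normalisation, and equivariant layers are future work.

The training loop runs on a compiled (RcppArmadillo) fused forward/backward
kernel; a pure-R reverse-mode tape implements the same network and serves
as the reference: the test suite checks both paths agree to machine
precision, and checks the tape itself against numerical differentiation.

Full-scale configuration: 6 blocks, hidden 256, 6 transformer layers, 8
heads. Desk-scale (`denoiser_config_tiny()`): 2 blocks, hidden 64, 4
transformer layers, 4 heads — small enough to train on a CPU in minutes.

## Evaluation metrics

* **RMSD** after optimal least-squares (Kabsch) superposition; a raw,
  unsuperposed variant is exposed because the plain formula contains no
  fit, but superposition is the default since that is how the quantity is
  used in practice.
* **eRMSD**: each ordered base pair (i, j) is described by base j's
  position in base i's frame, rescaled anisotropically (5 Å in-plane, 3 Å
  normal) and mapped through the smooth indicator G that vanishes beyond a
  rescaled distance of 2.4; the eRMSD is the root mean square of G
  differences normalised by residue count. The constants and G come from
  the published eRMSD definition and are validated against an independent
  implementation in the tests; values below 0.7 are conventionally read as
  native-like. Base frames are built from the coarse triangle (anchor, C2,
  C4/C6), so the metric runs on coarse-grained models directly.
* **INF** (Interaction Network Fidelity): the geometric mean of precision
  and recall over base-pair sets, here with the conventions that two empty
  sets score 1 and exactly one empty set scores 0. Canonical pairs for
  INF(WCF) come from the package's geometric annotator
  (`annotate_wcf_pairs`): complementary bases (G–U wobble counts as
  canonical by default), anchor–anchor distance in \[7.5, 10.5\] Å, C2–C2
  distance in \[4.5, 7.5\] Å, base planes within 35°, greedily resolved by
  closeness to ideal pair geometry with each residue in at most one pair.
  Non-canonical annotation is out of scope; INF(NWC) is reported only when
  externally computed pair sets are supplied.

## Synthetic fixtures

`make_helix()`, `make_hairpin()` and `make_multisegment_fixture()` build
idealized A-form-like geometry: 32.7° twist, 2.81 Å rise, and a per-residue
atom template (including C5′ and N3 beyond the coarse five, so descriptor
extraction and pair annotation run without full-atom libraries) whose
paired-base geometry sits at the centre of the annotator's acceptance
windows. The generator and the annotator are calibration-locked: at zero
perturbation the annotator recovers exactly the constructed pair set, which
the tests assert for all three fixture families. The fixtures emulate the
geometry the model consumes — helical stems, loops with continuous
backbones, multi-strand contacts — but not crystallographic detail,
sequence-dependent helical parameters, or thermodynamics; passing tests
demonstrate pipeline correctness on clean geometry, not predictive accuracy
on real RNA.

## Problem sizes, numerical choices, limitations

The test and acceptance runs use desk-scale sizes chosen to exercise every
code path on a single CPU: fixtures of 9–30 residues, T = 200 diffusion
steps, the tiny denoiser, a 26000-step overfit run on one 12-nt hairpin
(batch 2, learning rate 2e-3 halved every 5000 steps, an exponential
moving average of the weights kept for sampling), and Monte-Carlo
checks with 10⁴ scalar draws. The full-scale configuration (T = 5000,
6 blocks, hidden 256, batch 128, 800 epochs) is expressible through the
same configs but is not run here.

Degenerate inputs are handled explicitly: single-atom structures can be
centered; empty descriptor sets curate to empty; a node without edges
passes through a message block as a node-wise transform; coincident atoms
on an edge raise an error rather than producing NaN geometry; distances at
or beyond a basis cutoff produce exactly zero feature rows.

Known limitations. The fallback embedding is positionally blind, so atoms
of same-base residues are distinguishable only through graph context and
coordinates; overfit recovery would be easier with a contextual language
model. The denoiser is not rotation-equivariant, so models memorise the
training pose. Identity deduplication before structural deduplication
follows the listed order of the filters, and both scans are greedy — a
clustering formulation could keep different representatives. The merged
segment embedding sees spurious junction neighbours. Finally, the overfit
experiment operates at the edge of what a 137k-parameter network trained
for minutes on a CPU can do; its loss threshold is the hardest target in
the acceptance suite.
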