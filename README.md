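# rnadiff

Coarse-grained RNA 3D structure generation with graph neural networks and
denoising diffusion, in R.

## The problem

RNA function is tied to 3D structure, but solved RNA structures are scarce
and dominated by two families (rRNA, tRNA), which makes sequence-homology
methods fragile on everything else. `rnadiff` works at the level of **local
3D RNA descriptors** — substructures around a central residue that recur
even across non-homologous molecules — and learns **interatomic
interactions** directly: the molecule is a graph over a five-atom-per-residue
coarse representation (backbone P and C4′ plus the base triangle N9–C2–C6
for purines, N1–C2–C4 for pyrimidines), and a denoising diffusion
probabilistic model (DDPM) generates atom coordinates conditioned on the
user's sequence and canonical (Watson–Crick–Franklin) secondary structure
given in Vienna dot-bracket text.

The package is aimed at structural bioinformaticians who want a fully
inspectable, desk-scale implementation of this modelling stack: every stage
— descriptor extraction and curation, graph construction, diffusion
training, sampling, evaluation — is an exported, documented, tested R
function, and synthetic A-form fixtures let the whole pipeline run in
minutes with no downloads.

## The model in brief

*Forward process.* Scaled, centered coordinates are corrupted over T steps,
`x_t = √ᾱ_t x0 + √(1−ᾱ_t) ε`, with a linear β schedule chosen so that
ᾱ_T < 10⁻³ (white noise at the end). Only coordinates are noised; the
atom/residue identities and the static graph (covalent bonds + user pairing
constraints) are preserved.

*Denoiser.* Node features (atom one-hot, C4′ flag, residue one-hot, 256-d
per-residue sequence embedding, 16-d time embedding) enter a stack of
message-passing blocks, each with a local branch (covalent/pairing/≤5 Å
edges, radial Bessel + spherical-harmonic edge features) and a global
branch (5–16 Å edges, radial features), fused by learned attention; a
transformer encoder with full self-attention over atoms refines the states;
per-atom heads predict the noise ε̂. Training minimises `MSE(ε, ε̂)` with
uniform t, gradient clipping at 2, and Adam. Dynamic edges are rebuilt from
the current (noisy) coordinates at every step; each atom keeps at most 20
dynamic neighbours per class, so with 6 blocks information propagates at
most 30 Å through local edges and 96 Å through long-range ones.

*Evaluation.* Superposed RMSD (Kabsch), eRMSD (base-frame distances through
the smooth indicator G), and Interaction Network Fidelity
`INF = √(precision × recall)` over canonical base-pair sets from the
package's geometric pair annotator.

## Worked example

Build a hairpin fixture, train the tiny denoiser on it, sample a structure
from noise, and score it against the reference:

```r
library(rnadiff)

hp    <- make_hairpin(4, 4)            # 12-nt hairpin, 4 bp stem
inst  <- prepare_instance(hp$structure, hp$ss)
sched <- make_schedule(diffusion_config(T = 200))

model <- init_denoiser(denoiser_config_tiny(), seed = 1)
tr <- train_denoiser(model, list(inst), sched, steps = 8000,
                     state = training_state(lr = 2e-3, lr_decay = 0.5,
                                            decay_every = 3500, clip = 2,
                                            batch_size = 2),
                     seed = 11, log_every = 2000)
print(tr$log)
#>   step       loss    lr
#> 1 2000 0.59212415 2e-03
#> 2 4000 0.09486005 1e-03
#> 3 6000 0.04338159 1e-03
#> 4 8000 0.03379654 5e-04

samp <- sample_structure(tr$ema_model, NULL, hp$ss, sched, seed = 3,
                         instance = inst)
ref  <- coarse_grain(hp$structure)
kabsch_rmsd(samp, ref, atoms = "C4'")
#> [1] 0.128596
print(evaluate_structures(samp, ref))
#> RMSD 2.003 A | eRMSD 2.290 | INF(WCF) 0.707 | INF(NWC) n/a
#> pair confusion: TP 2 FP 0 FN 2
```

The training loss is the ε-prediction mean squared error (1.0 ≈ an
untrained model); after this ~4-minute demonstration run the regenerated
backbone lies within 0.13 Å C4′-RMSD of the training fixture. The all-atom
RMSD (2.0 Å) and the partial pair recovery (the strict geometric annotator
accepts 2 of the 4 stem pairs in the sampled geometry) show that base
placement converges more slowly than the backbone; the longer runs used in
the acceptance suite (26k steps) sharpen both. `INF(NWC)` is undefined here
because non-canonical annotation requires externally supplied pair sets.

A shell interface wraps the same functions
(`synth | extract | curate | graph-dump | train | predict | evaluate`):

```sh
rnadiff synth  --type hairpin --stem 4 --loop 4 --out fix/
rnadiff extract --pdb fix/fixture.pdb --out descs/
rnadiff train  --pdb fix/fixture.pdb --dbn fix/fixture.dbn --steps 8000 --out run/
rnadiff predict --dbn fix/fixture.dbn --checkpoint run/checkpoint.rds --out pred/
rnadiff evaluate --pred pred/prediction.pdb --ref fix/fixture.pdb --out eval/
```

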