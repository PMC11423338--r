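---
title: "Conditional molecule generation from interaction energy vectors"
author: "ievgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional molecule generation from interaction energy vectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ievgen)
```

## The problem

Structure-based de novo design asks for molecules that *bind a given
protein the way a known ligand does* while being structurally different
from it. Interaction fingerprints (bit vectors marking the presence of a
contact per residue) capture the binding mode only coarsely; an
**interaction energy vector (IEV)** refines this by recording, for every
residue of the binding pocket, the *strength* of three interaction
channels — van der Waals, Coulomb and hydrogen bonding — between the
docked ligand and that residue, in kcal/mol. For a pocket of $R$ residues
the IEV has exactly $3R$ entries, laid out as one `(vdw, coulomb, hbond)`
triplet per residue, residues ordered by their number in the protein's PDB
file.

`ievgen` implements the full pipeline: computing IEVs from a pose and a
pocket, learning a generative model of SMILES strings, learning a
generative model of IEVs, fusing the two latent spaces, and sampling new
molecules conditioned on a target IEV, plus the evaluation metrics used in
this corner of generative chemistry.

## The energy model

The original IEV descriptor is computed inside a commercial docking engine
whose functional forms are proprietary. `ievgen` substitutes an open,
standard nonbonded model, exposed behind the same vector layout:

* **van der Waals**: Lennard-Jones 12-6,
  $4\epsilon_{ij}\!\left[(\sigma_{ij}/r)^{12}-(\sigma_{ij}/r)^{6}\right]$,
  with Lorentz–Berthelot combining rules
  ($\epsilon_{ij}=\sqrt{\epsilon_i\epsilon_j}$,
  $\sigma_{ij}=(\sigma_i+\sigma_j)/2$) and a small per-element parameter
  table (overridable via `defaultEnergyParams()`).
* **Coulomb**: $k\,q_iq_j/(D\,r)$ with
  $k = 332.0636\ \mathrm{kcal\,\mathring{A}/(mol\,e^2)}$ and a
  distance-dependent dielectric $D = r$ by default (a common implicit
  screening choice; a constant dielectric is available in the parameter
  list).
* **Hydrogen bonds**: a 12-10 potential
  $\epsilon_{hb}\!\left[5(r_0/r)^{12}-6(r_0/r)^{10}\right]$
  ($\epsilon_{hb} = 1$ kcal/mol, $r_0 = 1.9$ Å) applied only to
  donor-hydrogen/acceptor pairs within 3.5 Å whose donor–H···acceptor
  angle is at least 120°; everything else contributes zero to this
  channel.

Atom pairs closer than 0.1 Å are clamped to 0.1 Å with a warning — this
only happens for degenerate poses, and clamping keeps batch jobs running.
Per-residue energies are the sums of the pairwise terms over all (ligand
atom, residue atom) pairs; the implementation is vectorized, and the test
suite checks it against a literal scalar double loop to $10^{-9}$.

Users with access to a docking engine that exports per-residue interaction
energies can bypass the open backend entirely: `readIevTable()` ingests a
CSV whose header spells out the `<residue>_<term>` layout, and every
downstream stage works unchanged. The per-residue triplet (interleaved)
layout was chosen over three residue-ordered blocks; the CSV schema makes
the choice explicit, so external tables can be permuted to match.

Pocket membership uses the *any heavy atom within radius* rule (default
12 Å of the grid center, typically the cocrystal ligand centroid); a
C$_\alpha$-based rule is available by argument. Waters, ions and hetero
residues are excluded by default. Protein partial charges come from a
small per-element table; ligand charges from a damped
electronegativity-equalization pass over the molecular graph (a
Gasteiger-type scheme, deterministic and dependency-free).

## The generative model

Three modules are trained in sequence:

1. **SMILES-VAE** — a variational autoencoder over tokenized SMILES.
   The encoder is a bidirectional GRU whose final states feed two linear
   heads producing the mean and log-variance of a 128-dimensional diagonal
   Gaussian; the decoder is a 3-layer GRU with dropout, conditioned on the
   latent both through its initial hidden state and by concatenating the
   latent to every input token embedding. The loss is the teacher-forced
   token cross-entropy (summed per sequence, averaged over the batch) plus
   $\alpha\,\mathrm{KL}(q\|N(0,I))$, with
   $\mathrm{KL} = \tfrac12\sum_d(\mu_d^2+\sigma_d^2-1-\ln\sigma_d^2)$.
   $\alpha$ is annealed linearly from 0 — the standard remedy against
   posterior collapse — at 5e-3 per epoch under the reference 100-epoch
   schedule, uncapped. Training uses Adam at a fixed 3e-4 with batch 512
   by default.
2. **IEV-VAE** — a VAE over IEVs with a convolutional front end (two
   1-d conv blocks, 32 then 64 channels, kernel 5, batch normalization
   with $\epsilon=10^{-5}$, ReLU/SELU activations with the original SELU
   constants, dropout 0.1), a fully connected stage, and a 56-dimensional
   latent; the decoder is a fully connected SELU stack. The objective is
   the *unweighted* sum of an L1 reconstruction loss (summed over
   dimensions, averaged over the batch) and the same closed-form KL.
   Adam's learning rate starts at 1e-3 and is multiplied by 0.9 every
   2000 batches.
3. **Fusion network ("Z-DNN") and end-to-end fine-tuning** — three fully
   connected layers (184 → 256 → 192 → 128, ReLU between layers) mapping
   the concatenated latents back into the SMILES latent space, so the
   output is directly decodable. During end-to-end training the SMILES
   encoder and the whole IEV-VAE are frozen (verified bit-exactly via
   parameter digests); only the decoder and fusion weights train, under
   the reconstruction cross-entropy alone, with learning rate
   1e-4 × 0.8^⌊epoch/20⌋. The latents fed to the fusion network are
   reparameterized samples from the frozen posteriors rather than their
   means — mirroring generation-time stochasticity; `useMean = TRUE`
   switches to the means. (Whether the original model feeds means or
   samples is not documented; samples were chosen because generation
   always sees stochastic latents.)

Generation conditioned on a target IEV repeats, per sample: encode the
target IEV and draw a latent from its posterior; draw a fresh
128-dimensional standard normal; concatenate, map through the fusion
network, and decode (multinomial token sampling by default, greedy by
flag). Invalid SMILES are kept and flagged so validity statistics refer to
all requested samples.

### Numerical machinery

No deep-learning framework is available to R in this package's dependency
footprint, so `ievgen` ships its own reverse-mode automatic
differentiation over matrix operations (a small tape), with the GRU
recurrence and the Adam update implemented as compiled kernels
(`src/nn_kernels.cpp`). Analytic gradients are validated against central
finite differences in the test suite, and the fused GRU layer against the
same check. Weights are initialized uniformly in
$[-1/\sqrt{H}, 1/\sqrt{H}]$; all randomness (initialization, shuffling,
reparameterization draws, dropout, token sampling) flows from the seed
arguments.

### Scaled training runs

The package's tests and acceptance script train at *fixture scale*: a
50–120 molecule fragment-grammar corpus, pockets of 3–8 residues, hidden
widths of 24–128, and a few thousand optimizer steps — sizes chosen so
the complete pipeline trains in minutes on one CPU while still exercising
every architectural element at the reference dimensionalities that matter
(128-d SMILES latent, 56-d IEV latent, 3 decoder layers, 3 fusion
layers). Two schedule knobs deserve comment:

* The KL weight is annealed so that it traverses the *same trajectory
  relative to training progress* as the reference schedule, which reaches
  $\alpha = 0.5$ at the end of its 100-epoch run: a scaled run of $E$
  epochs uses `klAnnealRate = 0.5/E`. Keeping the literal 5e-3-per-epoch
  increment while multiplying the epoch count would raise the final KL
  weight several-fold and change the optimum being approached, which is
  not what a capacity check is after. The 5e-3 default is untouched;
  schedule exactness ($\alpha(e) = \texttt{klInit} + e\cdot\texttt{rate}$,
  logged per epoch) is asserted in the tests at the default rate.
* Batch sizes are reduced (so that a small corpus still yields enough
  optimizer steps per epoch) rather than epoch counts alone being
  inflated.

## The synthetic fixtures

Real training data for this model would be docking-derived IEVs for
thousands of actives — unavailable offline and dependent on commercial
software. The fixtures module instead *plants* a structure→interaction
relationship that the fusion model can be tested against end to end:

* `makeToyCorpus()` assembles short molecules from a ~20-fragment grammar
  (heteroatom backbones; halogen, nitrile, phenyl, carboxyl, alkyl
  branches), canonicalized and deduplicated. Small vocabulary and short
  sequences keep the desk-scale SMILES-VAE in its memorization regime.
* `makeToyPocket()` places small backbone-fragment residues (N, CA, C=O
  plus an amide hydrogen donor) on a 4–10 Å shell around the grid center;
  coordinates are rounded to 0.001 Å so the pocket round-trips a PDB
  write/read bit-exactly.
* `placePose()` embeds a molecule with a *canonical* internal 3-D layout:
  breadth-first placement at standard bond lengths over a fixed
  clash-avoiding direction set, so the conformation is a pure function of
  the molecular graph (the seed only adds 0.05 Å of coordinate jitter).
  The pose is then selected the way docking pipelines keep the
  best-scored pose: a fixed set of rigid orientations and small (≤1.5 Å)
  translations of the conformer is scored with the package's energy
  backend and the lowest-energy candidate wins. This makes the IEV an
  energy-driven deterministic function of structure — similar molecules
  receive similar poses and hence correlated IEVs — without claiming
  physical realism beyond that.
* `makePairedDataset()` computes each molecule's IEV from its pose and
  adds i.i.d. Gaussian noise (default sd 0.1 kcal/mol) emulating docking
  noise. Because the pose, charges and H-bond roles are functions of the
  molecular graph, structurally similar molecules receive correlated
  IEVs — the planted signal; a property test verifies that the
  most-similar tenth of molecule pairs (by fingerprint Tanimoto) has
  higher median IEV cosine than the least-similar tenth.

What passing fixture-scale tests shows: the descriptor algebra, the
training contracts (schedules, frozen weights, loss decompositions), and
that the fused model extracts a real conditioning signal from IEVs — its
samples' recomputed interaction profiles track the target better than
random training molecules do. What it does not show: generalization on
real chemistry, docking-quality poses, or the headline numbers of
GPU-scale training on ~10^6 compounds; those require the commercial
docking stack and are out of scope by design.

## Evaluation metrics

For a generated set against its seed compound the package reports:
validity (% of requested samples that parse — a purpose-built SMILES
parser with valence checking does the judging, since lenient toolkits
quietly repair malformed strings); uniqueness (fraction of valid samples
with distinct canonical SMILES); internal diversity
$1-\mathrm{mean}_{(m_1,m_2)\in G\times G}\,T(m_1,m_2)^p$ with $p=1$,
self-pairs included (the MOSES convention; a flag excludes them); and the
three interaction-retention counts — IEV computable, IEV cosine ≥ 0.7,
and additionally Tanimoto ≤ 0.5 (thresholds are arguments). Tanimoto is
computed as $t/(S-f)$ over S-bit circular fingerprints; the tests verify
the algebraic identity with the $t/(a+b-t)$ intersection-over-union form.
The circular fingerprint (radius 2, 1024/2048 bits) is the package's own
Morgan-style implementation — deterministic and fixed-length, but its bit
positions are not interchangeable with other toolkits' ECFP bits; all
metrics here only compare fingerprints with each other. QED and logP come
from RDKit through the system `python`, the toolkit conventionally used
for those descriptors; chemical-space maps are the first two principal
components of the fingerprint matrix.

"Able to dock" is reinterpreted as "an IEV could be obtained" (from the
open backend or a user-supplied table), since docking itself is out of
scope.

## Degenerate inputs and tie-breaking

* K-means splitting uses a fixed seed with 10 restarts;
  nearest-to-centroid ties break to the lowest record index.
* Largest-component ties keep the first component; unparseable components
  are ignored, and a fully unparseable SMILES propagates as `NA` rather
  than an error.
* Zero IEVs have no direction: cosine similarity returns `NA` with a
  warning instead of inventing a value.
* Batch normalization refuses training batches of one; epoch-final ragged
  batches of one are dropped.
* Generation that never emits the end token truncates at `maxLength` and
  flags the sample.

## Known limitations

* The energy backend is a generic nonbonded model: IEVs are comparable
  *within* this package (or within any one imported table), not across
  backends.
* SMILES parsing covers the organic subset plus bracket atoms, charges,
  aromatic notation and ring closures; exotic features (polymers,
  extended stereo) are rejected as invalid, which is conservative for
  validity statistics.
* Poses are schematic; hydrogen-bond geometry in fixture poses is only as
  good as the deterministic layout.
* The conditioning signal at fixture scale is composition-dominated;
  claims about pose-specific selectivity would need real docking data.
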