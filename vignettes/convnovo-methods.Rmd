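---
title: "Methods: de novo peptide sequencing with dilated convolutional networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: de novo peptide sequencing with dilated convolutional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

De novo peptide sequencing infers a peptide's amino-acid sequence directly
from its tandem mass spectrum, without a protein sequence database. In
higher-energy collisional dissociation (HCD) the peptide backbone fragments
mostly into b-ions (N-terminal prefixes) and y-ions (C-terminal suffixes);
consecutive ions in either series differ by exactly one residue mass, so in
principle the sequence can be read off the "mass ladder". In practice ions
are missing (b1/b2 almost always), intensities vary over orders of
magnitude, and noise peaks abound, which is why modern tools learn the
mapping from spectrum to sequence from data.

`convnovo` implements a fully convolutional formulation of this task: the
spectrum is encoded as a fixed-length multi-channel vector and mapped by a
stack of dilated temporal-convolution (TCN) blocks to a 32-position x
23-class probability matrix, from which the peptide is decoded greedily and
then reconciled with the measured precursor mass.

## Spectrum encoding

A peak list is binned into half-open bins `[i*w, (i+1)*w)` with width `w`
(0.1 Th by default over 0--2000 Th, i.e. 20,000 bins, zero-padded to 20,480
so that five successive halvings remain integral). Peaks sharing a bin keep
the maximum (a sum option exists); the vector is normalized by its largest
entry, so channel 1 lies in [0, 1] with maximum exactly 1 for any non-empty
spectrum. Peaks within ±1.5 Th of the precursor m/z are removed first (the
default window covers the isotopic envelope; the removal itself is standard
practice because the unfragmented precursor carries no sequence
information).

Channel 2 carries the bin-center m/z scaled by `mz_max` and then damped to
`[0, 0.1]`. The damping is a numerical-conditioning choice we made after
measuring activation statistics: the m/z ramp is dense and identical across
spectra, while the informative intensity channel is sparse; at equal
amplitude the static ramp dominates the variance that the network's layer
normalizations divide by, and in controlled memorization runs (200 spectra,
same seeds) the training plateau lasted roughly twice as long at amplitude
1.0 as at 0.1. Channels 3 and 4 are channels 1 and 2 reversed along the bin
axis, giving the convolutions aligned views from both spectrum ends.

A 10-element meta vector (charge one-hot over 1..8, precursor m/z scaled by
`mz_max`, normalized collision energy / 100 or 0 when unknown) accompanies
the matrix.

## Network

Five TCN blocks process the input at successively halved resolution (max
pooling, factor 2), with the channel plan [192, 288, 384, 576, 768] — each
block roughly 1.5x wider than the previous one, compensating the halved
resolution. One block holds `n` dilated levels (dilation 1, 2, ..., 2^(n-1),
default n = 5); a level is two symmetric (non-causal) convolutions of width
`k = 5`, each followed by channel-wise layer normalization and ReLU, wrapped
in a residual connection. The receptive field of a block is therefore

```
RF = 1 + 2 * (k - 1) * (2^n - 1)
```

bins, which the test suite verifies empirically by measuring the width of
the nonzero gradient support of a probe block. Convolutions are non-causal
because a spectrum has no temporal direction.

**Fusion.** Each block's output is adaptively **max**-pooled to 32 steps,
linearly projected to a common width, and summed; two further convolutions
(width 9, the second with dilation 3, so their combined receptive field
covers all 32 steps) produce the fused feature tensor. Max pooling here is
a deliberate departure from the more common average pooling: peak-driven
activations are sparse along the m/z axis, and averaging 25-bin windows
attenuated them about an order of magnitude below the static activation
energy at initialization — with average pooling the desk-scale model could
not even memorize 200 training spectra, with max pooling it learns. The
block outputs at five resolutions give the decoder both local detail
(topmost block) and global context (bottom block).

**Decoder.** The meta vector passes through a linear layer with sigmoid and
is appended to the *flattened* fused tensor; 32 position-specific linear
maps then produce 23 logits each, and a softmax over classes yields the
32 x 23 probability matrix (20 residues, a start symbol reserved but never
a target, an end symbol, padding). Each output position reads the whole
fused representation rather than "its" pooled step: peptide position p has
no spatial correspondence with the p-th segment of the m/z axis, and wiring
position p only to step p left the decoder blind to the input in our
ablations.

**Auxiliary heads.** From the globally averaged fused tensor, five small
linear heads predict: tryptic C-terminus (binary), peptide length (30
classes), residue presence (20 binaries), length-normalized composition
(20 values), and adjacent residue pairs (400 binaries). These regularize
training; the length head in particular stabilizes the early epochs.

## Losses and training

The main loss is the masked cross-entropy — the mean negative log
probability of the target class over non-padding positions (residues plus
the end symbol). Added to it is `c * MAE`, where MAE is the absolute
difference between the true peptide mass and the *expected* mass under the
predicted distributions (`sum of p * residue_mass` over positions and
classes, plus water) — a differentiable surrogate that encourages
mass-consistent predictions without hard-constraining the decoder. The
weight `c` defaults to 1e-4, chosen so that `c * MAE` stays at or below 10%
of the total loss even early in training when the expected mass is far off;
a warning fires on logged batches if the cap is exceeded. Auxiliary tasks
use binary/categorical cross-entropy (MSE for composition) with default
weights 0.2 (0.05 for the single-unit tryptic head).

Training uses rectified Adam (plain Adam available) at learning rate 0.02,
batch size 32, with every random draw (weights, splits, batch order) under
one seed. Splits are peptide-disjoint: all spectra of one peptide land in
the same split, so validation measures generalization to unseen peptides,
not re-recognition of seen ones. The per-epoch validation metric is the
average argmax accuracy on non-padding positions, and the returned model
carries the weights of the best epoch.

The forward and backward passes are hand-written in C++ (RcppArmadillo,
float32, im2col-free tap-wise GEMMs). Backpropagation is verified in the
test suite by a directional finite-difference check (the derivative of the
loss along the full analytic gradient must equal the gradient's squared
norm) plus per-coordinate checks on head-adjacent parameters; float32
arithmetic and ReLU kinks make per-coordinate checks deep in the stack
noisy, which is why the directional form is the load-bearing assertion.

## Decoding, quality score, rescue

Positions are scanned left to right, emitting each column's argmax residue
(ties to the lowest class index) until the first column whose argmax is the
end symbol; a start/padding argmax before that is a decode failure, and a
missing end symbol truncates at 30 residues with a flag. The quality score
is the product of the emitted residues' probabilities (end excluded; empty
decode scores 0). If the decoded peptide's mass differs from the precursor
neutral mass by more than 10 ppm, each position in turn is substituted with
that column's second most probable residue; the first single-substitution
candidate within tolerance is reported with a `rescued` flag (scan order
and first-match-wins are declared tie-breaks; candidates never include the
special symbols, so rescue preserves length).

## The simulator

The synthetic generator emulates the features of HCD spectra the model
actually consumes: singly charged b/y ladders (doubly charged fragments for
3+ precursors), log-normal intensities with y-ions drawn weaker than
b-ions, strongly suppressed b1/b2 detection (0.2 by default; intermediate
for b3), a Poisson number (default mean 30) of uniform-m/z noise peaks
capped at a low quantile of the signal intensities, and a few ppm of
precursor m/z jitter (default 5, truncated at the bound). Defaults draw
tryptic-biased (90% C-terminal K/R) peptides of length 6--25 at charges
2+/3+. It deliberately omits neutral losses, isotope envelopes and internal
ions: its purpose is a learnable, verifiable stand-in whose
information-completeness we can prove (the test suite reconstructs peptides
from clean ladders with an independent greedy ladder reader), not physical
fidelity. Passing tests on synthetic data therefore demonstrate that the
pipeline can recover sequences when the ladder information is present at
realistic sparsity and noise — they do not certify accuracy on real
instrument data.

## Desk-scale recovery experiment

`desk_recovery_experiment()` is the package's end-to-end check, sized for
minutes on one CPU: 5,000 simulated spectra over the 8-residue alphabet
G, A, S, V, L, E, F, R (pairwise residue-mass gaps of at least 9 Da),
lengths 6--10, 2+ precursors, 50% tryptic, mild noise (internal-ion
detection 0.95, b1/b2 at 0.5, ~5 noise peaks, 2 ppm jitter); encoding at
2 Th per bin up to 1600 Th (800 bins — the coarse bins keep every residue
pair separable by more than 4 bins while cutting compute ~25x versus the
full-resolution geometry); a scale-0.1 model (channel plan [19, 29, 38,
58, 77], ~0.9M parameters); peptide-disjoint 85/5/10 split; 6 epochs at
learning rate 0.003 (the full-scale default of 0.02 assumes much larger
effective batches). These sizes are the package's choice of a desk-scale
working point; the full-resolution defaults remain available for real
data.

### What desk-scale training does and does not achieve

It is important to be explicit about what this experiment shows. The
pipeline runs end to end and every deterministic component is verified by
its own tests, but the *statistical* outcome at desk scale is weak: in our
runs the trained model learns peptide length and residue marginals
(validation argmax accuracy saturates around 0.3, driven largely by the
end-symbol position), while decoded peptides remain near-random. The
failure mode is instructive and reproducible. The network has ample
capacity to fit the training set — unregularized, the training
cross-entropy collapses within 10--20 epochs — but what it finds is
memorization of the few thousand training peptides, not the
translation-equivariant "two peaks separated by a residue mass" detectors
that generalize; the residue-presence auxiliary head, which needs exactly
those detectors, never beats its base rate. Regularization (decoder
dropout, decoupled weight decay, per-epoch augmentation with peak dropout
and intensity jitter) slows the memorization without redirecting it.
This is consistent with how the full-scale regime differs: roughly a
million unique training peptides make memorization impossible and force
the compositional solution, at a compute cost (tens of GPU-hours on a
~100x wider model) far outside a CPU session. The desk experiment is
therefore an end-to-end *mechanical* validation and an honest
characterization of small-data behaviour, not a demonstration of sequencing
accuracy.

## Numerical and degenerate-input conventions

* Empty spectra encode to the zero vector (no division by zero); empty
  decodes score 0; evaluation with an empty filtered set reports accuracy 0
  with an explicit `n_filtered = 0`; precision with no results above a
  threshold reports 1 with `n_above = 0`.
* Bin assignment is `floor(mz / w)` on 0-based half-open bins; peaks at or
  beyond `mz_max` are dropped.
* Ile and Leu share one monoisotopic mass; they remain distinct symbols but
  every accuracy metric collapses them.
* Positional accuracy uses the prefix-mass matching convention (residues
  match when equivalent and their N-terminal prefix masses agree within
  0.5 Da) so that a mass-preserving substitution de-synchronizes only
  locally; plain index matching is available behind a flag.
* Cysteine is used unmodified; fixed modifications are deferred.
* Layer-norm epsilon 1e-5; He-normal weight initialization; all arithmetic
  in the network is float32.

## Known limitations

* No post-translational modifications, a/c/x/z ions, neutral losses or
  isotope envelopes.
* Greedy decoding with single-substitution rescue only — no beam search or
  mass-constrained dynamic programming.
* Desk-scale training does not reach useful held-out sequencing accuracy
  (see above); training on large real spectral libraries at the full
  channel plan is the regime this architecture is designed for and is far
  beyond a single-CPU session.
* mzML support reads centroided MS2 scans through `mzR` and is intentionally
  thin; MGF is the canonical interchange format.
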