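---
title: "Learning electron densities from Patterson maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning electron densities from Patterson maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(patternet)
```

## The problem

A diffraction experiment on a crystal yields the amplitudes of the
structure factors `F(h,k,l)` but not their phases, and without phases the
electron density cannot be synthesized by the inverse Fourier transform
`rho = (1/V) * sum F * exp(-2*pi*i*(hx+ky+lz))`. The Patterson map — the
same synthesis with `|F|^2` in place of `F` — needs no phases and equals
the autocorrelation of the density. Its peaks are interatomic vectors: for
n atoms there are order n² peaks, which is why Patterson maps of anything
larger than a few atoms are uninterpretable by eye. `patternet` frames
Patterson interpretation as supervised learning: a convolutional network
is trained on pairs (Patterson map, density map) of small peptides so
that, at inference time, a density estimate is produced directly from a
phase-free input.

Three structural facts shape the whole design:

* **Translation invariance.** The Patterson map does not change when the
  cell contents are translated, so the mapping to a density is one-to-many
  along translation. Training targets are therefore centered by the
  molecule's center of mass, fixing the representative.
* **Centrosymmetric ambiguity.** A structure and its point-inverted twin
  have identical Patterson maps. For random point sets this ambiguity is
  unresolvable, but amino acids occur in a single enantiomer (L), so a
  network trained on peptides can learn the standard stereochemistry and
  pick one hand consistently. The synthetic generator fixes L chirality at
  every alpha carbon for exactly this reason, and `invert_atoms()` plus
  the twin tests keep the ambiguity measurable.
* **Periodicity.** Both maps live on the torus of the unit cell, which is
  why the network's first two phases use circular padding.

## The crystallographic core

All syntheses run on a periodic voxel grid (0-based indices, fractional
coordinate = index/count). Structure factors use point scatterers with
`f = Z` (the atomic number) and a global isotropic displacement factor
`g = exp(-B/(4 d^2))`, default `B = 15` Å², which suppresses
series-termination ripple at the working resolution of 1.5 Å. A
four-Gaussian form-factor table would change peak shapes slightly but
nothing in the learning problem, so the simpler model is used. `F(0,0,0)`
is excluded by default — experimental data lack it — making every density
zero-mean; a flag restores it for closed-form tests.

The conventions are fixed as: `+2*pi*i` in the forward (structure-factor)
direction, `-2*pi*i` in map synthesis, prefactor `1/V`; the resolution
boundary `d >= d_min` is inclusive; of each Friedel pair the
lexicographically larger index is stored and the conjugate mate is
restored at synthesis time. With these conventions the Patterson map
equals the circular autocorrelation of the band-limited density scaled by
`V / n_voxels` — an identity the test suite checks against a brute-force
spatial autocorrelation, with no FFT involved, on every run.

Grids derive from cell edge and spacing as `round(edge/spacing)` rounded
up to even (the network pools by 2), giving 40³ for 20 Å / 0.5 Å and 20³
for both 10 Å / 0.5 Å and 12 Å / 0.6 Å. Synthesis on a grid coarser than
`d_min/2` aliases and is refused by default.

## Data generation

Examples are dipeptides: either excised from user-supplied PDB files (two
sequence-adjacent residues, first altloc, hydrogens and HETATM records
dropped) or produced by the built-in conformer generator. The generator
builds heavy atoms from idealized internal coordinates (standard bond
lengths and angles, trans peptide bond), draws backbone φ/ψ uniformly from
two broad rectangles covering the α and β regions of the allowed map, and
side-chain torsions uniformly. It deliberately does not sample a
Ramachandran density or rotamer library: the tests need plausible,
diverse, seeded geometry, not conformational statistics. Consequences for
interpretation: passing tests show the pipeline and architecture work on
realistic peptide *geometry*; they say nothing about the conformational
*distribution* of real proteins, and desk-scale training sets are far too
small to support generalization claims.

The example pipeline is: center by mass → structure factors to 1.5 Å →
density and Patterson synthesis → per-map min-max normalization onto
[-1, 1]. Min-max was chosen over symmetric division by `max(abs(.))`
because the published procedure determines "maximum and minimum" per
tensor; the symmetric variant is available as `normalize_map(mode =
"maxabs")`. Constant maps normalize to zero rather than erroring so that
degenerate fixtures flow through. Examples whose molecule approaches a
periodic image closer than 2 Å (non-bonded contacts; bonded-range
contacts below 1.9 Å inside the molecule are chemistry, not clashes) are
rejected and regenerated — the published experiments report such
rejections without stating a threshold, so 2 Å, a typical van der Waals
contact floor, was fixed here once. Splits are assigned per source
structure, never per example, so no source leaks across train/validation;
the published "validation/test" sets are treated as a single held-out
split.

## The network

The U-net has three phases. *Encoding*: two 7³ convolutions
(1→23→25 channels in the baseline), each with batch normalization and
ReLU, then 2³ max pooling. *Learning Features*: seven residual blocks at
25 channels — 7³ conv+BN+ReLU, 7³ conv+BN, optional
squeeze-and-excitation gate (global average pool, bottleneck of half the
channels, sigmoid), skip addition, ReLU — then nearest-neighbour 2×
upsampling. *Decoding*: 5³ conv+BN+ReLU to 23 channels and a final 5³
convolution to one channel under tanh, matching the [-1, 1] targets.
Encoding and Learning Features convolutions use circular padding (the
input is periodic); Decoding uses zero padding, as only the first two
phases are specified periodic. Weights are He-normal, biases zero;
construction is seeded.

The published description names layers of 23 and 25 channels and seven
blocks but not the exact per-layer assignment; the widths above are a
reconstruction chosen so that two 7³ convolutions at 25 channels across
seven blocks dominate the budget, landing at 3,282,378 trainable scalars
— inside the stated "about three million". The enlarged variant for the
all-residue dataset (23→25, 25→30, eight blocks, SE gates) is
`model_config(enc_channels = c(25, 30), n_res_blocks = 8, use_se = TRUE,
dec_channels = 25)`.

There is no deep-learning framework in this stack, so the network is
implemented directly: im2col/col2im, pooling and upsampling as Rcpp
kernels, convolution as one GEMM per example through BLAS, batch
normalization (biased batch statistics for normalization, momentum-0.1
running averages for inference), and analytically derived backward passes
for every layer. The whole composition is verified against central finite
differences in the test suite; the check passes at relative error below
1e-6 for every sampled parameter, including SE and BN parameters and the
correlation loss term.

## Training

The loss is `MSE + w * (1 - PearsonCC)` with `w = 0.1` — the published
loss is "weighted heavily in favor of the MSE" without a printed value,
so a small fixed weight was chosen; `w = 0` recovers plain MSE exactly. A
constant target makes the correlation undefined; its term then
contributes zero with a warning. The learning rate follows
`base_lr * d1^min(e, p1) * d2^max(0, e - p1)`: the dialanine recipe is
(0.86, 12, 0.9991) under Adam for 1000 epochs at batch 146 accumulated ×3
(effective 438); the all-residue recipe is (0.91, 18, 0.9989) under AdamW
with weight decay 3e-2 (decoupled, applied to convolution/SE weight
tensors only) for 200 epochs at batch 58 accumulated ×16 (effective 928).
`base_lr` defaults to 1e-3: the original value came from a learning-rate
finder and is not reported, and a finder is out of scope. Batches must
share one grid shape — mixed-size datasets are rejected. The best
checkpoint is selected by validation median CC, the metric the published
tables report; whether model selection there used the combined or plain
loss is not stated, so the explicit CC criterion was adopted.

## Evaluation

`pearson_cc()` computes the product-moment correlation over the full maps
or over a centered cube (the enlarged-cell experiments correlate the
central 6 × 6 × 6 Å, since the rest is empty). `phase_error_by_shell()`
transforms both maps back to structure factors, wraps per-reflection
phase differences into [0°, 180°], and averages per shell of equal width
in 1/d² (20 shells by default), weighting by true amplitudes — the
convention of standard phase-matching tools; whether the published curves
are weighted is not stated, so an unweighted mode is a flag away. Because
the correlation is affine-invariant and phase error ignores any positive
scale, normalization never needs inverting. No origin or hand search is
applied before comparison: maps are centered by construction and the cell
is P1. This is a documented limitation — against predictions from any
other source, an origin search would be required first.

Two identities anchor the metrics: self-comparison gives CC = 1 and 0°
in every shell, and uniformly random phases give a mean absolute wrapped
error of 90° (the expectation of |wrap(Δφ)| under a uniform
distribution), which the suite verifies to ±2° on >2000 reflections.
The centrosymmetric twin satisfies Δφ = |wrap(−2φ)| per reflection —
the quantitative face of the inversion ambiguity.

## Desk-scale demonstration and problem sizes

The published headline numbers (median CC 0.93 / 0.98 / 0.87 at median
phase errors 52° / 25° / 64°) come from training 3–5 M-parameter models
on 28k–424k PDB-derived examples on a GPU. That experiment is
reproducible here in code but not in compute, so the package's own
demonstration of the learning claim is deliberately small: a reduced
network (`desk_profile()`: encoding 1→4→6, two residual blocks, 3³
kernels, ~5,500 parameters) trained 400 epochs on 8 synthetic dialanine
examples (10 Å cell, 0.5 Å spacing, 20³ grids) drives the training loss
below 10% of its initial value and the median training correlation above
0.9 in a few minutes on one CPU. This is an overfitting/capacity check —
the network can represent and learn the Patterson-to-density mapping on
real peptide geometry — not a generalization result; its two held-out
examples exist to exercise the validation path, and their CC is expected
to remain near zero at this training-set size. Oracle and invariant
checks use 12³–16³ grids and 2–6-atom structures, sizes chosen so the
brute-force references (per-voxel complex sums, spatial autocorrelations)
stay exact and fast.

## Numerical choices and degenerate inputs

* Phases are stored in degrees on (−180, 180]; the phase of an amplitude
  below 1e-12 of the maximum is pinned to 0.
* Reflections at an exact Nyquist index (possible only when
  `count = 2 * floor(edge/d_min)`) fold onto their Friedel mate; the
  shipped profiles keep `d_min = 1.5` Å well inside the grid band, and
  round-trip tests avoid the boundary.
* Batch normalization in a 1-example batch uses that example's statistics
  (biased variance), as in the reference framework.
* Max-pooling ties resolve to the first element in x-fastest order;
  gradients route to that element only.
* `normalize_map` of a constant map returns zeros; `pearson_cc` on a
  constant region errors (undefined), while the training loss treats an
  undefined correlation as a zero contribution so a degenerate batch
  cannot poison a run.
* All generators, builders and training loops take explicit integer
  seeds and restore the caller's RNG state.

## Known limitations

Orthogonal P1 cells only — no space-group symmetry, non-90° angles or
variable cell sizes; no anomalous scattering, anisotropic displacement or
occupancy; point scatterers rather than tabulated form factors; no
origin/hand search in evaluation; desk-scale training only, with the
full-scale recipes provided as configuration presets rather than results.
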