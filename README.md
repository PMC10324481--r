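# patternet

Neural interpretation of crystallographic Patterson maps, at desk scale.

An X-ray diffraction experiment measures only the amplitudes |F(h,k,l)| of
the structure factors

F(h,k,l) = Σⱼ fⱼ exp[2πi(h xⱼ + k yⱼ + l zⱼ)],

not their phases φ(h,k,l) — the *phase problem*. The one phase-free synthesis
always available from measured intensities is the Patterson function

P(u,v,w) = (1/V) Σ |F(h,k,l)|² cos[2π(hu + kv + lw)],

the autocorrelation of the electron density ρ(x,y,z): a 3D volume whose peaks
sit at interatomic vectors. `patternet` treats phasing as an image-to-image
learning problem: it builds paired (Patterson, density) volumes for
dipeptides in small cubic P1 cells, trains a 3D residual U-net to map the
normalized Patterson map directly to the normalized density, and scores
predictions by Pearson correlation and amplitude-weighted phase error per
resolution shell. It is aimed at crystallographic methods developers who
want a fully self-contained, CPU-sized laboratory for neural phasing.

Everything is implemented from first principles in R (+ a few Rcpp kernels):
structure factors, FFT map syntheses, a seeded idealized-geometry dipeptide
generator covering all 20 residues with fixed L chirality, the U-net
(circular-padded 7³ convolutions, residual and squeeze-and-excitation
blocks, tanh output) with hand-derived backpropagation, Adam/AdamW with
two-phase exponential learning-rate schedules and gradient accumulation,
and CCP4/MRC map I/O.

## Worked example

```r
library(patternet)

# ten dialanine examples in a 10 A cell, 0.5 A grid, 1.5 A resolution
prof <- desk_profile(seed = 1)
ds <- build_dataset(prof$dataset, prof$n_examples)
ds
#> <patterson_dataset: 10 examples (8 train / 2 validation), 20^3 grid, 0 clash-rejected>

model <- build_model(prof$model, seed = 1)
run <- train(model, ds, prof$train)   # ~5 min on one CPU
tail(run$log[, c("epoch", "lr", "train_loss", "val_median_cc")], 1)
#>     epoch          lr train_loss val_median_cc
#> 400   399 0.002014585 0.00796847     0.4009496

# the reduced network memorizes its 8 training Pattersons almost perfectly
# (with only 2 held-out examples, validation CC is noisy and low — true
# generalization is the published, GPU-scale experiment)
pred <- predict(run$final_model, ds$examples[[1]]$patterson)  # a train example
pearson_cc(pred, ds$examples[[1]]$density)
#> [1] 0.9527696

pe <- phase_error_by_shell(pred, ds$examples[[1]]$density, d_min = 1.5)
round(pe$overall, 1)   # amplitude-weighted mean phase error, degrees
#> [1] 11.7
```

The full-scale architecture is a call away — `build_model(model_config())`
is the ~3.3 M-parameter baseline and `run_profile("1a")`, `"1b"`, `"2"`
expand to the three published dataset/model/optimizer recipes (40³, 20³ and
20³ grids) — but training those needs GPU-scale compute and a PDB-derived
corpus, both out of scope here.

A command-line wrapper covers the same pipeline:

```sh
exec/patternet gen-data --profile 1b --n 8 --seed 1 --out ds/
exec/patternet train --data ds/ --profile 1b --epochs 5 --out run/
exec/patternet predict --model run/best.rds --in pat.mrc --out pred.mrc
exec/patternet evaluate --pred preds/ --truth truths/ --out report/
exec/patternet selfcheck
```

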