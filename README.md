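# bcidnn

Two-class motor-imagery EEG classification with a feed-forward network
used as an explicit kernel map and a **large-margin-distribution SVM**
(LM-SVM) in place of the network's output layer.

## The problem

In a cue-paced motor-imagery brain–computer interface, a subject imagines
moving the left or right hand while EEG is recorded over sensorimotor
cortex (typically C3, Cz, C4 at 128 Hz, 9-s trials with imagery from
second 4 to 9). Imagining a hand movement desynchronizes the mu rhythm
(8–12 Hz) over the *contralateral* hemisphere — event-related
desynchronization (ERD) — so the lateralized drop in mu band power
carries the class information. Decoding left vs right from single trials
is the core pattern-recognition problem for motor-imagery BCIs and for
EEG-driven rehabilitation devices.

## The model

The classifier combines two pieces:

**LM-SVM head.** A linear SVM with squared-hinge slacks whose objective
also rewards a large *mean* functional margin
γ̄ = (1/N) Σᵢ yᵢ(φ(xᵢ)ᵀw + b):

```
min_{w,b}  ½‖w‖² + C Σᵢ ξᵢ²  −  λ γ̄
s.t.       yᵢ(φ(xᵢ)ᵀw + b) ≥ 1 − ξᵢ,   ξᵢ ≥ 0
```

Optimizing a margin-distribution statistic rather than only the minimum
margin improves generalization on heavily overlapping classes. With
λ = 0 this is the standard L2-slack SVM. Because the slack penalty is
quadratic, the problem is equivalent to a smooth unconstrained convex
program, solved here by BFGS with the analytic gradient; an exact
active-set solver (`lmsvm_qp()`) provides an independent cross-check.

**Network kernel map.** Instead of choosing a kernel, a small fully
connected network (forward recurrence aʰ = σ(Wʰaʰ⁻¹ + bʰ)) is trained by
full-batch gradient descent on the one-hot MSE loss, its temporary output
layer is discarded, and the hidden stack becomes the explicit feature map
φ feeding the LM-SVM. Defaults: two hidden layers of (11, 6) sigmoid
units, learning rate 0.07, 2500 iterations, λ = 0.1, C = 1.

Around the classifier the package provides zero-phase Butterworth
band-pass filtering, epoching, log band-power features, a stratified
random half split, grid search over architecture/learning rate/λ, trial
I/O (a documented portable binary container plus the MATLAB v5 layout
used by the public BCI-competition motor-imagery datasets), a synthetic
ERD trial generator, and a command-line interface.

## Worked example

Simulate a 140-trial session with moderate ERD, preprocess, fit, and
score the held-out half:

```r
library(bcidnn)

ts <- generate_mi_trials(synth_config(n_per_class = 70, erd_depth = 0.5,
                                      seed = 42))
ts
#> EEG trial set: 140 trials x 3 channels x 1152 samples @ 128 Hz
#>   channels: C3, Cz, C4
#>   time span: 0.000 to 8.992 s (t0 = 0)
#>   labels: left (+1) n=70, right (-1) n=70

ts <- bandpass(ts, 0.5, 30)                  # zero-phase Butterworth
fm <- extract_features(ts, feature_spec())   # mu+beta log band power, 4-9 s
fm
#> feature matrix: 140 samples x 6 features (70 positive, 70 negative)

sp  <- split_half(fm, seed = 1)              # stratified 70/70 halves
fit <- idnn(sp$train, seed = 1)              # (11,6) map + LM-SVM head
fit
#> hybrid network/SVM classifier
#>   hidden layers: 11, 6; activation: sigmoid
#>   pretraining: lr = 0.07, 2500 iterations; head: C = 1, lambda = 0.1
#>   training accuracy: 1.0000; head mean margin: 1.0070

confusion_counts(sp$test$y, predict(fit, sp$test))
#> confusion counts: TP=35 TN=35 FP=0 FN=0 (accuracy 1.0000)
```

The mean margin reported with the fit is the γ̄ statistic the head
optimizes; the confusion counts give the exact test accuracy
(TP+TN)/(TP+TN+FP+FN) on the held-out 70 trials. At `erd_depth = 0.5`
the lateralized band-power contrast is strong, so the synthetic problem
is nearly separable; lower `erd_depth` or higher `noise_sd` makes it
arbitrarily harder.

The same pipeline runs from a shell:

```sh
bcidnn=$(Rscript -e 'cat(system.file("scripts","bcidnn",package="bcidnn"))')
Rscript $bcidnn simulate --out run1 --seed 42
Rscript $bcidnn train    --out run1 --input run1/trials.dat
cat run1/metrics.json
```

Real recordings in the competition layout load with
`read_trials("data.mat", "competition_mat")` and drop into the same
pipeline.

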