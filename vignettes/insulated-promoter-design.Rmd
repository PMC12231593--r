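---
title: "Insulated promoter design: model, purification and design procedures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Insulated promoter design: model, purification and design procedures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(orthodesign)
```

This vignette is the package's account of its science: the measurement
model, the purification logic, the predictor and its training recipe, the
two design procedures, the interpretation tools, and the synthetic system
that stands in for the wet lab — including what each numerical choice is
and why it was made.

## The measurement model and host-effect purification

An insulated regulatory system pairs a monomeric phage RNA polymerase with
its cognate promoter so that expression does not depend on host factors.
Measured fluorescence from a promoter library nevertheless mixes two
sources: the orthogonal polymerase reading its promoter, and the host
polymerase firing off cryptic promoters that arise easily in near-random
sequence. We model the observed induced activity as the **sum, on the
linear fluorescence scale**, of a host component and an orthogonal
component; the uninduced readout contains the host component alone. This
additivity is the only combination rule under which the purification step
`T = max(0, T_induced - T_uninduced)` recovers the orthogonal component
exactly in the noise-free limit, and it is the assumption the whole
pipeline rests on. Where the subtraction goes negative under measurement
noise it is floored at zero and the flooring count is logged.

Purification proceeds in three steps, in order: (I) a computational filter
removes sequences whose *predicted* host activity reaches `tau1` (default
10 activity units against a wild-type activity of 100; the host predictor
is trained in-package on uninduced activities); (II) a responsiveness
filter removes promoters with `(induced + eps) / (uninduced + eps)` below
`foldTau` (default 2, with pseudo-count `eps = 1` activity unit so that
floor-level signals cannot produce spurious ratios); (III) the
subtraction above. The `PurificationReport` accounts for every record.

## The synthetic cis-trans system

The simulator provides ground truth so that purification and design can be
validated end to end without wet-lab data.

* **Orthogonal oracle** — `activity(s) = Tmax * exp(-beta * sum(penalty))`
  with per-position mismatch penalties that are zero at the wild-type
  base. Function is **localized**: a contiguous 12-bp core (the
  polymerase's binding footprint) carries a strongly conserved 5-bp
  centre (penalties 0.8 + Exp(2)) and graded shoulders (Exp(1.4));
  flanking positions are near-neutral (Exp(50), mean 0.02). This mirrors
  the biology of phage-polymerase promoters, whose activity is determined
  by one localized element while flanks are irrelevant, and it makes the
  landscape smooth: the unique local optimum under single substitutions
  is the wild type. An optional pairwise-epistasis term (off by default)
  provides a harder, non-additive variant.
* **Host oracle** — `gain * sum(max(0, window PWM score - threshold))`
  over all windows of several host motifs, plus fixed boosts for exact
  "hot" subsequences that emulate cryptic host promoters. Thresholding
  creates cliffs, hence many local optima — the rugged landscape. The
  threshold is raised just above the wild type's best window so the
  designated wild type is host-silent, the premise of an insulated pair.
* **Measurement** — multiplicative lognormal noise (flow-cytometry
  fluorescence is approximately lognormal) with standard deviation 0.1 on
  the log scale, a detection floor of 0.1 units, and three independent
  replicates per condition. At these settings the oracle explains over
  97% of the variance of triplicate-averaged purified activities, which
  is what "low-noise" means throughout the tests.
* **Default library** — 1252 unique mutants of the 31-bp wild type, each
  within 8 substitutions (edit count uniform on 1..8, positions and bases
  uniform), measured induced and uninduced in triplicate.

What the simulator does *not* emulate: FACS bin sorting, growth effects,
plasmid copy number, sequence-length variation, and any epistasis beyond
the optional pairwise switch. Tests passing against this system show the
pipeline's logic is sound under its assumptions; they do not certify
performance on real libraries.

## The predictor and its training recipe

The main model is a CNN: four convolutions of width 5 with same-padding
(100, 200, 200, 5 kernels), ReLU activations, max-pooling (width 2) after
the second and fourth convolutions, and a dense scalar output; for a
31-bp input the positional trace is 31 - 31 - 15 - 15 - 7. Supplementary
architectures — a CNN-LSTM (conv/pool, two LSTM layers of 200 and 100
units, dense 1024, dense 1), a scaled-dot-product attention model
(conv/pool, shared 64-d query/key projection, 64-d values, flatten, dense
1024, dense 1), and a linear baseline (4L + 1 parameters) — share the
training loop.

Training is stochastic gradient descent with learning rate 5e-4, decay
1e-6 (applied to the learning rate per update step,
`lr_t = lr / (1 + decay * t)`; "decay" is ambiguous between weight decay
and learning-rate decay, and we implement the latter), momentum 0.9, and
MSE loss, with best-validation checkpointing. Defaults: at most 300
epochs, early-stopping patience 30, batch size 32 (unstated in the
original recipe; 32 is conventional at n of about a thousand). Splits of
80/10/10, 90/10 and 95/5 are supported; splits without an explicit
validation fraction carve a tenth of the training rows for checkpointing
only. An optional `refit95` mode refits on 95% of the data after
evaluation, reflecting the convention that evaluation uses held-out data
while the design-time model uses nearly all of it.

Two numerical choices matter. Targets are modelled on a `log1p` scale and
standardised internally (activities are lognormal-noised and span two
orders of magnitude; the linear scale was tried and generalises worse),
with predictions reported on the linear scale. And the CNN's heavy path
(im2col convolutions, backprop, the SGD loop) is compiled code running in
single precision — the standard precision for network training — while
prediction and design gradients run in double precision on the same
weights; gradients are verified against central finite differences in the
test suite at relative tolerance 1e-3 (observed agreement is ~1e-9).

R-squared is reported as the square of the Pearson correlation throughout
(the convention used for the headline figures), not the regression
coefficient of determination.

## Semi-rational design

A pool of 10 000 unique mutants within 8 substitutions of the wild type
is generated, candidates with predicted host activity at or above `tau1`
are discarded, and for each target level (fractions 1, 2/3, 1/2, 1/3,
1/4, 1/8, 1/16, 1/32 of the predicted wild-type activity; 58 designs in
total, allocated as evenly as possible with the remainder on the middle
levels) candidates nearest the target are selected greedily under the
constraint that **all** selected designs are pairwise at least 8 bp
apart. Levels are processed from the highest down because high-activity
candidates are the most distance-constrained; ties on closeness go to the
candidate farthest from the current selection. The fixed-level variant
(12 designs at 1/16 of wild type) restricts candidates to a band whose
predicted spread is at most 1.51-fold and then maximises diversity by
multi-start greedy farthest-point selection, which matches exhaustive
max-min search on small pools in the tests.

## De novo design

De novo design starts from uniformly random sequences, relaxes the
one-hot encoding to real values and iterates
`x <- x + eta * grad_x J(x)` with `eta = 1` for up to 1000 iterations,
decoding by per-position argmax. The objective `J` is the negative
squared deviation of the predicted activity from the target, on the
model's standardised log scale (so that `eta = 1` is a meaningful step
for encodings of unit scale), minus a hinge penalty on predicted host
activity above `tau1` (weight `hostLambda = 1`) — the differentiable form
of the restriction to host-silent sequence space, backed by a hard
post-hoc filter.

Naive ascent on the relaxed point fails in an instructive way: within a
few steps the relaxed encoding leaves the one-hot manifold and satisfies
the objective "out of distribution" while its decoded sequence stays
inactive. Four measures, all using only the trained models, make the
search reliable, and each was added after observing the corresponding
failure mode on the synthetic system:

1. **Straight-through gradients.** Gradients are evaluated at the decoded
   hard encoding and accumulated into the relaxed variable, so every
   gradient describes a real sequence and decoding changes exactly when
   accumulated gradient mass flips a position's argmax.
2. **Climb-then-match.** Every run first maximises predicted activity for
   `climbIters = 250` steps, assembling a functional core in the region
   where the model is calibrated, and only then descends to its target
   level. (Maximise-then-harvest is also available as
   `objective = "maximize"`, which ascends throughout and harvests
   intermediate levels from the trajectory.)
3. **Climb restarts.** A climb whose endpoint scores below 0.7 of the
   top target under the smoothed prediction (below), or that ends beyond
   the training-support radius (`maxEdit + descentLeash` substitutions
   from the wild type — no training evidence supports high activity out
   there), has climbed a hallucinated ridge; the design restarts from a
   fresh random sequence, up to `nStarts = 4` attempts. The iteration cap
   (`maxIters = 1000`) applies per attempt: each restart is a fresh
   optimization run.
4. **Masked descent with smoothed harvesting.** During descent only the
   `descentPositions = 2` highest-gradient positions are updated per step
   (the search mutates a couple of bases at a time) from an encoding
   reset to the decoded one-hot, candidates are only harvested within
   `descentLeash = 10` substitutions of the climb-end sequence (the
   design attenuates the core it climbed to instead of wandering), and
   near-target sequences are periodically re-scored by the **median
   model prediction over the sequence and all its single mutants**.
   Runs without a climb phase (`climbIters = 0`) skip the masking and
   leash and behave as plain deviation searches. Sharp out-of-distribution
   optima collapse under this neighbourhood median while genuine
   activity survives it; the harvested design and its reported predicted
   activity come from the best smoothed score. Convergence is declared
   at 10% relative deviation from the target, matching the granularity
   of the level menu.

The default batch designs 41 sequences over the 11 levels 5/4, 3/4, 1/2,
1/3, 1/4, 1/6, 1/8, 1/12, 1/16, 1/24, 1/32 (allocated as evenly as
possible, remainder on middle levels). Validation simulates triplicate
induced/uninduced measurements of each design against the oracles,
purifies by subtraction, and reports the squared Pearson correlation with
the designer's predictions.

## Landscapes, routes and motifs

Activity landscapes place each sequence at the per-sequence maxima of two
kernels of the last convolutional layer — the two with the largest
variance of maxima across the dataset, a deterministic and maximally
informative choice since the original axis choice is unstated — with the
landscape kind's activity as height (host: uninduced, trained-on-
uninduced model; mixed: induced; orthogonal: purified). A surface is
fitted by Nadaraya-Watson kernel smoothing with bandwidth 5% of each axis
range, and ruggedness is made testable by counting grid peaks that exceed
all eight neighbours by 2% of the height range. Optimization routes are
projected by decoding trajectory snapshots and recomputing their kernel
coordinates.

Kernel motifs follow the maximal-activation recipe: for each kernel, each
sequence contributes the receptive-field window around its
maximum-activation position (closed-form receptive fields: widths 5, 9,
18, 26 for the four conv layers, verified by perturbation tests);
edge-clipped windows are dropped rather than padded, since padding would
distort the base frequencies; stacked windows are normalised into a PWM.
Motif sets from two models are compared by k-means in the original
flattened-PWM space with k chosen by maximum mean silhouette over
5..min(30, n-1); a cluster is "pure" when it has at least three motifs of
one model type, none of the other, and its centroid is at least the
median pairwise distance of the full set away from the nearest foreign
point (the published purity rule gives no number; this is our
quantification). A small t-SNE implementation provides the 2-D display
embedding; clustering never uses it.

## Problem sizes in the test suite

The acceptance-level checks run the full study conditions: 1252 records,
the 10 000-mutant pool, 58 + 12 + 41 designs. Multi-seed property checks
(landscape-peak ordering across five simulation seeds, CNN vs CNN-LSTM
over five seeds, learning-curve plateau) run on reduced datasets
(150-250 records) with shortened training; these sizes are the package's
choice of the smallest problems at which the properties are stable.

## Known limitations

* The additive linear-scale combination of host and orthogonal activity
  is an idealisation; saturation or reporter-level interference would
  break exact subtraction.
* The purified-activity CNN extrapolates reliably near the functional
  core it has seen; far from the training ball its point predictions are
  untrustworthy, which is precisely why the de novo designer needs the
  smoothed-harvesting machinery. Design sets therefore concentrate 15-25
  substitutions from the wild type, not uniformly over sequence space.
* The host model is a weaker predictor than the orthogonal one (its
  target landscape is rugged by construction); the step-I filter and the
  design-time host penalty inherit that noise, which the hard `tau1`
  filter only partially compensates.
* Silhouette-based k selection assumes at least six motifs per model; the
  scanned range is truncated on small inputs with a warning.
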