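---
title: "Predicting cell-cycle phase from a DNA-stain channel: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cell-cycle phase from a DNA-stain channel: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Live-cell cell-cycle readouts usually require either fixation (flow
cytometry with propidium iodide) or a genetically encoded reporter such as
Fucci, whose red (mKO2/mCherry-hCdt1) and green (mAG-hGeminin) channels
mark G1 and S/G2/M respectively. Introducing Fucci into every cell model of
interest — patient-derived material in particular — is often impractical. A
low-toxicity DNA stain (SiR-DNA), by contrast, needs no genetic
manipulation. `ccphase` implements a supervised pipeline that learns to
predict the cell-cycle phase of an individual nucleus from morphology,
intensity and texture features of the DNA-stain channel alone, using Fucci
threshold gates as ground-truth labels, and then applies the learned models
to characterise drug-induced cell-cycle redistribution.

Because the underlying plate-imaging data are not publicly deposited, the
package ships a synthetic-data generator as a first-class, tested module.
The generator's role is to make the biological premises of the analysis
true by construction, so that every downstream claim can be verified
against known ground truth.

## The synthetic plate generator

A condition preset specifies a cell line, a drug and concentration, a
probability vector over the four gated classes (G1, early S, S/G2/M,
double negative) and an apoptotic fraction. Cells are drawn i.i.d.; DNA
content is 2 genome equivalents in G1, uniform on [2, 2.5] in early S and
[2.5, 4] in S/G2/M. Double-negative cells (late M / early G1, both
reporters off) carry content uniform on [2, 4]: nothing in the gating
definition constrains their DNA content, so the least informative choice
is made deliberately — a DN nucleus is morphologically indistinguishable
from a cycling nucleus of the same content, which puts a floor on the
reachable classification accuracy.

Rendering encodes the premises the classifier is meant to exploit:

* **Integrated DNA intensity** of a nucleus is proportional to its DNA
  content times a lognormal staining factor (sigma = 0.10).
* **Area** scales with content^(2/3) (volume proportional to content,
  projected area to volume^(2/3)) times a lognormal factor (sigma = 0.08);
  at the default scale a G1 nucleus has an equivalent diameter of ~16 px
  and a 4N nucleus ~21 px, matching a 10x objective at ~0.65 um/px on
  512 x 512 fields with ~100 nuclei per field.
* **Chromatin texture** is multiplicative band-passed Gaussian noise whose
  correlation length grows from G1 (1.2 px) through early S (1.5 px) to
  S/G2/M (2 px), so texture features carry genuine phase signal.
* **Fucci levels** are drawn per nucleus with at least a 25% margin on the
  correct side of each gating threshold; with probability
  `label_noise_rate` (default 2%, split between the two channels) a level
  is placed just across its threshold instead. Gating the noiseless
  rendering therefore recovers the true phase exactly, and under defaults
  the ground-truth labels carry ~2% class noise — the knob that controls
  how "clean" the supervision is.
* **Apoptotic nuclei** are rendered as 4-6 bright fragments over a dim
  body inside one footprint, which drives the within-ROI coefficient of
  variation far above the 70% exclusion threshold.
* **Noise model**: per channel, a smooth parabolic background dome
  (60 counts DNA / 20 counts Fucci), Poisson shot noise and Gaussian read
  noise (sd 3), quantized to 16 bits.

The built-in drug presets are qualitative: cytotoxic agents (5-FU 10 uM,
SN-38 0.1 uM) shift HeLa-like populations toward S/G2/M; ZSTK474 (1 uM)
accumulates MCF7-like populations in G1 while leaving HeLa-like ones
essentially unchanged; staurosporine mainly raises the apoptotic fraction;
selumetinib causes a mild G1 shift. The exact fractions are free
parameters, chosen once to be plausible for a 36-h exposure, not fitted to
any measured distribution.

What the generator does **not** emulate: optical point-spread functions
beyond Gaussian smoothing, cytoplasm or bright-field context, focus
drift, uneven illumination beyond a single smooth dome, cell clumping
(placement enforces non-overlap), or the heavy-tailed feature noise of
real high-content instruments. Tests passing on synthetic data therefore
validate the pipeline's mechanics and internal consistency, not
instrument-level performance on real plates.

## Background correction and segmentation

The DNA channel is corrected with a sliding-parabola filter: grey-scale
opening with the paraboloid `-c (u^2 + v^2)` subtracted from the image.
Because the paraboloid separates additively, the opening is computed
exactly, row-wise then column-wise, by a lower-envelope min-plus
convolution in O(n) — there is no structuring-element radius to choose,
only the curvature `c`. The default `c = 0.003` counts/px^2 sits between
the curvature of the background dome (~5e-4, which must be exceeded for
the background to be tracked) and the scale `peak/radius^2` of a nucleus
(~20, which must not be approached lest nuclei be flattened). The filter
is verified against a brute-force min-plus oracle. On noiseless fields the
top-hat is idempotent to well under one count; under shot noise a second
application differs by a few counts because any morphological opening
rides the lower envelope of the noise — this is a property of the
operator, not a numerical artifact.

Nuclei are then found by Gaussian smoothing (sigma 2 px), a global Otsu
threshold, hole filling, and a distance-transform watershed (tolerance
1 px) to separate touching objects; objects below 50 px or touching the
field border are discarded, the latter because partial nuclei would
distort area and intensity features. Fucci channel means are measured on
the *raw* reporter channels: the background correction is specified for
nucleus finding, and whether the original analysis measured reporter
intensities on filtered or raw channels is not documented — raw is the
default here and configurable.

## The 240-feature catalog

Per nucleus, in a frozen order: 9 intensity properties (mean, population
SD, median, max, min, sum, CV in percent, quantile-50%, Michelson
contrast); 4 basic morphology properties (area in um^2, roundness from a
Crofton-corrected perimeter, width and length from the second-moment
ellipse); 16 SER texture features (8 Hessian/gradient pattern filters —
spot, hole, ridge, valley, saddle, edge, bright, dark — at scales 1 and
2 px, each reduced over the ROI as mean squared response over squared mean
intensity); 4 Haralick statistics (contrast, correlation, homogeneity,
sum variance) of a 32-level co-occurrence matrix at distance 1 restricted
to within-ROI axis-aligned pairs; and 23 STAR intensity-weighted shape
descriptors (8 angular symmetry moments, 5 threshold-compactness values,
4 axial, 4 radial, 2 profile) computed on 9 image variants — the raw DNA
channel and the 8 SER responses at scale 1 — for 207 STAR features and
240 in total.

Degenerate inputs are given explicit finite conventions (constant ROIs,
masks of one or two pixels, variants with zero total intensity), so no
NaN ever enters the feature table; the conventions are documented with
each function. The vendor software that inspired these families does not
publish its formulas; the definitions above are this package's own
re-specifications, so absolute values are not comparable with vendor
output — only the pipeline's behaviour is reproduced. Population (not
sample) SD is used everywhere so that SD and CV are mutually consistent.

## Gating, exclusion and the dataset split

Classes follow hard threshold gates on the mean reporter intensities, with
the >= boundary on the "on" side: G1 = red on / green off, early S = both
on, S/G2/M = green on / red off, DN = both off. Thresholds are 700/2500
counts for HeLa-like data and 150/300 for MCF7-like data. Nuclei with
DNA-channel CV strictly above 70% are excluded when the apoptotic filter
is enabled — by default only for MCF7, where dead-cell contamination
motivated the rule. A consequence verified by the tests: with the filter
off, surviving apoptotic clusters gate as DN and inflate the DN fraction
slightly above its nominal value.

Training (n = 7500) and validation (n = 2500) sets are disjoint uniform
samples without replacement, not stratified by class. Min-max
normalization to [0, 1] is fitted on the training rows only and applied to
validation with clipping; fitting on the pooled data is available by
option but leaks validation extremes into the scaling, so per-training
bounds are the default. Labels are three one-vs-rest tasks (G1, early S,
S/G2/M); DN is negative in all three.

## Classifiers, selection and evaluation

Five families are implemented behind one interface: logistic regression on
all variables; backward-stepwise logistic regression (greedy elimination,
refitting without each remaining variable and dropping the one that most
improves the AIC until no removal improves it — exact but O(p^2) model
fits, so intended for moderate feature counts); an RBF support-vector
machine (cost 1, kernel width 1/p); a random forest (500 trees by
default, sqrt(p) variables per split, impurity importance); and a
feed-forward neural network with exactly three hidden layers (128/64/32
rectifier units, logistic output, Adam, early stopping on a 10% internal
holdout). The network is implemented directly with base matrix algebra
and is deterministic per seed. All hyperparameters are configurable and
recorded in the run manifest.

Families are compared by k-fold cross-validation (default 10-fold,
non-stratified, one shuffle per seed) on mean accuracy at probability
cutoff 0.5; ties break by the higher minimum fold accuracy and then a
fixed family order, never by validation data. The selected model is
refitted on the full training set and evaluated on validation: accuracy,
sensitivity, specificity (0/0 defined as 0) and AUC, computed by midranks
as the probability that a random positive outscores a random negative
with ties counted one half, and verified against brute-force pairwise
concordance.

Two properties of the default pipeline are worth stating honestly. First,
cross-validating the full five-family panel at 7500 x 240 is dominated by
the SVM, the network and especially backward elimination; the default
configuration therefore cross-validates the fast families (logistic
regression and random forest) and the remaining families are enabled
explicitly via `cv_families`. Second, on this synthetic data the forest
beats the linear baselines by a wide margin on every seed, but the
three-layer network is a close competitor and can edge the forest by
under a point on the S/G2/M task at small sample sizes — the synthetic
feature space is cleaner than real instrument output, which narrows the
forest's advantage. The test suite asserts the property that holds:
the forest dominates the linear baselines and stays within noise of the
best family.

## Reporting

Per condition (cell line, drug, concentration) the package reports the
gated class fractions alongside the fraction of validation nuclei called
positive by the G1 and S/G2/M models, as a table and a stacked-bar chart
— the informational content of per-well pie charts without the
per-figure geometry. Group comparisons of the top-importance features
(total intensity, area) between gated G1 and S/G2/M nuclei use the
two-sided Wilcoxon rank-sum test: exact by enumeration when the combined
sample is at most 12 without ties, otherwise the normal approximation
with tie and continuity corrections; the two agree within 0.02 for group
sizes of 10 and the exact path reproduces enumerated small-sample
p-values.

## Problem sizes, determinism and limitations

The default experiment is six conditions x 20 fields x ~100 nuclei
(~12 000 nuclei); the acceptance computation cross-validates 100-tree
forests on the 7500-row training partition, a forest size at which the
accuracy is within a fraction of a point of the 500-tree default. The
test suite exercises smaller geometries (320-768 px fields, hundreds to
a thousand nuclei) chosen so the whole suite runs on a laptop-class
single core. Every stochastic step — population sampling, rendering,
splitting, fold shuffling, forest and network fitting — draws its seed
from one master seed through a fixed integer derivation, and the RNG
state of the caller is never disturbed. Re-running any stage with the
same configuration reproduces its artifacts byte for byte.

Known limitations: the simulator's clean feature distributions make
classification easier than on real instrument data, so absolute
accuracies here should not be read as expected field performance; the
classifier never sees the Fucci channels, but it inherits the ~2% label
noise of the gates; DN-class morphology is deliberately uninformative;
and none of the vendor-inspired feature formulas claim numerical
equivalence with proprietary implementations.
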