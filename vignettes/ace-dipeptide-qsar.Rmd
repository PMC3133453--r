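---
title: "QSAR modeling of ACE-inhibitory dipeptides: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QSAR modeling of ACE-inhibitory dipeptides: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aceqsar)
```

## The problem

Angiotensin-converting enzyme (ACE) raises blood pressure by converting
angiotensin I to the vasoconstrictor angiotensin II; peptides that inhibit
ACE are therefore candidate functional-food ingredients. Short peptides
released by enzymatic hydrolysis of food proteins — here defatted wheat germ
protein (DWGP) — can inhibit ACE, with potency expressed as `log(1/IC50)`.
This package models the quantitative structure–activity relationship (QSAR)
of ACE-inhibitory *dipeptides* and uses the model to reason about which
proteins and proteases are promising for producing active hydrolysates.

## Descriptors and data

Each residue is described by the three Z-scale descriptors derived from
principal-components analysis of amino-acid physicochemical properties:
`z1` (hydrophilicity — hydrophobic residues score negative), `z2`
(side-chain size/shape) and `z3` (electronic properties). A dipeptide is
the concatenation of its two residues' triples, `Z11..Z23` (first digit =
position, second = descriptor), giving a 6-vector; see `encode_peptide()`.

The packaged training set (`ace_dipeptides()`) holds 58 dipeptides with
published `log(1/IC50)` activities. The printed source table is internally
inconsistent in places, and the package treats that as data to audit, not
to hide:

* the sequence `RP` appears twice (activities 1.1818 and 3.89), and the
  second row's descriptors actually match the dipeptide IP;
* the `AY` row carries descriptors matching VF;
* the printed table additionally ends with a 59th row (labelled IP,
  activity 3.89) whose descriptor block is shifted by one column and which
  duplicates the mislabeled second RP entry. Since the study design is
  explicit that 58 samples were used (39 training + 19 test), the packaged
  fixture keeps the first 58 printed rows and drops that garbled trailing
  row.

`ace_dipeptides("as-printed")` (the default training input) reproduces the
printed descriptor cells verbatim; `ace_dipeptides("canonical")` re-derives
all descriptors from the Z-scale table. `validate_dataset()` reports every
discrepancy between the two:

```{r}
v <- validate_dataset(ace_dipeptides("as-printed"))
v$duplicates
v$mismatches[, c("index", "sequence", "max_abs_diff")]
```

Whether the original model was trained on the printed matrix or a corrected
one is unknowable; "as-printed" is the default because it mirrors what the
published model most plausibly consumed, and both modes agree on sequences
and activities record-for-record.

## Normalization

Descriptors and (by default) the activity target are min-max normalized,
`z' = (z - z_min)/(z_max - z_min)`, with the minima and maxima fitted
per feature over the full 58-record set so that training and test records
share one scale (`fit_normalizer()`, `scale_on = "train"` available).
Normalizing the target keeps training errors on the conventional goal
scale; raw activities span roughly 1.18–5.7, so squared errors on the raw
scale would dwarf any 1e-2 goal. Values outside the fitted range are passed
through unclamped, with a message, since extrapolation is then in play.

## The network and its training protocol

The regression model is a three-layer feed-forward network: 6 inputs, `H`
hidden neurons with hyperbolic-tangent sigmoid transfer ("tansig"), one
linear output ("purelin"). Training is full-batch gradient descent on the
mean squared error with classical momentum,
`delta_w(t) = momentum * delta_w(t-1) - lr * grad`, stopping at an MSE goal
of 1e-2 or after 6000 epochs. Defaults (`bp_control()`): learning rate
0.01 and momentum 0.9 — the documented defaults of the classical
gradient-descent-with-momentum trainer this protocol emulates — and seeded
uniform weight initialization in [-0.5, 0.5] (the original initialization
is unstated; this is the package's choice, fully exposed).

### The trainer's target scale

One numerical decision deserves its own section. The published model
quality trio — overall r = 0.928, training MSE 0.0188, prediction MSE
0.2091 — is only arithmetically coherent if the squared errors were
measured on data scaled to [-1, 1], the classical toolbox's native
normalization: on that scale the 58 activities have variance 0.178, so a
training MSE of 0.0188 implies a training R² of 0.89 (r ≈ 0.95), which
matches r = 0.928; on a [0, 1] scale (variance 0.044) the same MSE would
imply R² = 0.58 (r ≈ 0.76), contradicting it. Moreover a training MSE
above the 0.01 goal means those runs hit the epoch cap without converging,
which happens at learning rate 0.01 but not at faster rates.

`train_protocol()` therefore maps the Eq-1-normalized data affinely onto
[-1, 1] for the optimizer (`trainer_scale = "symmetric"`, the default;
`"unit"` trains on [0, 1] directly) and applies the 1e-2 goal there. After
training, the affine map is absorbed back into the weights in closed form,
so the returned network consumes and emits the [0, 1] scale and every
reported MSE is on the Eq-1 scale (squared errors are exactly 4 times
smaller there). Hidden-layer activations — and therefore the
connection-weight importance products below — are provably invariant under
this absorption, which the test suite checks.

With this protocol, best-of-20-restart runs reproduce the published error
signature: training terminates at the epoch cap with train MSE around
0.005–0.008 on the Eq-1 scale (0.02–0.03 on the trainer scale, printed:
0.0188) and train-set r of 0.93–0.98 (printed: 0.928). The *all-58* r of
the same runs is 0.82–0.89 by master seed. The package reports train, test
and all-points r side by side; note that pooling the published train and
test errors themselves (39 x 0.0188 + 19 x 0.2091 on the trainer scale)
yields an overall residual incompatible with an all-points r of 0.928, so
the 0.928 figure is best read as a training-set ("study sample")
correlation.

### Restarts and splits

A "repeated modeling" protocol is operationalized as `restarts`
independent cycles of split (39 train / 19 test, uniform without
replacement) → normalize → initialize → train → evaluate, keeping the run
with the best all-points r; the default is 20 restarts. All per-run seeds
derive deterministically from one master seed, so protocols and sweeps
replay exactly.

### Hidden-size selection

`sweep_hidden()` trains each candidate size (default 4–10) five times on
independent splits and initializations and selects the size with the best
mean test-set r, ties toward the smaller network (fewer neurons being
preferred when convergence is comparable). A caveat the package's own
measurements make plain: with 19-point test sets and five repeats, the
between-size differences are dominated by split-to-split noise, and the
selection does not stabilize on any single size across master seeds — a
selection of 7 is one outcome among several. The sweep report retains all
per-run correlations so this can be judged directly.

## Back-stepping importance

The interpretation procedure walks the trained network backwards:

1. `select_hidden()` ranks hidden neurons by `|lw_j|`, the magnitude of
   their hidden-to-output weights; on the packaged published weight vector
   the top two are neurons 6 (-1.3532) and 7 (1.1885).
2. `backstep_importance()` scores each input through the selected neurons
   by the product-magnitude aggregate `score_i = sum_j |lw_j * iw_ji|`
   (`k_top = 2` by default, matching the two neurons examined in the
   original analysis). The published procedure "observes" the large
   weights rather than defining an aggregate; this sum makes it
   quantitative while reproducing its outcome, and the raw weight matrix
   is always carried in the report for direct inspection. With
   `k_top = hidden_size` the score coincides with an unsigned Garson-style
   connection-weight sum.
3. `sign_analysis()` reports the sign of each `lw_j * iw_ji` route and
   their sum; routes may disagree (for the C-terminal hydrophilicity
   descriptor Z21 they do), so per-neuron signs are reported honestly
   rather than collapsed.

```{r}
imp <- backstep_importance(published_network(), k_top = 2)
imp$ranking
round(imp$input_scores, 4)
```

Z21 — the hydrophilicity descriptor of the C-terminal residue — dominates,
with Z22 second: C-terminal hydrophobicity and bulk drive dipeptide ACE
inhibition. Scores are on the normalized-input weight scale (the network
consumes Eq-1-normalized inputs); no back-conversion to raw descriptor
units is attempted. Indices are 1-based in all human-facing output.

## The applied layer

`wheat_germ_composition()` packages the measured DWGP amino-acid
composition (g/100 g protein; Asp/Asn and Glu/Gln combined, as acid
hydrolysis leaves them). `class_fraction()` sums residue classes — the
default hydrophobic set {A,V,L,I,P,F,M,W,Y} reproduces the reported 42.84%
hydrophobic content to within printed rounding (component rows sum to
42.83), and {F,Y,W} gives the aromatic 8.89 (rows: 8.88). Combined entries
that only partially overlap a class are excluded with a message rather
than guessed. `composition_from_sequence()` converts a FASTA-read sequence
to mass fractions via average residue masses.

`builtin_protease_specs()` encodes four proteases' C-terminal tendencies.
The source text's "Try" abbreviation is ambiguous (Tyr or Trp); it is read
as Trp when Tyr is separately listed in the same enumeration and as Tyr
otherwise, giving Neutrase {Y,W,F}, Alcalase {I,L,V,M,F,Y,W}, Proteinase K
{F,Y,V,I,L,W,P,M} and Chymotrypsin C {Y,L,W,P,M,E,K}; all specificities
are user-overridable via CSV.

The digestion model is deliberately minimal: `candidate_dipeptides()`
enumerates adjacent residue pairs whose C-terminal residue the protease
tends to expose — no cleavage kinetics, no fragment-length model. It is an
illustration layer for "which protease could liberate high-activity
C-termini from this protein", not a hydrolysis simulator.
`rank_proteases()` scores each protease's candidates with the QSAR model
and orders by mean predicted activity (max and count also reported).

The assay calculators are closed-form: pH-stat degree of hydrolysis
`DH = (V_NaOH x N_NaOH)/(alpha x M_p x h_tot) x 100` with
`alpha = 10^(pH-pK)/(1+10^(pH-pK))` (mL x mol/L = mmol in the numerator,
`h_tot` in mmol peptide bonds per g — 7.69 for wheat germ protein, pK 9.0),
average peptide chain length `PLC = 100/DH`, and ACE inhibition
`I = (A - B)/A` from the 340 nm absorbance decreases of blank and sample.
Negative inhibition is reported with a warning, never clamped.

## The synthetic-data module

`synth_dipeptides()` generates datasets whose activity is a known
(configurable) function of the normalized descriptors plus Gaussian noise,
with sequences drawn uniformly over the residue alphabet so the data share
real dipeptide sets' discrete descriptor geometry. Defaults mirror the
study conditions: n = 58 records, 39/19 splits downstream. The generator is
validated independently of the network: with zero noise, ordinary least
squares on the normalized descriptors recovers the generating coefficients
to 1e-8.

`recovery_experiment()` closes the loop: generate → split → normalize →
train → back-step across seeds, reporting how often the truly dominant
descriptor is top-ranked and the held-out correlation. What passing
recovery shows is that the pipeline can find a strong single-descriptor
signal under modest noise (sd 0.05 on an activity range of ~1); it does
not show that the real 58-dipeptide dataset's importance ranking is
correct, since real activities have unknown noise and correlated effects.

## Problem sizes and numerical choices

All simulations are desk-scale: 58 x 6 data, networks of 4–10 hidden
neurons, 6000-epoch budgets; a full 20-restart protocol takes a few
seconds and a 4–10 sweep under a minute on one core. Gradients are
analytic and verified against central finite differences to 1e-6 relative
error. Ties in hidden-neuron and input rankings break toward the lower
index; constant features are rejected by the normalizer with the feature
named; training aborts with the epoch named if the loss overflows. Model
JSON persistence writes 17 significant digits so round-trips are exact.

## Known limitations

* The model is dipeptide-only; longer peptides would need a different
  descriptor layout and were never in scope.
* The published weight fixture (`published_network()`) has zero biases
  (they were never published); it supports the interpretation procedure
  but is not a usable predictor.
* Hidden-size selection at five repeats is noise-dominated (above).
* The protease layer ranks candidate C-termini; it does not predict
  degrees of hydrolysis or hydrolysate composition.
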