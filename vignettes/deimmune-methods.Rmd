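---
title: "Methods: immune visibility, the PWM classifier, and preference-aligned sequence design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune visibility, the PWM classifier, and preference-aligned sequence design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deimmune)
```

This vignette is the package's own account of the science it implements:
the immune-visibility metric, the calibrated position-weight-matrix (PWM)
presentation classifier, the miniature structure-conditioned sequence model,
the direct-preference-optimization (DPO) alignment loop, and the synthetic
data that stands behind every test. It also records the numerical choices
and the design decisions that were genuinely open, and is explicit about
what the desk-scale experiments do and do not demonstrate.

## 1. Immune visibility

MHC class I molecules display 8--10-residue peptides from intracellular
proteins on the cell surface. We define the **absolute visibility** of a
sequence as the number of its 8-, 9- and 10-mer windows that a presentation
predictor calls presented. Three conventions matter and are fixed
throughout:

* **Overlaps count separately.** Every window is assessed once; an
  L-residue chain contributes `max(0, L-k+1)` windows per length k.
* **Allele multiplicity counts once.** The predictor interface is pooled
  over the patient's alleles; a window presented by several alleles still
  adds one.
* **Unknown residues are "unclear".** Windows containing `X` are neither
  presented nor absent; they never add to visibility but their count is
  reported, so a caller can flag low-confidence sequences. In per-residue
  annotations (`annotate_residues()`) the precedence is anchor > epitope >
  unclear > none, where anchors are the second and terminal positions of a
  presented window.

**Relative visibility** divides a design's visibility by its template's; a
design presenting 9 windows against a template presenting 36 scores 0.25.
When the template's visibility is 0 the ratio is undefined and the package
returns `NA` rather than 0 or an error -- a zero-visibility template makes
"fraction retained" meaningless, and silently returning 0 would reward
degenerate templates. Coordinates in reports are 0-based half-open; this is
recorded in every report rather than assumed.

Visibility is deliberately *not* immunogenicity: presentation is necessary
but not sufficient for a T-cell response. Nothing in the package predicts
immunogenicity.

For multi-chain inputs, visibility is computed per chain and summed; no
window spans a chain break (the proteasome does not splice chains).

## 2. The PWM presentation classifier

Neural presentation predictors are far too slow to call inside a training
loop that scores two candidate sequences per backbone per refresh. The
package therefore distills a reference predictor into one PWM per peptide
length:

1. Sample a large pool of uniform random 8--10-mers (`sample_random_peptides()`).
2. Label each with the reference predictor.
3. For each length L, estimate
   `entry(aa, pos) = log((count + c) / (n_presented + 20c))` over the
   *presented* peptides only.
4. Score any peptide by summing its column entries, and calibrate a
   per-length threshold so that the classifier reproduces the reference
   predictor's presented **count** on the random set.

Numerical choices:

* **Pseudocount** `c = 0.5` per residue per column by default. Zero counts
  otherwise produce `-Inf` entries that poison every sum they touch;
  `c = 0` remains available for exact hand-checkable probabilities.
* **Boundary convention**: score >= threshold counts as presented. With a
  strict `>` the calibrated count could never include the boundary score
  group; `>=` lets calibration hit the target count exactly whenever scores
  are untied.
* **Ties**: the full tied boundary group is admitted, which can overshoot
  the target count; the achieved and target counts are both recorded in the
  classifier's calibration metadata rather than hidden.
* **Per-length calibration**: presented fractions differ slightly by
  length, so fractions and thresholds are computed per length rather than
  pooled.
* **Alleles are pooled into a single matrix set** -- the classifier
  emulates "presented by any of the patient's alleles", not allele-specific
  binding, which is a non-goal.

The calibration-closure property -- the calibrated classifier predicts
exactly the reference predictor's presented count on its own calibration
set when scores are untied -- is the load-bearing invariant and is tested at
the 50,000-peptide scale. Against the synthetic motif oracle (section 6) the
PWM is a near-perfect surrogate because the oracle *is* a position-specific
rule; against a neural predictor the agreement would be looser, which is
exactly why evaluation in a production setting should fall back to the
external predictor (the optional netMHCpan adapter) rather than the PWM.

## 3. The miniature sequence-design model

The alignment loop needs a structure-conditioned autoregressive sequence
model in the style of message-passing inverse-folding networks: an encoder
over the k-nearest-neighbor graph of residues, and a decoder that emits one
amino acid per step in an **arbitrary decoding order**, conditioning on the
backbone and the already-decoded neighbors. The package implements a
CPU-sized model with exactly that interface:

* **Featurization** uses pairwise distances and chain offsets only (local
  backbone bond distances, CA--CA distances at sequence offsets 1 and 2,
  RBF-encoded neighbor distances, signed and scaled sequence offsets), so
  all embeddings are invariant under rigid motions by construction -- a
  property the tests verify to machine precision rather than assume.
* **Encoder**: 2 message-passing layers over the k = 16 nearest CA
  neighbors, feature width D = 64 by default. The full-scale preset values
  (D = 128, k = 48) are available through `model_config()` but are not
  needed at desk scale.
* **Decoder**: the already-decoded neighbor tokens enter through a learned
  token embedding averaged per residue; a 2-layer tanh MLP maps
  `[node embedding; context]` to 21 logits. The output layer is
  zero-initialized, so a fresh model is exactly uniform over the
  vocabulary.
* **Vocabulary**: 20 amino acids plus `X`. `X` is input-only: its logit is
  masked when sampling.

A deliberate asymmetry: the encoder weights are seeded at initialization
and **frozen**; supervised fitting and DPO update the decoder only. This
keeps every gradient a short chain of dense matrix products that is written
out analytically in base R -- no autodiff dependency -- while preserving the
interface of the full-scale models. The decoder sees the structure only
through the encoder embeddings, so a frozen random encoder acts as a fixed
featurization; at the scale of the synthetic experiments this loses little,
and it makes training exactly reproducible across platforms.

Two probability conventions deserve a note because they interact:

* `next_token_distribution()` and `sequence_log_prob()` use the **full
  21-way softmax**. For a fixed decoding order the probabilities of all
  `21^L` sequences sum to one exactly (tested exhaustively on a restricted
  toy alphabet), and a fresh model scores any length-L sequence at
  `L * log(1/21)`.
* `sample_sequence()` masks `X` when drawing each token but reports the
  *unmasked* 21-way log-probabilities of the realized tokens, so the sum of
  its per-token log-probabilities equals `sequence_log_prob()` of the
  sampled sequence under the same order. Temperature shapes the draw only,
  never the reported likelihoods; the policy densities entering the DPO
  ratios are therefore temperature-free.

Likelihoods condition on a single decoding order rather than marginalizing
over all orders. Each sequence's order is drawn uniformly when the sequence
is sampled and is persisted with it; the tuned and reference policies of
one preference example always use the same orders, so the DPO
log-likelihood ratios are well-defined. Whether the two responses of one
pair should share an order is genuinely open; the package gives each
response its own order, fixed at pair creation.

Supervised fitting (`train_supervised()`) maximizes the arbitrary-order
likelihood of native sequences with a fresh order per visit -- the same
objective, at miniature scale, as the native-sequence-recovery training of
the full-scale models. The package uses it to build its own base model from
synthetic data, since pretrained full-scale weights are outside its scope.

## 4. DPO alignment

For each training backbone, the **current** tuned model samples two
complete designs at the preference-sampling temperature; the PWM classifier
scores their absolute visibility; the less visible design is preferred. The
loss per pair is

$$\mathcal{L} = -\log \sigma\big(\beta(\Delta_w - \Delta_l)\big), \qquad
\Delta = \log \pi_\theta(y \mid x) - \log \pi_{\mathrm{ref}}(y \mid x),$$

estimated by the minibatch mean, with the reference policy frozen at the
base model for the entire run. Every two epochs (configurable) the
preference dataset is rebuilt from the newly tuned model -- generating
preferences from the *tuned* model, not the base model, is what lets the
procedure walk progressively further from the base outputs -- while
$\pi_{\mathrm{ref}}$ never moves.

Decisions and defaults:

* **Ties are dropped.** Equal-visibility candidate pairs carry no
  preference signal; random assignment would inject label noise into a
  logistic objective. One pair per backbone per refresh.
* **Optimizer**: Adam, no scheduler, global gradient-norm clipping at 1.0
  (an engineering addition for stability, recorded here). The identity
  policy sits at loss `log 2`, and one step on a single pair provably
  increases the preference margin -- both are tested.
* **Default hyperparameters** for the desk-scale experiments: beta 0.0343
  and preference temperature 0.759 (the first shipped preset), with Adam
  learning rate `1e-3`. The presets' published learning rates (~1e-6) are
  plain-SGD-scale values for a 1.7-million-parameter network; the mini
  model's decoder is three orders of magnitude smaller and Adam-normalized,
  so the package keeps the preset's beta and temperature and uses the
  standard Adam rate. Both presets load exactly via `dpo_presets()`.
* **Preference-sampling temperature is a hyperparameter**, distinct from
  the fixed 0.1 design-generation temperature of the evaluation protocol.
* **Divergence handling**: a non-finite loss aborts with a diagnostic, as
  does a refresh in which the sampled sequences collapse to >90%
  single-residue composition -- the constant-chain failure mode of
  too-aggressive runs. `dpo_sweep()` records such runs as failed and
  continues; sweeps in the source study also lost runs to instability.
* **Batching** is by pair count (default 8) under a 10,000-token budget per
  step; both limits are parameters because the right batch unit for DPO
  pairs versus a token budget is unspecified in the source protocol.
* **KL anchoring**: at matched step counts, larger beta leaves the tuned
  policy measurably closer to the base model. The effect is a saturation
  effect -- large beta saturates the logistic early and stops pushing -- so
  the test checks it coarsely, over order-of-magnitude-spaced beta values
  and enough epochs for saturation to bind.

## 5. Design generation and evaluation

The design protocol: sample 3 candidates at temperature 0.1, remove
candidates with fewer than 10 distinct amino-acid types (strictly fewer:
exactly 10 is kept), predict a structure for each survivor, assign TM-score
0 to failed predictions, then select -- among candidates with TM-score
strictly above 0.9, the least visible; otherwise the maximum-TM candidate.
Visibility ties inside the gate break to the first candidate in input
order. At desk scale the sharpened mini model often fails the diversity
filter at temperature 0.1 (its per-position distributions are
composition-dominated), which is the very failure mode the filter exists
for; the evaluation helpers therefore accept an explicit temperature, and
the synthetic experiments evaluate at temperature 1.

**TM-score.** The built-in scorer assumes positional correspondence --
appropriate for fixed-backbone design where the design's predicted
structure has the template's length -- and computes
$\tfrac{1}{L}\sum_i 1/(1 + (d_i/d_0)^2)$ with
$d_0 = 1.24(L-15)^{1/3} - 1.8$ (floored at 0.5), after iterative Kabsch
superposition: fit, drop residues beyond the distance cutoff
$\max(d_0, 4.5)$ angstrom, refit until the aligned set stabilizes, and keep the best
score seen. Normalization is by the reference (template) length, recorded
per score. An external TMalign adapter handles anything with indels; a
missing executable raises an error rather than returning 0, because 0 is
reserved for failed structure predictions. Scores near 1 mean the same
structure; below ~0.2 is the unrelated-structure regime, above 0.5 the
same fold.

**Structure prediction** is an interface. The desk-scale default is a stub
that perturbs the template with seeded Gaussian noise (default sigma 0.3
angstrom per coordinate, sub-angstrom like a high-confidence prediction; at
L = 60 this lands near TM 0.96) and can be configured to fail at a given
rate, so the TM > 0.9 gate and the failure path are both exercisable
without a folding engine. Plugging in a real predictor means supplying any
function `(sequence, template) -> structure or NULL`.

**Trade-off summaries.** `evaluate_checkpoint()` reports per-structure rows
and their arithmetic means; mean relative visibility is the mean of
per-structure ratios (not the ratio of means), matching the per-design
normalization of the published trade-off plots. The large-set protocol
samples each design once; the small-set protocol uses best-of-3.

## 6. Synthetic data: what it emulates, and what passing tests show

Every test and experiment runs from generated inputs:

* **Motif oracle.** Presented iff position 2 is in {L, M, I, V} *and* the
  C-terminal residue is in {V, L, F, Y} -- the anchor-residue structure of
  real MHC-I motifs. Expected presented fraction on uniform peptides:
  (4/20)(4/20) = 4%, between the strong-binder (0.5% rank) and weak-binder
  (2% rank) regimes of neural predictors; shrinking the anchor sets
  emulates stricter rank cutoffs. A motif oracle (rather than, say, a
  random hash) is essential: it gives the alignment loop a *learnable*
  mechanism -- avoid anchor residues -- mirroring the mechanism available
  against real predictors.
* **Toy backbones.** Ideal-geometry single-chain helices (1.5 angstrom rise, 100
  degrees/residue, CA radius 2.3 angstrom, consecutive CA--CA ~3.8 angstrom), extended
  strands, and mixed topologies, with optional seeded coordinate noise.
* **Native sequences.** Drawn per residue from secondary-structure-specific
  propensities (helix formers A/L/E/K/... in helical segments, beta-branched
  V/I/T/F/Y/... in extended segments), with the segment read off the CA
  geometry. Two properties matter. First, the native sequence is
  *predictable from the backbone*, so the base model attains above-chance
  sequence recovery -- with a structure-agnostic (e.g. uniform) native
  composition, expected recovery is 1/20 for *every* policy and the
  recovery axis of the trade-off would be unmeasurable. Second, hydrophobic
  anchor-prone residues carry substantial mass in both propensity sets, as
  in natural proteins, so native-like sequences are immune-visible and
  deimmunization has something to remove.

The seeded end-to-end experiment in the test suite uses 20 backbones of
length 60, a 60,000-peptide PWM, 40 supervised epochs for the base model,
and 12 DPO epochs with refresh every 2 -- sizes chosen so the full suite
runs in well under a minute while every effect is far from its noise floor.
At the pre-registered seeds the run cuts mean sampled visibility from ~13.6
to ~1.6 while mean recovery declines (both against the native sequences and
against the base model's own designs), visibility falls monotonically
across the epoch-2/6/10/final checkpoints, and lower visibility goes with
lower recovery along the trajectory -- the qualitative frontier shape of
full-scale alignment.

What this does **not** show: the synthetic benchmark cannot reproduce
full-scale numbers (those require pretrained inverse-folding weights, a
neural presentation predictor, and a folding engine); the oracle is far
simpler than real presentation, so the PWM surrogate is more faithful here
than it would be in production; and toy backbones are not realistic folds,
so TM-scores against stub predictions validate plumbing and selection
logic, not structural designability. The package's claims are about the
machinery -- calibration closure, likelihood normalization, the loss's
analytic properties, the selection rule, and the direction of the
visibility/recovery trade-off -- each of which is tested directly.

## 7. Known limitations

* MHC class I only; MHC-II, antibody epitopes and immunogenicity are out of
  scope, as are allele-specific PWMs.
* The built-in TM-score requires equal lengths and positional
  correspondence; use the TMalign adapter otherwise.
* Likelihoods are single-decoding-order, not order-marginalized.
* The mini model's frozen random encoder caps how much structural signal
  the decoder can use; it is a deliberate trade for exact, dependency-free
  gradients at desk scale.
* The external netMHCpan adapter shells out per batch and is intended for
  evaluation only; it is never consulted during tuning.
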