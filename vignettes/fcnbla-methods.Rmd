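---
title: "Dual-branch CNN/BiLSTM classification with two-level attention: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-branch CNN/BiLSTM classification with two-level attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcnbla)
```

## The problem and the model

The package predicts a single disease label for a free-text clinical record
treated as one token sequence. Two encoder branches read the same embedded
document and summarise it with different emphases, and their summaries are
fused before classification.

**Embedding.** Each token id indexes a column of a trainable table
$H \in \mathbb{R}^{d\times|V|}$, $x_t = He_t$, initialised uniformly on
$[-\sqrt{3/d},\,+\sqrt{3/d}]$ (default $d = 300$, so the bound is $0.1$).
The padding column is fixed at zero and never updated. During training a
dropout mask (rate 0.2 by default, inverted scaling) is applied once to the
embedded document, which is then shared by both branches.

**Local branch (CNN).** Filters of heights $k \in \{2,3,4\}$ (50 per height)
slide over the $T\times d$ embedding matrix with stride 1 in "valid" mode,
so a height-$k$ map has $N = T-k+1$ rows; each row $Z_i$ — a *phrase
vector* — holds the $j$ filter responses over $k$ adjacent words. A ReLU
follows the affine filter response (configurable to identity; the
architecture family conventionally uses one, and a bounded-below $Z_i$
interacts well with the $\tanh$ attention projection). Per-filter max
pooling over the valid rows, concatenated across heights, gives the local
summary $z_C$ (dimension $3\times 50 = 150$ by default).

**Context branch (BiLSTM).** A standard single-layer LSTM (input, forget,
cell and output gates; forget-gate bias initialised at 1, orthogonal
recurrent and uniform input weights) runs in both directions over the real
tokens; $h_t$ is the concatenation of the two directional states
(dimension $2H = 400$ under the default $H = 200$). The sentence summary
$z_B$ is the concatenation of the two directional final states — the
conventional BiLSTM summary, which matches the 400-dimensional size the
model requires; a max-over-$t$ pooled alternative is available via
`context_summary = "maxpool"` because the construction is genuinely open.

**Two attention levels.** Both use the same additive form. Phrase level,
per height: $v_i = \tanh(W_r Z_i + b_r)$, $\beta_i \propto
\exp(v_i^\top u_p)$ over valid rows, $l_r = \sum_i \beta_i Z_i$. Word
level: $u_t = \tanh(W_c h_t + b_c)$, $\alpha_t \propto \exp(u_t^\top u_w)$
over real positions, $l_w = \sum_t \alpha_t h_t$. The context vectors
$u_p, u_w$ are trainable and randomly initialised. Because the three filter
heights produce maps of different $N$, each height gets its own attention
parameters and the per-height outputs are concatenated (dimension 150,
matching $z_C$, so the heads are comparable); sharing across heights is a
config option. Masked positions receive $-\infty$ score before the softmax,
so weights always normalise over real content only.

**Fusion and combination.** $l_F = [l_r, l_w]$ passes through a one-layer
MLP, $p_F = \tanh(W l_F + b)$ (dimension 200 by default; activation and
size configurable). Three fully connected heads score the classes:
$s_C$ from $[z_C, p_F]$, $s_B$ from $[z_B, p_F]$, and $s_F$ from $p_F$;
they are blended as
$$f = \alpha\, s_C + \tfrac{1-\alpha}{2}\, s_B + \tfrac{1-\alpha}{2}\, s_F,
\qquad \alpha = 0.3 \text{ by default},$$
and $p = \mathrm{softmax}(f)$. The loss is the cross-entropy summed over
documents (per-document means are logged so learning-rate semantics stay
conventional); argmax ties break toward the lowest class index for
determinism. The three heads do not share parameters.

**Training.** Adam (learning rate 0.001), shuffled batches of 16, dropout
only on the embedding outputs and only during training, at most 100 epochs
with early stopping after 20 epochs without validation-loss improvement;
the best checkpoint (minimum validation loss) is restored. Validation loss
is the monitored quantity — it is what the loss defines — with validation
macro-F logged alongside. Everything (initialisation, batch order, dropout)
derives from one integer seed. No gradient clipping by default
(`grad_clip` exposes it). Variable-length documents are padded per document
rather than per batch; since every layer masks padding exactly, per-batch
padding would change nothing but memory layout.

## Ablation variants

`variant =` selects: **FNOA** (both attentions replaced by masked mean
pooling — the exact uniform-weight limit of the attention softmax, which is
why mean pooling is the substitute), **FCNA** (phrase attention only),
**FBLA** (word attention only), **CNBL** (middle module removed entirely;
the two branch heads are blended as $\alpha s_C + (1-\alpha) s_B$, the
two-head analogue of the pairwise rule), and **TCNBLA** ($[z_C, z_B, p_F]$
through a single fully connected + softmax head). All variants share the
same training loop and evaluation.

## The synthetic corpus generator

`generate_corpus()` produces the corpus the tests and the acceptance run
train on. It emulates the statistical structure the model exploits, not the
surface of clinical text:

* **Imbalanced classes.** Default proportions follow the ten-disease study
  corpus (about 30% down to 1.6%), apportioned deterministically by largest
  remainders so counts are exact. This is what makes the macro-averaged
  metrics informative.
* **Two kinds of signal.** Each sampling step emits, with probability
  `p_sig` (default 0.7), either a class-signature unigram or a
  class-signature collocation placed as an adjacent token pair
  (`bigram_frac`, default 0.5); otherwise a background token shared across
  classes. Collocations give the phrase level signal that bag-of-words
  pooling cannot see, which is what separates the ablation variants.
* **Stratified 70/10/20 split.** Per-class largest remainders with a
  controlled-rounding correction, so global split sizes are exact and each
  class deviates from 70:10:20 by less than one document.
* **Document lengths** uniform on 20–50 tokens by default — long enough
  for every filter height, short enough for fast CPU training.

It does **not** emulate Chinese morphology, the 18-item structured record
layout, real length distributions, topical correlation between classes, or
label noise. A model that is perfect here can therefore still be far from
the real-corpus numbers; passing tests demonstrate that the implementation
learns what it is pointed at, not clinical performance.

`corpus_separability_report()` checks the generator itself: the empirical
signal rate per class (counting an adjacent collocation pair as one event)
estimates `p_sig` exactly.

## Numerical choices

* Softmax and cross-entropy are computed in the log domain with
  max-subtraction; probabilities are strictly positive and normalised to
  1e-6 or better.
* Gradients are fully hand-derived (including BPTT through both LSTM
  directions and both attention softmaxes) and verified against central
  finite differences at 1e-4 relative tolerance for all six variants and
  all configuration switches.
* A document shorter than the largest filter height is padded up to it;
  windows overlapping padding are excluded from pooling and attention
  except in that degenerate case, where the single all-covering window
  (padding rows embed to zero) is kept so every height always has at least
  one phrase vector.
* Attention projection dimensions default to the input dimension ($j$ and
  $2H$); the model is insensitive to this within reason and it avoids a
  second arbitrary size.

## Problem sizes used by the tests and the acceptance run

The architectural checks build the full default model (d = 300, H = 200,
50 filters per height). Training-based checks use a documented desk scale
chosen so the whole pipeline — generator, training, evaluation — runs
end-to-end on one CPU in minutes while remaining comfortably
over-parameterised for the synthetic task: d = 32, H = 24, 12 filters per
height, p-dim 32, 8 epochs on the default 1,000-document corpus (the
learning check requires held-out accuracy at least 0.95; the fit reaches
1.0). The ablation comparison uses a harder, sparser corpus (5 classes,
300 documents, `p_sig = 0.25`, `bigram_frac = 0.8`, lengths 20–40) at
d = 16 / H = 12 / 8 filters for 6 epochs over 5 seeds: with mostly
background tokens, uniform pooling dilutes the signal and attention's
advantage is measurable.

## Known limitations

* Pure-R training: fine at desk scale, not intended for 18k-document
  corpora at d = 300 — the package's contribution is a transparent,
  verifiable implementation, not a fast one.
* Single tokenizer assumption: the package never segments text itself;
  for unsegmented languages the caller supplies a segmenter function.
* `alpha` is a fixed hyperparameter, as specified; no calibration is
  attempted.
* Early-stopping patience is counted in epochs; with no validation set,
  training simply runs to `max_epochs`.
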