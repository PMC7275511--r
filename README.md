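# fcnbla

Dual-branch neural document classification for clinical free text, in plain
R. The package predicts a disease label for a record treated as one token
sequence, using a convolutional branch for local phrase patterns, a BiLSTM
branch for sequential context, additive attention at the **phrase level**
(over convolution windows) and the **word level** (over hidden states), and
a three-head combination strategy that blends a local head, a context head
and a fused head.

It is written for researchers who want a fully inspectable implementation
of this architecture family: every layer, the complete backpropagation and
the Adam loop are base-R matrix code, verified against scalar-loop oracles
and finite differences in the test suite. A seeded generator of
class-imbalanced synthetic corpora makes the whole pipeline testable
without any external data.

## The model

With token embeddings $x_t = He_t$ ($H \in \mathbb{R}^{d\times|V|}$,
uniform init on $[-\sqrt{3/d}, +\sqrt{3/d}]$, $d = 300$ by default):

* **Local branch:** filters of heights $k\in\{2,3,4\}$ (50 each) give
  feature maps $Z$ with rows $Z_i$ ("phrase vectors"); max pooling over
  valid rows yields $z_C$ (dim 150).
* **Context branch:** a BiLSTM ($H = 200$ per direction) gives per-token
  states $h_t$; the concatenated directional final states form $z_B$
  (dim 400).
* **Attention:** $v_i=\tanh(W_rZ_i+b_r)$, $\beta_i\propto\exp(v_i^\top u_p)$,
  $l_r=\sum_i\beta_iZ_i$ (per height, concatenated); likewise
  $u_t=\tanh(W_ch_t+b_c)$, $\alpha_t\propto\exp(u_t^\top u_w)$,
  $l_w=\sum_t\alpha_th_t$.
* **Fusion and heads:** $p_F=\tanh(W[l_r,l_w]+b)$; heads score
  $[z_C,p_F]$, $[z_B,p_F]$ and $p_F$, blended as
  $f=\alpha s_C+\frac{1-\alpha}{2}s_B+\frac{1-\alpha}{2}s_F$
  ($\alpha=0.3$), and $p=\mathrm{softmax}(f)$ with summed cross-entropy
  loss.

Training follows the stated protocol: Adam (lr 0.001), batch 16, dropout
0.2 on the embedding outputs, early stopping with patience 20 within 100
epochs, best-validation checkpoint restored. Ablation variants `FNOA`,
`FCNA`, `FBLA`, `CNBL` and `TCNBLA` disable the attentions, the middle
module, or the pairwise heads. Evaluation reports accuracy and per-class /
macro-averaged precision, recall and F-score.

## Worked example

```r
library(fcnbla)

corpus <- generate_corpus(synth_config(n_classes = 5, n_docs = 300,
                                       doc_length_range = c(15L, 30L),
                                       background_vocab_size = 120L, seed = 42))
ctl <- fcnbla_control(embedding_dim = 16L, hidden_size = 12L,
                      filters_per_height = 8L, p_dim = 16L,
                      max_epochs = 5L, patience = 5L)
fit <- fcnbla(corpus$train, corpus$validation, labels = corpus$labels,
              control = ctl, seed = 1)
fit
#> Dual-branch CNN/BiLSTM attention classifier (variant FCNBLA)
#>   classes:   5 (class01, class02, class03, class04, ...)
#>   vocabulary: 177 tokens
#>   parameters: 8919
#>   trained:   5 epochs (best at 5, val loss 0.9496)

evaluate_records(fit, corpus$test)
#> Evaluation on 60 documents
#>
#>    class  n precision recall      f
#>  class01 12    1.0000 0.3333 0.5000
#>  class02 12    1.0000 1.0000 1.0000
#>  class03 12    0.6667 1.0000 0.8000
#>  class04 12    1.0000 1.0000 1.0000
#>  class05 12    0.8571 1.0000 0.9231
#>
#>   Precision_macro 0.9048  Recall_macro 0.8667  F-score_macro 0.8446  Accuracy 0.8667
```

Five epochs on a 300-document corpus already separate most classes; the
per-class rows show where the short training still confuses the first
class, and the macro averages weight every class equally regardless of
prevalence. Longer training (the default corpus and the settings used by
the acceptance run) reaches held-out accuracy above 0.99.
`predict(fit, records, type = "prob")` returns the full per-class
probability matrix, `type = "rank"` the candidate diseases in score order,
and `attention_weights(fit, records)` exports both attention levels per
document for inspection. `run_ablation_suite()` trains all six variants
under identical data and seeds and tabulates their macro metrics.

A command-line front end (`inst/cli/fcnbla.R`) exposes `synth`, `train`,
`predict`, `evaluate` and `ablate` subcommands over the same functions and
writes a manifest (resolved config, seed, artifact hashes) per run.

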