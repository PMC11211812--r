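# codexr

Counterfactual modeling of high-throughput perturbation screens in R.

High-throughput screens expose cancer cell lines — in bulk or as single
cells — to chemical and genetic interventions and record the downstream
consequences: a drug-synergy score, or a perturbed transcriptome. The
combinatorial space of interventions (drug pairs, dosages, combinatorial
CRISPR-interference knockouts) is far too large to measure exhaustively,
so the practical question is counterfactual: *given an unperturbed
profile, what would happen under an intervention (or combination) that
was never tested?*

`codexr` implements a counterfactual deep-learning architecture for this
problem, together with the simulation machinery, baselines, metrics and
cross-validation designs needed to evaluate it.

## The model

Each training example is a triplet: an unperturbed profile `x`, a
multi-hot intervention vector `t = (t_1, ..., t_K)` (optionally with
dosages `d`), and an outcome `y`. The model is

    y_hat = d( sum_k t_k * f_k( e(x) ) )

* `e : R^p -> R^d` — a shared encoder embedding the unperturbed state;
* `f_k : R^d -> R^d` — one branch network per intervention, applied only
  when `t_k != 0`; for dosed screens the transformed dose enters the
  first branch layer as an extra input;
* the active branch outputs are **summed** in latent space (treatment
  combinations need no dedicated parameters, which is what lets the
  model extrapolate to unseen combinations);
* `d` — a shared decoder: a scalar head trained with mean squared error
  for synergy-score regression, or a heteroscedastic Gaussian head
  predicting per-gene means and variances, trained with the Gaussian
  negative log likelihood `sum 0.5 * (log s2 + (mu - y)^2 / s2)` with
  every variance floored at `1e-6`.

For a perturbation never observed in training, a **proxy treatment
vector** stands in for the missing branch: gene–gene similarities are
computed as the Jaccard index of pathway memberships (`read_gmt()`),
L1-normalized over the observed perturbations, and added to the observed
part of the treatment vector; e.g. `(1,0,0,0,0) + (0,0.4,0.35,0.25,0) =
(1,0.4,0.35,0.25,0)`.

Included baselines: the **linear baseline** (average of observed
single-perturbation mean profiles), the **lin-CODEX ablation**
(single-branch model predictions combined in outcome space, either
averaged or summed as effects), and the **control-centroid random
baseline** used to normalize reconstruction errors.

## Worked example

Simulate a screen of 4 perturbations measured alone and in all 6 pairs
with a strong latent interaction, hold the pair P1+P2 out of training,
and compare the model's reconstruction of the unseen combination with
the additivity baseline:

```r
library(codexr)

pairs <- data.frame(k = c(1, 1, 1, 2, 2, 3), l = c(2, 3, 4, 3, 4, 4),
                    gamma = 2)
sim <- simulate_screen(synth_config(
  n_genes = 100, n_perturbations = 4, n_cells_per_condition = 100,
  conditions = c(list(integer(0)), as.list(1:4),
                 lapply(1:6, function(i) c(pairs$k[i], pairs$l[i]))),
  interaction_pairs = pairs, seed = 42))
screen <- sim$screen
screen
#> <perturb_screen> 1100 triplets, 100 controls, 100 genes, 4 interventions, profile outcomes

sig  <- apply(screen$design$matrix, 1, function(r)
  paste(sort(screen$design$perturbation_ids[r != 0]), collapse = "+"))
fold <- list(train = which(sig != "P1+P2"), test = which(sig == "P1+P2"))

model <- codex_model(
  codex_config(latent_dim = 4, encoder_widths = 64, decoder_widths = 8,
               head = "gaussian", dropout = 0.1, latent_noise = 0.3,
               seed = 42),
  n_genes_in = 100, perturbation_ids = screen$design$perturbation_ids)
fit <- train_codex(model, screen, fold,
                   train_config(epochs = 1500, batch_size = 128,
                                weight_decay = 1e-3, ema_decay = 0.999,
                                early_stop_patience = 2000, seed = 42))

X     <- unclass(screen$controls)[screen$pairing[fold$test], ]
pred  <- colMeans(codex_forward(fit$model, X, c(1, 1, 0, 0))$mu)
truth <- unclass(screen$outcomes)[fold$test, ]
cm    <- colMeans(unclass(screen$controls))

eval_condition(pred, truth, cm, k = 50)[, c("r2_topk", "pcc_effect")]
#>    r2_topk pcc_effect
#> 1 0.814166  0.8098014
eval_condition(linear_baseline(screen, c("P1", "P2")), truth, cm,
               k = 50)[, c("r2_topk", "pcc_effect")]
#>     r2_topk pcc_effect
#> 1 0.7463634  0.5847358
```

`r2_topk` is the coefficient of determination on the 50 most
differentially expressed genes of the held-out pair's mean profile;
`pcc_effect` is the Pearson correlation of the predicted perturbation
*effect* (profile minus control mean). The trained model reaches
R² ≈ 0.81 and effect correlation ≈ 0.81 on a combination it never saw,
while the linear baseline — blind to the simulated interaction and
halving every effect by averaging — trails at 0.75 and 0.58. Training
takes about a minute on one CPU.

A thin command-line wrapper over the same functions is installed at
`inst/cli/codex.R` (`simulate`, `ingest`, `train`, `predict`, `evaluate`,
`proxy`).

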