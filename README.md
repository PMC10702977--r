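# gfdnet

Severity staging of dementia from 2D brain-MRI slices, built around a
class-imbalance-aware loss: the **Categorical Generalized Focal Dice
loss**, the convex fusion

```
L = (1 - λ) · GDL + λ · FL,          λ = 0.5
FL  = mean_n [ -α (1 - p_t)^γ log p_t ],        γ = 2, α = 4
GDL = 1 - 2 (Σ_l w_l Σ_n r_ln p_ln + ε) / (Σ_l w_l Σ_n (r_ln + p_ln) + ε),
      w_l = 1 / (Σ_n r_ln)²
```

optimized by a compact residual-block CNN (double 3×3 conv stages with
GroupNorm/ReLU, projection shortcuts, 2×2 max-pooling, global average
pooling, FC softmax head; Xavier init; ADAM) over slices restored by
wavelet-MAD noise estimation → Non-Local Means → CLAHE. The four classes,
in fixed order, are NonDemented, VeryMildDemented, MildDemented,
ModerateDemented; typical collections are imbalanced about
2050 : 1075 : 573 : 42, which is the regime the loss is designed for.

The package is for researchers who want the loss, the architecture, or
the full pipeline as testable R components. No dataset download is
required: a synthetic brain-phantom generator produces 176×208 labeled
slices with a monotone atrophy signal and configurable imbalance, so the
entire chain runs end-to-end out of the box. The network's forward and
backward passes are implemented from scratch (conv/pool kernels in
Rcpp/RcppArmadillo); EBImage stands behind CLAHE, affine augmentation and
resizing.

## Worked example

```r
library(gfdnet)

## the full-scale architecture and its parameter budget
net <- build_model(model_config(), seed = 1)
count_parameters(net)
#> [1] 5023076                      # 5.02 M, under the 5.45 M budget

## the fused loss on a two-sample batch
p <- rbind(c(0.8, 0.2), c(0.4, 0.6))
r <- rbind(c(1, 0), c(0, 1))
generalized_dice_loss(p, r, loss_config(epsilon = 1e-300))
#> [1] 0.3                          # 1 - 2·1.4/4.0, by hand
focal_loss(rbind(c(0.9, 0.1)), rbind(c(1, 0)), loss_config())
#> [1] 0.004214421                  # 4·(0.1)²·(-ln 0.9)

## end-to-end on synthetic slices (desk scale: 22×26 inputs, 3 stages)
ds <- generate_dataset(synthetic_spec(n_total = 200, noise_sigma = 0.05,
                                      seed = 11))
ds <- downsample(ds, 8)
sp <- split_train_val(ds, val_fraction = 0.2, seed = 11)
cfg <- train_config(batch_size = 32, epochs = 30, learning_rate = 1e-3,
                    seed = 11,
                    model = model_config(stage_widths = c(8, 16, 32),
                                         gn_groups = 4, head_width = 32,
                                         input_shape = c(22, 26)))
fit <- train(sp$train, sp$val, cfg)
max(fit$history$val_accuracy)
#> [1] 1                            # validation accuracy from epoch ~20 on

rep <- evaluate(fit$model, sp$val)
c(rep$accuracy, rep$sensitivity, rep$specificity)
#> [1] 1 1 1
```

The first number is the headline structural claim: the full 5-stage
network (32/64/128/256/512 channels, 256-unit head, 4-class softmax) holds
5,023,076 trainable parameters. The loss values are exact hand-checkable
evaluations of the formulas above. The training run shows the pipeline
optimizing the fused loss to a perfect split of the phantom classes at
desk scale — a wiring check, not a claim about real MRI.

A command-line front end over the same functions lives in
`inst/cli/gfdnet.R` (subcommands `simulate`, `preprocess`, `describe`,
`train`, `evaluate`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/gfdnet.R", package="gfdnet"))')" describe
```

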