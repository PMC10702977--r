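default_net <- build_model(model_config(), seed = 1)

test_that("layer parameter counts match closed-form arithmetic", {
  d <- describe_model(default_net)
  expect_equal(d$params[d$layer == "s1.conv_a"], 9 * 1 * 32 + 32)    # 320
  expect_equal(d$params[d$layer == "head.fc2"], 256 * 4 + 4)         # 1028
  # a 3x3 conv 32->64 holds 9*32*64 = 18432 weights (bias counted apart)
  expect_equal(length(default_net$params[["s2.conv_a.W"]]) -
                 9 * 32 * 64, 0)
  expect_equal(attr(d, "total_params"), sum(d$params))
})

test_that("direct enumeration and the description table agree on the total", {
  expect_equal(count_parameters(default_net),
               attr(describe_model(default_net), "total_params"))
})

test_that("the default architecture stays within the parameter budget", {
  expect_lte(count_parameters(default_net), 5450000)
})

test_that("weights are Xavier-initialized and biases zero", {
  xs <- xavier_stats_check(default_net)
  big <- xs[xs$n >= 100, ]
  expect_true(all(abs(big$ratio - 1) < 0.25))
  # closed-form targets
  expect_equal(xs$target_var[xs$layer == "s2.conv_a"], 2 / (288 + 576))
  expect_equal(xs$target_var[xs$layer == "head.fc1"], 2 / (512 + 256))
  expect_true(all(default_net$params[["s1.conv_a.b"]] == 0))
  expect_true(all(default_net$params[["head.fc1.b"]] == 0))
})

test_that("the forward pass emits normalized, deterministic probabilities", {
  cfg <- desk_model_config()
  net <- build_model(cfg, seed = 42)
  set.seed(3)
  xs <- lapply(1:3, function(i) matrix(runif(22 * 26), 22, 26))
  p1 <- predict_probs(net, xs)
  expect_equal(dim(p1), c(3L, 4L))
  expect_equal(rowSums(p1), rep(1, 3), tolerance = 1e-5)
  p2 <- predict_probs(build_model(cfg, seed = 42), xs)
  expect_equal(p1, p2, tolerance = 1e-6)
  expect_error(predict_probs(net, matrix(0.5, 10, 10)), "expects")
})

test_that("five pooling stages reduce 176x208 to a 5x6 map", {
  fw <- gfdnet:::sample_forward(default_net, matrix(0.5, 176, 208),
                                keep_cache = TRUE)
  expect_equal(fw$cache$feat_dim, c(5L, 6L, 512L))
  expect_equal(length(fw$logits), 4L)
})

test_that("invalid architecture configurations are rejected", {
  expect_error(model_config(stage_widths = c(30, 64), gn_groups = 8),
               "divide")
  expect_error(model_config(stage_widths = rep(8, 6),
                            input_shape = c(32, 32)), "too small")
})

test_that("identity shortcuts appear when widths repeat, projections otherwise", {
  d <- describe_model(default_net)
  # every default stage changes width, so every stage carries a projection
  expect_equal(sum(d$kind == "conv1x1"), 5)
  samew <- build_model(model_config(stage_widths = c(8, 8), gn_groups = 4,
                                    head_width = 16,
                                    input_shape = c(32, 32)), seed = 1)
  ds <- describe_model(samew)
  expect_equal(sum(ds$kind == "conv1x1"), 1)  # only the 1->8 stage projects
  # identity-shortcut path still runs
  p <- predict_probs(samew, matrix(0.5, 32, 32))
  expect_equal(sum(p), 1, tolerance = 1e-6)
})

test_that("removing residual connections removes only the projection convs", {
  cfg_res <- model_config(stage_widths = c(8, 16), gn_groups = 4,
                          head_width = 16, input_shape = c(32, 32))
  cfg_abl <- model_config(stage_widths = c(8, 16), gn_groups = 4,
                          head_width = 16, input_shape = c(32, 32),
                          residual = FALSE)
  n_res <- count_parameters(build_model(cfg_res, seed = 1))
  n_abl <- count_parameters(build_model(cfg_abl, seed = 1))
  proj <- (1 * 8 + 8) + (8 * 16 + 16)
  expect_equal(n_res - n_abl, proj)
})

test_that("one small ADAM step on a tiny batch decreases the fused loss", {
  cfg <- model_config(stage_widths = c(4, 8), gn_groups = 2, head_width = 8,
                      n_classes = 4, input_shape = c(16, 16))
  net <- build_model(cfg, seed = 5)
  set.seed(11)
  xs <- lapply(1:4, function(i) matrix(runif(256), 16, 16))
  labels <- c(1L, 2L, 3L, 4L)
  lcfg <- loss_config()
  loss_now <- function(n) {
    pr <- gfdnet:::softmax_rows(gfdnet:::batch_forward(n, xs, FALSE)$logits)
    fusion_loss(pr, gfdnet:::onehot(labels, 4), lcfg)
  }
  l0 <- loss_now(net)
  fw <- gfdnet:::batch_forward(net, xs, TRUE)
  pr <- gfdnet:::softmax_rows(fw$logits)
  dpr <- fusion_loss_grad(pr, gfdnet:::onehot(labels, 4), lcfg)
  grads <- gfdnet:::batch_backward(net, fw$caches,
                                   gfdnet:::softmax_backprop(pr, dpr))
  upd <- gfdnet:::adam_step(net$params, grads, gfdnet:::adam_init(net$params),
                            lr = 1e-4)
  net$params <- upd$params
  expect_lt(loss_now(net), l0)
})

test_that("checkpoints round-trip and verify their configuration", {
  cfg <- model_config(stage_widths = c(4, 8), gn_groups = 2, head_width = 8,
                      input_shape = c(16, 16))
  net <- build_model(cfg, seed = 9)
  dir <- tempfile()
  save_checkpoint(net, dir)
  back <- load_checkpoint(dir, expected_cfg = cfg)
  for (k in names(net$params))
    expect_equal(back$params[[k]], net$params[[k]], ignore_attr = TRUE,
                 tolerance = 1e-12)
  other <- model_config(stage_widths = c(4, 8), gn_groups = 2,
                        head_width = 16, input_shape = c(16, 16))
  expect_error(load_checkpoint(dir, expected_cfg = other), "match")
})
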