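test_that("focal loss matches hand-derived scalar values", {
  # perfect prediction: log(1) = 0 regardless of gamma/alpha
  p <- rbind(c(1, 0), c(0, 1))
  expect_equal(focal_loss(p, p, loss_config()), 0)
  # gamma=0, alpha=1 on p_t = 0.5 reduces to cross-entropy ln 2
  expect_equal(
    focal_loss(rbind(c(0.5, 0.5)), rbind(c(1, 0)),
               loss_config(gamma = 0, alpha = 1)),
    log(2), tolerance = 1e-12)
  # defaults gamma=2, alpha=4 on p_t = 0.9
  expect_equal(
    focal_loss(rbind(c(0.9, 0.1)), rbind(c(1, 0)), loss_config()),
    4 * 0.1^2 * -log(0.9), tolerance = 1e-12)
})

test_that("focal loss at gamma=0, alpha=1 equals mean cross-entropy", {
  cfg <- loss_config(gamma = 0, alpha = 1)
  for (s in 1:100) {
    b <- random_batch(n = 7, C = 4, seed = s)
    ce <- mean(-log(rowSums(b$probs * b$targets)))
    expect_equal(focal_loss(b$probs, b$targets, cfg), ce,
                 tolerance = 1e-9)
  }
})

test_that("modulating factor only ever shrinks the cross-entropy", {
  for (g in c(0.5, 1, 2, 5)) {
    b <- random_batch(n = 50, C = 4, seed = 99 + g)
    ce <- mean(-log(rowSums(b$probs * b$targets)))
    expect_lte(focal_loss(b$probs, b$targets,
                          loss_config(gamma = g, alpha = 1)), ce)
  }
})

test_that("focal loss decreases monotonically in the true-class probability", {
  pts <- seq(0.05, 0.95, by = 0.05)
  vals <- vapply(pts, function(pt)
    focal_loss(rbind(c(pt, 1 - pt)), rbind(c(1, 0)), loss_config()),
    numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("a zero true-class probability is clamped to a finite loss", {
  v <- focal_loss(rbind(c(0, 1)), rbind(c(1, 0)),
                  loss_config(gamma = 0, alpha = 1))
  expect_true(is.finite(v))
  expect_equal(v, -log(1e-5), tolerance = 1e-9)
})

test_that("Dice class weights are inverse squared class counts", {
  expect_equal(gdl_class_weights(rbind(c(1, 0), c(1, 0), c(0, 1))),
               c(0.25, 1))
  expect_equal(gdl_class_weights(diag(3)), rep(1, 3))
  # absent class takes the maximum finite weight of the present ones
  t3 <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(gdl_class_weights(t3), c(0.25, 1, 1))
})

test_that("generalized Dice loss matches its term-by-term evaluation", {
  eps0 <- loss_config(epsilon = 1e-300)  # numerically identical to eps = 0
  p <- rbind(c(0.8, 0.2), c(0.4, 0.6))
  r <- rbind(c(1, 0), c(0, 1))
  # w = (1,1); intersection 0.8 + 0.6 = 1.4, union 2 + 2 = 4
  expect_equal(generalized_dice_loss(p, r, eps0), 1 - 2 * 1.4 / 4.0)
  expect_equal(generalized_dice_loss(p, r, eps0), 0.3)
  # perfect one-hot prediction: intersection is half the union
  expect_lt(generalized_dice_loss(r, r, loss_config()), 1e-5)
  # disjoint one-hot prediction
  wrong <- rbind(c(0, 1), c(1, 0))
  expect_equal(generalized_dice_loss(wrong, r, eps0), 1)
})

test_that("generalized Dice loss stays in [0,1] and ignores label order", {
  for (s in 1:50) {
    b <- random_batch(n = 6, C = 4, seed = 200 + s)
    v <- generalized_dice_loss(b$probs, b$targets, loss_config())
    expect_gte(v, 0); expect_lte(v, 1)
    perm <- sample.int(4)
    vp <- generalized_dice_loss(b$probs[, perm], b$targets[, perm],
                                loss_config())
    expect_equal(vp, v, tolerance = 1e-12)
  }
})

test_that("fusion loss is the convex combination of its endpoints", {
  b <- random_batch(n = 8, C = 4, seed = 7)
  gdl <- generalized_dice_loss(b$probs, b$targets, loss_config(lam = 0))
  fl <- focal_loss(b$probs, b$targets, loss_config(lam = 1))
  expect_equal(fusion_loss(b$probs, b$targets, loss_config(lam = 0)), gdl)
  expect_equal(fusion_loss(b$probs, b$targets, loss_config(lam = 1)), fl)
  for (lam in c(0.1, 0.25, 0.5, 0.9)) {
    expect_equal(fusion_loss(b$probs, b$targets, loss_config(lam = lam)),
                 (1 - lam) * gdl + lam * fl, tolerance = 1e-12)
  }
})

test_that("analytic loss gradients match central differences", {
  cfgs <- list(loss_config(),
               loss_config(gamma = 0, alpha = 1, lam = 1),
               loss_config(gamma = 3, alpha = 2, lam = 0.3),
               loss_config(lam = 0))
  for (i in seq_along(cfgs)) {
    b <- random_batch(n = 4, C = 3, seed = 300 + i)
    for (fn in list(c(focal_loss, focal_loss_grad),
                    c(generalized_dice_loss, generalized_dice_loss_grad),
                    c(fusion_loss, fusion_loss_grad))) {
      ga <- fn[[2]](b$probs, b$targets, cfgs[[i]])
      gn <- num_grad(function(pp) {
        dim(pp) <- dim(b$probs)
        fn[[1]](pp, b$targets, cfgs[[i]])
      }, b$probs)
      expect_lt(max(abs(ga - gn)), 1e-4)
    }
  }
})

test_that("invalid loss inputs are rejected", {
  p <- rbind(c(0.5, 0.5))
  expect_error(focal_loss(p, diag(3)[1:2, ], loss_config()),
               "shape mismatch")
  expect_error(loss_config(lam = 1.5), "lam")
  expect_error(loss_config(epsilon = 0), "epsilon")
  expect_error(focal_loss(rbind(c(0.7, 0.7)), rbind(c(1, 0))), "sum to 1")
  expect_error(focal_loss(p, rbind(c(0.5, 0.5))), "one-hot")
})

test_that("loss configuration round-trips through JSON and YAML", {
  cfg <- loss_config(gamma = 2, alpha = 4, lam = 0.5, epsilon = 1e-5)
  for (ext in c("json", "yaml")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_loss_config(cfg, path)
    back <- read_loss_config(path)
    expect_equal(unclass(back), unclass(cfg))
  }
})
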