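test_that("noise estimation is zero for a constant image and tracks sigma", {
  flat <- image_slice(matrix(0.4, 64, 64))
  expect_equal(estimate_noise_sigma(flat), 0)
  # injected sigma = 0.10 on a smooth unclipped phantom, 20 seeds
  ests <- vapply(1:20, function(s) {
    set.seed(s)
    px <- smooth_phantom() + rnorm(176 * 208, sd = 0.1)
    estimate_noise_sigma(image_slice(pmin(pmax(px, 0), 1)))
  }, numeric(1))
  expect_lt(abs(mean(ests) / 0.1 - 1), 0.2)
  # doubling sigma doubles the estimate
  ests2 <- vapply(1:20, function(s) {
    set.seed(500 + s)
    px <- smooth_phantom() + rnorm(176 * 208, sd = 0.2)
    estimate_noise_sigma(image_slice(pmin(pmax(px, 0), 1)))
  }, numeric(1))
  expect_lt(abs(mean(ests2) / mean(ests) - 2), 0.2)
})

test_that("NLM at sigma 0 is the identity and negative sigma errors", {
  img <- image_slice(smooth_phantom(32, 32))
  out <- nlm_denoise(img, 0)
  expect_equal(out$pixels, img$pixels, tolerance = 1e-6)
  expect_equal(out$stage, "denoised")
  expect_error(nlm_denoise(img, -0.1), "non-negative")
})

test_that("NLM denoising moves a noisy phantom toward the clean one", {
  clean <- smooth_phantom()
  ratios <- vapply(1:20, function(s) {
    set.seed(s)
    noisy <- image_slice(pmin(pmax(clean + rnorm(length(clean), sd = 0.1),
                                   0), 1))
    den <- nlm_denoise(noisy, estimate_noise_sigma(noisy))
    mean((den$pixels - clean)^2) / mean((noisy$pixels - clean)^2)
  }, numeric(1))
  expect_gte(mean(ratios < 1), 0.95)   # MSE reduced in >= 95% of seeds
  expect_lt(max(ratios), 1.05)         # never degraded by more than 5%
})

test_that("explicit arguments and config defaults give identical NLM output", {
  set.seed(12)
  img <- image_slice(pmin(pmax(smooth_phantom(48, 48) +
                                 rnorm(48 * 48, sd = 0.08), 0), 1))
  a <- nlm_denoise(img, 0.08, preprocess_config())
  b <- nlm_denoise(img, 0.08, preprocess_config(patch_size = 2,
                                                patch_distance = 1))
  expect_identical(a$pixels, b$pixels)
  expect_equal(preprocess_config()$clahe_clip, 2.6)
})

test_that("CLAHE leaves a constant image constant", {
  flat <- image_slice(matrix(0.5, 176, 208))
  out <- clahe_enhance(flat)
  expect_equal(out$scale, "uint8")
  expect_equal(sd(out$pixels), 0)
})

test_that("CLAHE raises the histogram entropy of a low-contrast ramp", {
  # 8 intensity steps confined to [100, 140] of 255
  steps <- round(seq(100, 140, length.out = 8))[rep(1:8, each = 26)]
  ramp <- matrix(rep(steps, each = 176), 176, 208)
  img <- image_slice(ramp, scale = "uint8")
  out <- clahe_enhance(img)
  expect_gt(hist_entropy(out$pixels), hist_entropy(ramp))
  cfg <- preprocess_config()
  cfg$clahe_clip <- 0                  # non-positive clip is rejected
  expect_error(clahe_enhance(img, cfg), "clahe_clip")
  expect_error(preprocess_config(clahe_clip = -1), "clahe_clip")
})

test_that("every restoration stage preserves the image dimensions", {
  set.seed(5)
  img <- generate_slice(2, synthetic_spec(noise_sigma = 0.05))
  sig <- estimate_noise_sigma(img)
  den <- nlm_denoise(img, sig)
  enh <- clahe_enhance(den)
  expect_equal(dim(den), dim(img))
  expect_equal(dim(enh), dim(img))
})

test_that("the composed preprocess chain equals the manual composition", {
  set.seed(6)
  img <- generate_slice(1, synthetic_spec(noise_sigma = 0.05))
  manual <- clahe_enhance(nlm_denoise(img, estimate_noise_sigma(img)))
  composed <- preprocess_slice(img)
  expect_identical(composed$pixels, manual$pixels)
  expect_equal(composed$stage, "enhanced")
})

test_that("augmentation multiplies per-class counts and is seeded", {
  ds <- generate_dataset(synthetic_spec(n_total = 12,
                                        class_proportions = rep(0.25, 4),
                                        noise_sigma = 0.02, seed = 8))
  aug <- augment_dataset(ds, factor = 2, seed = 21)
  expect_equal(length(aug), 2L * length(ds))
  expect_equal(unname(class_counts(aug)), 2L * unname(class_counts(ds)))
  expect_equal(augment_dataset(ds, factor = 1, seed = 21), ds)
  # augmented copies carry the provenance tag
  expect_equal(aug$slices[[length(ds) + 1L]]$stage, "augmented")
  # reproducible under the seed, different across seeds
  aug2 <- augment_dataset(ds, factor = 2, seed = 21)
  aug3 <- augment_dataset(ds, factor = 2, seed = 22)
  i <- length(ds) + 1L
  expect_identical(aug$slices[[i]]$pixels, aug2$slices[[i]]$pixels)
  expect_false(identical(aug$slices[[i]]$pixels, aug3$slices[[i]]$pixels))
  # dimensions survive the affine warps
  expect_equal(dim(aug$slices[[i]]), dim(ds$slices[[1]]))
  # empty dataset passes through
  empty <- labeled_dataset(list(), integer())
  expect_equal(length(augment_dataset(empty, 2, 1)), 0L)
})

test_that("slices round-trip through PNG files and the directory layout", {
  ds <- generate_dataset(synthetic_spec(n_total = 8,
                                        class_proportions = rep(0.25, 4),
                                        noise_sigma = 0.02, seed = 10))
  dir <- tempfile()
  write_dataset(ds, dir, manifest = file.path(dir, "manifest.csv"))
  back <- read_dataset(dir)
  expect_equal(unname(class_counts(back)), unname(class_counts(ds)))
  expect_equal(dim(back$slices[[1]]), dim(ds$slices[[1]]))
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 8)
  # reading back groups slices by class; compare within 8-bit quantization
  orig_by_class <- unlist(lapply(1:4, function(ci)
    which(ds$labels == ci)), use.names = FALSE)
  for (j in seq_along(orig_by_class))
    expect_lt(max(abs(back$slices[[j]]$pixels -
                        ds$slices[[orig_by_class[j]]]$pixels)), 1 / 255)
})
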