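#' Configuration of the fused focal--dice loss
#'
#' Holds the tunables of the Categorical Generalized Focal Dice loss, the
#' convex fusion `(1 - lam) * GDL + lam * FL` of Focal Loss and Generalized
#' Dice Loss.
#'
#' @param gamma Focusing exponent of the focal term, >= 0. Larger values
#'   down-weight easy (high-probability) samples more aggressively.
#' @param alpha Positive balancing factor multiplying the focal term. Either
#'   a scalar applied uniformly to all classes or a length-C vector of
#'   per-class factors.
#' @param lam Fusion weight in \[0, 1\]: 0 gives pure Generalized Dice Loss,
#'   1 gives pure Focal Loss.
#' @param epsilon Smoothing value > 0; added to the Dice numerator and
#'   denominator and used as the floor when clamping probabilities before
#'   the focal log term.
#'
#' @return A `loss_config` object (a validated list).
#' @examples
#' loss_config()                    # gamma=2, alpha=4, lam=0.5
#' loss_config(gamma = 0, alpha = 1, lam = 1)  # plain cross-entropy
#' @export
loss_config <- function(gamma = 2, alpha = 4, lam = 0.5, epsilon = 1e-5) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0)
    stop("`gamma` must be a single number >= 0", call. = FALSE)
  if (!is.numeric(alpha) || any(alpha <= 0))
    stop("`alpha` must be positive", call. = FALSE)
  if (!is.numeric(lam) || length(lam) != 1L || lam < 0 || lam > 1)
    stop("`lam` must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("`epsilon` must be > 0", call. = FALSE)
  structure(list(gamma = gamma, alpha = alpha, lam = lam, epsilon = epsilon),
            class = "loss_config")
}

#' Serialize / deserialize a loss configuration
#'
#' Round-trips the configuration through a flat mapping
#' `{gamma, alpha, lambda, epsilon}` in JSON or YAML.
#'
#' @param cfg A `loss_config`.
#' @param path File path; extension `.json` or `.yaml`/`.yml` selects the
#'   format.
#' @return `write_loss_config` returns `path` invisibly; `read_loss_config`
#'   returns a `loss_config`.
#' @export
write_loss_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "loss_config"))
  x <- list(gamma = cfg$gamma, alpha = cfg$alpha, lambda = cfg$lam,
            epsilon = cfg$epsilon)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_loss_config
#' @export
read_loss_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  loss_config(gamma = x$gamma, alpha = unlist(x$alpha), lam = x$lambda,
              epsilon = x$epsilon)
}

check_prob_batch <- function(probs) {
  if (!is.matrix(probs) || ncol(probs) < 2L)
    stop("`probs` must be an N x C matrix with C >= 2", call. = FALSE)
  if (any(probs < -1e-9) || any(probs > 1 + 1e-9))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-6))
    stop("probability rows must sum to 1 (within 1e-6)", call. = FALSE)
  invisible(probs)
}

check_onehot_batch <- function(targets) {
  if (!is.matrix(targets))
    stop("`targets` must be an N x C matrix", call. = FALSE)
  if (!all(targets %in% c(0, 1)) || any(rowSums(targets) != 1))
    stop("`targets` must be one-hot: entries in {0,1}, one 1 per row",
         call. = FALSE)
  invisible(targets)
}

check_shapes <- function(probs, targets) {
  if (!identical(dim(probs), dim(targets)))
    stop(sprintf("shape mismatch: probs %dx%d vs targets %dx%d",
                 nrow(probs), ncol(probs), nrow(targets), ncol(targets)),
         call. = FALSE)
}

# per-sample alpha and clamped true-class probability, shared by FL fwd/grad
focal_parts <- function(probs, targets, cfg) {
  pt <- rowSums(probs * targets)
  a <- if (length(cfg$alpha) == 1L) rep(cfg$alpha, nrow(probs))
       else cfg$alpha[max.col(targets, ties.method = "first")]
  list(pt = pmin(pmax(pt, cfg$epsilon), 1), raw = pt, alpha = a)
}

#' Focal loss for multi-class probabilities
#'
#' Mean over samples of `-alpha * (1 - p_t)^gamma * log(p_t)` where `p_t` is
#' the probability the model assigned to the true class. `p_t` is clamped to
#' `[epsilon, 1]` before the logarithm so a zero probability yields a large
#' finite loss rather than infinity. With `gamma = 0, alpha = 1` this is the
#' mean categorical cross-entropy.
#'
#' @param probs N x C matrix of predicted class probabilities; rows sum to 1.
#' @param targets N x C one-hot matrix of ground-truth labels.
#' @param cfg A [loss_config()].
#' @return A non-negative scalar.
#' @examples
#' p <- rbind(c(0.9, 0.1)); r <- rbind(c(1, 0))
#' focal_loss(p, r, loss_config())          # 4 * 0.1^2 * -log(0.9)
#' @export
focal_loss <- function(probs, targets, cfg = loss_config()) {
  check_prob_batch(probs); check_onehot_batch(targets)
  check_shapes(probs, targets)
  fp <- focal_parts(probs, targets, cfg)
  mean(-fp$alpha * (1 - fp$pt)^cfg$gamma * log(fp$pt))
}

#' Gradient of the focal loss with respect to the probabilities
#'
#' @inheritParams focal_loss
#' @return N x C matrix `d(loss)/d(probs)`; zero at non-true-class entries
#'   and inside the clamped region.
#' @export
focal_loss_grad <- function(probs, targets, cfg = loss_config()) {
  check_shapes(probs, targets)
  fp <- focal_parts(probs, targets, cfg)
  n <- nrow(probs)
  g <- cfg$gamma
  # d/dp [-(1-p)^g log p] = g (1-p)^(g-1) log p - (1-p)^g / p
  mod <- if (g > 0) g * (1 - fp$pt)^(g - 1) * log(fp$pt) else 0
  dpt <- fp$alpha / n * (mod - (1 - fp$pt)^g / fp$pt)
  if (g > 0) dpt[fp$pt >= 1] <- 0    # one-sided limit at p_t = 1 is 0
  dpt[!is.finite(dpt)] <- 0
  dpt[fp$raw < cfg$epsilon | fp$raw > 1] <- 0  # clamp region: flat
  targets * dpt
}

#' Per-class Generalized Dice weights
#'
#' Weights `w_l = 1 / (sum_n r_ln)^2`, the inverse squared class volume,
#' which rebalance the Dice overlap so small classes contribute as much as
#' large ones. Classes absent from the batch would get infinite weight; they
#' are assigned the maximum finite weight among the classes present (or 1
#' if the batch is degenerate), keeping the loss finite while preserving
#' the emphasis on rarity.
#'
#' @param targets N x C one-hot matrix.
#' @return Numeric length-C vector of non-negative finite weights.
#' @examples
#' gdl_class_weights(rbind(c(1,0), c(1,0), c(0,1)))  # c(0.25, 1)
#' @export
gdl_class_weights <- function(targets) {
  check_onehot_batch(targets)
  counts <- colSums(targets)
  w <- 1 / counts^2
  if (any(!is.finite(w))) {
    fin <- w[is.finite(w)]
    w[!is.finite(w)] <- if (length(fin)) max(fin) else 1
  }
  w
}

gdl_parts <- function(probs, targets, cfg) {
  w <- gdl_class_weights(targets)
  num <- sum(w * colSums(targets * probs)) + cfg$epsilon
  den <- sum(w * colSums(targets + probs)) + cfg$epsilon
  list(w = w, num = num, den = den)
}

#' Generalized Dice loss over a batch
#'
#' `1 - 2 * (sum_l w_l sum_n r_ln p_ln + eps) / (sum_l w_l sum_n (r_ln +
#' p_ln) + eps)` with weights from [gdl_class_weights()]. The class sum runs
#' over all C classes and the sample index runs over the batch (the
#' segmentation formulation's per-pixel index becomes per-sample here).
#' Always lies in \[0, 1\]: 0 for a perfect prediction, 1 for a disjoint
#' one (as `epsilon` tends to 0).
#'
#' @inheritParams focal_loss
#' @return Scalar in \[0, 1\].
#' @export
generalized_dice_loss <- function(probs, targets, cfg = loss_config()) {
  check_prob_batch(probs); check_onehot_batch(targets)
  check_shapes(probs, targets)
  gp <- gdl_parts(probs, targets, cfg)
  1 - 2 * gp$num / gp$den
}

#' Gradient of the Generalized Dice loss with respect to the probabilities
#'
#' The class weights depend only on the targets and are treated as constant.
#'
#' @inheritParams focal_loss
#' @return N x C matrix `d(loss)/d(probs)`.
#' @export
generalized_dice_loss_grad <- function(probs, targets, cfg = loss_config()) {
  check_shapes(probs, targets)
  gp <- gdl_parts(probs, targets, cfg)
  wmat <- matrix(gp$w, nrow(probs), ncol(probs), byrow = TRUE)
  # d/dp (1 - 2 num/den): num' = w_l r_nl, den' = w_l
  -2 * (wmat * targets * gp$den - gp$num * wmat) / gp$den^2
}

#' Categorical Generalized Focal Dice loss (the fused loss)
#'
#' Convex combination `(1 - lam) * GDL + lam * FL` evaluated on the same
#' batch. `lam = 0` reduces to [generalized_dice_loss()], `lam = 1` to
#' [focal_loss()]; the default `lam = 0.5` weights both equally.
#'
#' @inheritParams focal_loss
#' @return Non-negative scalar.
#' @examples
#' p <- rbind(c(0.8, 0.2), c(0.4, 0.6))
#' r <- rbind(c(1, 0), c(0, 1))
#' fusion_loss(p, r, loss_config(lam = 0.5))
#' @export
fusion_loss <- function(probs, targets, cfg = loss_config()) {
  if (cfg$lam < 0 || cfg$lam > 1)
    stop("fusion weight `lam` must lie in [0, 1]", call. = FALSE)
  (1 - cfg$lam) * generalized_dice_loss(probs, targets, cfg) +
    cfg$lam * focal_loss(probs, targets, cfg)
}

#' @rdname fusion_loss
#' @return `fusion_loss_grad`: N x C gradient matrix.
#' @export
fusion_loss_grad <- function(probs, targets, cfg = loss_config()) {
  (1 - cfg$lam) * generalized_dice_loss_grad(probs, targets, cfg) +
    cfg$lam * focal_loss_grad(probs, targets, cfg)
}
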