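#' Training configuration
#'
#' @param batch_size Minibatch size; default 32.
#' @param epochs Number of passes over the training set.
#' @param learning_rate ADAM step size; default 1e-4.
#' @param val_fraction Fraction of the data held out for validation when a
#'   split is made; default 0.2.
#' @param k_folds Folds for cross-validation; default 5.
#' @param seed Integer seed governing shuffling and initialization.
#' @param loss A [loss_config()].
#' @param model A [model_config()].
#' @param mode `"multiclass"` (all four stages) or `"binary"` (no-dementia
#'   versus any dementia).
#' @return A `train_config` object.
#' @export
train_config <- function(batch_size = 32L, epochs = 30L,
                         learning_rate = 1e-4, val_fraction = 0.2,
                         k_folds = 5L, seed = 1L, loss = loss_config(),
                         model = model_config(),
                         mode = c("multiclass", "binary")) {
  mode <- match.arg(mode)
  stopifnot(batch_size >= 1, epochs >= 0, learning_rate > 0,
            val_fraction > 0, val_fraction < 1, k_folds >= 2)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 val_fraction = val_fraction, k_folds = as.integer(k_folds),
                 seed = as.integer(seed), loss = loss, model = model,
                 mode = mode),
            class = "train_config")
}

#' Stratified train / validation split
#'
#' Splits per class so the validation set preserves the class proportions:
#' each class contributes `round(val_fraction * n_class)` samples. A class
#' with fewer than 2 samples is kept whole in the training set with a
#' warning. Deterministic given `seed`.
#'
#' @param ds A `labeled_dataset`.
#' @param val_fraction Fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `val`, both `labeled_dataset`s; disjoint,
#'   union equal to `ds`.
#' @export
split_train_val <- function(ds, val_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(ds, "labeled_dataset"),
            val_fraction > 0, val_fraction < 1)
  val_idx <- integer(0)
  with_seed(seed, {
    for (ci in seq_along(ds$class_names)) {
      members <- which(ds$labels == ci)
      if (length(members) == 0L) next
      if (length(members) < 2L) {
        warning(sprintf("class %d has < 2 samples; kept whole in train", ci),
                call. = FALSE)
        next
      }
      n_val <- round(val_fraction * length(members))
      if (n_val > 0)
        val_idx <- c(val_idx, sample(members, n_val))
    }
  })
  train_idx <- setdiff(seq_along(ds$labels), val_idx)
  list(train = dataset_subset(ds, train_idx),
       val = dataset_subset(ds, sort(val_idx)))
}

#' k disjoint cross-validation folds
#'
#' Partitions `1..n` into `k` folds whose sizes differ by at most one,
#' after a seeded shuffle. `stratified_kfold` does the same per class so
#' every fold preserves the class proportions within one sample.
#'
#' @param n Number of items; must satisfy `k <= n`.
#' @param k Number of folds, >= 2.
#' @param seed Integer seed.
#' @return List of `k` integer index vectors partitioning `1..n`.
#' @export
kfold_indices <- function(n, k = 5L, seed = 1L) {
  if (k > n) stop("`k` must not exceed `n`", call. = FALSE)
  idx <- with_seed(seed, sample.int(n))
  grp <- rep(seq_len(k), length.out = n)  # sizes differ by at most 1
  lapply(seq_len(k), function(f) sort(idx[grp == f]))
}

#' @rdname kfold_indices
#' @param labels Integer class labels of the `n` items.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  n <- length(labels)
  if (k > n) stop("`k` must not exceed `n`", call. = FALSE)
  folds <- vector("list", k)
  with_seed(seed, {
    for (ci in unique(labels)) {
      members <- sample(which(labels == ci))
      grp <- rep(seq_len(k), length.out = length(members))
      for (f in seq_len(k))
        folds[[f]] <- c(folds[[f]], members[grp == f])
    }
  })
  lapply(folds, sort)
}

onehot <- function(labels, C) {
  m <- matrix(0, length(labels), C)
  m[cbind(seq_along(labels), labels)] <- 1
  m
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (k in names(grads)) {
    g <- grads[[k]]
    state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * g
    state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / corr1) / (sqrt(state$v[[k]] / corr2) + eps)
  }
  list(params = params, state = state)
}

# map the fused-loss gradient wrt probabilities back through the softmax
softmax_backprop <- function(probs, dprobs) {
  probs * (dprobs - rowSums(dprobs * probs))
}

collapse_binary <- function(labels) ifelse(labels == 1L, 1L, 2L)

dataset_matrices <- function(cfg_model, ds) slices_as_matrices(cfg_model, ds)

#' Train the residual network with ADAM on the fused loss
#'
#' Minibatch ADAM optimization of the Categorical Generalized Focal Dice
#' loss ([fusion_loss()]), fully reproducible given `cfg$seed`: the seed
#' fixes the Xavier initialization and every epoch's shuffling. After each
#' epoch the validation loss and accuracy are recorded and the weights with
#' the best validation accuracy so far are retained as the checkpoint.
#' Training aborts with a diagnostic if the loss turns non-finite.
#'
#' @param train_ds,val_ds Non-empty `labeled_dataset`s. In `"binary"` mode
#'   four-stage labels are collapsed to no-dementia vs dementia, and
#'   `cfg$model$n_classes` must be 2.
#' @param cfg A [train_config()].
#' @return List with `model` (best checkpoint, a `gfd_model`), `final_model`
#'   (last epoch), and `history` (data frame: epoch, train_loss, val_loss,
#'   val_accuracy).
#' @export
train <- function(train_ds, val_ds, cfg = train_config()) {
  stopifnot(inherits(cfg, "train_config"),
            length(train_ds) > 0, length(val_ds) > 0)
  C <- cfg$model$n_classes
  tr_labels <- train_ds$labels
  va_labels <- val_ds$labels
  if (cfg$mode == "binary") {
    if (C != 2L)
      stop("binary mode requires a 2-class model", call. = FALSE)
    tr_labels <- collapse_binary(tr_labels)
    va_labels <- collapse_binary(va_labels)
  } else if (max(c(tr_labels, va_labels)) > C) {
    stop("dataset has more classes than the model", call. = FALSE)
  }
  xs_tr <- dataset_matrices(cfg$model, train_ds)
  xs_va <- dataset_matrices(cfg$model, val_ds)
  net <- build_model(cfg$model, seed = cfg$seed)
  if (cfg$epochs == 0L)
    return(list(model = net, final_model = net,
                history = data.frame(epoch = integer(), train_loss = numeric(),
                                     val_loss = numeric(),
                                     val_accuracy = numeric())))
  st <- adam_init(net$params)
  n <- length(xs_tr)
  hist <- vector("list", cfg$epochs)
  best <- list(acc = -Inf, params = net$params)
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; n_batches <- 0L
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        fw <- batch_forward(net, xs_tr[idx], keep_cache = TRUE)
        probs <- softmax_rows(fw$logits)
        tgt <- onehot(tr_labels[idx], C)
        loss <- fusion_loss(probs, tgt, cfg$loss)
        if (!is.finite(loss))
          stop(sprintf("training diverged at epoch %d (non-finite loss)", ep),
               call. = FALSE)
        dprobs <- fusion_loss_grad(probs, tgt, cfg$loss)
        grads <- batch_backward(net, fw$caches,
                                softmax_backprop(probs, dprobs))
        upd <- adam_step(net$params, grads, st, cfg$learning_rate)
        net$params <- upd$params
        st <- upd$state
        ep_loss <- ep_loss + loss
        n_batches <- n_batches + 1L
      }
      va_probs <- softmax_rows(batch_forward(net, xs_va, FALSE)$logits)
      va_tgt <- onehot(va_labels, C)
      va_loss <- fusion_loss(va_probs, va_tgt, cfg$loss)
      va_acc <- mean(max.col(va_probs, ties.method = "first") == va_labels)
      if (va_acc >= best$acc) best <- list(acc = va_acc, params = net$params)
      hist[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss / n_batches,
                               val_loss = va_loss, val_accuracy = va_acc)
    }
  })
  best_net <- net
  best_net$params <- best$params
  list(model = best_net, final_model = net, history = do.call(rbind, hist))
}

#' Evaluate a trained model on a test dataset
#'
#' Argmax class decisions, then confusion-matrix metrics. In `"binary"`
#' mode the three dementia stages collapse into one positive class; a
#' 4-class model's predictions are collapsed the same way, so either a
#' binary or a 4-class model can be scored on the binary task.
#'
#' @param net A `gfd_model`.
#' @param test_ds A `labeled_dataset`.
#' @param mode `"multiclass"` or `"binary"`.
#' @return A [metrics_report()] augmented with the prediction vector.
#' @export
evaluate <- function(net, test_ds, mode = c("multiclass", "binary")) {
  mode <- match.arg(mode)
  C <- net$cfg$n_classes
  labels <- test_ds$labels
  probs <- predict_probs(net, test_ds)
  pred <- max.col(probs, ties.method = "first")
  if (mode == "binary") {
    if (!C %in% c(2L, 4L))
      stop("binary evaluation needs a 2- or 4-class model", call. = FALSE)
    if (C == 4L) pred <- collapse_binary(pred)
    labels <- collapse_binary(labels)
    cm <- confusion(pred, labels, 2L)
    names_used <- c("NonDemented", "Demented")
  } else {
    if (max(labels) > C)
      stop("dataset has more classes than the model", call. = FALSE)
    cm <- confusion(pred, labels, C)
    names_used <- head(test_ds$class_names, C)
  }
  rep <- metrics_report(cm, names_used)
  rep$predictions <- pred
  rep
}

#' k-fold cross-validation of the full training procedure
#'
#' Stratified folds; each fold is held out once while the rest train a
#' fresh model (with a further internal validation split for checkpoint
#' selection).
#'
#' @param ds A `labeled_dataset`.
#' @param cfg A [train_config()]; `cfg$k_folds` folds are used.
#' @return List of per-fold [evaluate()] reports plus a `summary` data
#'   frame of fold accuracies.
#' @export
cross_validate <- function(ds, cfg = train_config()) {
  folds <- stratified_kfold(ds$labels, cfg$k_folds, cfg$seed)
  reports <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    test_ds <- dataset_subset(ds, folds[[f]])
    rest <- dataset_subset(ds, setdiff(seq_along(ds$labels), folds[[f]]))
    sp <- split_train_val(rest, cfg$val_fraction, cfg$seed + f)
    fit <- suppressWarnings(train(sp$train, sp$val, cfg))
    reports[[f]] <- evaluate(fit$model, test_ds, cfg$mode)
  }
  acc <- vapply(reports, function(r) r$accuracy, numeric(1))
  list(folds = reports,
       summary = data.frame(fold = seq_along(folds), accuracy = acc))
}
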