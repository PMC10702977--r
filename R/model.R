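#' Architecture configuration of the residual classifier
#'
#' Describes the residual-block convolutional network: a sequence of stages,
#' each `conv3x3 -> GroupNorm -> ReLU -> conv3x3 -> GroupNorm`, a residual
#' addition (identity when channels match, 1x1 projection otherwise),
#' ReLU, and 2x2 max-pooling; then global average pooling, one hidden
#' fully-connected layer with ReLU, and a softmax output layer.
#'
#' The defaults (stages 32/64/128/256/512, 8 normalization groups, 256-unit
#' head, 4 classes, 176 x 208 input) instantiate the full-scale classifier,
#' which stays within a 5.45-million trainable-parameter budget.
#'
#' @param stage_widths Integer vector of output channels per residual stage.
#' @param gn_groups GroupNorm group count; must divide every stage width.
#' @param head_width Hidden units of the fully-connected head.
#' @param n_classes Number of output classes.
#' @param input_shape Integer length-2 `(H, W)` of the grayscale input.
#' @param residual Keep the residual (shortcut) connections; `FALSE` is an
#'   ablation switch that removes the additions and their projection convs.
#' @return A `model_config` object.
#' @export
model_config <- function(stage_widths = c(32L, 64L, 128L, 256L, 512L),
                         gn_groups = 8L, head_width = 256L, n_classes = 4L,
                         input_shape = c(176L, 208L), residual = TRUE) {
  stage_widths <- as.integer(stage_widths)
  if (any(stage_widths %% gn_groups != 0L))
    stop("`gn_groups` must divide every stage width", call. = FALSE)
  h <- input_shape[1]; w <- input_shape[2]
  for (i in seq_along(stage_widths)) { h <- h %/% 2L; w <- w %/% 2L }
  if (h < 1L || w < 1L)
    stop("input too small for the number of pooling stages", call. = FALSE)
  structure(list(stage_widths = stage_widths,
                 gn_groups = as.integer(gn_groups),
                 head_width = as.integer(head_width),
                 n_classes = as.integer(n_classes),
                 input_shape = as.integer(input_shape),
                 residual = isTRUE(residual)),
            class = "model_config")
}

xavier_init <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

#' Build the residual network
#'
#' Instantiates the network described by `cfg` with Xavier (Glorot uniform)
#' weight initialization — conv and fully-connected weights drawn from
#' `U(-a, a)` with `a = sqrt(6 / (fan_in + fan_out))`, biases zero,
#' GroupNorm scale 1 and offset 0 — reproducibly from `seed`.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for the weight draw.
#' @return A `gfd_model`: configuration, named parameter arrays, and the
#'   layer-by-layer [describe_model()] table.
#' @examples
#' net <- build_model(model_config(stage_widths = c(8, 16), gn_groups = 4,
#'                                 head_width = 16, input_shape = c(32, 32)))
#' count_parameters(net)
#' @export
build_model <- function(cfg = model_config(), seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  params <- list()
  desc <- list()
  add <- function(name, kind, in_ch, out_ch, kernel, n) {
    desc[[length(desc) + 1L]] <<- data.frame(
      layer = name, kind = kind, in_ch = in_ch, out_ch = out_ch,
      kernel = kernel, params = n, stringsAsFactors = FALSE)
  }
  with_seed(seed, {
    in_ch <- 1L
    for (s in seq_along(cfg$stage_widths)) {
      out_ch <- cfg$stage_widths[s]
      nm <- function(part) sprintf("s%d.%s", s, part)
      params[[nm("conv_a.W")]] <- xavier_init(c(3, 3, in_ch, out_ch),
                                              9 * in_ch, 9 * out_ch)
      params[[nm("conv_a.b")]] <- numeric(out_ch)
      add(nm("conv_a"), "conv3x3", in_ch, out_ch, "3x3",
          9 * in_ch * out_ch + out_ch)
      params[[nm("gn_a.gamma")]] <- rep(1, out_ch)
      params[[nm("gn_a.beta")]] <- numeric(out_ch)
      add(nm("gn_a"), "groupnorm", out_ch, out_ch, "-", 2 * out_ch)
      params[[nm("conv_b.W")]] <- xavier_init(c(3, 3, out_ch, out_ch),
                                              9 * out_ch, 9 * out_ch)
      params[[nm("conv_b.b")]] <- numeric(out_ch)
      add(nm("conv_b"), "conv3x3", out_ch, out_ch, "3x3",
          9 * out_ch * out_ch + out_ch)
      params[[nm("gn_b.gamma")]] <- rep(1, out_ch)
      params[[nm("gn_b.beta")]] <- numeric(out_ch)
      add(nm("gn_b"), "groupnorm", out_ch, out_ch, "-", 2 * out_ch)
      if (cfg$residual && in_ch != out_ch) {
        params[[nm("proj.W")]] <- xavier_init(c(1, 1, in_ch, out_ch),
                                              in_ch, out_ch)
        params[[nm("proj.b")]] <- numeric(out_ch)
        add(nm("proj"), "conv1x1", in_ch, out_ch, "1x1",
            in_ch * out_ch + out_ch)
      }
      add(nm("pool"), "maxpool2x2", out_ch, out_ch, "2x2", 0)
      in_ch <- out_ch
    }
    add("gap", "global_avg_pool", in_ch, in_ch, "-", 0)
    params[["head.fc1.W"]] <- xavier_init(c(in_ch, cfg$head_width),
                                          in_ch, cfg$head_width)
    dim(params[["head.fc1.W"]]) <- c(in_ch, cfg$head_width)
    params[["head.fc1.b"]] <- numeric(cfg$head_width)
    add("head.fc1", "fc", in_ch, cfg$head_width, "-",
        in_ch * cfg$head_width + cfg$head_width)
    params[["head.fc2.W"]] <- xavier_init(c(cfg$head_width, cfg$n_classes),
                                          cfg$head_width, cfg$n_classes)
    dim(params[["head.fc2.W"]]) <- c(cfg$head_width, cfg$n_classes)
    params[["head.fc2.b"]] <- numeric(cfg$n_classes)
    add("head.fc2", "fc", cfg$head_width, cfg$n_classes, "-",
        cfg$head_width * cfg$n_classes + cfg$n_classes)
    add("softmax", "softmax", cfg$n_classes, cfg$n_classes, "-", 0)
  })
  description <- do.call(rbind, desc)
  attr(description, "total_params") <- sum(description$params)
  structure(list(cfg = cfg, params = params, description = description),
            class = "gfd_model")
}

#' @export
print.gfd_model <- function(x, ...) {
  cat(sprintf("<gfd_model: %d stages (%s), %s trainable parameters>\n",
              length(x$cfg$stage_widths),
              paste(x$cfg$stage_widths, collapse = "/"),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Layer-by-layer network description
#'
#' @param net A `gfd_model`.
#' @return A data frame with one row per layer (kind, channels, kernel,
#'   parameter count) and attribute `total_params`; the total equals the sum
#'   of the rows and matches [count_parameters()].
#' @export
describe_model <- function(net) {
  stopifnot(inherits(net, "gfd_model"))
  net$description
}

#' Count trainable parameters by direct enumeration
#'
#' Sums the lengths of every parameter array actually stored in the model —
#' an independent path from the per-layer formula totals of
#' [describe_model()].
#'
#' @param net A `gfd_model`.
#' @return Integer-valued scalar.
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "gfd_model"))
  sum(vapply(net$params, length, integer(1)))
}

#' Class probabilities for a batch of slices
#'
#' Runs the forward pass and softmax. Deterministic for fixed weights and
#' input.
#'
#' @param net A `gfd_model`.
#' @param x A `labeled_dataset`, a list of `image_slice`/matrices, or a
#'   single H x W matrix. Slices must match `cfg$input_shape` and are used
#'   on the unit scale.
#' @return N x `n_classes` matrix of probabilities; rows sum to 1.
#' @export
predict_probs <- function(net, x) {
  xs <- slices_as_matrices(net$cfg, x)
  softmax_rows(batch_forward(net, xs, keep_cache = FALSE)$logits)
}

# normalize the accepted input forms to a list of unit-scale H x W matrices
slices_as_matrices <- function(cfg, x) {
  if (inherits(x, "labeled_dataset")) x <- x$slices
  if (is.matrix(x)) x <- list(x)
  xs <- lapply(x, function(s) {
    if (inherits(s, "image_slice")) s <- as_unit_scale(s)$pixels
    if (!identical(dim(s), as.integer(cfg$input_shape)))
      stop(sprintf("input slice is %s but the model expects %s",
                   paste(dim(s), collapse = "x"),
                   paste(cfg$input_shape, collapse = "x")), call. = FALSE)
    s
  })
  xs
}

#' Empirical check of the Xavier initialization
#'
#' For every conv / fully-connected weight tensor reports the empirical
#' variance next to the Glorot target `2 / (fan_in + fan_out)`.
#'
#' @param net A freshly built `gfd_model`.
#' @return Data frame with columns `layer`, `n`, `emp_var`, `target_var`,
#'   `ratio`.
#' @export
xavier_stats_check <- function(net) {
  stopifnot(inherits(net, "gfd_model"))
  rows <- list()
  for (name in names(net$params)) {
    if (!grepl("\\.W$", name)) next
    W <- net$params[[name]]
    d <- dim(W)
    if (length(d) == 4L) {
      fan_in <- d[1] * d[2] * d[3]; fan_out <- d[1] * d[2] * d[4]
    } else {
      fan_in <- d[1]; fan_out <- d[2]
    }
    target <- 2 / (fan_in + fan_out)
    rows[[length(rows) + 1L]] <- data.frame(
      layer = sub("\\.W$", "", name), n = length(W),
      emp_var = var(as.numeric(W)), target_var = target,
      ratio = var(as.numeric(W)) / target, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a directory holding the serialized weights
#' (`weights.json`) together with the `model_config` that produced them
#' (`config.json`); loading verifies the stored config equals the requested
#' one.
#'
#' @param net A `gfd_model`.
#' @param dir Checkpoint directory (created if needed).
#' @return `save_checkpoint`: `dir` invisibly; `load_checkpoint`: a
#'   `gfd_model`.
#' @export
save_checkpoint <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- net$cfg
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  flat <- lapply(net$params, function(p)
    list(dim = if (is.null(dim(p))) length(p) else dim(p),
         values = as.numeric(p)))
  jsonlite::write_json(flat, file.path(dir, "weights.json"), digits = NA)
  invisible(dir)
}

#' @rdname save_checkpoint
#' @param expected_cfg Optional `model_config`; if given, loading fails
#'   unless it matches the stored one.
#' @export
load_checkpoint <- function(dir, expected_cfg = NULL) {
  cj <- jsonlite::read_json(file.path(dir, "config.json"),
                            simplifyVector = TRUE)
  cfg <- model_config(stage_widths = cj$stage_widths,
                      gn_groups = cj$gn_groups, head_width = cj$head_width,
                      n_classes = cj$n_classes, input_shape = cj$input_shape,
                      residual = cj$residual)
  if (!is.null(expected_cfg) && !identical(unclass(cfg),
                                           unclass(expected_cfg)))
    stop("checkpoint config does not match the expected config",
         call. = FALSE)
  net <- build_model(cfg, seed = 0L)
  wj <- jsonlite::read_json(file.path(dir, "weights.json"),
                            simplifyVector = TRUE)
  for (name in names(net$params)) {
    v <- wj[[name]]$values
    d <- wj[[name]]$dim
    if (length(d) > 1L) dim(v) <- d
    net$params[[name]] <- v
  }
  net
}
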