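#' Backbone specification
#'
#' The image-feature extractor shared by the centerline and radius heads.
#' `tiny_conv` -- four 3x3 convolution blocks (8, 16, 32, 64 filters),
#' each followed by ReLU and 2x2 average pooling -- is the CPU-scale
#' backbone implemented by this package and the default for all
#' experiments here; it emits a flat feature vector of
#' `(image_size/16)^2 * 64` entries. The constructor interface is
#' pluggable so that larger extractors (ResNet-class, EfficientNet-class,
#' transformer-class) can be swapped in by supplying a `builder` function
#' returning a layer stack with the same contract.
#'
#' @param name backbone identifier.
#' @param input_channels number of input distance maps stacked as
#'   channels.
#' @param image_size square input size in pixels (multiple of 16 for
#'   `tiny_conv`).
#' @param builder optional function `(input_channels, image_size) ->
#'   list(layers =, feature_dim =)` for custom backbones.
#' @return object of class `backbone_spec`.
#' @export
backbone_spec <- function(name = "tiny_conv", input_channels = 3L,
                          image_size = 512L, builder = NULL) {
  if (is.null(builder) && name != "tiny_conv")
    stop("only the 'tiny_conv' backbone is built in; supply `builder` ",
         "for other feature extractors")
  if (name == "tiny_conv" && image_size %% 16L != 0L)
    stop("tiny_conv needs image_size divisible by 16")
  structure(list(name = name, input_channels = as.integer(input_channels),
                 image_size = as.integer(image_size), builder = builder),
            class = "backbone_spec")
}

build_backbone <- function(spec) {
  if (!is.null(spec$builder)) return(spec$builder(spec$input_channels,
                                                  spec$image_size))
  ch <- c(spec$input_channels, 8L, 16L, 32L, 64L)
  layers <- list()
  for (i in 1:4) {
    layers <- c(layers, list(layer_conv(ch[i], ch[i + 1]), layer_relu(),
                             layer_pool()))
  }
  layers <- c(layers, list(layer_flatten()))
  list(layers = layers,
       feature_dim = as.integer((spec$image_size / 16L)^2 * 64L))
}

# MLP head: dense/BN/ReLU per hidden layer, linear output
build_mlp_head <- function(in_dim, hidden, out_dim) {
  layers <- list()
  d <- in_dim
  for (h in hidden) {
    layers <- c(layers, list(layer_dense(d, h), layer_bn(h), layer_relu()))
    d <- h
  }
  c(layers, list(layer_dense(d, out_dim)))
}

#' Training configuration
#'
#' Hyperparameters of the reconstruction networks: Adam with learning
#' rate 5e-4 and L2 weight decay, batch size 8, a main joint phase (300
#' epochs at full scale) and, for the multi-stage model, a radius
#' fine-tuning phase (50 epochs) with the backbone frozen. `lambda` is
#' the arclength-regularization rate of the centerline loss (0.1, with
#' the 1/batch-size normalization of the length term applied explicitly
#' inside the loss). `mu` is the radius weight of the single-stage loss;
#' `NULL` selects it by the order-of-magnitude balancing rule
#' ([mu_balance()]) from the first epoch's running errors, frozen
#' thereafter.
#'
#' @param learning_rate Adam learning rate.
#' @param weight_decay L2 coefficient on weights.
#' @param batch_size samples per gradient step.
#' @param epochs_main joint-training epochs.
#' @param epochs_radius_finetune per-branch radius fine-tuning epochs.
#' @param lambda arclength-regularization rate (>= 0).
#' @param mu single-stage radius weight (> 0), or `NULL` for the
#'   balancing rule.
#' @param signed_length use the signed arclength difference in the
#'   centerline loss (see [centerline_loss()]).
#' @param seed RNG seed covering initialization and batch order.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-4, weight_decay = 1e-4,
                         batch_size = 8L, epochs_main = 300L,
                         epochs_radius_finetune = 50L, lambda = 0.1,
                         mu = NULL, signed_length = FALSE, seed = 1L) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (!is.null(mu) && mu <= 0) stop("mu must be > 0")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs_main = as.integer(epochs_main),
                 epochs_radius_finetune = as.integer(epochs_radius_finetune),
                 lambda = lambda, mu = mu, signed_length = signed_length,
                 seed = as.integer(seed)),
            class = "train_config")
}

# ---- sample plumbing ------------------------------------------------------

# samples: list of list(maps = list of k HxW matrices, tree = M x N x 4)
# -> input array (H, W, k, B) (normalized) and target arrays
stack_inputs <- function(samples, idx, input_max) {
  k <- length(samples[[1]]$maps)
  H <- nrow(samples[[1]]$maps[[1]])
  x <- array(0, c(H, H, k, length(idx)))
  for (b in seq_along(idx))
    for (c in seq_len(k))
      x[, , c, b] <- samples[[idx[b]]]$maps[[c]]
  x / input_max
}

target_arrays <- function(samples, idx) {
  tr <- samples[[idx[1]]]$tree
  M <- dim(tr)[1]; N <- dim(tr)[2]
  B <- length(idx)
  y <- array(0, c(B, M, N, 3)); r <- array(0, c(B, M, N))
  for (b in seq_along(idx)) {
    tb <- unclass(samples[[idx[b]]]$tree)
    y[b, , , ] <- tb[, , 1:3]
    r[b, , ] <- tb[, , 4]
  }
  list(y = y, r = r)
}

# batch matrix (B x M*N*3) <-> array (B, M, N, 3)
vec_to_coord_array <- function(Y, M, N) {
  B <- nrow(Y)
  aperm(array(t(Y), c(M, N, 3, B)), c(4, 1, 2, 3))
}
coord_array_to_vec <- function(A) {
  d <- dim(A)
  t(matrix(aperm(A, c(2, 3, 4, 1)), prod(d[2:4]), d[1]))
}

# normalization statistics: input scale, shared-isotropy coordinate
# standardization (per-axis mean, one common sd so geometry and
# arclengths survive the transform up to a uniform scale), radius
# mean/sd
norm_stats <- function(samples) {
  input_max <- max(vapply(samples, function(s)
    max(vapply(s$maps, max, 0)), 0))
  if (input_max <= 0) input_max <- 1
  coords <- do.call(rbind, lapply(samples, function(s) {
    tb <- unclass(s$tree)
    matrix(tb[, , 1:3], ncol = 3)
  }))
  rads <- unlist(lapply(samples, function(s) unclass(s$tree)[, , 4]))
  list(input_max = input_max,
       coord_mean = colMeans(coords),
       coord_sd = sqrt(mean(apply(coords, 2, stats::var))),
       r_mean = mean(rads), r_sd = max(stats::sd(rads), 1e-6))
}

# ---- model objects --------------------------------------------------------

new_recon_model <- function(mode, backbone, bspec, heads, M, N, norm,
                            config) {
  structure(list(mode = mode, backbone = backbone, backbone_spec = bspec,
                 heads = heads, M = M, N = N, norm = norm, config = config,
                 history = NULL),
            class = "coronary_recon")
}

#' @export
print.coronary_recon <- function(x, ...) {
  cat("Coronary reconstruction network (", x$mode, "-stage)\n", sep = "")
  cat("  backbone:", x$backbone_spec$name, "- input",
      x$backbone_spec$image_size, "px x", x$backbone_spec$input_channels,
      "channel(s),", n_params(x$backbone), "parameters\n")
  if (x$mode == "multi") {
    cat("  centerline head:", n_params(x$heads$centerline), "parameters ->",
        x$M, "x", x$N, "x 3\n")
    cat("  radius heads:", length(x$heads$radius), "x",
        n_params(x$heads$radius[[1]]), "parameters ->", x$N, "each\n")
  } else {
    cat("  head:", n_params(x$heads$joint), "parameters ->",
        x$M, "x", x$N, "x 4\n")
  }
  if (!is.null(x$history))
    cat("  trained:", max(x$history$epoch), "epochs; final loss",
        format(utils::tail(x$history$total, 1), digits = 4), "\n")
  invisible(x)
}

#' Hidden-layer widths of the model's regression heads
#'
#' Structural accessor used to assert the head architecture: the
#' centerline perceptron has four hidden layers (1024, 1024, 1024, 512)
#' and each per-branch radius perceptron has three hidden layers of 128.
#'
#' @param model a trained or untrained `coronary_recon`.
#' @return named list of integer vectors.
#' @export
head_widths <- function(model) {
  widths <- function(layers) {
    dense <- Filter(function(l) l$type == "dense", layers)
    w <- vapply(dense, function(l) ncol(l$params$W), 0L)
    w[-length(w)]                       # hidden layers only
  }
  if (model$mode == "multi")
    list(centerline = widths(model$heads$centerline),
         radius = lapply(model$heads$radius, widths))
  else list(joint = widths(model$heads$joint))
}

# forward through backbone + heads; returns mm-space predictions and the
# caches needed for backprop
model_forward_full <- function(model, x, training = TRUE) {
  bb <- net_forward(model$backbone, x, training)
  feat <- bb$out
  M <- model$M; N <- model$N; nm <- model$norm
  if (model$mode == "multi") {
    ch <- net_forward(model$heads$centerline, feat, training)
    yv <- ch$out                         # B x M*N*3, normalized
    ya <- vec_to_coord_array(yv, M, N)
    y_mm <- ya * nm$coord_sd
    for (j in 1:3) y_mm[, , , j] <- y_mm[, , , j] + nm$coord_mean[j]
    rh <- lapply(model$heads$radius, function(h)
      net_forward(h, feat, training))
    r_mm <- array(0, c(nrow(feat), M, N))
    for (m in seq_len(M)) r_mm[, m, ] <- rh[[m]]$out * nm$r_sd + nm$r_mean
    list(bb = bb, ch = ch, rh = rh, y_mm = y_mm, r_mm = r_mm)
  } else {
    jh <- net_forward(model$heads$joint, feat, training)
    out <- jh$out                        # B x M*N*4
    B <- nrow(out)
    arr <- aperm(array(t(out), c(M, N, 4, B)), c(4, 1, 2, 3))
    y_mm <- arr[, , , 1:3, drop = FALSE] * nm$coord_sd
    for (j in 1:3) y_mm[, , , j] <- y_mm[, , , j] + nm$coord_mean[j]
    r_mm <- array(arr[, , , 4, drop = FALSE], c(B, M, N)) * nm$r_sd +
      nm$r_mean
    list(bb = bb, jh = jh, y_mm = y_mm, r_mm = r_mm)
  }
}

#' Reconstruct a coronary tree from distance maps
#'
#' Runs the trained network in inference mode on a set of
#' distance-transformed binary projections (no view geometry is -- or can
#' be -- supplied: the method is uncalibrated by construction). Radii are
#' floored at 0.01 mm so the result is a valid tree matrix.
#'
#' @param object a trained `coronary_recon`.
#' @param maps list of `input_channels` distance maps (matrices).
#' @param ... unused.
#' @return a [coronary_tree()] of dimension `M x N x 4`.
#' @export
predict.coronary_recon <- function(object, maps, ...) {
  k <- object$backbone_spec$input_channels
  if (length(maps) != k)
    stop("expected ", k, " input maps, got ", length(maps))
  H <- object$backbone_spec$image_size
  x <- array(0, c(H, H, k, 1L))
  for (c in seq_len(k)) x[, , c, 1] <- maps[[c]]
  x <- x / object$norm$input_max
  fw <- model_forward_full(object, x, training = FALSE)
  M <- object$M; N <- object$N
  out <- array(0, c(M, N, 4))
  out[, , 1:3] <- array(fw$y_mm[1, , , , drop = FALSE], c(M, N, 3))
  out[, , 4] <- pmax(array(fw$r_mm[1, , , drop = FALSE], c(M, N)), 0.01)
  coronary_tree(out, validate = FALSE)
}

#' @export
plot.coronary_recon <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  graphics::plot(h$epoch, h$total, type = "l", log = "y",
                 xlab = "epoch", ylab = "training loss",
                 main = paste0(x$mode, "-stage training"), ...)
  if (!is.null(h$radius))
    graphics::lines(h$epoch, h$radius, col = 2)
  invisible(x)
}
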