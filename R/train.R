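#' Train the multi-stage reconstruction network
#'
#' Phase 1 jointly trains the shared backbone, the centerline head
#' (arclength-regularized loss, [centerline_loss()]) and all per-branch
#' radius heads (plain MSE, [radius_loss()]) for `epochs_main` epochs.
#' Phase 2 freezes the backbone (and centerline head) and fine-tunes each
#' radius head separately for `epochs_radius_finetune` epochs on its own
#' branch, amplifying the contribution of stenosis points that would
#' otherwise be diluted in the full tree. Losses are computed in
#' millimetre space (predictions are de-standardized before the loss), so
#' `lambda` keeps its physical meaning.
#'
#' Training samples pair the network input (a fixed number of
#' distance-transform maps, stacked as channels in ascending view-index
#' order) with the ground-truth tree matrix. View geometry never enters.
#'
#' @param samples list of `list(maps = list of k matrices, tree = M x N x
#'   4)`; non-empty.
#' @param config a [train_config()].
#' @param backbone a [backbone_spec()]; its `input_channels` must match
#'   the samples.
#' @param val_samples optional validation samples; per-epoch validation
#'   losses are recorded when supplied.
#' @return a trained `coronary_recon` (mode `"multi"`) with a `history`
#'   data frame.
#' @export
train_multistage <- function(samples, config = train_config(),
                             backbone = NULL, val_samples = NULL) {
  if (!length(samples)) stop("empty training set")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed)
  k <- length(samples[[1]]$maps)
  H <- nrow(samples[[1]]$maps[[1]])
  if (is.null(backbone))
    backbone <- backbone_spec("tiny_conv", input_channels = k, image_size = H)
  tr1 <- unclass(samples[[1]]$tree)
  M <- dim(tr1)[1]; N <- dim(tr1)[2]
  nm <- norm_stats(samples)
  bb <- build_backbone(backbone)
  model <- new_recon_model(
    "multi", bb$layers, backbone,
    heads = list(
      centerline = build_mlp_head(bb$feature_dim, c(1024, 1024, 1024, 512),
                                  M * N * 3),
      radius = lapply(seq_len(M), function(m)
        build_mlp_head(bb$feature_dim, c(128, 128, 128), N))),
    M = M, N = N, norm = nm, config = config)

  opt <- list(bb = adam_init(model$backbone),
              ch = adam_init(model$heads$centerline),
              rh = lapply(model$heads$radius, adam_init))
  n <- length(samples)
  hist <- list(); t_adam <- 0L
  for (epoch in seq_len(config$epochs_main)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_c <- 0; ep_r <- 0
    for (bidx in batches) {
      x <- stack_inputs(samples, bidx, nm$input_max)
      tg <- target_arrays(samples, bidx)
      fw <- model_forward_full(model, x, training = TRUE)
      model$backbone <- fw$bb$layers
      model$heads$centerline <- fw$ch$layers
      for (m in seq_len(M)) model$heads$radius[[m]] <- fw$rh[[m]]$layers
      Lc <- centerline_loss(tg$y, fw$y_mm, config$lambda,
                            config$signed_length)
      Lr <- radius_loss(tg$r, fw$r_mm)
      ep_c <- ep_c + Lc * length(bidx); ep_r <- ep_r + Lr * length(bidx)
      dy <- centerline_loss_grad(tg$y, fw$y_mm, config$lambda,
                                 config$signed_length) * nm$coord_sd
      dr <- radius_loss_grad(tg$r, fw$r_mm) * nm$r_sd
      bw_c <- net_backward(model$heads$centerline, fw$ch$caches,
                           coord_array_to_vec(dy))
      dfeat <- bw_c$dx
      bw_r <- vector("list", M)
      for (m in seq_len(M)) {
        g <- matrix(dr[, m, ], nrow = dim(dr)[1])
        bw_r[[m]] <- net_backward(model$heads$radius[[m]], fw$rh[[m]]$caches, g)
        dfeat <- dfeat + bw_r[[m]]$dx
      }
      bw_b <- net_backward(model$backbone, fw$bb$caches, dfeat)
      t_adam <- t_adam + 1L
      st <- adam_step(model$backbone, bw_b$grads, opt$bb,
                      config$learning_rate, config$weight_decay, t_adam)
      model$backbone <- st$layers; opt$bb <- st$state
      st <- adam_step(model$heads$centerline, bw_c$grads, opt$ch,
                      config$learning_rate, config$weight_decay, t_adam)
      model$heads$centerline <- st$layers; opt$ch <- st$state
      for (m in seq_len(M)) {
        st <- adam_step(model$heads$radius[[m]], bw_r[[m]]$grads, opt$rh[[m]],
                        config$learning_rate, config$weight_decay, t_adam)
        model$heads$radius[[m]] <- st$layers; opt$rh[[m]] <- st$state
      }
    }
    hist[[epoch]] <- data.frame(epoch = epoch, phase = 1L,
                                centerline = ep_c / n, radius = ep_r / n,
                                total = (ep_c + ep_r) / n)
  }

  # phase 2: backbone and centerline head frozen; per-branch fine-tuning
  feats <- precompute_features(model, samples, nm)
  for (m in seq_len(M)) {
    t2 <- 0L
    for (epoch in seq_len(config$epochs_radius_finetune)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_r <- 0
      for (bidx in batches) {
        fb <- feats[bidx, , drop = FALSE]
        rb <- t(vapply(bidx, function(i)
          unclass(samples[[i]]$tree)[m, , 4], numeric(N)))
        fw <- net_forward(model$heads$radius[[m]], fb, training = TRUE)
        model$heads$radius[[m]] <- fw$layers
        r_mm <- fw$out * nm$r_sd + nm$r_mean
        ep_r <- ep_r + radius_loss(rb, r_mm) * length(bidx)
        g <- radius_loss_grad(rb, r_mm) * nm$r_sd
        bw <- net_backward(model$heads$radius[[m]], fw$caches, g)
        t2 <- t2 + 1L
        st <- adam_step(model$heads$radius[[m]], bw$grads, opt$rh[[m]],
                        config$learning_rate, config$weight_decay,
                        t_adam + t2)
        model$heads$radius[[m]] <- st$layers; opt$rh[[m]] <- st$state
      }
      hist[[length(hist) + 1L]] <-
        data.frame(epoch = config$epochs_main + epoch, phase = 1L + m,
                   centerline = NA_real_, radius = ep_r / n,
                   total = ep_r / n)
    }
  }
  # BN inference statistics from the full training set
  model$heads$centerline <- calibrate_bn_mlp(model$heads$centerline, feats)
  for (m in seq_len(M))
    model$heads$radius[[m]] <- calibrate_bn_mlp(model$heads$radius[[m]], feats)
  model$history <- do.call(rbind, hist)
  if (!is.null(val_samples))
    model$val_metrics <- evaluate_losses(model, val_samples)
  model
}

precompute_features <- function(model, samples, nm) {
  n <- length(samples)
  idx_chunks <- split(seq_len(n), ceiling(seq_len(n) / 16))
  do.call(rbind, lapply(idx_chunks, function(ix) {
    x <- stack_inputs(samples, ix, nm$input_max)
    net_forward(model$backbone, x, training = FALSE)$out
  }))
}

evaluate_losses <- function(model, samples) {
  nm <- model$norm
  n <- length(samples)
  Lc <- 0; Lr <- 0
  for (ix in split(seq_len(n), ceiling(seq_len(n) / 8))) {
    x <- stack_inputs(samples, ix, nm$input_max)
    tg <- target_arrays(samples, ix)
    fw <- model_forward_full(model, x, training = FALSE)
    Lc <- Lc + centerline_loss(tg$y, fw$y_mm, model$config$lambda) * length(ix)
    Lr <- Lr + radius_loss(tg$r, fw$r_mm) * length(ix)
  }
  c(centerline = Lc / n, radius = Lr / n)
}

#' Train the single-stage comparator network
#'
#' Same backbone and hyperparameters as the multi-stage model, but a
#' single perceptron head regresses the full `M x N x 4` matrix under the
#' weighted loss [single_stage_loss()]; one training phase only. When
#' `mu` is `NULL` it is set after the first epoch by the balancing rule
#' ([mu_balance()]) on that epoch's running coordinate and radius errors
#' (the first epoch itself runs with a provisional `mu = 1`), then
#' frozen.
#'
#' @inheritParams train_multistage
#' @return a trained `coronary_recon` (mode `"single"`).
#' @export
train_single_stage <- function(samples, config = train_config(),
                               backbone = NULL, val_samples = NULL) {
  if (!length(samples)) stop("empty training set")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed)
  k <- length(samples[[1]]$maps)
  H <- nrow(samples[[1]]$maps[[1]])
  if (is.null(backbone))
    backbone <- backbone_spec("tiny_conv", input_channels = k, image_size = H)
  tr1 <- unclass(samples[[1]]$tree)
  M <- dim(tr1)[1]; N <- dim(tr1)[2]
  nm <- norm_stats(samples)
  bb <- build_backbone(backbone)
  model <- new_recon_model(
    "single", bb$layers, backbone,
    heads = list(joint = build_mlp_head(bb$feature_dim,
                                        c(1024, 1024, 1024, 512),
                                        M * N * 4)),
    M = M, N = N, norm = nm, config = config)
  opt <- list(bb = adam_init(model$backbone),
              jh = adam_init(model$heads$joint))
  n <- length(samples)
  mu <- if (is.null(config$mu)) 1 else config$mu
  hist <- list(); t_adam <- 0L
  for (epoch in seq_len(config$epochs_main)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0; ep_cmse <- 0; ep_rmse <- 0
    for (bidx in batches) {
      x <- stack_inputs(samples, bidx, nm$input_max)
      tg <- target_arrays(samples, bidx)
      fw <- model_forward_full(model, x, training = TRUE)
      model$backbone <- fw$bb$layers
      model$heads$joint <- fw$jh$layers
      L <- single_stage_loss(tg$y, fw$y_mm, tg$r, fw$r_mm, mu)
      ep_loss <- ep_loss + L * length(bidx)
      ep_cmse <- ep_cmse + mean((tg$y - fw$y_mm)^2) * 3 * length(bidx)
      ep_rmse <- ep_rmse + mean((tg$r - fw$r_mm)^2) * length(bidx)
      gr <- single_stage_loss_grad(tg$y, fw$y_mm, tg$r, fw$r_mm, mu)
      B <- length(bidx)
      darr <- array(0, c(B, M, N, 4))
      darr[, , , 1:3] <- gr$dy * nm$coord_sd
      darr[, , , 4] <- gr$dr * nm$r_sd
      dvec <- t(matrix(aperm(darr, c(2, 3, 4, 1)), M * N * 4, B))
      bw_h <- net_backward(model$heads$joint, fw$jh$caches, dvec)
      bw_b <- net_backward(model$backbone, fw$bb$caches, bw_h$dx)
      t_adam <- t_adam + 1L
      st <- adam_step(model$backbone, bw_b$grads, opt$bb,
                      config$learning_rate, config$weight_decay, t_adam)
      model$backbone <- st$layers; opt$bb <- st$state
      st <- adam_step(model$heads$joint, bw_h$grads, opt$jh,
                      config$learning_rate, config$weight_decay, t_adam)
      model$heads$joint <- st$layers; opt$jh <- st$state
    }
    if (epoch == 1L && is.null(config$mu))
      mu <- mu_balance(ep_cmse / n, ep_rmse / n)
    hist[[epoch]] <- data.frame(epoch = epoch, phase = 1L,
                                centerline = ep_cmse / n / 3,
                                radius = ep_rmse / n,
                                total = ep_loss / n, mu = mu)
  }
  model$mu <- mu
  feats <- precompute_features(model, samples, nm)
  model$heads$joint <- calibrate_bn_mlp(model$heads$joint, feats)
  model$history <- do.call(rbind, hist)
  if (!is.null(val_samples))
    model$val_metrics <- evaluate_losses(model, val_samples)
  model
}

# set BN running statistics of an MLP head to full-dataset statistics
# (standard post-training calibration; BN inference then matches the
# data distribution rather than lagging behind a momentum average)
calibrate_bn_mlp <- function(layers, X) {
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "bn") {
      mu <- colMeans(X)
      layers[[i]]$state$mean <- mu
      layers[[i]]$state$var <- colMeans(sweep(X, 2, mu)^2)
    }
    X <- layer_forward(layers[[i]], X, training = FALSE)$out
  }
  layers
}
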