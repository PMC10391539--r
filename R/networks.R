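# The three 2-D architectures: a dense-block U-shaped network for full-slice
# multi-organ segmentation, a residual attention network (cascaded spatial
# then channel attention inside residual blocks) for the esophagus crop, and
# a plain U-Net baseline. Feature maps are (H, W, C, N) arrays; all weight
# initialization is seeded through the network config.

#' Channel-attention kernel size
#'
#' The 1-D convolution over the pooled channel column uses a kernel that
#' grows with the channel count: `K = max(1, round(log2(C)))`, rounding
#' half-up, so the cross-channel receptive field widens as the encoder
#' deepens.
#'
#' @param C Channel count (>= 1).
#' @return Integer kernel length.
#' @export
attention_kernel_size <- function(C) {
  if (C < 1) ts_error("channel count must be >= 1", "ts_contract_error")
  max(1L, as.integer(floor(log2(C) + 0.5)))
}

init_conv_w <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

# parameter registry used by the builders
new_registry <- function() new.env(parent = emptyenv())

reg_conv <- function(P, name, kh, kw, cin, cout) {
  w <- ad_param(init_conv_w(kh, kw, cin, cout), paste0(name, ".w"))
  b <- ad_param(numeric(cout), paste0(name, ".b"))
  assign(paste0(name, ".w"), w, envir = P)
  assign(paste0(name, ".b"), b, envir = P)
  list(w = w, b = b)
}

reg_conv1d <- function(P, name, K) {
  w <- ad_param(rnorm(K, 0, sqrt(1 / K)), paste0(name, ".w"))
  b <- ad_param(0, paste0(name, ".b"))
  assign(paste0(name, ".w"), w, envir = P)
  assign(paste0(name, ".b"), b, envir = P)
  list(w = w, b = b)
}

registry_params <- function(P) {
  nm <- sort(ls(P))
  setNames(lapply(nm, function(n) get(n, envir = P)), nm)
}

# spatial attention: channel-wise max and mean pooling stacked into a 2-map
# image, convolved, sigmoid -> per-position gate in (0,1), broadcast over
# channels
spatial_gate_fwd <- function(f, conv, pad) {
  mx <- ad_pool_over_channels(f, "max")
  mn <- ad_pool_over_channels(f, "mean")
  s <- ad_concat_channels(mx, mn)
  ad_sigmoid(ad_conv2d(s, conv$w, conv$b, 1L, pad))
}

# channel attention: global max and mean pooling into two C-columns, a shared
# 1-D convolution of kernel K applied to each, summed, sigmoid -> per-channel
# gate
channel_gate_fwd <- function(f, conv) {
  vmax <- ad_pool_over_space(f, "max")
  vmean <- ad_pool_over_space(f, "mean")
  ad_sigmoid(ad_add(ad_conv1d_channels(vmax, conv$w, conv$b),
                    ad_conv1d_channels(vmean, conv$w, conv$b)))
}

#' Apply spatial attention to a feature map
#'
#' Channel-wise max- and mean-pooled maps are stacked, convolved with the
#' supplied kernel, and squashed to a per-position gate in (0, 1) that
#' multiplies every channel of the input.
#'
#' @param f Feature map array `(H, W, C)` or `(H, W, C, N)`.
#' @param weights List with `w` (array `(k, k, 2, 1)`) and `b` (length-1).
#' @return Gated feature map of the same shape, with the gate in attribute
#'   `"gate"`.
#' @export
spatial_attention <- function(f, weights) {
  x <- ad_input(fm4(f))
  pad <- (dim(weights$w)[1] - 1L) %/% 2L
  g <- spatial_gate_fwd(x, list(w = ad_input(weights$w),
                                b = ad_input(weights$b)), pad)
  out <- ad_scale_spatial(x, g)
  structure(array(out$value, dim = dim(f)), gate = drop(g$value))
}

#' Apply channel attention to a feature map
#'
#' Global max- and mean-pooled channel columns pass through a shared 1-D
#' convolution of kernel length `length(weights$w)`; their sum is squashed
#' to a per-channel gate in (0, 1) that multiplies every position.
#'
#' @param f Feature map array `(H, W, C)` or `(H, W, C, N)`.
#' @param weights List with `w` (numeric kernel) and `b` (scalar).
#' @return Gated feature map of the same shape, with the gate in attribute
#'   `"gate"`.
#' @export
channel_attention <- function(f, weights) {
  x <- ad_input(fm4(f))
  g <- channel_gate_fwd(x, list(w = ad_input(weights$w),
                                b = ad_input(weights$b)))
  out <- ad_scale_channel(x, g)
  structure(array(out$value, dim = dim(f)), gate = drop(g$value))
}

# residual block whose main path is conv -> relu -> conv -> spatial
# attention -> channel attention; shortcut is the input itself (identity
# mode, widths must match) or a 1x1 convolution (convolution mode)
mk_attention_block <- function(P, name, cin, cout,
                               mode = c("convolution", "identity"),
                               spatial_kernel = 7L) {
  mode <- match.arg(mode)
  if (mode == "identity" && cin != cout)
    ts_error("identity residual attention block needs equal in/out widths",
             "ts_config_error")
  conv1 <- reg_conv(P, paste0(name, ".conv1"), 3L, 3L, cin, cout)
  conv2 <- reg_conv(P, paste0(name, ".conv2"), 3L, 3L, cout, cout)
  sa <- reg_conv(P, paste0(name, ".sa"), spatial_kernel, spatial_kernel, 2L, 1L)
  ca <- reg_conv1d(P, paste0(name, ".ca"), attention_kernel_size(cout))
  sc <- if (mode == "convolution") reg_conv(P, paste0(name, ".sc"), 1L, 1L, cin, cout)
  pad_sa <- (spatial_kernel - 1L) %/% 2L
  function(x) {
    m <- ad_relu(ad_conv2d(x, conv1$w, conv1$b, 1L, 1L))
    m <- ad_conv2d(m, conv2$w, conv2$b, 1L, 1L)
    m <- ad_scale_spatial(m, spatial_gate_fwd(m, sa, pad_sa))
    m <- ad_scale_channel(m, channel_gate_fwd(m, ca))
    shortcut <- if (mode == "convolution") ad_conv2d(x, sc$w, sc$b, 1L, 0L) else x
    ad_add(m, shortcut)
  }
}

#' One residual attention block applied to a feature map
#'
#' Main path: 3x3 conv, ReLU, 3x3 conv, then cascaded spatial and channel
#' attention; the result is added to the shortcut (the raw input in
#' `"identity"` mode, a 1x1 convolution of it in `"convolution"` mode).
#' Weights are drawn from the seeded initializer unless supplied.
#'
#' @param f Feature map array `(H, W, C)` or `(H, W, C, N)`.
#' @param out_width Output channel count (must equal the input width in
#'   identity mode).
#' @param mode `"convolution"` or `"identity"`.
#' @param spatial_kernel Odd kernel size of the spatial-attention conv.
#' @param seed Seed for weight initialization.
#' @return Feature map array `(H, W, out_width[, N])`.
#' @export
attention_residual_block <- function(f, out_width = dim(fm4(f))[3],
                                     mode = c("convolution", "identity"),
                                     spatial_kernel = 7L, seed = 1L) {
  mode <- match.arg(mode)
  x4 <- fm4(f)
  P <- new_registry()
  blk <- with_seed(seed, mk_attention_block(P, "blk", dim(x4)[3], out_width,
                                            mode, spatial_kernel))
  out <- blk(ad_input(x4))
  if (length(dim(f)) == 3L) array(out$value, dim = dim(out$value)[1:3]) else out$value
}

ts_model <- function(arch, cfg, params, forward) {
  structure(list(arch = arch, cfg = cfg, params = params, forward = forward),
            class = "ts_model")
}

#' @export
print.ts_model <- function(x, ...) {
  cat(sprintf("<ts_model:%s> %d parameter tensors, %d weights\n",
              x$arch, length(x$params), count_params(x)))
  invisible(x)
}

#' Total number of trainable weights in a model
#' @param model A `ts_model`.
#' @return Integer count.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, function(p) length(p$value), numeric(1)))
}

#' Network configuration
#'
#' @param arch `"residual_attention"`, `"dense_unet"` or `"unet"`.
#' @param in_channels Input channels (1 for CT slices).
#' @param n_classes Output logit channels.
#' @param widths Encoder stage widths (residual attention / U-Net).
#' @param stem_width,n_stages,block_layers,growth_rate,compression Dense
#'   U-net structure: stem channels, encoder stages, conv layers per dense
#'   block, channels added per layer, transition compression factor.
#' @param spatial_kernel Spatial-attention conv kernel (odd).
#' @param seed Weight-initialization seed.
#' @return A `network_config` list.
#' @export
network_config <- function(arch = c("residual_attention", "dense_unet", "unet"),
                           in_channels = 1L, n_classes = 2L,
                           widths = c(8L, 16L, 32L),
                           stem_width = 12L, n_stages = 4L, block_layers = 4L,
                           growth_rate = 12L, compression = 0.5,
                           spatial_kernel = 7L, seed = 1L) {
  arch <- match.arg(arch)
  if (any(widths < 1L) || n_classes < 1L || in_channels < 1L)
    ts_error("widths and channel counts must be positive", "ts_config_error")
  if (spatial_kernel %% 2L != 1L)
    ts_error("spatial_kernel must be odd", "ts_config_error")
  structure(list(arch = arch, in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes), widths = as.integer(widths),
                 stem_width = as.integer(stem_width), n_stages = as.integer(n_stages),
                 block_layers = as.integer(block_layers),
                 growth_rate = as.integer(growth_rate), compression = compression,
                 spatial_kernel = as.integer(spatial_kernel), seed = as.integer(seed)),
            class = "network_config")
}

#' Output width of a dense block
#'
#' Dense connectivity concatenates the block input with every layer's output,
#' so a block of `n_layers` layers with growth rate `growth` widens
#' `width_in` to `width_in + n_layers * growth` channels.
#'
#' @param width_in Input channel count.
#' @param n_layers Convolution layers in the block.
#' @param growth Channels added by each layer.
#' @return Integer output width.
#' @export
dense_block_out_width <- function(width_in, n_layers, growth) {
  as.integer(width_in + n_layers * growth)
}

mk_dense_block <- function(P, name, cin, n_layers, growth) {
  convs <- lapply(seq_len(n_layers), function(l)
    reg_conv(P, sprintf("%s.l%d", name, l), 3L, 3L,
             cin + (l - 1L) * growth, growth))
  function(x) {
    acc <- x
    for (l in seq_len(n_layers)) {
      y <- ad_conv2d(ad_relu(acc), convs[[l]]$w, convs[[l]]$b, 1L, 1L)
      acc <- ad_concat_channels(acc, y)
    }
    acc
  }
}

#' Build the stage-2 residual attention network
#'
#' U-shaped encoder/decoder. Each encoder level applies a convolution
#' residual attention block then an identity residual attention block;
#' levels are linked by stride-2 convolutions. Each decoder level applies
#' nearest-neighbor upsampling, concatenates the matching encoder output
#' (long skip connection), merges with a 3x3 convolution and applies an
#' identity residual attention block. A final 1x1 convolution emits
#' `n_classes` logit channels.
#'
#' @param cfg A [network_config] with `arch = "residual_attention"`.
#' @return A `ts_model`.
#' @export
build_residual_attention_net <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  w <- cfg$widths; L <- length(w)
  P <- new_registry()
  with_seed(cfg$seed, {
    stem <- reg_conv(P, "stem", 3L, 3L, cfg$in_channels, w[1])
    enc_conv <- enc_id <- vector("list", L)
    down <- vector("list", L - 1L)
    for (l in seq_len(L)) {
      cin <- w[l]
      enc_conv[[l]] <- mk_attention_block(P, sprintf("enc%d.conv", l), cin, w[l],
                                          "convolution", cfg$spatial_kernel)
      enc_id[[l]] <- mk_attention_block(P, sprintf("enc%d.id", l), w[l], w[l],
                                        "identity", cfg$spatial_kernel)
      if (l < L) down[[l]] <- reg_conv(P, sprintf("down%d", l), 3L, 3L, w[l], w[l + 1L])
    }
    merge <- dec_id <- vector("list", L - 1L)
    for (l in seq_len(L - 1L)) {
      merge[[l]] <- reg_conv(P, sprintf("dec%d.merge", l), 3L, 3L, w[l + 1L] + w[l], w[l])
      dec_id[[l]] <- mk_attention_block(P, sprintf("dec%d.id", l), w[l], w[l],
                                        "identity", cfg$spatial_kernel)
    }
    head <- reg_conv(P, "head", 1L, 1L, w[1], cfg$n_classes)
  })
  forward <- function(x) {
    h <- ad_relu(ad_conv2d(x, stem$w, stem$b, 1L, 1L))
    skips <- vector("list", L)
    for (l in seq_len(L)) {
      h <- enc_id[[l]](enc_conv[[l]](h))
      skips[[l]] <- h
      if (l < L) h <- ad_relu(ad_conv2d(h, down[[l]]$w, down[[l]]$b, 2L, 1L))
    }
    for (l in rev(seq_len(L - 1L))) {
      h <- ad_upsample2(h)
      h <- ad_concat_channels(h, skips[[l]])
      h <- ad_relu(ad_conv2d(h, merge[[l]]$w, merge[[l]]$b, 1L, 1L))
      h <- dec_id[[l]](h)
    }
    ad_conv2d(h, head$w, head$b, 1L, 0L)
  }
  ts_model("residual_attention", cfg, registry_params(P), forward)
}

#' Build the stage-1 dense U-shaped network
#'
#' Encoder stages are dense blocks (every layer's output concatenated onto
#' the running feature stack) linked by transition layers (1x1 compression
#' convolution followed by a stride-2 convolution); the decoder mirrors the
#' encoder with nearest-neighbor upsampling and long skip connections.
#'
#' @param cfg A [network_config] with `arch = "dense_unet"`.
#' @return A `ts_model`.
#' @export
build_dense_unet <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  S <- cfg$n_stages; g <- cfg$growth_rate; bl <- cfg$block_layers
  P <- new_registry()
  with_seed(cfg$seed, {
    stem <- reg_conv(P, "stem", 3L, 3L, cfg$in_channels, cfg$stem_width)
    win <- cfg$stem_width
    blocks <- trans <- vector("list", S)
    skip_w <- integer(S)
    for (s in seq_len(S)) {
      blocks[[s]] <- mk_dense_block(P, sprintf("dense%d", s), win, bl, g)
      bout <- dense_block_out_width(win, bl, g)
      skip_w[s] <- bout
      wnext <- max(4L, as.integer(floor(bout * cfg$compression)))
      trans[[s]] <- list(
        compress = reg_conv(P, sprintf("trans%d.c", s), 1L, 1L, bout, wnext),
        down = reg_conv(P, sprintf("trans%d.d", s), 3L, 3L, wnext, wnext))
      win <- wnext
    }
    bott <- mk_dense_block(P, "bottleneck", win, bl, g)
    wdeep <- dense_block_out_width(win, bl, g)
    merge <- vector("list", S)
    dec_w <- integer(S)
    for (s in rev(seq_len(S))) {
      dw <- max(8L, as.integer(floor(skip_w[s] * cfg$compression)))
      merge[[s]] <- reg_conv(P, sprintf("dec%d.merge", s), 3L, 3L, wdeep + skip_w[s], dw)
      dec_w[s] <- dw
      wdeep <- dw
    }
    head <- reg_conv(P, "head", 1L, 1L, wdeep, cfg$n_classes)
  })
  forward <- function(x) {
    h <- ad_relu(ad_conv2d(x, stem$w, stem$b, 1L, 1L))
    skips <- vector("list", S)
    for (s in seq_len(S)) {
      h <- blocks[[s]](h)
      skips[[s]] <- h
      h <- ad_conv2d(ad_relu(h), trans[[s]]$compress$w, trans[[s]]$compress$b, 1L, 0L)
      h <- ad_relu(ad_conv2d(h, trans[[s]]$down$w, trans[[s]]$down$b, 2L, 1L))
    }
    h <- bott(h)
    for (s in rev(seq_len(S))) {
      h <- ad_upsample2(h)
      h <- ad_concat_channels(h, skips[[s]])
      h <- ad_relu(ad_conv2d(h, merge[[s]]$w, merge[[s]]$b, 1L, 1L))
    }
    ad_conv2d(h, head$w, head$b, 1L, 0L)
  }
  ts_model("dense_unet", cfg, registry_params(P), forward)
}

#' Build the baseline U-Net
#'
#' Symmetric encoder/decoder with two 3x3 conv + ReLU layers per level,
#' stride-2 convolution downsampling, nearest-neighbor upsampling and skip
#' concatenation; same I/O contract as [build_dense_unet].
#'
#' @param cfg A [network_config] with `arch = "unet"`.
#' @return A `ts_model`.
#' @export
build_baseline_unet <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  w <- cfg$widths; L <- length(w)
  P <- new_registry()
  with_seed(cfg$seed, {
    enc <- vector("list", L); down <- vector("list", L - 1L)
    cin <- cfg$in_channels
    for (l in seq_len(L)) {
      enc[[l]] <- list(c1 = reg_conv(P, sprintf("enc%d.c1", l), 3L, 3L, cin, w[l]),
                       c2 = reg_conv(P, sprintf("enc%d.c2", l), 3L, 3L, w[l], w[l]))
      if (l < L) down[[l]] <- reg_conv(P, sprintf("down%d", l), 3L, 3L, w[l], w[l + 1L])
      cin <- w[l + 1L]
    }
    dec <- vector("list", L - 1L)
    for (l in seq_len(L - 1L)) {
      dec[[l]] <- list(c1 = reg_conv(P, sprintf("dec%d.c1", l), 3L, 3L, w[l + 1L] + w[l], w[l]),
                       c2 = reg_conv(P, sprintf("dec%d.c2", l), 3L, 3L, w[l], w[l]))
    }
    head <- reg_conv(P, "head", 1L, 1L, w[1], cfg$n_classes)
  })
  forward <- function(x) {
    h <- x
    skips <- vector("list", L)
    for (l in seq_len(L)) {
      h <- ad_relu(ad_conv2d(h, enc[[l]]$c1$w, enc[[l]]$c1$b, 1L, 1L))
      h <- ad_relu(ad_conv2d(h, enc[[l]]$c2$w, enc[[l]]$c2$b, 1L, 1L))
      skips[[l]] <- h
      if (l < L) h <- ad_relu(ad_conv2d(h, down[[l]]$w, down[[l]]$b, 2L, 1L))
    }
    for (l in rev(seq_len(L - 1L))) {
      h <- ad_upsample2(h)
      h <- ad_concat_channels(h, skips[[l]])
      h <- ad_relu(ad_conv2d(h, dec[[l]]$c1$w, dec[[l]]$c1$b, 1L, 1L))
      h <- ad_relu(ad_conv2d(h, dec[[l]]$c2$w, dec[[l]]$c2$b, 1L, 1L))
    }
    ad_conv2d(h, head$w, head$b, 1L, 0L)
  }
  ts_model("unet", cfg, registry_params(P), forward)
}

#' Build a network from its configuration
#' @param cfg A [network_config].
#' @return A `ts_model`.
#' @export
build_network <- function(cfg) {
  switch(cfg$arch,
         residual_attention = build_residual_attention_net(cfg),
         dense_unet = build_dense_unet(cfg),
         unet = build_baseline_unet(cfg),
         ts_error("unknown architecture", "ts_config_error"))
}

#' Run a model forward on a plain array
#'
#' @param model A `ts_model`.
#' @param x Input array `(H, W)` (one grayscale slice), `(H, W, C)` or
#'   `(H, W, C, N)`.
#' @return Logit array `(H, W, n_classes, N)`.
#' @export
model_forward <- function(model, x) {
  model$forward(ad_input(fm4(x)))$value
}

#' Save model weights and configuration
#' @param model A `ts_model`.
#' @param path Output `.rds` path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(arch = model$arch, cfg = model$cfg,
               weights = lapply(model$params, function(p) p$value)), path)
  invisible(NULL)
}

#' Load a model checkpoint
#' @param path Path written by [save_checkpoint].
#' @return A `ts_model` with restored weights.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_network(ck$cfg)
  stopifnot(identical(sort(names(model$params)), sort(names(ck$weights))))
  for (nm in names(ck$weights)) model$params[[nm]]$value <- ck$weights[[nm]]
  model
}
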