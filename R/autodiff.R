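# Minimal reverse-mode automatic differentiation over 4-D feature maps with
# layout (H, W, C, N). Each node is an environment holding a value, parent
# nodes and a backward closure that maps the upstream gradient to per-parent
# gradients. This is the engine under every network in the package; the
# convolution kernels live in C++.

.ad_state <- new.env(parent = emptyenv())
.ad_state$counter <- 0L

ad_node <- function(value, parents = list(), bw = NULL) {
  e <- new.env(parent = emptyenv())
  .ad_state$counter <- .ad_state$counter + 1L
  e$id <- .ad_state$counter
  e$value <- value
  e$parents <- parents
  e$bw <- bw
  e$grad <- NULL
  e$param <- FALSE
  class(e) <- "ts_tensor"
  e
}

ad_input <- function(value) ad_node(value)

ad_param <- function(value, name = "") {
  n <- ad_node(value)
  n$param <- TRUE
  n$name <- name
  n
}

fm4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("feature maps must be arrays")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

#' @keywords internal
ad_backward <- function(loss) {
  topo <- vector("list", 256L); ntopo <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(loss)
  # iterative post-order DFS
  state <- list(list(node = loss, i = 0L)); nstate <- 1L
  assign(as.character(loss$id), TRUE, envir = seen)
  while (nstate > 0L) {
    fr <- state[[nstate]]
    if (fr$i < length(fr$node$parents)) {
      state[[nstate]]$i <- fr$i + 1L
      p <- fr$node$parents[[fr$i + 1L]]
      key <- as.character(p$id)
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        nstate <- nstate + 1L
        state[[nstate]] <- list(node = p, i = 0L)
      }
    } else {
      ntopo <- ntopo + 1L
      topo[[ntopo]] <- fr$node
      nstate <- nstate - 1L
    }
  }
  topo <- topo[seq_len(ntopo)]
  for (n in topo) if (!n$param) n$grad <- NULL
  loss$grad <- 1
  for (k in rev(seq_len(ntopo))) {
    n <- topo[[k]]
    if (is.null(n$bw) || is.null(n$grad)) next
    grads <- n$bw(n$grad)
    for (i in seq_along(n$parents)) {
      g <- grads[[i]]
      if (is.null(g)) next
      p <- n$parents[[i]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(loss)
}

# ---- primitive ops ---------------------------------------------------------

ad_conv2d <- function(x, w, b, stride = 1L, pad = 0L) {
  got <- .conv2d_fwd(x$value, dim(x$value), w$value, dim(w$value), b$value,
                     as.integer(stride), as.integer(pad), FALSE)
  ad_node(got$y, list(x, w, b), function(gy) {
    g <- .conv2d_bwd(x$value, dim(x$value), w$value, dim(w$value), gy,
                     as.integer(stride), as.integer(pad))
    list(g$gx, g$gw, g$gb)
  })
}

# forward-only convolution (no patch cache kept)
conv2d_infer <- function(x, w, b, stride = 1L, pad = 0L) {
  .conv2d_fwd(x, dim(x), w, dim(w), b, as.integer(stride), as.integer(pad), FALSE)$y
}

ad_relu <- function(x) {
  m <- x$value > 0
  ad_node(x$value * m, list(x), function(gy) list(gy * m))
}

ad_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  ad_node(s, list(x), function(gy) list(gy * s * (1 - s)))
}

ad_add <- function(a, b) {
  ad_node(a$value + b$value, list(a, b), function(gy) list(gy, gy))
}

# f: (H,W,C,N) scaled by a spatial gate (H,W,1,N), broadcast over channels
ad_scale_spatial <- function(f, gate) {
  d <- dim(f$value); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  gb <- array(gate$value[, , rep(1L, C), , drop = FALSE], dim = d)
  ad_node(f$value * gb, list(f, gate), function(gy) {
    gf <- gy * gb
    prod <- gy * f$value
    # sum over channel dim -> (H,W,1,N)
    m <- matrix(aperm(prod, c(1, 2, 4, 3)), ncol = C)
    gg <- array(aperm(array(rowSums(m), dim = c(H, W, N, 1L)), c(1, 2, 4, 3)),
                dim = c(H, W, 1L, N))
    list(gf, gg)
  })
}

# f scaled by a channel gate (1,1,C,N), broadcast over positions
ad_scale_channel <- function(f, gate) {
  d <- dim(f$value); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  gv <- rep(as.vector(gate$value), each = H * W)
  ad_node(f$value * gv, list(f, gate), function(gy) {
    gf <- gy * gv
    gg <- array(colSums(matrix(gy * f$value, nrow = H * W)), dim = c(1L, 1L, C, N))
    list(gf, gg)
  })
}

# channel-wise pooling over C -> (H,W,1,N)
ad_pool_over_channels <- function(x, kind = c("max", "mean")) {
  kind <- match.arg(kind)
  d <- dim(x$value); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  m <- matrix(aperm(x$value, c(1, 2, 4, 3)), ncol = C)   # rows: (h,w,n)
  if (kind == "max") {
    j <- max.col(m, ties.method = "first")
    vals <- m[cbind(seq_len(nrow(m)), j)]
    bw <- function(gy) {
      gm <- matrix(0, nrow(m), C)
      gm[cbind(seq_len(nrow(m)), j)] <- as.vector(gy)
      list(aperm(array(gm, dim = c(H, W, N, C)), c(1, 2, 4, 3)))
    }
  } else {
    vals <- rowMeans(m)
    bw <- function(gy) {
      gm <- matrix(rep(as.vector(gy) / C, C), nrow(m), C)
      list(aperm(array(gm, dim = c(H, W, N, C)), c(1, 2, 4, 3)))
    }
  }
  y <- array(aperm(array(vals, dim = c(H, W, N, 1L)), c(1, 2, 4, 3)),
             dim = c(H, W, 1L, N))
  ad_node(y, list(x), bw)
}

# global spatial pooling over H,W -> (1,1,C,N)
ad_pool_over_space <- function(x, kind = c("max", "mean")) {
  kind <- match.arg(kind)
  d <- dim(x$value); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  m <- matrix(x$value, nrow = H * W)                      # cols: (c,n)
  if (kind == "max") {
    j <- apply(m, 2, which.max)
    vals <- m[cbind(j, seq_len(ncol(m)))]
    bw <- function(gy) {
      gm <- matrix(0, H * W, ncol(m))
      gm[cbind(j, seq_len(ncol(m)))] <- as.vector(gy)
      list(array(gm, dim = d))
    }
  } else {
    vals <- colMeans(m)
    bw <- function(gy) {
      gm <- matrix(rep(as.vector(gy) / (H * W), each = H * W), H * W, ncol(m))
      list(array(gm, dim = d))
    }
  }
  ad_node(array(vals, dim = c(1L, 1L, C, N)), list(x), bw)
}

ad_concat_channels <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(da[1] == db[1], da[2] == db[2], da[4] == db[4])
  y <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a$value
  y[, , da[3] + seq_len(db[3]), ] <- b$value
  ad_node(y, list(a, b), function(gy) {
    list(gy[, , seq_len(da[3]), , drop = FALSE],
         gy[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

# nearest-neighbor 2x upsampling
ad_upsample2 <- function(x) {
  d <- dim(x$value); H <- d[1]; W <- d[2]
  ri <- rep(seq_len(H), each = 2L); ci <- rep(seq_len(W), each = 2L)
  y <- x$value[ri, ci, , , drop = FALSE]
  ad_node(y, list(x), function(gy) {
    o <- seq(1L, 2L * H, by = 2L); p <- seq(1L, 2L * W, by = 2L)
    gx <- gy[o, p, , , drop = FALSE] + gy[o + 1L, p, , , drop = FALSE] +
          gy[o, p + 1L, , , drop = FALSE] + gy[o + 1L, p + 1L, , , drop = FALSE]
    list(gx)
  })
}

# 1-D convolution along the channel axis of a (1,1,C,N) column; kernel length
# K with same-length zero padding (asymmetric when K is even: floor((K-1)/2)
# leading, the rest trailing).
ad_conv1d_channels <- function(x, w, b) {
  d <- dim(x$value); C <- d[3]; N <- d[4]
  K <- length(w$value)
  left <- (K - 1L) %/% 2L
  xm <- matrix(x$value, C, N)
  pad <- rbind(matrix(0, left, N), xm, matrix(0, K - 1L - left, N))
  y <- matrix(b$value, C, N)
  for (k in seq_len(K)) y <- y + w$value[k] * pad[(k - 1L) + seq_len(C), , drop = FALSE]
  ad_node(array(y, dim = c(1L, 1L, C, N)), list(x, w, b), function(gy) {
    gm <- matrix(gy, C, N)
    gw <- vapply(seq_len(K), function(k)
      sum(gm * pad[(k - 1L) + seq_len(C), , drop = FALSE]), numeric(1))
    gpad <- matrix(0, C + K - 1L, N)
    for (k in seq_len(K))
      gpad[(k - 1L) + seq_len(C), ] <- gpad[(k - 1L) + seq_len(C), ] + w$value[k] * gm
    gx <- array(gpad[left + seq_len(C), , drop = FALSE], dim = d)
    list(gx, gw, sum(gm))
  })
}

# ---- losses ---------------------------------------------------------------

softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

# Weighted sum of class-balanced voxel cross-entropy and (1 - macro
# soft-Dice) over softmax probabilities. Each class present in the target
# contributes equally to the cross-entropy regardless of its voxel count;
# without this the thin air-column organs (trachea, esophagus, cord) are
# swamped by background and lung. logits: (H,W,C,N); target: one-hot array
# of the same dim.
loss_softmax_ce_dice <- function(logits, target, dice_weight = 0.5, eps = 1) {
  d <- dim(logits$value); C <- d[3]
  zm <- matrix(aperm(logits$value, c(1, 2, 4, 3)), ncol = C)
  gm <- matrix(aperm(target, c(1, 2, 4, 3)), ncol = C)
  p <- softmax_rows(zm)
  G <- colSums(gm)
  present <- G > 0
  # per-voxel weight: 1 / (n_voxels_of_its_class * n_present_classes)
  wv <- gm %*% ifelse(present, 1 / (pmax(G, 1) * sum(present)), 0)
  ce <- -sum(wv * log(pmax(rowSums(p * gm), 1e-12)))
  S <- colSums(p * gm); P <- colSums(p)
  dice <- (2 * S + eps) / (P + G + eps)
  ld <- 1 - mean(dice)
  val <- (1 - dice_weight) * ce + dice_weight * ld
  ad_node(val, list(logits), function(gy) {
    dce_dp <- -as.vector(wv) * gm / pmax(rowSums(p * gm), 1e-12)
    denom <- (P + G + eps)
    dd_dp <- sweep(gm, 2, 2 * denom, "*") - matrix(2 * S + eps, nrow(p), C, byrow = TRUE)
    dld_dp <- -sweep(dd_dp, 2, denom^2, "/") / C
    dp <- (1 - dice_weight) * dce_dp + dice_weight * dld_dp
    dz <- p * (dp - rowSums(dp * p))
    gz <- aperm(array(dz, dim = c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
    list(gy * gz)
  })
}

# Weighted sum of class-balanced binary cross-entropy and (1 - soft-Dice)
# over sigmoid probabilities. Foreground and background voxels contribute
# equally to the cross-entropy whatever their counts; the esophagus fills a
# few dozen pixels of a 64x64 crop. logits: (H,W,1,N); target: 0/1 array of
# the same dim.
loss_sigmoid_bce_dice <- function(logits, target, dice_weight = 0.5, eps = 1) {
  z <- logits$value
  p <- 1 / (1 + exp(-z))
  npos <- sum(target); nneg <- length(p) - npos
  wv <- ifelse(target > 0,
               if (npos > 0) 1 / (2 * npos) else 0,
               if (nneg > 0) 1 / (2 * nneg) else 0)
  bce <- -sum(wv * (target * log(pmax(p, 1e-12)) +
                    (1 - target) * log(pmax(1 - p, 1e-12))))
  S <- sum(p * target); P <- sum(p); G <- npos
  dice <- (2 * S + eps) / (P + G + eps)
  val <- (1 - dice_weight) * bce + dice_weight * (1 - dice)
  ad_node(val, list(logits), function(gy) {
    dbce_dp <- wv * (p - target) / pmax(p * (1 - p), 1e-12)
    denom <- P + G + eps
    dd_dp <- (2 * target * denom - (2 * S + eps)) / denom^2
    dp <- (1 - dice_weight) * dbce_dp - dice_weight * dd_dp
    list(gy * dp * p * (1 - p))
  })
}

# ---- optimizer ------------------------------------------------------------

#' @keywords internal
adam_state <- function(params) {
  list(params = params, t = 0L)
}

adam_step <- function(st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (p in st$params) {
    if (is.null(p$grad)) next
    if (is.null(p$m)) { p$m <- p$grad * 0; p$v <- p$grad * 0 }
    p$m <- beta1 * p$m + (1 - beta1) * p$grad
    p$v <- beta2 * p$v + (1 - beta2) * p$grad^2
    mhat <- p$m / (1 - beta1^st$t)
    vhat <- p$v / (1 - beta2^st$t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
    p$grad <- NULL
  }
  st
}
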