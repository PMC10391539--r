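# Brute-force O(n^2) oracles for the surface-distance metrics, independent of
# the package's distance-transform implementation, plus small fixture helpers.

bf_surface_coords <- function(mask) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  offs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  keep <- vapply(seq_len(nrow(idx)), function(r) {
    v <- idx[r, ]
    for (o in offs) {
      w <- v + o
      if (any(w < 1) || any(w > d) || !mask[w[1], w[2], w[3]]) return(TRUE)
    }
    FALSE
  }, logical(1))
  idx[keep, , drop = FALSE]
}

bf_directed <- function(A, B, sp) {
  D2 <- outer(A[, 1] * sp[1], B[, 1] * sp[1], "-")^2 +
        outer(A[, 2] * sp[2], B[, 2] * sp[2], "-")^2 +
        outer(A[, 3] * sp[3], B[, 3] * sp[3], "-")^2
  sqrt(apply(D2, 1, min))
}

bf_metrics <- function(a, b, sp) {
  A <- bf_surface_coords(a); B <- bf_surface_coords(b)
  dab <- bf_directed(A, B, sp); dba <- bf_directed(B, A, sp)
  list(
    hd95 = max(quantile(dab, 0.95, type = 7), quantile(dba, 0.95, type = 7)),
    hd100 = max(max(dab), max(dba)),
    asd = (sum(dab) + sum(dba)) / (length(dab) + length(dba))
  )
}

random_mask <- function(dims, p = 0.2) {
  m <- array(runif(prod(dims)) < p, dim = dims)
  if (!any(m)) m[sample(length(m), 1)] <- TRUE
  m
}

blob_mask <- function(dims, n_seeds = 2) {
  m <- array(FALSE, dim = dims)
  for (k in seq_len(n_seeds)) {
    c0 <- sapply(dims, function(n) sample(n, 1))
    r <- runif(1, 1, max(dims) / 2)
    g <- expand.grid(z = seq_len(dims[1]), y = seq_len(dims[2]), x = seq_len(dims[3]))
    d2 <- (g$z - c0[1])^2 + (g$y - c0[2])^2 + (g$x - c0[3])^2
    m[d2 <= r^2] <- TRUE
  }
  if (!any(m)) m[sample(length(m), 1)] <- TRUE
  m
}

tiny_phantom_cfg <- function(image_size = 64L, n_slices = 6L, carina_slice = 2L, ...) {
  phantom_config(image_size = image_size, n_slices = n_slices,
                 carina_slice = carina_slice, ...)
}

tiny_dense_cfg <- function(n_classes = 6L, seed = 1L)
  network_config("dense_unet", n_classes = n_classes, stem_width = 8L,
                 n_stages = 3L, block_layers = 2L, growth_rate = 6L, seed = seed)

tiny_ra_cfg <- function(n_classes = 1L, seed = 1L)
  network_config("residual_attention", n_classes = n_classes,
                 widths = c(8L, 16L), seed = seed)

tiny_unet_cfg <- function(n_classes = 6L, seed = 1L)
  network_config("unet", n_classes = n_classes, widths = c(8L, 16L, 32L), seed = seed)

# mean foreground DSC of an argmax prediction against integer labels
mean_fg_dsc <- function(pred, y, codes) {
  ds <- c()
  for (k in codes[-1])
    if (any(y == k) || any(pred == k))
      ds <- c(ds, 2 * sum(pred == k & y == k) / (sum(pred == k) + sum(y == k)))
  mean(ds)
}

zero_params <- function(obj) {
  for (p in obj) { p$value[] <- 0 }
  invisible(NULL)
}
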