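# Minimal dense-array neural primitives for the attention-augmented feature
# extractors. Feature maps are numeric arrays of dimension (channels, height,
# width); weights are plain R arrays so every computation is deterministic
# and inspectable.

sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) pmax(x, 0)

# 2-D convolution on a (C_in, H, W) array with weights (C_out, C_in, kh, kw).
# 'same' zero padding when pad = "same"; stride >= 1.
conv2d <- function(x, w, b = NULL, stride = 1L, pad = "same") {
  dx <- dim(x); dw <- dim(w)
  stopifnot(length(dx) == 3L, length(dw) == 4L, dx[1L] == dw[2L])
  kh <- dw[3L]; kw <- dw[4L]
  if (identical(pad, "same")) {
    ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  } else {
    ph <- pw <- as.integer(pad)
  }
  H <- dx[2L] + 2L * ph; W <- dx[3L] + 2L * pw
  xp <- array(0, c(dx[1L], H, W))
  xp[, (ph + 1L):(ph + dx[2L]), (pw + 1L):(pw + dx[3L])] <- x
  oh <- (H - kh) %/% stride + 1L
  ow <- (W - kw) %/% stride + 1L
  ri <- seq(1L, by = stride, length.out = oh)
  ci <- seq(1L, by = stride, length.out = ow)
  out <- array(if (is.null(b)) 0 else rep(b, each = 1), c(dw[1L], oh, ow))
  if (!is.null(b)) out <- array(rep(b, oh * ow), c(dw[1L], oh, ow))
  for (o in seq_len(dw[1L])) {
    acc <- matrix(0, oh, ow)
    for (c in seq_len(dx[1L])) {
      xc <- xp[c, , ]
      for (i in seq_len(kh)) for (j in seq_len(kw)) {
        wij <- w[o, c, i, j]
        if (wij == 0) next
        acc <- acc + wij * xc[ri + (i - 1L), ci + (j - 1L), drop = FALSE]
      }
    }
    out[o, , ] <- out[o, , ] + acc
  }
  out
}

# Global average / max pooling over the spatial dims -> length-C vectors
gap_pool <- function(x) apply(x, 1L, mean)
gmp_pool <- function(x) apply(x, 1L, max)

# Scale each channel c of x by g[c]
scale_channels <- function(x, g) {
  d <- dim(x)
  x * array(rep(g, d[2L] * d[3L]), d)
}

# Scale every channel elementwise by a (H, W) map
scale_spatial <- function(x, m) {
  d <- dim(x)
  x * aperm(array(rep(m, d[1L]), c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
}

# Bilinear upsampling of an (h, w) matrix to (H, W)
upsample_bilinear <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  if (h == H && w == W) return(m)
  # align-corners mapping; degenerate axes replicate
  ry <- if (h == 1L) rep(1, H) else seq(1, h, length.out = H)
  rx <- if (w == 1L) rep(1, W) else seq(1, w, length.out = W)
  y0 <- clamp(floor(ry), 1, h); y1 <- clamp(y0 + 1, 1, h); fy <- ry - y0
  x0 <- clamp(floor(rx), 1, w); x1 <- clamp(x0 + 1, 1, w); fx <- rx - x0
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  c_ <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  fy_m <- matrix(fy, H, W); fx_m <- matrix(fx, H, W, byrow = TRUE)
  a * (1 - fy_m) * (1 - fx_m) + b * (1 - fy_m) * fx_m +
    c_ * fy_m * (1 - fx_m) + d * fy_m * fx_m
}

# He-normal initialized conv weights, deterministic given the current RNG
init_conv <- function(c_out, c_in, k) {
  array(rnorm(c_out * c_in * k * k, 0, sqrt(2 / (c_in * k * k))),
        c(c_out, c_in, k, k))
}

init_dense <- function(n_out, n_in) {
  matrix(rnorm(n_out * n_in, 0, sqrt(2 / n_in)), n_out, n_in)
}
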