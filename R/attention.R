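# Attention blocks operating on (C, H, W) feature maps: the sequential CBAM
# block, a parallel channel/spatial variant (CSPM), and the channel-only
# squeeze-and-excitation (SE) block used by the audio network.

#' Create weights for an attention block
#'
#' Draws all learnable parameters of a [cbam_block()] / [cspm_block()] /
#' [se_block()] from the current state of R's RNG (wrap in a seed for
#' reproducibility). The channel bottleneck is a two-layer perceptron
#' `C -> C/reduction -> C`; the spatial branch is a single
#' `spatial_kernel x spatial_kernel` convolution over the 2-channel
#' (mean, max) descriptor map.
#'
#' @param channels Number of feature-map channels.
#' @param reduction Channel bottleneck reduction ratio; must divide
#'   `channels` for CBAM/CSPM.
#' @param spatial_kernel 3 or 7.
#' @return List of weight arrays.
#' @export
attention_weights <- function(channels, reduction = 4, spatial_kernel = 7) {
  if (!spatial_kernel %in% c(3, 7))
    rlang::abort("spatial_kernel must be 3 or 7")
  if (channels %% reduction != 0)
    rlang::abort("channels must be divisible by reduction")
  hidden <- max(1L, channels %/% reduction)
  list(w1 = init_dense(hidden, channels), b1 = numeric(hidden),
       w2 = init_dense(channels, hidden), b2 = numeric(channels),
       w_sp = init_conv(1L, 2L, spatial_kernel), b_sp = 0,
       spatial_kernel = spatial_kernel)
}

# shared-bottleneck channel gate from a length-C descriptor
channel_mlp <- function(wt, v) {
  as.numeric(wt$w2 %*% relu(wt$w1 %*% v + wt$b1) + wt$b2)
}

# channel gates sigma(MLP(avg) + MLP(max)); length C
channel_gates <- function(x, wt) {
  sigmoid(channel_mlp(wt, gap_pool(x)) + channel_mlp(wt, gmp_pool(x)))
}

# spatial map sigma(conv([mean_c; max_c])); (H, W)
spatial_map <- function(x, wt) {
  d <- dim(x)
  desc <- array(0, c(2L, d[2L], d[3L]))
  desc[1L, , ] <- apply(x, c(2L, 3L), mean)
  desc[2L, , ] <- apply(x, c(2L, 3L), max)
  sigmoid(conv2d(desc, wt$w_sp, b = wt$b_sp, pad = "same")[1L, , ])
}

#' CBAM: sequential channel-then-spatial attention
#'
#' Channel attention first: average- and max-pooled channel descriptors pass
#' through a shared bottleneck perceptron, their sum through a sigmoid gives
#' per-channel gates. The channel-scaled map then gets spatial attention:
#' channel-wise mean and max maps, a `spatial_kernel` convolution, sigmoid,
#' and elementwise scaling. Output shape equals input shape.
#'
#' @param x Feature map array `(C, H, W)`.
#' @param weights From [attention_weights()] with matching `channels`.
#' @return Array of the same shape as `x`.
#' @export
cbam_block <- function(x, weights) {
  stopifnot(length(dim(x)) == 3L)
  x1 <- scale_channels(x, channel_gates(x, weights))
  scale_spatial(x1, spatial_map(x1, weights))
}

#' CSPM: parallel channel/spatial attention with residual fusion
#'
#' Channel gates and the spatial map are both computed from the input (not
#' sequentially), fused into a single attention field (their broadcast
#' product), applied to the input, and added back residually:
#' `out = x * (gate_c x map_s) + x`. With all gates forced to 1 the block
#' reduces to `2 * x`. Output shape equals input shape; the spatial kernel
#' (3 or 7) is set in the weights.
#'
#' @inheritParams cbam_block
#' @return Array of the same shape as `x`.
#' @export
cspm_block <- function(x, weights) {
  stopifnot(length(dim(x)) == 3L)
  g <- channel_gates(x, weights)
  s <- spatial_map(x, weights)
  gated <- scale_spatial(scale_channels(x, g), s)
  gated + x
}

#' Squeeze-and-excitation channel reweighting
#'
#' Squeeze: global average pooling to a channel descriptor. Excitation: a
#' bottleneck perceptron (`C -> C/reduction -> C`) with ReLU then sigmoid,
#' giving per-channel gates that rescale the input.
#'
#' @param x Feature map array `(C, H, W)`.
#' @param weights List with `w1`, `b1`, `w2`, `b2` as produced by
#'   [attention_weights()] (the spatial branch is unused).
#' @return Array of the same shape as `x`.
#' @export
se_block <- function(x, weights) {
  stopifnot(length(dim(x)) == 3L)
  g <- sigmoid(channel_mlp(weights, gap_pool(x)))
  scale_channels(x, g)
}
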