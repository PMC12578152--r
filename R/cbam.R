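#' Convolutional block attention module (CBAM) forward pass
#'
#' Pure array implementations of the channel attention module (CAM) and
#' spatial attention module (SAM) and their sequential composition. A
#' feature map is a numeric array of shape `C x H x W`. Weights are
#' supplied (or generated for testing with [cbam_random_weights()]), never
#' trained here.
#'
#' @name cbam
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) pmax(x, 0)

check_feature_map <- function(f) {
  if (!is.array(f) || length(dim(f)) != 3L) {
    stop("feature map must be a 3-d array (channels x height x width)",
         call. = FALSE)
  }
  if (!all(is.finite(f))) stop("feature map must be finite", call. = FALSE)
  invisible(f)
}

#' CBAM weight container
#'
#' The shared two-layer MLP of the channel path (`mlp_hidden`: `C/r x C`,
#' `mlp_out`: `C x C/r`, used identically for the average- and max-pooled
#' descriptors) and the 7x7 convolution of the spatial path over the
#' 2-channel `[mean; max]` stack.
#'
#' @param mlp_hidden Matrix `C/r x C`.
#' @param mlp_out Matrix `C x C/r`.
#' @param reduction Positive integer `r` with `C` divisible by `r`.
#' @param spatial_kernel Array `7 x 7 x 2`.
#' @param spatial_bias Scalar bias of the spatial convolution.
#' @return A list of class `cbam_weights`.
#' @export
cbam_weights <- function(mlp_hidden, mlp_out, reduction, spatial_kernel,
                         spatial_bias = 0) {
  C <- ncol(mlp_hidden)
  if (C %% reduction != 0L) {
    stop("channel count must be divisible by the reduction ratio", call. = FALSE)
  }
  if (nrow(mlp_hidden) != C %/% reduction || !all(dim(mlp_out) == c(C, C %/% reduction))) {
    stop("MLP weight shapes inconsistent with C and reduction", call. = FALSE)
  }
  if (!all(dim(spatial_kernel) == c(7L, 7L, 2L))) {
    stop("spatial kernel must be 7 x 7 x 2", call. = FALSE)
  }
  structure(list(mlp_hidden = mlp_hidden, mlp_out = mlp_out,
                 reduction = as.integer(reduction),
                 spatial_kernel = spatial_kernel,
                 spatial_bias = as.numeric(spatial_bias)),
            class = "cbam_weights")
}

#' Seeded random CBAM weights
#'
#' Gaussian weights scaled by fan-in, for tests and demonstrations.
#'
#' @param channels Number of channels `C`.
#' @param reduction Reduction ratio `r` (default 2).
#' @param seed Integer seed.
#' @param sd Weight standard deviation scale.
#' @return A [cbam_weights()] object.
#' @export
cbam_random_weights <- function(channels, reduction = 2L, seed = 1L, sd = 0.5) {
  stopifnot(channels %% reduction == 0L)
  hidden <- channels %/% reduction
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  cbam_weights(
    mlp_hidden = matrix(stats::rnorm(hidden * channels, sd = sd / sqrt(channels)),
                        hidden, channels),
    mlp_out = matrix(stats::rnorm(channels * hidden, sd = sd / sqrt(hidden)),
                     channels, hidden),
    reduction = reduction,
    spatial_kernel = array(stats::rnorm(7 * 7 * 2, sd = sd / sqrt(98)),
                           dim = c(7L, 7L, 2L)),
    spatial_bias = stats::rnorm(1L, sd = sd))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Channel attention gate
#'
#' Global average- and max-pooled channel descriptors are passed through the
#' shared MLP (ReLU between layers), summed, and squashed:
#' `gate = sigmoid(MLP(avgpool(f)) + MLP(maxpool(f)))`.
#'
#' @param f Feature map array `C x H x W`.
#' @param w A [cbam_weights()] object.
#' @return Numeric vector of length `C`, every entry in `(0, 1)`.
#' @export
channel_attention <- function(f, w) {
  check_feature_map(f)
  C <- dim(f)[1L]
  if (ncol(w$mlp_hidden) != C) stop("channel count mismatch", call. = FALSE)
  avg <- apply(f, 1L, mean)
  mx <- apply(f, 1L, max)
  mlp <- function(v) as.numeric(w$mlp_out %*% relu(w$mlp_hidden %*% v))
  sigmoid(mlp(avg) + mlp(mx))
}

#' Spatial attention gate
#'
#' Channel-wise mean and max maps are stacked into a 2-channel `H x W` image
#' and convolved with the 7x7 kernel (stride 1, zero padding 3 so the output
#' keeps the input's spatial size), then squashed through a sigmoid.
#'
#' @param f Feature map array `C x H x W`.
#' @param w A [cbam_weights()] object.
#' @return Matrix `H x W` of gates in `(0, 1)`.
#' @export
spatial_attention <- function(f, w) {
  check_feature_map(f)
  H <- dim(f)[2L]; W <- dim(f)[3L]
  pooled <- array(0, dim = c(H, W, 2L))
  pooled[, , 1L] <- apply(f, c(2L, 3L), mean)
  pooled[, , 2L] <- apply(f, c(2L, 3L), max)
  out <- matrix(w$spatial_bias, H, W)
  pad <- 3L
  for (dy in -pad:pad) {
    ys <- seq_len(H) + dy
    ok_y <- ys >= 1L & ys <= H
    if (!any(ok_y)) next
    for (dx in -pad:pad) {
      xs <- seq_len(W) + dx
      ok_x <- xs >= 1L & xs <= W
      if (!any(ok_x)) next
      for (ch in 1:2) {
        k <- w$spatial_kernel[dy + pad + 1L, dx + pad + 1L, ch]
        if (k == 0) next
        out[ok_y, ok_x] <- out[ok_y, ok_x] +
          k * pooled[ys[ok_y], xs[ok_x], ch]
      }
    }
  }
  sigmoid(out)
}

#' Full CBAM refinement
#'
#' Sequential gating: the input is first scaled per channel by the channel
#' gate, then per pixel by the spatial gate computed on the channel-refined
#' map. Output shape equals input shape, and because both gates lie strictly
#' inside `(0, 1)` every nonzero input entry strictly shrinks in magnitude.
#'
#' @param f Feature map array `C x H x W`.
#' @param w A [cbam_weights()] object.
#' @return Refined feature map, same shape as `f`.
#' @export
cbam_forward <- function(f, w) {
  check_feature_map(f)
  cg <- channel_attention(f, w)
  f1 <- f * cg  # recycles along the first (channel) dimension
  sg <- spatial_attention(f1, w)
  f2 <- f1
  for (c_i in seq_len(dim(f)[1L])) f2[c_i, , ] <- f1[c_i, , ] * sg
  f2
}
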