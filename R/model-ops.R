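# Individual model operations, exposed one-to-one with the architecture:
# embeddings, scaled dot-product attention, care-aware (multihead) attention,
# feedforward refinement, positional encoding, temporal encoder, pooling and
# the softmax classifier. The batched training engine in model-forward.R
# computes the same functions vectorized over windows and frames.

#' Normalize keypoints for model input
#'
#' Coordinates are divided by the frame size and centered at the hip midpoint
#' of each frame, giving translation invariance across seating positions.
#' Confidence scores are not part of the model input.
#'
#' @param keypoints `T x 17 x 2` array (or one `17 x 2` frame) in pixels.
#' @param frame_size Pixel extent of the virtual frame.
#' @return Array of the same shape, normalized.
#' @export
normalize_keypoints <- function(keypoints, frame_size = 640) {
  kp <- as_kp_array(keypoints) / frame_size
  hip_mid <- (kp[, 12L, , drop = FALSE] + kp[, 13L, , drop = FALSE]) / 2
  kp <- kp - hip_mid[, rep(1L, 17L), , drop = FALSE]
  kp
}

# flatten one 17 x 2 frame to the 34-vector (x1, y1, x2, y2, ...)
flatten_frame <- function(frame_keypoints) {
  as.vector(t(frame_keypoints))
}

#' Embed one frame of keypoints
#'
#' The 17 (x, y) pairs are flattened to a 34-vector and passed through a
#' linear layer: `token = x W_k + b_k`.
#'
#' @param frame_keypoints `17 x 2` matrix of normalized coordinates.
#' @param params `cstt_params` (uses `W_k`, `b_k`).
#' @return `1 x d` token.
#' @export
embed_keypoints <- function(frame_keypoints, params) {
  x <- flatten_frame(as.matrix(frame_keypoints))
  if (anyNA(x)) abort("keypoints contain NA")
  matrix(x, 1L) %*% params$W_k + rep(params$b_k, each = 1L)
}

# "same" zero-padded 2D convolution with a single k x k kernel
conv2d_same <- function(img, kernel, bias = 0) {
  k <- nrow(kernel)
  r <- (k - 1L) %/% 2L
  h <- nrow(img)
  w <- ncol(img)
  pad <- matrix(0, h + 2L * r, w + 2L * r)
  pad[(r + 1L):(r + h), (r + 1L):(r + w)] <- img
  out <- matrix(bias, h, w)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      out <- out + kernel[a, b] * pad[a:(a + h - 1L), b:(b + w - 1L)]
    }
  }
  out
}

# split a 64 x 64 map into (64/patch)^2 flattened patches; row p = patch
# (gy, gx) with gy fastest, pixel order column-major within the patch
patchify <- function(img, patch) {
  g <- nrow(img) %/% patch
  a <- array(img, c(patch, g, patch, g))
  a <- aperm(a, c(1L, 3L, 2L, 4L))
  t(matrix(a, patch * patch, g * g))
}

#' Embed one depth heatmap into spatial patch tokens
#'
#' The map passes through a small convolution (temporal kernel extent 1, so
#' the convolution acts per frame) and is then cut into
#' `(64/heatmap_patch)^2` patches, each flattened and linearly projected to
#' the latent dimension.
#'
#' @param map `64 x 64` matrix in `[0,1]`.
#' @param params `cstt_params` (uses `conv_w`, `conv_b`, `W_p`, `b_p`).
#' @param config A [cstt_config()].
#' @return `T_p x d` token matrix.
#' @export
embed_heatmap <- function(map, params, config) {
  map <- as.matrix(map)
  if (!all(dim(map) == c(64L, 64L))) abort("heatmap must be 64 x 64")
  cv <- conv2d_same(map, params$conv_w, params$conv_b)
  p <- patchify(cv, config$heatmap_patch)
  p %*% params$W_p + rep(params$b_p, each = nrow(p))
}

#' Embed a care level
#'
#' The scalar care level is rescaled to `(care_level - 3) / 2` in `[-1, 1]`
#' and passed through a linear layer `token = s W_c + b_c`.
#'
#' @param care_level Integer in 1..5.
#' @param params `cstt_params` (uses `W_c`, `b_c`).
#' @return `1 x d` token.
#' @export
embed_care_level <- function(care_level, params) {
  if (!all(care_level %in% 1:5)) abort("care_level must be in 1..5")
  s <- (care_level - 3) / 2
  outer(s, params$W_c) + rep(params$b_c, each = length(s))
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d)) V`; every weight row sums to 1.
#'
#' @param Q `n_q x d` query matrix.
#' @param K,V `n_k x d` key and value matrices.
#' @return List with `values` (`n_q x d_v`) and `weights` (`n_q x n_k`).
#' @export
scaled_dot_attention <- function(Q, K, V) {
  Q <- as.matrix(Q)
  K <- as.matrix(K)
  V <- as.matrix(V)
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  s <- Q %*% t(K) / sqrt(ncol(Q))
  w <- softmax_rows(s)
  list(values = w %*% V, weights = w)
}

#' Care-aware attention over one frame's tokens (single head)
#'
#' The projected care embedding is the sole query; the concatenated keypoint
#' and heatmap tokens are keys and values. The result is one latent vector
#' per frame: a care-weighted sum of the frame's features.
#'
#' @param tokens List with `care` (`1 x d`), and any of `keypoint` (`1 x d`)
#'   and `heatmap` (`T_p x d`); at least one key/value token is required.
#' @param params `cstt_params` (uses the `cam.` projections, full width).
#' @return List with `values` (`1 x d`) and `weights` over the
#'   keypoint-then-heatmap token order.
#' @export
care_aware_attention <- function(tokens, params) {
  kv <- rbind(tokens$keypoint, tokens$heatmap)
  if (is.null(kv) || nrow(kv) == 0L) abort("no key/value tokens")
  q <- as.matrix(tokens$care) %*% params$cam.Wq + rep(params$cam.bq, each = 1L)
  k <- kv %*% params$cam.Wk + rep(params$cam.bk, each = nrow(kv))
  v <- kv %*% params$cam.Wv + rep(params$cam.bv, each = nrow(kv))
  scaled_dot_attention(q, k, v)
}

#' Multihead care-aware attention
#'
#' Runs [care_aware_attention()] independently on `n_heads` subspaces of
#' dimension `d / n_heads`, concatenates the heads and projects with `W_o`.
#'
#' @inheritParams care_aware_attention
#' @param config A [cstt_config()].
#' @return List with `values` (`1 x d` frame feature) and per-head `weights`
#'   (`n_heads x n_tokens` matrix; each row sums to 1).
#' @export
multihead_care_attention <- function(tokens, params, config) {
  d <- config$d
  nh <- config$n_heads
  dh <- d %/% nh
  kv <- rbind(tokens$keypoint, tokens$heatmap)
  if (is.null(kv) || nrow(kv) == 0L) abort("no key/value tokens")
  q <- as.matrix(tokens$care) %*% params$cam.Wq + rep(params$cam.bq, each = 1L)
  k <- kv %*% params$cam.Wk + rep(params$cam.bk, each = nrow(kv))
  v <- kv %*% params$cam.Wv + rep(params$cam.bv, each = nrow(kv))
  heads <- matrix(0, 1L, d)
  weights <- matrix(0, nh, nrow(kv))
  for (h in seq_len(nh)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    att <- scaled_dot_attention(
      q[, cols, drop = FALSE], k[, cols, drop = FALSE], v[, cols, drop = FALSE]
    )
    heads[, cols] <- att$values
    weights[h, ] <- att$weights
  }
  list(
    values = heads %*% params$cam.Wo + rep(params$cam.bo, each = 1L),
    weights = weights
  )
}

#' Feedforward refinement with residual connection
#'
#' `y = x + relu(x F1 + b1) F2 + b2`; with zero weights this is the identity.
#'
#' @param x `n x d` matrix of frame features.
#' @param params `cstt_params` (uses the `cam.F*` weights).
#' @return `n x d` matrix.
#' @export
feedforward <- function(x, params) {
  x <- as.matrix(x)
  h1 <- pmax(x %*% params$cam.F1 + rep(params$cam.f1b, each = nrow(x)), 0)
  x + h1 %*% params$cam.F2 + rep(params$cam.f2b, each = nrow(x))
}

#' Sinusoidal positional encoding
#'
#' Row `t` (0-based position) has `sin(t / rho^(2i/d))` in even dimensions
#' `2i` and `cos(t / rho^(2i/d))` in the following odd dimension.
#'
#' @param T_len Number of positions.
#' @param d Encoding dimension.
#' @param rho Base constant (10,000).
#' @return `T_len x d` matrix with entries in `[-1, 1]`.
#' @export
positional_encoding <- function(T_len, d, rho = 10000) {
  stopifnot(T_len >= 1L, d >= 1L, rho > 0)
  pos <- 0:(T_len - 1L)
  pe <- matrix(0, T_len, d)
  for (j in 0:(d - 1L)) {
    i <- j %/% 2L
    freq <- rho^(-2 * i / d)
    pe[, j + 1L] <- if (j %% 2L == 0L) sin(pos * freq) else cos(pos * freq)
  }
  pe
}

layer_norm <- function(x, g, b, eps = 1e-5) {
  n <- nrow(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  xhat <- xc / sqrt(v + eps)
  xhat * rep(g, each = n) + rep(b, each = n)
}

#' Temporal transformer encoder
#'
#' Pre-norm encoder layers applied across the temporal dimension: each layer
#' is multihead self-attention and a feedforward block, both with residual
#' connections and layer normalization on their inputs. With zero layers this
#' is the identity. Positional encoding is expected to have been added.
#'
#' @param Z `T x d` matrix of per-frame features.
#' @param params `cstt_params` (uses the `t<l>.` weights).
#' @param config A [cstt_config()].
#' @return `T x d` matrix.
#' @export
temporal_encode <- function(Z, params, config) {
  Z <- as.matrix(Z)
  d <- config$d
  nh <- config$n_heads
  dh <- d %/% nh
  for (l in seq_len(config$n_temporal_layers)) {
    p <- function(nm) params[[paste0("t", l, ".", nm)]]
    u <- layer_norm(Z, p("ln1_g"), p("ln1_b"))
    q <- u %*% p("Wq") + rep(p("bq"), each = nrow(u))
    k <- u %*% p("Wk") + rep(p("bk"), each = nrow(u))
    v <- u %*% p("Wv") + rep(p("bv"), each = nrow(u))
    o <- matrix(0, nrow(Z), d)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      o[, cols] <- scaled_dot_attention(
        q[, cols, drop = FALSE], k[, cols, drop = FALSE],
        v[, cols, drop = FALSE]
      )$values
    }
    Z <- Z + o %*% p("Wo") + rep(p("bo"), each = nrow(Z))
    v2 <- layer_norm(Z, p("ln2_g"), p("ln2_b"))
    h1 <- pmax(v2 %*% p("F1") + rep(p("f1b"), each = nrow(v2)), 0)
    Z <- Z + h1 %*% p("F2") + rep(p("f2b"), each = nrow(Z))
  }
  Z
}

#' Mean pooling over the temporal axis
#'
#' @param Z `T x d` matrix (`T >= 1`).
#' @return `1 x d` matrix: the arithmetic mean over frames.
#' @export
mean_pool <- function(Z) {
  Z <- as.matrix(Z)
  if (nrow(Z) == 0L) abort("cannot pool an empty sequence")
  matrix(colMeans(Z), 1L)
}

#' Softmax activity classifier
#'
#' `softmax(z W_cls + b_cls)`; probabilities sum to 1 over the classes.
#'
#' @param z `n x d` matrix of pooled sequence features.
#' @param params `cstt_params` (uses `W_cls`, `b_cls`).
#' @return `n x n_classes` matrix of class probabilities.
#' @export
classify <- function(z, params) {
  z <- as.matrix(z)
  logits <- z %*% params$W_cls + rep(params$b_cls, each = nrow(z))
  softmax_rows(logits)
}
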