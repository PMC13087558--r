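# Batched forward pass and backpropagation for the CSTT/TSTT network.
#
# Windows are processed as one flat frame axis (BT = windows x frames):
# embeddings and the care-aware attention are vectorized over all frames and
# heads, temporal self-attention loops over windows and heads (T x T
# matrices). The heatmap convolution + patchification + projection are fused:
# each patch is extracted with its kernel halo, and the convolution kernel
# and patch projection combine into a single effective projection matrix, so
# the convolution costs one BLAS call. The backward pass mirrors the forward
# exactly; test-suite gradient checks compare it against central finite
# differences.

#' Assemble model-ready window tensors from a dataset
#'
#' Cuts every sample into windows of `config$window` frames, normalizes
#' keypoints ([normalize_keypoints()]), and stacks keypoint vectors, heatmap
#' frames, care levels and labels into flat arrays. In partial-skeleton modes
#' a per-sample joint mask (fraction `config$mask_rate`, derived
#' deterministically from the sample id and `mask_seed`) zeroes masked
#' coordinates.
#'
#' @param d A `har_dataset`.
#' @param config A [cstt_config()].
#' @param mode Mode string (see [parse_mode()]).
#' @param stride Window stride in frames.
#' @param mask_seed Seed for partial-skeleton joint masks.
#' @return A `cstt_windows` list: `Xk` (`BT x 34`), precomputed heatmap halo
#'   patches `Ph` with their geometry `geo`, and `care`, `y`, `session_id`,
#'   `subject_id`, `sample_id` per window, plus sizes `n` and `T`.
#' @export
prepare_windows <- function(d, config, mode = "cstt", stride = 8L,
                            mask_seed = 1L) {
  stopifnot(inherits(d, "har_dataset"), inherits(config, "cstt_config"))
  modep <- if (is.list(mode)) mode else parse_mode(mode)
  T_w <- config$window
  counts <- vapply(d$samples, function(s) {
    t_f <- n_frames(s)
    if (t_f < T_w) 0L else as.integer((t_f - T_w) %/% stride + 1L)
  }, integer(1))
  n_win <- sum(counts)
  if (n_win == 0L) abort("no sample is long enough for the window length")
  Xk <- matrix(0, n_win * T_w, 34L)
  geo <- NULL
  Ph <- NULL
  if (modep$use_heatmap) {
    # halo patches depend only on the data: extract them once here so the
    # training loop reduces the convolution to a single matrix product
    geo <- halo_geometry(config$heatmap_patch, config$conv_kernel)
    Ph <- matrix(0, n_win * T_w * geo$Tp, geo$hs * geo$hs)
  }
  care <- integer(n_win)
  y <- integer(n_win)
  session_id <- character(n_win)
  subject_id <- character(n_win)
  sample_id <- character(n_win)
  w <- 0L
  n_mask <- max(1L, round(config$mask_rate * 17L))
  interleave <- as.vector(rbind(1:17, 18:34))
  for (si in seq_along(d$samples)) {
    if (counts[si] == 0L) next
    s <- d$samples[[si]]
    kp <- normalize_keypoints(s$skeleton$keypoints, config$frame_size)
    if (modep$partial_skeleton) {
      sid_key <- sum(utf8ToInt(s$sample_id) * seq_len(nchar(s$sample_id)))
      masked <- withr::with_seed(
        derive_seed(mask_seed, 77L, sid_key),
        sample(17L, n_mask)
      )
      kp[, masked, ] <- 0
    }
    starts <- seq(1L, n_frames(s) - T_w + 1L, by = stride)
    for (st in starts) {
      w <- w + 1L
      rows <- ((w - 1L) * T_w + 1L):(w * T_w)
      fr <- st:(st + T_w - 1L)
      # 34-vector per frame: (x1, y1, x2, y2, ...)
      Xk[rows, ] <- cbind(
        kp[fr, , 1L, drop = FALSE][, , 1L],
        kp[fr, , 2L, drop = FALSE][, , 1L]
      )[, interleave]
      if (modep$use_heatmap) {
        prow <- ((w - 1L) * T_w * geo$Tp + 1L):(w * T_w * geo$Tp)
        Ph[prow, ] <- halo_patches(
          aperm(s$heatmaps$maps[fr, , , drop = FALSE], c(2L, 3L, 1L)), geo
        )
      }
      care[w] <- s$care$care_level
      y[w] <- s$label
      session_id[w] <- s$session_id
      subject_id[w] <- s$care$subject_id
      sample_id[w] <- s$sample_id
    }
  }
  structure(
    list(
      Xk = Xk, Ph = Ph, geo = geo, care = care, y = y, session_id = session_id,
      subject_id = subject_id, sample_id = sample_id,
      n = n_win, T = T_w
    ),
    class = "cstt_windows"
  )
}

# --- fused convolution + patchification -------------------------------------

# index geometry for halo patches: every patch of side `patch` is extracted
# from the zero-padded image together with its r-pixel margin
halo_geometry <- function(patch, kernel, size = 64L) {
  r <- (kernel - 1L) %/% 2L
  g <- size %/% patch
  hs <- patch + 2L * r
  padn <- size + 2L * r
  rowidx <- outer(seq_len(hs), (seq_len(g) - 1L) * patch, `+`) # hs x g
  colidx <- rowidx
  idx <- kronecker((colidx - 1L) * padn, matrix(1L, hs, g)) +
    kronecker(matrix(1L, hs, g), rowidx)
  # halo-local index of the input pixel feeding output pixel o via kernel (a,b)
  py <- rep(seq_len(patch), patch)
  px <- rep(seq_len(patch), each = patch)
  hidx <- vector("list", kernel * kernel)
  for (a in seq_len(kernel)) {
    for (b in seq_len(kernel)) {
      hidx[[(b - 1L) * kernel + a]] <- (py + a - 1L) + hs * (px + b - 2L)
    }
  }
  list(
    r = r, g = g, hs = hs, padn = padn, Tp = g * g,
    idx = idx, hidx = hidx, patch = patch, kernel = kernel
  )
}

# (Tp * n_frames) x hs^2 halo-patch matrix; rows: patch fastest within frame
halo_patches <- function(HM, geo) {
  n <- dim(HM)[3L]
  pad <- array(0, c(geo$padn, geo$padn, n))
  pad[(geo$r + 1L):(geo$r + 64L), (geo$r + 1L):(geo$r + 64L), ] <- HM
  pm <- matrix(pad, geo$padn * geo$padn, n)
  gat <- pm[as.vector(geo$idx), , drop = FALSE] # (hs^2 * Tp) x n
  a <- array(gat, c(geo$hs * geo$hs, geo$Tp, n))
  matrix(aperm(a, c(2L, 3L, 1L)), geo$Tp * n, geo$hs * geo$hs)
}

# effective projection: halo patch -> token, combining conv kernel and W_p
conv_aw <- function(conv_w, geo) {
  A <- matrix(0, geo$hs * geo$hs, geo$patch * geo$patch)
  p2 <- geo$patch * geo$patch
  for (a in seq_len(geo$kernel)) {
    for (b in seq_len(geo$kernel)) {
      A[cbind(geo$hidx[[(b - 1L) * geo$kernel + a]], seq_len(p2))] <- conv_w[a, b]
    }
  }
  A
}

ln_fwd <- function(x, g, b, eps = 1e-5) {
  n <- nrow(x)
  mu <- rowMeans(x)
  xc <- x - mu
  inv_sd <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv_sd
  list(y = xhat * rep(g, each = n) + rep(b, each = n), xhat = xhat, inv_sd = inv_sd)
}

ln_bwd <- function(dy, cache, g) {
  n <- nrow(dy)
  dxhat <- dy * rep(g, each = n)
  gg <- colSums(dy * cache$xhat)
  gb <- colSums(dy)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dx <- cache$inv_sd * (dxhat - m1 - cache$xhat * m2)
  list(dx = dx, gg = gg, gb = gb)
}

drop_mask <- function(n_row, n_col, p) {
  matrix((runif(n_row * n_col) >= p) / (1 - p), n_row, n_col)
}

add_rowvec <- function(M, v) M + rep(v, each = nrow(M))

#' Forward pass of the CSTT/TSTT network over a set of windows
#'
#' @param data A `cstt_windows` object from [prepare_windows()].
#' @param idx Window indices to process (defaults to all).
#' @param params A `cstt_params` list.
#' @param config A [cstt_config()].
#' @param mode Mode string or parsed mode list.
#' @param training If `TRUE`, applies dropout (caller seeds the RNG).
#' @param keep_cache Keep intermediate activations for [cstt_backward()].
#' @return List with `probs` (`B x n_classes`), `pred` (argmax class codes,
#'   lowest index on ties), `attn` (per-window mean care-attention mass on
#'   the keypoint token, care token and heatmap patches), and `cache`.
#' @export
cstt_forward <- function(data, idx = NULL, params, config, mode = "cstt",
                         training = FALSE, keep_cache = FALSE) {
  modep <- if (is.list(mode)) mode else parse_mode(mode)
  if (is.null(idx)) idx <- seq_len(data$n)
  B <- length(idx)
  T_w <- data$T
  BT <- B * T_w
  d <- config$d
  nh <- config$n_heads
  dh <- d %/% nh
  drop_p <- if (training) config$dropout else 0
  hmask <- kronecker(diag(nh), matrix(1, dh, 1L)) # d x nh head indicator
  hexp <- rep(seq_len(nh), each = dh) # expand head cols to d cols
  isq <- 1 / sqrt(dh)

  frame_rows <- as.vector(outer(seq_len(T_w), (idx - 1L) * T_w, `+`))
  ca <- list()

  # --- embeddings -----------------------------------------------------------
  Xk <- data$Xk[frame_rows, , drop = FALSE]
  K_tok <- if (modep$use_skeleton) {
    add_rowvec(Xk %*% params$W_k, params$b_k)
  } else {
    NULL
  }
  Tp <- 0L
  H_tok <- NULL
  geo <- NULL
  if (modep$use_heatmap) {
    geo <- data$geo
    if (is.null(geo)) abort("windows were prepared without heatmaps")
    Tp <- geo$Tp
    patch_rows <- as.vector(outer(
      seq_len(T_w * Tp), (idx - 1L) * T_w * Tp, `+`
    ))
    Ph <- data$Ph[patch_rows, , drop = FALSE]
    A_w <- conv_aw(params$conv_w, geo)
    W_eff <- A_w %*% params$W_p
    b_eff <- params$conv_b * colSums(params$W_p) + params$b_p
    H_tok <- add_rowvec(Ph %*% W_eff, b_eff)
    rep_f <- rep(seq_len(BT), each = Tp)
    if (keep_cache) {
      ca$Ph <- Ph
      ca$A_w <- A_w
      ca$geo <- geo
    }
  }
  s_care <- (data$care[idx] - 3) / 2
  C_emb <- add_rowvec(outer(s_care, params$W_c), params$b_c) # B x d
  t_rep <- rep(seq_len(B), each = T_w)
  Crep <- if (modep$care_query) {
    C_emb[t_rep, , drop = FALSE]
  } else {
    matrix(params$q_tok, BT, d, byrow = TRUE)
  }
  C_tok <- if (modep$care_token) C_emb[t_rep, , drop = FALSE] else NULL

  # --- care-aware attention (query: care / learned token) -------------------
  Q <- add_rowvec(Crep %*% params$cam.Wq, params$cam.bq)
  KKk <- VVk <- KKc <- VVc <- KKp <- VVp <- Qrep <- NULL
  if (!is.null(K_tok)) {
    KKk <- add_rowvec(K_tok %*% params$cam.Wk, params$cam.bk)
    VVk <- add_rowvec(K_tok %*% params$cam.Wv, params$cam.bv)
  }
  if (!is.null(C_tok)) {
    KKc <- add_rowvec(C_tok %*% params$cam.Wk, params$cam.bk)
    VVc <- add_rowvec(C_tok %*% params$cam.Wv, params$cam.bv)
  }
  if (!is.null(H_tok)) {
    KKp <- add_rowvec(H_tok %*% params$cam.Wk, params$cam.bk)
    VVp <- add_rowvec(H_tok %*% params$cam.Wv, params$cam.bv)
    Qrep <- Q[rep_f, , drop = FALSE]
  }
  # per-head scores for all frames at once: (Q * K) summed within head blocks
  sk <- if (!is.null(KKk)) (Q * KKk) %*% hmask * isq # BT x nh
  sc <- if (!is.null(KKc)) (Q * KKc) %*% hmask * isq
  sp <- if (!is.null(KKp)) (Qrep * KKp) %*% hmask * isq # BT*Tp x nh
  m <- matrix(-Inf, BT, nh)
  if (!is.null(sk)) m <- pmax(m, sk)
  if (!is.null(sc)) m <- pmax(m, sc)
  if (!is.null(sp)) {
    spm <- matrix(sp, Tp) # Tp x (BT * nh): token index fastest
    m <- pmax(m, matrix(apply(spm, 2L, max), BT, nh))
  }
  denom <- matrix(0, BT, nh)
  ek <- ec <- ep <- NULL
  if (!is.null(sk)) {
    ek <- exp(sk - m)
    denom <- denom + ek
  }
  if (!is.null(sc)) {
    ec <- exp(sc - m)
    denom <- denom + ec
  }
  if (!is.null(sp)) {
    ep <- exp(sp - m[rep_f, , drop = FALSE])
    denom <- denom + rowsum(ep, rep_f, reorder = FALSE)
  }
  w_k <- if (!is.null(ek)) ek / denom
  w_c <- if (!is.null(ec)) ec / denom
  w_p <- if (!is.null(ep)) ep / denom[rep_f, , drop = FALSE]
  A <- matrix(0, BT, d)
  if (!is.null(w_k)) A <- A + w_k[, hexp, drop = FALSE] * VVk
  if (!is.null(w_c)) A <- A + w_c[, hexp, drop = FALSE] * VVc
  if (!is.null(w_p)) {
    A <- A + rowsum(w_p[, hexp, drop = FALSE] * VVp, rep_f, reorder = FALSE)
  }
  attn_out <- add_rowvec(A %*% params$cam.Wo, params$cam.bo)

  # --- per-frame feedforward refinement -------------------------------------
  h1 <- pmax(add_rowvec(attn_out %*% params$cam.F1, params$cam.f1b), 0)
  cam_mask <- if (drop_p > 0) drop_mask(BT, config$ffn_hidden, drop_p) else NULL
  h1d <- if (is.null(cam_mask)) h1 else h1 * cam_mask
  Y <- attn_out + add_rowvec(h1d %*% params$cam.F2, params$cam.f2b)

  # --- temporal encoder ------------------------------------------------------
  pe <- positional_encoding(T_w, d, config$pe_constant)
  Z <- Y + pe[rep(seq_len(T_w), times = B), , drop = FALSE]
  layers <- list()
  for (l in seq_len(config$n_temporal_layers)) {
    p <- function(nm) params[[paste0("t", l, ".", nm)]]
    lc <- list()
    ln1 <- ln_fwd(Z, p("ln1_g"), p("ln1_b"))
    u <- ln1$y
    qm <- add_rowvec(u %*% p("Wq"), p("bq"))
    km <- add_rowvec(u %*% p("Wk"), p("bk"))
    vm <- add_rowvec(u %*% p("Wv"), p("bv"))
    o <- matrix(0, BT, d)
    attw <- array(0, c(T_w, T_w, B, nh))
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * T_w + 1L):(b * T_w)
      for (h in seq_len(nh)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        s <- tcrossprod(qm[rows, cols, drop = FALSE], km[rows, cols, drop = FALSE]) * isq
        wm <- softmax_rows(s)
        attw[, , b, h] <- wm
        o[rows, cols] <- wm %*% vm[rows, cols, drop = FALSE]
      }
    }
    Z <- Z + add_rowvec(o %*% p("Wo"), p("bo"))
    lc <- c(lc, list(ln1 = ln1, u = u, qm = qm, km = km, vm = vm, o = o, attw = attw))
    ln2 <- ln_fwd(Z, p("ln2_g"), p("ln2_b"))
    lh1 <- pmax(add_rowvec(ln2$y %*% p("F1"), p("f1b")), 0)
    lmask <- if (drop_p > 0) drop_mask(BT, config$ffn_hidden, drop_p) else NULL
    lh1d <- if (is.null(lmask)) lh1 else lh1 * lmask
    Z <- Z + add_rowvec(lh1d %*% p("F2"), p("f2b"))
    lc <- c(lc, list(ln2 = ln2, h1 = lh1, mask = lmask, h1d = lh1d))
    layers[[l]] <- lc
  }

  # --- pooling and classification -------------------------------------------
  lnf <- ln_fwd(Z, params$ln_f_g, params$ln_f_b)
  pool <- rowsum(lnf$y, t_rep, reorder = FALSE) / T_w
  rownames(pool) <- NULL
  logits <- add_rowvec(pool %*% params$W_cls, params$b_cls)
  probs <- softmax_rows(logits)
  pred <- max.col(probs, ties.method = "first") - 1L

  # attention diagnostics: mean mass per token group (heads and frames pooled)
  attn <- tibble(
    window = idx,
    care_level = data$care[idx],
    keypoint = if (!is.null(w_k)) {
      unname(rowsum(rowMeans(w_k), t_rep, reorder = FALSE)[, 1L]) / T_w
    } else {
      0
    },
    care_token = if (!is.null(w_c)) {
      unname(rowsum(rowMeans(w_c), t_rep, reorder = FALSE)[, 1L]) / T_w
    } else {
      0
    },
    heatmap = if (!is.null(w_p)) {
      unname(rowsum(rowsum(rowMeans(w_p), rep_f, reorder = FALSE)[, 1L], t_rep,
        reorder = FALSE
      )[, 1L]) / T_w
    } else {
      0
    }
  )

  if (keep_cache) {
    ca <- c(ca, list(
      modep = modep, idx = idx, B = B, T = T_w, BT = BT, Tp = Tp,
      d = d, nh = nh, dh = dh, t_rep = t_rep, hmask = hmask, hexp = hexp,
      Xk = Xk, K_tok = K_tok, H_tok = H_tok, C_tok = C_tok,
      s_care = s_care, Crep = Crep,
      Q = Q, Qrep = Qrep, KKk = KKk, VVk = VVk, KKc = KKc, VVc = VVc,
      KKp = KKp, VVp = VVp,
      w_k = w_k, w_c = w_c, w_p = w_p, A = A, attn_out = attn_out,
      h1 = h1, cam_mask = cam_mask, h1d = h1d,
      layers = layers, lnf = lnf, pool = pool, probs = probs
    ))
  }
  list(probs = probs, pred = pred, attn = attn, cache = if (keep_cache) ca else NULL)
}

#' Cross-entropy loss and parameter gradients
#'
#' Runs backpropagation through the cached forward pass. Gradients of
#' parameters not used by the mode (for example the care projection `W_c`
#' in the care-blind TSTT mode) are exactly zero.
#'
#' @param cache Cache from [cstt_forward()] with `keep_cache = TRUE`.
#' @param y Integer class codes (0-based) for the processed windows.
#' @param params,config As in [cstt_forward()].
#' @return List with `loss` (mean cross-entropy), `grads` (named like
#'   `params`) and `dC` (gradient w.r.t. the care embedding, `B x d`).
#' @export
cstt_backward <- function(cache, y, params, config) {
  ca <- cache
  B <- ca$B
  T_w <- ca$T
  BT <- ca$BT
  Tp <- ca$Tp
  d <- ca$d
  nh <- ca$nh
  dh <- ca$dh
  modep <- ca$modep
  hexp <- ca$hexp
  isq <- 1 / sqrt(dh)
  grads <- lapply(params, function(a) {
    a[] <- 0
    a
  })
  y1 <- cbind(seq_len(B), y + 1L)
  loss <- -mean(log(pmax(ca$probs[y1], 1e-300)))

  dlogits <- ca$probs / B
  dlogits[y1] <- dlogits[y1] - 1 / B
  grads$W_cls <- crossprod(ca$pool, dlogits)
  grads$b_cls <- colSums(dlogits)
  dpool <- tcrossprod(dlogits, params$W_cls)
  dZf <- dpool[ca$t_rep, , drop = FALSE] / T_w
  lb <- ln_bwd(dZf, ca$lnf, params$ln_f_g)
  grads$ln_f_g <- lb$gg
  grads$ln_f_b <- lb$gb
  dZ <- lb$dx

  for (l in rev(seq_len(config$n_temporal_layers))) {
    p <- function(nm) params[[paste0("t", l, ".", nm)]]
    gn <- function(nm) paste0("t", l, ".", nm)
    lc <- ca$layers[[l]]
    # FFN block: z_out = z_mid + (relu(LN2(z_mid)) [mask]) F2 + f2b
    dh1d <- tcrossprod(dZ, p("F2"))
    grads[[gn("F2")]] <- crossprod(lc$h1d, dZ)
    grads[[gn("f2b")]] <- colSums(dZ)
    dh1 <- if (is.null(lc$mask)) dh1d else dh1d * lc$mask
    dh1 <- dh1 * (lc$h1 > 0)
    grads[[gn("F1")]] <- crossprod(lc$ln2$y, dh1)
    grads[[gn("f1b")]] <- colSums(dh1)
    dv2 <- tcrossprod(dh1, p("F1"))
    lb2 <- ln_bwd(dv2, lc$ln2, p("ln2_g"))
    grads[[gn("ln2_g")]] <- lb2$gg
    grads[[gn("ln2_b")]] <- lb2$gb
    dZmid <- dZ + lb2$dx
    # attention block: z_mid = z_in + o Wo + bo
    do_ <- tcrossprod(dZmid, p("Wo"))
    grads[[gn("Wo")]] <- crossprod(lc$o, dZmid)
    grads[[gn("bo")]] <- colSums(dZmid)
    dq <- matrix(0, BT, d)
    dk <- matrix(0, BT, d)
    dv <- matrix(0, BT, d)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * T_w + 1L):(b * T_w)
      for (h in seq_len(nh)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        wm <- lc$attw[, , b, h]
        do_h <- do_[rows, cols, drop = FALSE]
        dwm <- tcrossprod(do_h, lc$vm[rows, cols, drop = FALSE])
        dv[rows, cols] <- crossprod(wm, do_h)
        ds <- wm * (dwm - rowSums(dwm * wm))
        dq[rows, cols] <- ds %*% lc$km[rows, cols, drop = FALSE] * isq
        dk[rows, cols] <- crossprod(ds, lc$qm[rows, cols, drop = FALSE]) * isq
      }
    }
    grads[[gn("Wq")]] <- crossprod(lc$u, dq)
    grads[[gn("bq")]] <- colSums(dq)
    grads[[gn("Wk")]] <- crossprod(lc$u, dk)
    grads[[gn("bk")]] <- colSums(dk)
    grads[[gn("Wv")]] <- crossprod(lc$u, dv)
    grads[[gn("bv")]] <- colSums(dv)
    du <- tcrossprod(dq, p("Wq")) + tcrossprod(dk, p("Wk")) + tcrossprod(dv, p("Wv"))
    lb1 <- ln_bwd(du, lc$ln1, p("ln1_g"))
    grads[[gn("ln1_g")]] <- lb1$gg
    grads[[gn("ln1_b")]] <- lb1$gb
    dZ <- dZmid + lb1$dx
  }

  # positional encoding is constant: dY = dZ
  dY <- dZ
  # CAM feedforward: Y = attn_out + (relu(attn_out F1) [mask]) F2
  dh1d <- tcrossprod(dY, params$cam.F2)
  grads$cam.F2 <- crossprod(ca$h1d, dY)
  grads$cam.f2b <- colSums(dY)
  dh1 <- if (is.null(ca$cam_mask)) dh1d else dh1d * ca$cam_mask
  dh1 <- dh1 * (ca$h1 > 0)
  grads$cam.F1 <- crossprod(ca$attn_out, dh1)
  grads$cam.f1b <- colSums(dh1)
  dattn <- dY + tcrossprod(dh1, params$cam.F1)

  # attention output projection
  dA <- dattn %*% t(params$cam.Wo)
  grads$cam.Wo <- crossprod(ca$A, dattn)
  grads$cam.bo <- colSums(dattn)

  rep_f <- if (Tp > 0L) rep(seq_len(BT), each = Tp)
  dA_rep <- if (Tp > 0L) dA[rep_f, , drop = FALSE]
  dQ <- matrix(0, BT, d)
  dKKk <- dVVk <- dKKc <- dVVc <- dKKp <- dVVp <- NULL
  dwk <- if (!is.null(ca$w_k)) (dA * ca$VVk) %*% ca$hmask
  dwc <- if (!is.null(ca$w_c)) (dA * ca$VVc) %*% ca$hmask
  dwp <- if (!is.null(ca$w_p)) (dA_rep * ca$VVp) %*% ca$hmask
  if (!is.null(ca$w_k)) dVVk <- ca$w_k[, hexp, drop = FALSE] * dA
  if (!is.null(ca$w_c)) dVVc <- ca$w_c[, hexp, drop = FALSE] * dA
  if (!is.null(ca$w_p)) dVVp <- ca$w_p[, hexp, drop = FALSE] * dA_rep
  # softmax backward over the token axis of each frame (per head)
  sdot <- matrix(0, BT, nh)
  if (!is.null(dwk)) sdot <- sdot + ca$w_k * dwk
  if (!is.null(dwc)) sdot <- sdot + ca$w_c * dwc
  if (!is.null(dwp)) sdot <- sdot + rowsum(ca$w_p * dwp, rep_f, reorder = FALSE)
  if (!is.null(dwk)) {
    dsk <- ca$w_k * (dwk - sdot)
    dQ <- dQ + dsk[, hexp, drop = FALSE] * ca$KKk * isq
    dKKk <- dsk[, hexp, drop = FALSE] * ca$Q * isq
  }
  if (!is.null(dwc)) {
    dsc <- ca$w_c * (dwc - sdot)
    dQ <- dQ + dsc[, hexp, drop = FALSE] * ca$KKc * isq
    dKKc <- dsc[, hexp, drop = FALSE] * ca$Q * isq
  }
  if (!is.null(dwp)) {
    dsp <- ca$w_p * (dwp - sdot[rep_f, , drop = FALSE])
    dQ <- dQ + rowsum(dsp[, hexp, drop = FALSE] * ca$KKp, rep_f, reorder = FALSE) * isq
    dKKp <- dsp[, hexp, drop = FALSE] * ca$Qrep * isq
  }

  # projections of Q/K/V back to tokens
  grads$cam.Wq <- crossprod(ca$Crep, dQ)
  grads$cam.bq <- colSums(dQ)
  dCrep <- tcrossprod(dQ, params$cam.Wq)
  dK_tok <- dH_tok <- dC_tok <- NULL
  if (!is.null(dKKk)) {
    grads$cam.Wk <- grads$cam.Wk + crossprod(ca$K_tok, dKKk)
    grads$cam.Wv <- grads$cam.Wv + crossprod(ca$K_tok, dVVk)
    grads$cam.bk <- grads$cam.bk + colSums(dKKk)
    grads$cam.bv <- grads$cam.bv + colSums(dVVk)
    dK_tok <- tcrossprod(dKKk, params$cam.Wk) + tcrossprod(dVVk, params$cam.Wv)
  }
  if (!is.null(dKKc)) {
    grads$cam.Wk <- grads$cam.Wk + crossprod(ca$C_tok, dKKc)
    grads$cam.Wv <- grads$cam.Wv + crossprod(ca$C_tok, dVVc)
    grads$cam.bk <- grads$cam.bk + colSums(dKKc)
    grads$cam.bv <- grads$cam.bv + colSums(dVVc)
    dC_tok <- tcrossprod(dKKc, params$cam.Wk) + tcrossprod(dVVc, params$cam.Wv)
  }
  if (!is.null(dKKp)) {
    grads$cam.Wk <- grads$cam.Wk + crossprod(ca$H_tok, dKKp)
    grads$cam.Wv <- grads$cam.Wv + crossprod(ca$H_tok, dVVp)
    grads$cam.bk <- grads$cam.bk + colSums(dKKp)
    grads$cam.bv <- grads$cam.bv + colSums(dVVp)
    dH_tok <- tcrossprod(dKKp, params$cam.Wk) + tcrossprod(dVVp, params$cam.Wv)
  }

  # embeddings
  if (!is.null(dK_tok)) {
    grads$W_k <- crossprod(ca$Xk, dK_tok)
    grads$b_k <- colSums(dK_tok)
  }
  if (!is.null(dH_tok)) {
    # H_tok = Ph (A_w W_p) + conv_b colSums(W_p) + b_p
    dWeff <- crossprod(ca$Ph, dH_tok) # hs^2 x d
    db_eff <- colSums(dH_tok)
    grads$W_p <- crossprod(ca$A_w, dWeff) +
      params$conv_b * matrix(db_eff, nrow(params$W_p), d, byrow = TRUE)
    grads$b_p <- db_eff
    grads$conv_b <- sum(colSums(params$W_p) * db_eff)
    dA_w <- tcrossprod(dWeff, params$W_p)
    geo <- ca$geo
    p2 <- geo$patch * geo$patch
    gw <- matrix(0, geo$kernel, geo$kernel)
    for (a in seq_len(geo$kernel)) {
      for (b in seq_len(geo$kernel)) {
        gw[a, b] <- sum(dA_w[cbind(geo$hidx[[(b - 1L) * geo$kernel + a]], seq_len(p2))])
      }
    }
    grads$conv_w <- gw
  }
  # care embedding: query path and/or key-value token path
  dC <- matrix(0, B, d)
  if (modep$care_query) {
    dC <- dC + rowsum(dCrep, ca$t_rep, reorder = FALSE)
  } else {
    grads$q_tok <- colSums(dCrep)
  }
  if (!is.null(dC_tok)) dC <- dC + rowsum(dC_tok, ca$t_rep, reorder = FALSE)
  if (modep$care_query || !is.null(dC_tok)) {
    grads$W_c <- as.vector(crossprod(dC, ca$s_care))
    grads$b_c <- colSums(dC)
  }
  list(loss = loss, grads = grads, dC = dC)
}
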