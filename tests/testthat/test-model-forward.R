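# Batched forward pass: equivalence with a from-scratch composition, mode
# semantics, care sensitivity and gradient checks.

# from-scratch forward for one window in full (care-query) mode, composed of
# the loop oracles in helper-oracles.R plus explicit embedding arithmetic
oracle_forward_window <- function(sample, params, cfg) {
  T_w <- cfg$window
  kp <- sample$skeleton$keypoints[1:T_w, , , drop = FALSE] / cfg$frame_size
  nh <- cfg$n_heads
  dh <- cfg$d %/% nh
  Z <- matrix(0, T_w, cfg$d)
  for (t in 1:T_w) {
    fr <- kp[t, , ]
    hip <- (fr[12, ] + fr[13, ]) / 2
    fr <- sweep(fr, 2, hip)
    flat <- as.vector(t(fr))
    k_tok <- matrix(flat, 1) %*% params$W_k + matrix(params$b_k, 1)
    # convolution + patch tokens via the exported single-map embedding,
    # itself verified against an explicit loop in test-model-ops
    h_tok <- embed_heatmap(sample$heatmaps$maps[t, , ], params, cfg)
    s <- (sample$care$care_level - 3) / 2
    c_tok <- matrix(s * params$W_c + params$b_c, 1)
    kv <- rbind(k_tok, h_tok)
    q <- c_tok %*% params$cam.Wq + matrix(params$cam.bq, 1)
    kk <- kv %*% params$cam.Wk + matrix(params$cam.bk, nrow(kv), cfg$d, byrow = TRUE)
    vv <- kv %*% params$cam.Wv + matrix(params$cam.bv, nrow(kv), cfg$d, byrow = TRUE)
    heads <- c()
    for (h in 1:nh) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      heads <- cbind(heads, oracle_attention(
        q[, cols, drop = FALSE], kk[, cols, drop = FALSE], vv[, cols, drop = FALSE]
      )$values)
    }
    x <- heads %*% params$cam.Wo + matrix(params$cam.bo, 1)
    h1 <- pmax(x %*% params$cam.F1 + matrix(params$cam.f1b, 1), 0)
    Z[t, ] <- x + h1 %*% params$cam.F2 + matrix(params$cam.f2b, 1)
  }
  Z <- Z + oracle_positional_encoding(T_w, cfg$d, cfg$pe_constant)
  for (l in seq_len(cfg$n_temporal_layers)) {
    Z <- oracle_encoder_layer(Z, params, l, nh)
  }
  Z <- oracle_layer_norm(Z, params$ln_f_g, params$ln_f_b)
  pool <- matrix(colMeans(Z), 1)
  oracle_softmax_classifier(pool, params$W_cls, params$b_cls)
}

interaction_free_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(generator_spec(
        n_subjects = 5, frames = 6, seed = 5,
        care_level_distribution = c(0.2, 0.2, 0.2, 0.2, 0.2)
      ))
    }
    cache
  }
})

test_that("the batched forward pass matches the from-scratch composition", {
  d <- interaction_free_dataset()
  cfg <- cstt_config(
    d = 8, n_heads = 2, n_temporal_layers = 2, ffn_hidden = 10,
    window = 2, heatmap_patch = 16, dropout = 0
  )
  pr <- init_cstt_params(cfg, 21)
  win <- prepare_windows(d, cfg, "cstt", stride = 4)
  fw <- cstt_forward(win, 1:5, pr, cfg, "cstt")
  for (b in 1:5) {
    sid <- win$sample_id[b]
    s <- d$samples[[match(sid, d$manifest$sample_id)]]
    # windows of one sample appear consecutively: b's window number is its
    # occurrence index among the windows of that sample
    wno <- sum(win$sample_id[1:b] == sid)
    s_cut <- window_sample(s, cfg$window, 4L)[[wno]]
    expect_equal(fw$probs[b, ], as.vector(oracle_forward_window(s_cut, pr, cfg)),
      tolerance = 1e-6
    )
  }
})

test_that("probabilities sum to 1 and attention masses sum to 1 in every mode", {
  d <- interaction_free_dataset()
  cfg <- tiny_config()
  pr <- init_cstt_params(cfg, 22)
  for (mode in c("cstt", "tstt", "tstt+c", "s+c", "sp+c", "d+c", "sp+d+c")) {
    win <- prepare_windows(d, cfg, mode, stride = 3)
    fw <- cstt_forward(win, 1:6, pr, cfg, mode)
    expect_equal(rowSums(fw$probs), rep(1, 6))
    expect_equal(
      fw$attn$keypoint + fw$attn$care_token + fw$attn$heatmap,
      rep(1, 6),
      tolerance = 1e-12
    )
  }
})

test_that("embedding stage is linear: zero inputs give zero tokens", {
  cfg <- tiny_config()
  pr <- init_cstt_params(cfg, 23)
  pr$b_k[] <- 0
  pr$b_p[] <- 0
  pr$conv_b <- 0
  expect_equal(
    as.vector(embed_keypoints(matrix(0, 17, 2), pr)),
    numeric(cfg$d)
  )
  expect_equal(max(abs(embed_heatmap(matrix(0, 64, 64), pr, cfg))), 0)
  # scaling: f(a x) = a f(x)
  withr::with_seed(23, img <- matrix(runif(64 * 64) / 2, 64, 64))
  expect_equal(
    embed_heatmap(2 * img, pr, cfg),
    2 * embed_heatmap(img, pr, cfg),
    tolerance = 1e-12
  )
})

test_that("TSTT output is bitwise invariant to the care level; CSTT is not", {
  d <- interaction_free_dataset()
  cfg <- tiny_config()
  pr <- init_cstt_params(cfg, 24)
  win <- prepare_windows(d, cfg, "cstt", stride = 3)
  win1 <- win
  win1$care[] <- 1L
  win5 <- win
  win5$care[] <- 5L
  idx <- 1:6
  t1 <- cstt_forward(win1, idx, pr, cfg, "tstt")
  t5 <- cstt_forward(win5, idx, pr, cfg, "tstt")
  expect_identical(t1$probs, t5$probs)
  c1 <- cstt_forward(win1, idx, pr, cfg, "cstt")
  c5 <- cstt_forward(win5, idx, pr, cfg, "cstt")
  expect_gt(max(abs(c1$probs - c5$probs)), 0)
  # care level steers the attention weights themselves
  expect_gt(max(abs(c1$attn$keypoint - c5$attn$keypoint)), 0)
})

test_that("care-embedding gradient is nonzero for CSTT and exactly zero for TSTT", {
  d <- interaction_free_dataset()
  cfg <- tiny_config()
  pr <- init_cstt_params(cfg, 25)
  win <- prepare_windows(d, cfg, "cstt", stride = 3)
  idx <- 1:6
  fw_c <- cstt_forward(win, idx, pr, cfg, "cstt", keep_cache = TRUE)
  bw_c <- cstt_backward(fw_c$cache, win$y[idx], pr, cfg)
  expect_gt(max(abs(bw_c$grads$W_c)), 0)
  expect_gt(max(abs(bw_c$dC)), 0)
  fw_t <- cstt_forward(win, idx, pr, cfg, "tstt", keep_cache = TRUE)
  bw_t <- cstt_backward(fw_t$cache, win$y[idx], pr, cfg)
  expect_identical(max(abs(bw_t$grads$W_c)), 0)
  expect_identical(max(abs(bw_t$grads$b_c)), 0)
  expect_identical(max(abs(bw_t$dC)), 0)
  expect_gt(max(abs(bw_t$grads$q_tok)), 0)
})

test_that("analytic gradients match central finite differences in every mode", {
  d <- interaction_free_dataset()
  cfg <- tiny_config()
  for (mode in c("cstt", "tstt+c", "sp+d+c")) {
    win <- prepare_windows(d, cfg, mode, stride = 3)
    pr <- init_cstt_params(cfg, 26)
    idx <- 1:4
    y <- win$y[idx]
    fw <- cstt_forward(win, idx, pr, cfg, mode, keep_cache = TRUE)
    bw <- cstt_backward(fw$cache, y, pr, cfg)
    lossfn <- function(p) {
      f <- cstt_forward(win, idx, p, cfg, mode, keep_cache = TRUE)
      cstt_backward(f$cache, y, p, cfg)$loss
    }
    withr::with_seed(27, {
      for (nm in names(pr)) {
        j <- sample(length(pr[[nm]]), 1)
        eps <- 1e-5
        p1 <- pr
        p1[[nm]][j] <- p1[[nm]][j] + eps
        p2 <- pr
        p2[[nm]][j] <- p2[[nm]][j] - eps
        num <- (lossfn(p1) - lossfn(p2)) / (2 * eps)
        ana <- bw$grads[[nm]][j]
        expect_equal(ana, num, tolerance = 1e-3)
      }
    })
  }
})

test_that("partial-skeleton masks are deterministic per sample and zero 30% of joints", {
  d <- interaction_free_dataset()
  cfg <- tiny_config()
  w1 <- prepare_windows(d, cfg, "sp+d+c", stride = 3, mask_seed = 4)
  w2 <- prepare_windows(d, cfg, "sp+d+c", stride = 3, mask_seed = 4)
  expect_identical(w1$Xk, w2$Xk)
  full <- prepare_windows(d, cfg, "cstt", stride = 3, mask_seed = 4)
  # exactly round(0.3 * 17) = 5 joints zeroed per frame
  frame1_masked <- w1$Xk[1, ] == 0 & full$Xk[1, ] != 0
  expect_equal(sum(frame1_masked), 2 * 5)
})

test_that("checkpoints round-trip through the YAML archive", {
  cfg <- tiny_config()
  pr <- init_cstt_params(cfg, 28)
  model <- structure(
    list(
      params = pr, config = cfg, mode = "cstt",
      train_cfg = train_config(epochs = 1), stride = 3L,
      history = tibble::tibble(epoch = 1L, loss = 0.5)
    ),
    class = "cstt_model"
  )
  path <- withr::local_tempfile(fileext = ".yaml")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  for (nm in names(pr)) {
    expect_equal(back$params[[nm]], pr[[nm]], ignore_attr = TRUE, tolerance = 1e-15)
  }
  expect_equal(back$config$d, cfg$d)
  d <- interaction_free_dataset()
  win <- prepare_windows(d, cfg, "cstt", stride = 3)
  expect_equal(
    cstt_forward(win, 1:3, back$params, cfg, "cstt")$probs,
    cstt_forward(win, 1:3, pr, cfg, "cstt")$probs,
    tolerance = 1e-12
  )
})
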