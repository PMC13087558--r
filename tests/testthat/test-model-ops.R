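# Individual network operations against trivial cases and loop oracles.

test_that("keypoint embedding is the stated linear map", {
  cfg <- tiny_config()
  pr <- init_cstt_params(cfg, 1)
  kp0 <- matrix(0, 17, 2)
  pr0 <- pr
  pr0$b_k[] <- 0
  expect_equal(as.vector(embed_keypoints(kp0, pr0)), numeric(cfg$d))
  # all-ones weights: every output equals the sum of all 34 inputs
  withr::with_seed(1, kp <- matrix(rnorm(34), 17, 2))
  pr1 <- pr0
  pr1$W_k <- matrix(1, 34, cfg$d)
  expect_equal(
    as.vector(embed_keypoints(kp, pr1)),
    rep(sum(kp), cfg$d)
  )
  # random case: independent matrix multiply
  flat <- as.vector(t(kp))
  expect_equal(
    embed_keypoints(kp, pr),
    matrix(flat, 1) %*% pr$W_k + matrix(pr$b_k, 1),
    tolerance = 1e-12
  )
  expect_error(embed_keypoints(matrix(NA_real_, 17, 2), pr), "NA")
  # linearity with zero bias
  expect_equal(embed_keypoints(3 * kp, pr0), 3 * embed_keypoints(kp, pr0))
})

test_that("heatmap embedding equals an explicit sliding-window convolution", {
  cfg <- tiny_config()
  pr <- init_cstt_params(cfg, 2)
  withr::with_seed(2, img <- matrix(runif(64 * 64), 64, 64))
  tok <- embed_heatmap(img, pr, cfg)
  expect_equal(dim(tok), c((64 / cfg$heatmap_patch)^2, cfg$d))
  # explicit loop convolution with zero padding
  k <- cfg$conv_kernel
  r <- (k - 1) / 2
  cv <- matrix(0, 64, 64)
  for (i in 1:64) {
    for (j in 1:64) {
      acc <- pr$conv_b
      for (a in 1:k) {
        for (b in 1:k) {
          ii <- i + a - 1 - r
          jj <- j + b - 1 - r
          if (ii >= 1 && ii <= 64 && jj >= 1 && jj <= 64) {
            acc <- acc + pr$conv_w[a, b] * img[ii, jj]
          }
        }
      }
      cv[i, j] <- acc
    }
  }
  # patch (gy, gx), gy fastest; pixels column-major within patch
  p <- cfg$heatmap_patch
  g <- 64 / p
  for (pi in 1:(g * g)) {
    gy <- (pi - 1) %% g + 1
    gx <- (pi - 1) %/% g + 1
    vec <- as.vector(cv[((gy - 1) * p + 1):(gy * p), ((gx - 1) * p + 1):(gx * p)])
    expect_equal(tok[pi, ], as.vector(vec %*% pr$W_p) + pr$b_p, tolerance = 1e-10)
  }
  # zero map, zero bias -> zero tokens
  pr0 <- pr
  pr0$conv_b <- 0
  pr0$b_p[] <- 0
  expect_equal(max(abs(embed_heatmap(matrix(0, 64, 64), pr0, cfg))), 0)
  expect_error(embed_heatmap(matrix(0, 32, 32), pr, cfg), "64")
})

test_that("degenerate 1x1 kernel with full-size patch reduces to a flat projection", {
  cfg <- cstt_config(
    d = 4, n_heads = 2, conv_kernel = 1L, heatmap_patch = 64L,
    ffn_hidden = 4, window = 2
  )
  pr <- init_cstt_params(cfg, 3)
  pr$conv_w <- matrix(1, 1, 1)
  pr$conv_b <- 0
  withr::with_seed(3, img <- matrix(runif(64 * 64), 64, 64))
  tok <- embed_heatmap(img, pr, cfg)
  expect_equal(dim(tok), c(1L, 4L))
  expect_equal(tok, matrix(as.vector(img), 1) %*% pr$W_p + matrix(pr$b_p, 1))
})

test_that("care embedding rescales to [-1, 1] and is the stated scalar map", {
  cfg <- tiny_config()
  pr <- init_cstt_params(cfg, 4)
  pr0 <- pr
  pr0$b_c[] <- 0
  expect_equal(as.vector(embed_care_level(3, pr0)), numeric(cfg$d))
  pr1 <- pr0
  pr1$W_c <- c(1, numeric(cfg$d - 1))
  expect_equal(as.vector(embed_care_level(5, pr1)), c(1, numeric(cfg$d - 1)))
  for (cl in 1:5) {
    expect_equal(
      embed_care_level(cl, pr),
      matrix((cl - 3) / 2 * pr$W_c + pr$b_c, 1)
    )
  }
  expect_error(embed_care_level(6, pr), "1..5")
  # distinct care levels, nonzero weights -> distinct tokens
  toks <- vapply(1:5, function(cl) embed_care_level(cl, pr)[1, ], numeric(cfg$d))
  expect_equal(nrow(unique(t(toks))), 5L)
})

test_that("scaled dot-product attention: singleton, constants and oracle", {
  withr::with_seed(5, {
    q <- matrix(rnorm(4), 1)
    k1 <- matrix(rnorm(4), 1)
    v1 <- matrix(rnorm(4), 1)
    att <- scaled_dot_attention(q, k1, v1)
    expect_equal(att$values, v1)
    expect_equal(att$weights, matrix(1))
    # identical keys -> uniform weights
    K <- matrix(rep(rnorm(4), 5), 5, byrow = TRUE)
    V <- matrix(rnorm(20), 5)
    att2 <- scaled_dot_attention(q, K, V)
    expect_equal(as.vector(att2$weights), rep(1 / 5, 5))
    for (i in 1:50) {
      Q <- matrix(rnorm(12), 3, 4)
      K <- matrix(rnorm(20), 5, 4)
      V <- matrix(rnorm(20), 5, 4)
      got <- scaled_dot_attention(Q, K, V)
      exp_ <- oracle_attention(Q, K, V)
      expect_equal(got$values, exp_$values, tolerance = 1e-10)
      expect_equal(got$weights, exp_$weights, tolerance = 1e-10)
      expect_equal(rowSums(got$weights), rep(1, 3))
    }
  })
})

test_that("multihead care attention reduces to a single head with identity output projection", {
  cfg <- cstt_config(
    d = 6, n_heads = 1, ffn_hidden = 4, window = 2,
    heatmap_patch = 32
  )
  pr <- init_cstt_params(cfg, 6)
  pr$cam.Wo <- diag(6)
  pr$cam.bo[] <- 0
  withr::with_seed(6, tokens <- list(
    care = matrix(rnorm(6), 1),
    keypoint = matrix(rnorm(6), 1),
    heatmap = matrix(rnorm(18), 3)
  ))
  single <- care_aware_attention(tokens, pr)
  multi <- multihead_care_attention(tokens, pr, cfg)
  expect_equal(multi$values, single$values)
  expect_equal(as.vector(multi$weights), as.vector(single$weights))
})

test_that("multihead care attention matches an explicit two-slice computation", {
  cfg <- tiny_config()
  pr <- init_cstt_params(cfg, 7)
  withr::with_seed(7, {
    for (i in 1:50) {
      tokens <- list(
        care = matrix(rnorm(8), 1),
        keypoint = matrix(rnorm(8), 1),
        heatmap = matrix(rnorm(4 * 8), 4)
      )
      got <- multihead_care_attention(tokens, pr, cfg)
      kv <- rbind(tokens$keypoint, tokens$heatmap)
      q <- tokens$care %*% pr$cam.Wq + matrix(pr$cam.bq, 1)
      k <- kv %*% pr$cam.Wk + matrix(pr$cam.bk, 5, 8, byrow = TRUE)
      v <- kv %*% pr$cam.Wv + matrix(pr$cam.bv, 5, 8, byrow = TRUE)
      heads <- c()
      for (h in 1:2) {
        cols <- ((h - 1) * 4 + 1):(h * 4)
        o <- oracle_attention(
          q[, cols, drop = FALSE], k[, cols, drop = FALSE],
          v[, cols, drop = FALSE]
        )
        heads <- cbind(heads, o$values)
        expect_equal(got$weights[h, ], as.vector(o$weights), tolerance = 1e-10)
        expect_equal(sum(got$weights[h, ]), 1)
      }
      expect_equal(got$values, heads %*% pr$cam.Wo + matrix(pr$cam.bo, 1),
        tolerance = 1e-10
      )
    }
  })
})

test_that("with the keypoint token alone, attention returns its projected value with weight 1", {
  cfg <- tiny_config()
  pr <- init_cstt_params(cfg, 41)
  withr::with_seed(41, tokens <- list(
    care = matrix(rnorm(8), 1), keypoint = matrix(rnorm(8), 1)
  ))
  att <- multihead_care_attention(tokens, pr, cfg)
  expect_equal(unname(att$weights), matrix(1, 2, 1))
  v <- tokens$keypoint %*% pr$cam.Wv + matrix(pr$cam.bv, 1)
  expect_equal(att$values, v %*% pr$cam.Wo + matrix(pr$cam.bo, 1))
})

test_that("attention output is equivariant to permutations of the key/value tokens", {
  cfg <- tiny_config()
  pr <- init_cstt_params(cfg, 8)
  withr::with_seed(8, tokens <- list(
    care = matrix(rnorm(8), 1),
    keypoint = matrix(rnorm(8), 1),
    heatmap = matrix(rnorm(5 * 8), 5)
  ))
  perm <- c(4, 1, 5, 3, 2)
  tokens2 <- tokens
  tokens2$heatmap <- tokens$heatmap[perm, ]
  expect_equal(
    multihead_care_attention(tokens, pr, cfg)$values,
    multihead_care_attention(tokens2, pr, cfg)$values
  )
})

test_that("feedforward with zero weights is the identity and matches its oracle", {
  cfg <- tiny_config()
  pr <- init_cstt_params(cfg, 9)
  withr::with_seed(9, x <- matrix(rnorm(3 * 8), 3))
  pr0 <- pr
  pr0$cam.F1[] <- 0
  pr0$cam.f1b[] <- 0
  pr0$cam.F2[] <- 0
  pr0$cam.f2b[] <- 0
  expect_equal(feedforward(x, pr0), x)
  expect_equal(feedforward(matrix(0, 2, 8), pr0), matrix(0, 2, 8))
  manual <- x + pmax(
    x %*% pr$cam.F1 + matrix(pr$cam.f1b, 3, 10, byrow = TRUE), 0
  ) %*% pr$cam.F2 + matrix(pr$cam.f2b, 3, 8, byrow = TRUE)
  expect_equal(feedforward(x, pr), manual, tolerance = 1e-12)
})

test_that("positional encoding: position zero, range and elementwise oracle", {
  pe <- positional_encoding(5, 8)
  expect_equal(pe[1, ], rep(c(0, 1), 4))
  expect_true(all(pe >= -1 & pe <= 1))
  withr::with_seed(10, {
    for (i in 1:50) {
      T_len <- sample(1:12, 1)
      d <- sample(2:16, 1)
      expect_equal(
        positional_encoding(T_len, d),
        oracle_positional_encoding(T_len, d),
        tolerance = 1e-12
      )
    }
  })
})

test_that("temporal encoder: zero depth is the identity, one layer matches the oracle", {
  cfg0 <- cstt_config(
    d = 8, n_heads = 2, n_temporal_layers = 0, ffn_hidden = 10,
    window = 3, heatmap_patch = 32
  )
  pr0 <- init_cstt_params(cfg0, 11)
  withr::with_seed(11, Z <- matrix(rnorm(3 * 8), 3))
  expect_equal(temporal_encode(Z, pr0, cfg0), Z)
  cfg1 <- tiny_config()
  withr::with_seed(12, {
    for (i in 1:50) {
      pr1 <- init_cstt_params(cfg1, 100 + i)
      Z <- matrix(rnorm(2 * 8), 2)
      expect_equal(
        temporal_encode(Z, pr1, cfg1),
        oracle_encoder_layer(Z, pr1, 1, 2),
        tolerance = 1e-8
      )
    }
  })
})

test_that("mean pooling and the softmax classifier match their oracles", {
  expect_equal(mean_pool(matrix(c(1, 1, 1, 2, 2, 2), 2, byrow = TRUE)), matrix(c(1.5, 1.5, 1.5), 1))
  v <- matrix(rnorm(4), 1)
  expect_equal(mean_pool(rbind(v, -v)), matrix(0, 1, 4))
  expect_equal(mean_pool(rbind(v, v)), v)
  cfg <- tiny_config()
  pr <- init_cstt_params(cfg, 13)
  pr0 <- pr
  pr0$W_cls[] <- 0
  pr0$b_cls[] <- 0
  expect_equal(as.vector(classify(matrix(rnorm(8), 1), pr0)), rep(0.25, 4))
  pr_sat <- pr0
  pr_sat$b_cls <- c(1000, 0, 0, 0)
  expect_equal(as.vector(classify(matrix(0, 1, 8), pr_sat)), c(1, 0, 0, 0))
  withr::with_seed(13, {
    for (i in 1:50) {
      z <- matrix(rnorm(3 * 8), 3)
      expect_equal(
        classify(z, pr),
        oracle_softmax_classifier(z, pr$W_cls, pr$b_cls),
        tolerance = 1e-12
      )
      expect_equal(rowSums(classify(z, pr)), rep(1, 3))
    }
  })
})
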