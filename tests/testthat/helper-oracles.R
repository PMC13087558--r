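# Independent brute-force oracles, written as plain loops so they share no
# code path with the package implementation.

oracle_mpjad <- function(a, b) {
  t_c <- min(nrow(a), nrow(b))
  tot <- 0
  n <- 0L
  for (t in seq_len(t_c)) {
    for (k in 1:17) {
      if (is.finite(a[t, k]) && is.finite(b[t, k])) {
        tot <- tot + abs(a[[t, k]] - b[[t, k]])
        n <- n + 1L
      }
    }
  }
  as.numeric(tot / n)
}

oracle_cosine_dissimilarity <- function(a, b) {
  num <- 0
  na <- 0
  nb <- 0
  for (i in seq_along(a)) {
    num <- num + a[i] * b[i]
    na <- na + a[i]^2
    nb <- nb + b[i]^2
  }
  1 - num / (sqrt(na) * sqrt(nb))
}

# plain-loop HOG with the same stated configuration: central-difference
# gradients (one-sided at borders), unsigned orientations, linear votes
# between the two nearest of 9 bin centers, 8x8 cells, 2x2 blocks, L2-Hys
oracle_hog <- function(img, cell = 8L, block = 2L, nbins = 9L, clip = 0.2) {
  h <- nrow(img)
  w <- ncol(img)
  gx <- matrix(0, h, w)
  gy <- matrix(0, h, w)
  for (i in 1:h) {
    for (j in 1:w) {
      gx[i, j] <- if (j == 1) {
        img[i, 2] - img[i, 1]
      } else if (j == w) {
        img[i, w] - img[i, w - 1]
      } else {
        (img[i, j + 1] - img[i, j - 1]) / 2
      }
      gy[i, j] <- if (i == 1) {
        img[2, j] - img[1, j]
      } else if (i == h) {
        img[h, j] - img[h - 1, j]
      } else {
        (img[i + 1, j] - img[i - 1, j]) / 2
      }
    }
  }
  ncy <- h %/% cell
  ncx <- w %/% cell
  hist <- array(0, c(ncy, ncx, nbins))
  bw <- 180 / nbins
  for (i in 1:h) {
    for (j in 1:w) {
      mag <- sqrt(gx[i, j]^2 + gy[i, j]^2)
      ang <- (atan2(gy[i, j], gx[i, j]) * 180 / pi) %% 180
      pos <- ang / bw - 0.5
      lo <- floor(pos)
      fr <- pos - lo
      b1 <- (lo %% nbins) + 1
      b2 <- ((lo + 1) %% nbins) + 1
      cy <- (i - 1) %/% cell + 1
      cx <- (j - 1) %/% cell + 1
      hist[cy, cx, b1] <- hist[cy, cx, b1] + mag * (1 - fr)
      hist[cy, cx, b2] <- hist[cy, cx, b2] + mag * fr
    }
  }
  feat <- c()
  for (bx in 1:(ncx - block + 1)) {
    for (by in 1:(ncy - block + 1)) {
      v <- as.vector(hist[by:(by + block - 1), bx:(bx + block - 1), ])
      v <- v / sqrt(sum(v^2) + 1e-10)
      v <- pmin(v, clip)
      v <- v / sqrt(sum(v^2) + 1e-10)
      feat <- c(feat, v)
    }
  }
  feat
}

oracle_attention <- function(Q, K, V) {
  nq <- nrow(Q)
  nk <- nrow(K)
  d <- ncol(Q)
  out <- matrix(0, nq, ncol(V))
  W <- matrix(0, nq, nk)
  for (i in 1:nq) {
    s <- numeric(nk)
    for (j in 1:nk) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d)
    e <- exp(s - max(s))
    w <- e / sum(e)
    W[i, ] <- w
    for (j in 1:nk) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  list(values = out, weights = W)
}

oracle_positional_encoding <- function(T_len, d, rho = 10000) {
  pe <- matrix(0, T_len, d)
  for (t in 0:(T_len - 1)) {
    for (j in 0:(d - 1)) {
      i <- j %/% 2
      arg <- t / rho^(2 * i / d)
      pe[t + 1, j + 1] <- if (j %% 2 == 0) sin(arg) else cos(arg)
    }
  }
  pe
}

oracle_layer_norm <- function(x, g, b, eps = 1e-5) {
  out <- x
  for (i in seq_len(nrow(x))) {
    mu <- mean(x[i, ])
    v <- mean((x[i, ] - mu)^2)
    out[i, ] <- (x[i, ] - mu) / sqrt(v + eps) * g + b
  }
  out
}

# one pre-norm encoder layer, written step by step with loops over heads
oracle_encoder_layer <- function(Z, params, l, nh) {
  d <- ncol(Z)
  dh <- d %/% nh
  p <- function(nm) params[[paste0("t", l, ".", nm)]]
  u <- oracle_layer_norm(Z, p("ln1_g"), p("ln1_b"))
  q <- u %*% p("Wq") + matrix(p("bq"), nrow(u), d, byrow = TRUE)
  k <- u %*% p("Wk") + matrix(p("bk"), nrow(u), d, byrow = TRUE)
  v <- u %*% p("Wv") + matrix(p("bv"), nrow(u), d, byrow = TRUE)
  o <- matrix(0, nrow(Z), d)
  for (h in 1:nh) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    o[, cols] <- oracle_attention(
      q[, cols, drop = FALSE], k[, cols, drop = FALSE], v[, cols, drop = FALSE]
    )$values
  }
  Z <- Z + o %*% p("Wo") + matrix(p("bo"), nrow(Z), d, byrow = TRUE)
  v2 <- oracle_layer_norm(Z, p("ln2_g"), p("ln2_b"))
  h1 <- pmax(v2 %*% p("F1") + matrix(p("f1b"), nrow(Z), length(p("f1b")), byrow = TRUE), 0)
  Z + h1 %*% p("F2") + matrix(p("f2b"), nrow(Z), d, byrow = TRUE)
}

oracle_softmax_classifier <- function(z, W, b) {
  out <- matrix(0, nrow(z), ncol(W))
  for (i in seq_len(nrow(z))) {
    s <- as.vector(z[i, ] %*% W) + b
    e <- exp(s - max(s))
    out[i, ] <- e / sum(e)
  }
  out
}

# AUC by explicit pair counting: correctly ordered pairs + half ties
oracle_auc <- function(z, s) {
  pos <- s[z == 1]
  neg <- s[z == 0]
  tot <- 0
  for (p in pos) {
    for (n in neg) {
      tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
    }
  }
  tot / (length(pos) * length(neg))
}
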