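# Metrics, ROC/AUC, cumulative gains, confusion matrices, attention export.

prob_matrix <- function(pred, n_classes = 4L, conf = 0.9) {
  p <- matrix((1 - conf) / (n_classes - 1), length(pred), n_classes)
  p[cbind(seq_along(pred), pred + 1L)] <- conf
  p
}

test_that("classification metrics: perfect, hand-counted and degenerate predictors", {
  y <- c(0L, 1L, 2L, 3L, 0L, 1L, 2L, 3L)
  mx <- classification_metrics(y, prob_matrix(y))
  expect_equal(mx$macro$precision, 1)
  expect_equal(mx$macro$recall, 1)
  expect_equal(mx$macro$f1, 1)
  expect_equal(mx$macro$accuracy, 1)

  # y_true = (0,0,1,1), predictions (0,1,1,1): accuracy 3/4, class-1 precision 2/3
  mx2 <- classification_metrics(c(0L, 0L, 1L, 1L), c(0L, 1L, 1L, 1L), n_classes = 2L)
  expect_equal(mx2$macro$accuracy, 0.75)
  expect_equal(mx2$per_class$precision[2], 2 / 3)
  expect_equal(mx2$per_class$recall[1], 1 / 2)
  expect_equal(mx2$per_class$recall[2], 1)

  # all-one-class predictor on balanced 4-class data
  mx3 <- classification_metrics(y, rep(0L, 8))
  expect_equal(mx3$macro$accuracy, 0.25)
  # never-predicted classes have NA precision, excluded from the macro
  expect_true(all(is.na(mx3$per_class$precision[2:4])))
  expect_equal(mx3$macro$precision, 0.25)
})

test_that("a class absent from y_true gets NA recall and is excluded from macros", {
  y <- c(0L, 0L, 1L, 1L)
  mx <- classification_metrics(y, prob_matrix(c(0L, 0L, 1L, 1L)))
  expect_true(is.na(mx$per_class$recall[3]))
  expect_true(is.na(mx$per_class$recall[4]))
  expect_equal(mx$macro$recall, 1)
})

test_that("argmax breaks exact probability ties toward the lowest class index", {
  p <- matrix(0.25, 2, 4)
  mx <- classification_metrics(c(0L, 0L), p)
  expect_equal(mx$macro$accuracy, 1)
  # three-way tie at 0.3 resolves to class 0, so a true class 1 is missed
  p2 <- matrix(c(0.3, 0.3, 0.3, 0.1), 1, 4)
  expect_equal(classification_metrics(1L, p2)$per_class$recall[2], 0)
})

test_that("ROC/AUC: separable scores give 1, constant scores 0.5, oracle agreement", {
  y <- rep(0:3, each = 3)
  mx <- roc_auc_ovr(y, prob_matrix(y))
  expect_equal(mx$per_class$auc, rep(1, 4))
  expect_equal(mx$micro_auc, 1)
  const <- matrix(0.25, 12, 4)
  mx2 <- roc_auc_ovr(y, const)
  expect_equal(mx2$per_class$auc, rep(0.5, 4))
  # 12-point toy score set against explicit pair counting
  withr::with_seed(16, {
    z <- rep(c(0L, 1L), 6)
    s <- round(runif(12), 1) # coarse grid forces ties
    got <- roc_auc_ovr(z, cbind(1 - s, s))
    expect_equal(got$per_class$auc[2], oracle_auc(z, s))
  })
})

test_that("trapezoidal AUC equals the pair-counting oracle on 100 random score sets", {
  withr::with_seed(17, {
    for (i in 1:100) {
      n <- sample(6:20, 1)
      z <- sample(c(0L, 1L), n, replace = TRUE)
      if (length(unique(z)) < 2) z[1:2] <- c(0L, 1L)
      s <- sample(seq(0, 1, 0.05), n, replace = TRUE)
      probs <- cbind(1 - s, s)
      got <- roc_auc_ovr(z, probs)
      expect_equal(got$per_class$auc[2], oracle_auc(z, s), tolerance = 1e-10)
      expect_equal(got$per_class$auc[1], oracle_auc(1L - z, 1 - s), tolerance = 1e-10)
    }
  })
})

test_that("our AUC agrees with pROC as an independent implementation", {
  withr::with_seed(18, {
    for (i in 1:10) {
      z <- sample(c(0L, 1L), 30, replace = TRUE)
      if (length(unique(z)) < 2) z[1:2] <- c(0L, 1L)
      s <- runif(30)
      ours <- roc_auc_ovr(z, cbind(1 - s, s))$per_class$auc[2]
      ref <- as.numeric(pROC::auc(pROC::roc(z, s,
        quiet = TRUE,
        direction = "<"
      )))
      expect_equal(ours, ref, tolerance = 1e-10)
    }
  })
})

test_that("degenerate classes get NA AUC and are excluded from the macro", {
  y <- c(0L, 0L, 1L, 1L)
  mx <- roc_auc_ovr(y, prob_matrix(y))
  expect_true(all(is.na(mx$per_class$auc[3:4])))
  expect_equal(mx$macro_auc, 1)
})

test_that("cumulative gain: perfect ranking, manual count and the random baseline", {
  # perfect ranking at 10% prevalence reaches gain 1 at x = 0.1
  y <- c(rep(1L, 2), rep(0L, 18))
  p <- cbind(1 - seq(0.99, 0.05, length.out = 20), seq(0.99, 0.05, length.out = 20))
  g <- cumulative_gain(y, p, 1L)
  expect_equal(g$gain[g$fraction_inspected == 0.1], 1)
  expect_equal(g$gain[1], 0)
  expect_equal(tail(g$gain, 1), 1)

  # 8-sample toy case against a manual sort-and-count
  y8 <- c(1L, 0L, 1L, 0L, 0L, 1L, 0L, 0L)
  s8 <- c(0.9, 0.8, 0.3, 0.75, 0.1, 0.6, 0.5, 0.2)
  g8 <- cumulative_gain(y8, cbind(1 - s8, s8), 1L)
  ord <- order(s8, decreasing = TRUE)
  manual <- cumsum(y8[ord] == 1L) / 3
  expect_equal(g8$gain[-1], manual)

  # random scores stay near the diagonal on average
  withr::with_seed(19, {
    dev <- replicate(40, {
      yr <- sample(c(rep(1L, 30), rep(0L, 70)))
      sr <- runif(100)
      gr <- cumulative_gain(yr, cbind(1 - sr, sr), 1L)
      mean(gr$gain - gr$fraction_inspected)
    })
    expect_lt(abs(mean(dev)), 0.03)
  })
  expect_error(cumulative_gain(c(0L, 0L), matrix(0.5, 2, 2), 1L), "no positives")
})

test_that("confusion matrices are row-normalized with absent classes dropped", {
  y <- c(0L, 0L, 1L, 1L, 2L, 3L, 0L, 1L)
  p <- c(0L, 1L, 1L, 1L, 2L, 3L, 0L, 0L)
  gr <- c("low", "low", "low", "mid", "mid", "mid", "high", "high")
  cms <- confusion_by_group(y, p, gr)
  expect_equal(rowSums(cms$overall), setNames(rep(1, 4), activity_levels()))
  # high group saw only classes 0/1: its matrix has exactly those rows
  expect_equal(rownames(cms$high), c("sitting", "eating"))
  expect_equal(
    attr(cms$high, "absent_classes"),
    c("stand_up", "trying_to_stand_up")
  )
  expect_equal(unname(rowSums(cms$high)), rep(1, 2))
  # perfect predictions give identity matrices
  cid <- confusion_by_group(y, y, gr)
  expect_equal(unname(cid$overall), diag(4), ignore_attr = TRUE)
  # an empty group is omitted with a warning
  expect_warning(
    out <- confusion_by_group(y[1:6], p[1:6], gr[1:6]),
    "high"
  )
  expect_null(out$high)
})

test_that("metrics are invariant to a permutation of the sample order", {
  withr::with_seed(20, {
    y <- sample(0:3, 40, replace = TRUE)
    p <- matrix(runif(160), 40)
    p <- p / rowSums(p)
    perm <- sample(40)
    m1 <- classification_metrics(y, p)
    m2 <- classification_metrics(y[perm], p[perm, ])
    expect_equal(m1, m2)
    r1 <- roc_auc_ovr(y, p)
    r2 <- roc_auc_ovr(y[perm], p[perm, ])
    expect_equal(r1$per_class, r2$per_class)
    expect_equal(r1$micro_auc, r2$micro_auc)
  })
})

test_that("attention export needs a care query, averages per care level, rows sum to 1", {
  d <- generate_dataset(generator_spec(
    n_subjects = 4, frames = 6, seed = 30,
    care_level_distribution = c(0.2, 0.2, 0.2, 0.2, 0.2)
  ))
  cfg <- tiny_config()
  model <- structure(
    list(
      params = init_cstt_params(cfg, 31), config = cfg, mode = "cstt",
      train_cfg = train_config(), stride = 3L,
      history = tibble::tibble(epoch = integer(), loss = numeric())
    ),
    class = "cstt_model"
  )
  am <- export_attention_matrix(model, d)
  expect_equal(unname(rowSums(am)), rep(1, nrow(am)))
  expect_true(all(rownames(am) %in% paste0("CL", 1:5)))
  # the keypoint column varies across care levels (care steers attention)
  expect_gt(stats::var(am[, "keypoint"]), 0)
  model$mode <- "tstt"
  expect_error(export_attention_matrix(model, d), "care query")
})
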