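# Optimization loop, cross-day splitting and ablation orchestration.

#' Training configuration
#'
#' Defaults follow the deployment recipe: batch size 8, initial learning rate
#' 0.001, weight decay 0.0005, 25 epochs. The loss is plain (unweighted)
#' cross-entropy — no class-imbalance handling — optimized with an adaptive
#' moment estimator using decoupled weight decay on the projection matrices,
#' at a constant learning rate and with no early stopping.
#'
#' @param batch_size Windows per optimization step.
#' @param learning_rate Constant learning rate.
#' @param weight_decay Decoupled weight decay on weight matrices.
#' @param epochs Training epochs.
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @param split_fraction Target fraction of samples in the train split.
#' @return A `train_config` object.
#' @export
train_config <- function(batch_size = 8L, learning_rate = 0.001,
                         weight_decay = 0.0005, epochs = 25L, seed = 1L,
                         split_fraction = 0.8) {
  stopifnot(
    is_count(batch_size), learning_rate > 0, weight_decay >= 0,
    is_count(epochs), split_fraction > 0, split_fraction < 1
  )
  structure(
    list(
      batch_size = as.integer(batch_size), learning_rate = learning_rate,
      weight_decay = weight_decay, epochs = as.integer(epochs),
      seed = as.integer(seed), split_fraction = split_fraction
    ),
    class = "train_config"
  )
}

#' Cross-day train/test split
#'
#' Whole sessions (recording days) are assigned to one side, so no session
#' contributes to both: a greedy pass over sessions in decreasing size order
#' gives each session to the side with the larger remaining sample deficit
#' relative to the target fraction. Deterministic given the seed (which only
#' breaks ties between equal-size sessions).
#'
#' @param d A `har_dataset`, or a data frame with a `session_id` column
#'   (one row per sample).
#' @param cfg A [train_config()].
#' @return A `split_plan` with `train_sessions`, `test_sessions` and the
#'   achieved train fraction.
#' @export
make_split <- function(d, cfg = train_config()) {
  man <- if (inherits(d, "har_dataset")) d$manifest else as.data.frame(d)
  stopifnot("session_id" %in% names(man))
  sizes <- table(man$session_id)
  if (length(sizes) < 2L) {
    abort("cross-day split impossible: dataset has a single session")
  }
  ids <- names(sizes)
  n <- as.integer(sizes)
  withr::local_seed(derive_seed(cfg$seed, 5L))
  ord <- order(-n, sample(length(n)))
  total <- sum(n)
  target <- cfg$split_fraction
  train <- character()
  test <- character()
  tr_sum <- te_sum <- 0
  for (i in ord) {
    cap_train <- target * total - tr_sum
    cap_test <- (1 - target) * total - te_sum
    if (cap_train >= cap_test) {
      train <- c(train, ids[i])
      tr_sum <- tr_sum + n[i]
    } else {
      test <- c(test, ids[i])
      te_sum <- te_sum + n[i]
    }
  }
  if (length(test) == 0L) {
    mv <- train[which.min(sizes[train])]
    test <- mv
    train <- setdiff(train, mv)
  }
  if (length(train) == 0L) {
    mv <- test[which.min(sizes[test])]
    train <- mv
    test <- setdiff(test, mv)
  }
  structure(
    list(
      train_sessions = sort(train), test_sessions = sort(test),
      train_fraction = sum(sizes[train]) / total
    ),
    class = "split_plan"
  )
}

adam_decay_set <- function(params) {
  names(params)[vapply(
    params,
    function(a) !is.null(dim(a)) && length(dim(a)) == 2L, logical(1)
  )]
}

#' Train a CSTT/TSTT model
#'
#' Cross-entropy training with the adaptive-moment optimizer over windows of
#' the train sessions. Fully deterministic on one thread given the seeds in
#' `train_cfg`: the same configuration trained twice yields identical
#' weights.
#'
#' @param d A `har_dataset`.
#' @param model_cfg A [cstt_config()].
#' @param train_cfg A [train_config()].
#' @param mode Mode string (see [parse_mode()]).
#' @param split Optional [make_split()] plan; computed from `train_cfg` if
#'   missing.
#' @param stride Window stride in frames.
#' @param verbose Print per-epoch loss.
#' @return A `cstt_model`: trained `params`, `config`, `mode`, the split,
#'   and `history` (per-epoch mean training loss).
#' @export
cstt_train <- function(d, model_cfg = cstt_config(), train_cfg = train_config(),
                       mode = "cstt", split = NULL, stride = 8L,
                       verbose = FALSE) {
  stopifnot(inherits(d, "har_dataset"))
  modep <- parse_mode(mode)
  if (is.null(split)) split <- make_split(d, train_cfg)
  stopifnot(length(intersect(split$train_sessions, split$test_sessions)) == 0L)
  win <- prepare_windows(d, model_cfg, modep,
    stride = stride,
    mask_seed = train_cfg$seed
  )
  tr_idx <- which(win$session_id %in% split$train_sessions)
  if (length(tr_idx) == 0L) abort("empty train split")

  params <- init_cstt_params(model_cfg, seed = train_cfg$seed)
  m <- lapply(params, function(a) {
    a[] <- 0
    a
  })
  v <- m
  decay <- adam_decay_set(params)
  b1 <- 0.9
  b2 <- 0.999
  eps <- 1e-8
  lr <- train_cfg$learning_rate
  wd <- train_cfg$weight_decay
  step <- 0L
  history <- numeric(train_cfg$epochs)

  withr::local_seed(derive_seed(train_cfg$seed, 6L))
  for (ep in seq_len(train_cfg$epochs)) {
    sh <- sample(tr_idx)
    losses <- numeric(0)
    for (b0 in seq(1L, length(sh), by = train_cfg$batch_size)) {
      bidx <- sh[b0:min(b0 + train_cfg$batch_size - 1L, length(sh))]
      fw <- cstt_forward(win, bidx, params, model_cfg, modep,
        training = TRUE, keep_cache = TRUE
      )
      bw <- cstt_backward(fw$cache, win$y[bidx], params, model_cfg)
      losses <- c(losses, bw$loss)
      step <- step + 1L
      c1 <- 1 - b1^step
      c2 <- 1 - b2^step
      for (nm in names(params)) {
        g <- bw$grads[[nm]]
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g * g
        upd <- (m[[nm]] / c1) / (sqrt(v[[nm]] / c2) + eps)
        if (wd > 0 && nm %in% decay) upd <- upd + wd * params[[nm]]
        params[[nm]] <- params[[nm]] - lr * upd
      }
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d: loss %.4f", ep, history[ep]))
  }
  structure(
    list(
      params = params, config = model_cfg, mode = modep$name,
      train_cfg = train_cfg, split = split, stride = stride,
      history = tibble(epoch = seq_len(train_cfg$epochs), loss = history)
    ),
    class = "cstt_model"
  )
}

#' @export
print.cstt_model <- function(x, ...) {
  cat(sprintf(
    "<cstt_model mode=%s, d=%d, %d heads, %d temporal layers, %d params>\n",
    x$mode, x$config$d, x$config$n_heads, x$config$n_temporal_layers,
    n_params(x$params)
  ))
  if (nrow(x$history) > 0) {
    cat(sprintf(
      "  trained %d epochs, final loss %.4f\n",
      nrow(x$history), tail(x$history$loss, 1)
    ))
  }
  invisible(x)
}

#' Predict activity probabilities for a dataset
#'
#' @param object A `cstt_model`.
#' @param newdata A `har_dataset` or a `cstt_windows` object.
#' @param sessions Optional session ids to restrict to.
#' @param ... Unused.
#' @return A tibble with one row per window: identifiers, true label, the
#'   predicted class (argmax, lowest class index on ties) and per-class
#'   probabilities `.p_<activity>`.
#' @export
predict.cstt_model <- function(object, newdata, sessions = NULL, ...) {
  win <- if (inherits(newdata, "cstt_windows")) {
    newdata
  } else {
    prepare_windows(newdata, object$config, object$mode,
      stride = object$stride %||% 8L,
      mask_seed = object$train_cfg$seed %||% 1L
    )
  }
  idx <- seq_len(win$n)
  if (!is.null(sessions)) idx <- which(win$session_id %in% sessions)
  fw <- cstt_forward(win, idx, object$params, object$config, object$mode)
  probs <- fw$probs
  colnames(probs) <- paste0(".p_", activity_levels())
  dplyr::bind_cols(
    tibble(
      sample_id = win$sample_id[idx], session_id = win$session_id[idx],
      subject_id = win$subject_id[idx], care_level = win$care[idx],
      group = care_group(win$care[idx]),
      label = win$y[idx], pred = fw$pred
    ),
    as_tibble(probs)
  )
}

#' @export
tidy.cstt_model <- function(x, ...) x$history

#' @export
glance.cstt_model <- function(x, ...) {
  tibble(
    mode = x$mode, n_params = n_params(x$params),
    epochs = nrow(x$history),
    final_loss = if (nrow(x$history)) tail(x$history$loss, 1) else NA_real_,
    train_fraction = x$split$train_fraction
  )
}

#' Run the ablation harness
#'
#' Trains one model per mode on the shared cross-day split (same split and
#' seed for every mode) and evaluates macro precision/recall/F1 and accuracy
#' on the test sessions.
#'
#' @param d A `har_dataset`.
#' @param modes Character vector of mode strings (see [parse_mode()]).
#' @param model_cfg,train_cfg,stride As in [cstt_train()].
#' @return A tibble with one row per mode.
#' @export
run_ablation <- function(d, modes, model_cfg = cstt_config(),
                         train_cfg = train_config(), stride = 8L) {
  modes_canon <- vapply(modes, function(m) parse_mode(m)$name, character(1))
  split <- make_split(d, train_cfg)
  rows <- purrr::map(seq_along(modes), function(i) {
    model <- cstt_train(d, model_cfg, train_cfg,
      mode = modes[i],
      split = split, stride = stride
    )
    pr <- predict(model, d, sessions = split$test_sessions)
    mx <- classification_metrics(pr$label, as.matrix(dplyr::select(
      pr,
      dplyr::starts_with(".p_")
    )))
    dplyr::bind_cols(tibble(mode = modes_canon[i]), mx$macro)
  })
  dplyr::bind_rows(rows)
}
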