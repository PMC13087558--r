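# Classification metrics, one-vs-rest ROC/AUC, cumulative gains, per-care-
# group confusion matrices and attention-weight export.

#' Per-class and macro classification metrics
#'
#' Standard precision/recall/F1 per class from argmax predictions (lowest
#' class index wins exact probability ties), plus unweighted macro averages
#' and accuracy. A class absent from `y_true` has undefined recall and is
#' excluded from the macro averages; a class never predicted has undefined
#' precision, excluded likewise.
#'
#' @param y_true Integer class codes 0..K-1.
#' @param y_prob `n x K` probability matrix (rows sum to 1), or an integer
#'   vector of predicted codes.
#' @param n_classes Number of classes.
#' @return List with `per_class` (tibble: class, activity, precision, recall,
#'   f1, support) and `macro` (tibble: precision, recall, f1, accuracy).
#' @export
classification_metrics <- function(y_true, y_prob, n_classes = 4L) {
  y_true <- as.integer(y_true)
  y_pred <- if (is.matrix(y_prob)) {
    apply(y_prob, 1L, argmax_first) - 1L
  } else {
    as.integer(y_prob)
  }
  stopifnot(length(y_true) == length(y_pred))
  ks <- 0:(n_classes - 1L)
  per <- purrr::map_dfr(ks, function(k) {
    tp <- sum(y_true == k & y_pred == k)
    fp <- sum(y_true != k & y_pred == k)
    fn <- sum(y_true == k & y_pred != k)
    prec <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
    rec <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
    f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) {
      NA_real_
    } else {
      2 * prec * rec / (prec + rec)
    }
    tibble(
      class = k,
      activity = if (n_classes == 4L) label_name(k) else as.character(k),
      precision = prec, recall = rec, f1 = f1,
      support = sum(y_true == k)
    )
  })
  macro <- tibble(
    precision = mean(per$precision, na.rm = TRUE),
    recall = mean(per$recall, na.rm = TRUE),
    f1 = mean(per$f1, na.rm = TRUE),
    accuracy = mean(y_true == y_pred)
  )
  list(per_class = per, macro = macro)
}

# binary ROC with rank-averaged tie handling: one curve point per distinct
# score, AUC by trapezoidal integration (equals pair counting with half ties)
binary_roc <- function(z, s) {
  np <- sum(z == 1L)
  nn <- sum(z == 0L)
  if (np == 0L || nn == 0L) {
    return(list(auc = NA_real_, curve = NULL))
  }
  o <- order(s, decreasing = TRUE)
  z <- z[o]
  s <- s[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(z)
  fp <- cumsum(1 - z)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(
    auc = auc,
    curve = tibble(fpr = fpr, tpr = tpr, threshold = c(Inf, s[last]))
  )
}

#' One-vs-rest ROC curves and AUCs
#'
#' Per-class one-vs-rest AUC by trapezoidal integration (ties handled by
#' rank averaging), the micro average over all pooled one-vs-rest decisions,
#' and the macro average over the defined per-class AUCs. A class with no
#' positives or no negatives gets `NA`.
#'
#' @param y_true Integer class codes 0..K-1.
#' @param y_prob `n x K` probability (score) matrix.
#' @return List with `per_class` (tibble: class, auc), `micro_auc`,
#'   `macro_auc` and `curves` (tibble: class, fpr, tpr, threshold; class
#'   `"micro"` rows included).
#' @export
roc_auc_ovr <- function(y_true, y_prob) {
  y_true <- as.integer(y_true)
  y_prob <- as.matrix(y_prob)
  ks <- seq_len(ncol(y_prob)) - 1L
  curves <- list()
  aucs <- purrr::map_dbl(ks, function(k) {
    r <- binary_roc(as.integer(y_true == k), y_prob[, k + 1L])
    if (!is.null(r$curve)) {
      curves[[length(curves) + 1L]] <<- dplyr::mutate(r$curve,
        class = as.character(k), .before = 1L
      )
    }
    r$auc
  })
  micro <- binary_roc(
    as.integer(as.vector(vapply(ks, function(k) y_true == k, logical(length(y_true))))),
    as.vector(y_prob)
  )
  if (!is.null(micro$curve)) {
    curves[[length(curves) + 1L]] <- dplyr::mutate(micro$curve,
      class = "micro", .before = 1L
    )
  }
  list(
    per_class = tibble(class = ks, auc = aucs),
    micro_auc = micro$auc,
    macro_auc = mean(aucs, na.rm = TRUE),
    curves = dplyr::bind_rows(curves)
  )
}

#' Cumulative gain curve for one class
#'
#' Windows are ranked by descending predicted probability of class `class_k`
#' (ties keep input order); the curve is the fraction of that class's
#' positives captured within the top-ranked fraction of samples. The diagonal
#' is the random-ranking baseline.
#'
#' @param y_true Integer class codes.
#' @param y_prob Probability matrix.
#' @param class_k Class code (0-based).
#' @return Tibble with `fraction_inspected` and `gain`, starting at (0, 0).
#' @export
cumulative_gain <- function(y_true, y_prob, class_k) {
  y_true <- as.integer(y_true)
  s <- as.matrix(y_prob)[, class_k + 1L]
  np <- sum(y_true == class_k)
  if (np == 0L) abort("class has no positives; gain curve undefined")
  o <- order(s, decreasing = TRUE) # stable: ties keep input order
  hits <- cumsum(y_true[o] == class_k)
  n <- length(y_true)
  tibble(
    fraction_inspected = c(0, seq_len(n) / n),
    gain = c(0, hits / np)
  )
}

#' Row-normalized confusion matrices, overall and per care group
#'
#' Rows are true classes, columns predicted classes; each row with any
#' occurrences sums to 1. Classes structurally absent from a group (the
#' stand-up activities in the high group) are dropped from that group's rows
#' and reported in the `absent_classes` attribute. Empty groups are omitted
#' with a warning.
#'
#' @param y_true,y_pred Integer class codes.
#' @param groups Character vector of care groups aligned with the samples.
#' @param n_classes Number of classes.
#' @return Named list of matrices: `overall` plus one per group present.
#' @export
confusion_by_group <- function(y_true, y_pred, groups, n_classes = 4L) {
  stopifnot(length(y_true) == length(y_pred), length(groups) == length(y_true))
  ks <- 0:(n_classes - 1L)
  lab <- if (n_classes == 4L) activity_levels() else as.character(ks)
  one <- function(sel) {
    cm <- matrix(0, n_classes, n_classes, dimnames = list(lab, lab))
    tt <- table(
      factor(y_true[sel], levels = ks),
      factor(y_pred[sel], levels = ks)
    )
    cm[] <- as.numeric(tt)
    present <- rowSums(cm) > 0
    cmn <- cm[present, , drop = FALSE] / rowSums(cm)[present]
    attr(cmn, "absent_classes") <- lab[!present]
    cmn
  }
  out <- list(overall = one(rep(TRUE, length(y_true))))
  for (g in c("low", "mid", "high")) {
    sel <- groups == g
    if (!any(sel)) {
      warn(paste("no samples in care group", g, "- omitted"))
      next
    }
    out[[g]] <- one(sel)
  }
  out
}

#' Export the care-attention weight matrix
#'
#' For a care-query (CSTT-mode) model, runs the forward pass and averages,
#' per care level, the attention mass the care query puts on the keypoint
#' token versus the heatmap patches (heads and frames pooled). Rows sum to 1.
#'
#' @param model A `cstt_model` trained in a care-query mode.
#' @param newdata A `har_dataset` or `cstt_windows`.
#' @return Matrix with one row per care level present and columns
#'   `keypoint`, `heatmap`.
#' @export
export_attention_matrix <- function(model, newdata) {
  modep <- parse_mode(model$mode)
  if (!modep$care_query) {
    abort("attention export requires a care-query (CSTT) model: TSTT has no care query")
  }
  win <- if (inherits(newdata, "cstt_windows")) {
    newdata
  } else {
    prepare_windows(newdata, model$config, model$mode,
      stride = model$stride %||% 8L, mask_seed = model$train_cfg$seed %||% 1L
    )
  }
  fw <- cstt_forward(win, NULL, model$params, model$config, model$mode)
  agg <- fw$attn |>
    dplyr::group_by(.data$care_level) |>
    dplyr::summarise(
      keypoint = mean(.data$keypoint),
      heatmap = mean(.data$heatmap), .groups = "drop"
    )
  m <- as.matrix(agg[, c("keypoint", "heatmap")])
  rownames(m) <- paste0("CL", agg$care_level)
  m
}

#' Full evaluation report on the test sessions
#'
#' @param model A `cstt_model`.
#' @param d A `har_dataset`.
#' @param sessions Sessions to evaluate (defaults to the model's test split).
#' @return An `eval_report`: predictions, metrics, ROC, per-class gain
#'   curves, confusion matrices by care group and (for care-query models)
#'   the attention matrix.
#' @export
evaluate_model <- function(model, d, sessions = NULL) {
  sessions <- sessions %||% model$split$test_sessions
  pr <- predict(model, d, sessions = sessions)
  probs <- as.matrix(dplyr::select(pr, dplyr::starts_with(".p_")))
  mx <- classification_metrics(pr$label, probs)
  roc <- roc_auc_ovr(pr$label, probs)
  gains <- purrr::map(
    setNames(0:3, activity_levels()),
    function(k) {
      if (sum(pr$label == k) == 0L) {
        return(NULL)
      }
      cumulative_gain(pr$label, probs, k)
    }
  )
  conf <- confusion_by_group(pr$label, pr$pred, pr$group)
  attn <- if (parse_mode(model$mode)$care_query) {
    export_attention_matrix(model, d)
  } else {
    NULL
  }
  structure(
    list(
      predictions = pr, metrics = mx, roc = roc, gains = gains,
      confusion = conf, attention = attn
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(x$metrics$macro)
  cat(sprintf(
    "micro AUC %.3f, macro AUC %.3f\n",
    x$roc$micro_auc, x$roc$macro_auc
  ))
  invisible(x)
}

#' @export
glance.eval_report <- function(x, ...) {
  dplyr::bind_cols(
    x$metrics$macro,
    tibble(micro_auc = x$roc$micro_auc, macro_auc = x$roc$macro_auc)
  )
}
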