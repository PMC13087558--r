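# Model configuration, parameter initialization, ablation-mode parsing and
# plain-text checkpoint serialization.

#' CSTT architecture configuration
#'
#' Defaults give a compact CPU-trainable model: latent dimension 64 split over
#' 4 heads, 2 temporal encoder layers, feedforward width 128. The positional-
#' encoding constant is 10,000.
#'
#' @param d Latent dimension (divisible by `n_heads`).
#' @param n_heads Attention heads.
#' @param n_temporal_layers Temporal transformer-encoder depth.
#' @param ffn_hidden Feedforward hidden width.
#' @param n_classes Number of activity classes.
#' @param window Frames per model window.
#' @param heatmap_patch Patch side in pixels; `(64/heatmap_patch)^2` heatmap
#'   tokens per frame.
#' @param conv_kernel Spatial side of the heatmap convolution kernel (odd).
#' @param dropout Dropout rate on feedforward hidden units during training.
#' @param pe_constant Positional-encoding base constant.
#' @param frame_size Pixel extent used to normalize keypoint coordinates.
#' @param mask_rate Fraction of joints zeroed in partial-skeleton modes.
#' @return A `cstt_config` object.
#' @export
cstt_config <- function(d = 64L, n_heads = 4L, n_temporal_layers = 2L,
                        ffn_hidden = 128L, n_classes = 4L, window = 16L,
                        heatmap_patch = 8L, conv_kernel = 3L, dropout = 0.1,
                        pe_constant = 10000, frame_size = 640,
                        mask_rate = 0.3) {
  stopifnot(
    d %% n_heads == 0L, pe_constant > 0, n_classes >= 2L,
    64L %% heatmap_patch == 0L, conv_kernel %% 2L == 1L,
    dropout >= 0, dropout < 1, n_temporal_layers >= 0L
  )
  structure(
    list(
      d = as.integer(d), n_heads = as.integer(n_heads),
      n_temporal_layers = as.integer(n_temporal_layers),
      ffn_hidden = as.integer(ffn_hidden), n_classes = as.integer(n_classes),
      window = as.integer(window), heatmap_patch = as.integer(heatmap_patch),
      conv_kernel = as.integer(conv_kernel), dropout = dropout,
      pe_constant = pe_constant, frame_size = frame_size,
      mask_rate = mask_rate
    ),
    class = "cstt_config"
  )
}

xavier <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialize CSTT parameters
#'
#' Returns a flat named list of weight arrays: embedding projections
#' (`W_k` 34 x d, heatmap conv kernel and patch projection `W_p`, care
#' projection `W_c` 1 x d), the learned care-independent query used by the
#' care-blind TSTT variant, the care-aware attention block, the temporal
#' encoder layers (`t<l>.` prefix) and the softmax classifier.
#'
#' @param config A [cstt_config()].
#' @param seed Initialization seed.
#' @return Named list of numeric arrays (class `cstt_params`).
#' @export
init_cstt_params <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cstt_config"))
  withr::local_seed(derive_seed(seed, 11L))
  d <- config$d
  h <- config$ffn_hidden
  k <- config$conv_kernel
  p2 <- config$heatmap_patch^2
  pr <- list(
    W_k = xavier(34L, d), b_k = numeric(d),
    conv_w = matrix(rnorm(k * k, 0, 0.2), k, k), conv_b = 0,
    W_p = xavier(p2, d), b_p = numeric(d),
    W_c = xavier(1L, d)[1L, ], b_c = numeric(d),
    q_tok = rnorm(d, 0, 0.02),
    cam.Wq = xavier(d, d), cam.bq = numeric(d),
    cam.Wk = xavier(d, d), cam.bk = numeric(d),
    cam.Wv = xavier(d, d), cam.bv = numeric(d),
    cam.Wo = xavier(d, d), cam.bo = numeric(d),
    cam.F1 = xavier(d, h), cam.f1b = numeric(h),
    cam.F2 = xavier(h, d), cam.f2b = numeric(d)
  )
  for (l in seq_len(config$n_temporal_layers)) {
    lp <- list(
      ln1_g = rep(1, d), ln1_b = numeric(d),
      Wq = xavier(d, d), bq = numeric(d),
      Wk = xavier(d, d), bk = numeric(d),
      Wv = xavier(d, d), bv = numeric(d),
      Wo = xavier(d, d), bo = numeric(d),
      ln2_g = rep(1, d), ln2_b = numeric(d),
      F1 = xavier(d, h), f1b = numeric(h),
      F2 = xavier(h, d), f2b = numeric(d)
    )
    names(lp) <- paste0("t", l, ".", names(lp))
    pr <- c(pr, lp)
  }
  pr <- c(pr, list(
    ln_f_g = rep(1, d), ln_f_b = numeric(d),
    W_cls = xavier(d, config$n_classes), b_cls = numeric(config$n_classes)
  ))
  structure(pr, class = "cstt_params")
}

#' Number of learnable parameters
#' @param params A `cstt_params` list.
#' @return Integer count.
#' @export
n_params <- function(params) {
  sum(vapply(params, length, integer(1)))
}

#' Parse an ablation mode string
#'
#' Modes match the ablation rows: `"cstt"` (alias `"s+d+c"`) is the full
#' model with the care-level query; `"tstt"` (`"s+d"`) replaces the care
#' query with a learned care-independent token; `"tstt+c"` (`"s+d+c(tstt)"`)
#' keeps the learned query but appends the care embedding as an extra
#' key/value token; `"s+c"`, `"sp+c"`, `"d+c"`, `"sp+d+c"` restrict the
#' key/value token set (Sp = partial skeleton with randomly masked joints).
#'
#' @param mode Mode string (case-insensitive).
#' @return List of flags `care_query`, `use_skeleton`, `use_heatmap`,
#'   `partial_skeleton`, `care_token`, plus the canonical `name`.
#' @export
parse_mode <- function(mode) {
  key <- gsub("[ ()]", "", tolower(mode))
  modes <- list(
    "cstt" = list(TRUE, TRUE, TRUE, FALSE, FALSE),
    "s+d+c" = list(TRUE, TRUE, TRUE, FALSE, FALSE),
    "cstts+d+c" = list(TRUE, TRUE, TRUE, FALSE, FALSE),
    "tstt" = list(FALSE, TRUE, TRUE, FALSE, FALSE),
    "s+d" = list(FALSE, TRUE, TRUE, FALSE, FALSE),
    "tstts+d" = list(FALSE, TRUE, TRUE, FALSE, FALSE),
    "tstt+c" = list(FALSE, TRUE, TRUE, FALSE, TRUE),
    "tstts+d+c" = list(FALSE, TRUE, TRUE, FALSE, TRUE),
    "s+c" = list(TRUE, TRUE, FALSE, FALSE, FALSE),
    "cstts+c" = list(TRUE, TRUE, FALSE, FALSE, FALSE),
    "sp+c" = list(TRUE, TRUE, FALSE, TRUE, FALSE),
    "csttsp+c" = list(TRUE, TRUE, FALSE, TRUE, FALSE),
    "d+c" = list(TRUE, FALSE, TRUE, FALSE, FALSE),
    "csttd+c" = list(TRUE, FALSE, TRUE, FALSE, FALSE),
    "sp+d+c" = list(TRUE, TRUE, TRUE, TRUE, FALSE),
    "csttsp+d+c" = list(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  if (!key %in% names(modes)) abort(paste("unknown mode:", mode))
  f <- modes[[key]]
  list(
    name = key, care_query = f[[1L]], use_skeleton = f[[2L]],
    use_heatmap = f[[3L]], partial_skeleton = f[[4L]], care_token = f[[5L]]
  )
}

#' Save a model checkpoint
#'
#' Single-file YAML archive: schema string, configuration block, training
#' mode and named weight arrays (dims + values). Plain text, loadable with
#' [load_checkpoint()].
#'
#' @param model A `cstt_model` (from [cstt_train()]) or a list with elements
#'   `params`, `config`, `mode`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(!is.null(model$params), !is.null(model$config))
  ser <- lapply(model$params, function(a) {
    list(dim = as.integer(dim(a) %||% length(a)), data = as.numeric(a))
  })
  yaml::write_yaml(
    list(
      schema = "cstt-checkpoint-1",
      config = unclass(model$config),
      mode = model$mode %||% "cstt",
      params = ser
    ),
    path,
    precision = 17L
  )
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#' @param path Checkpoint file.
#' @return List with `params`, `config`, `mode` (class `cstt_model`).
#' @export
load_checkpoint <- function(path) {
  ck <- yaml::read_yaml(path)
  if (!identical(ck$schema, "cstt-checkpoint-1")) {
    abort("unrecognized checkpoint schema")
  }
  params <- lapply(ck$params, function(e) {
    a <- as.numeric(e$data)
    if (length(e$dim) > 1L) dim(a) <- e$dim
    a
  })
  class(params) <- "cstt_params"
  cfg <- do.call(cstt_config, ck$config)
  structure(
    list(params = params, config = cfg, mode = ck$mode),
    class = "cstt_model"
  )
}
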