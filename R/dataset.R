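# Dataset container and on-disk format.
#
# Layout of a dataset directory:
#   manifest.csv                      sample_id, subject_id, session_id,
#                                     care_level, label
#   keypoints/<sample_id>.csv         frame, joint, x, y, conf (0-based indices)
#   heatmaps/<sample_id>_<frame>.tif  16-bit grayscale 64x64, values mapped
#                                     linearly [0,1] <-> [0,65535]

#' Construct a dataset from a list of labeled samples
#'
#' @param samples List of [labeled_sample()] objects.
#' @return A `har_dataset`: the sample list plus a manifest tibble with one
#'   row per sample (sample, subject, session, care level, label).
#' @export
har_dataset <- function(samples) {
  stopifnot(is.list(samples))
  for (s in samples) stopifnot(inherits(s, "labeled_sample"))
  ids <- purrr::map_chr(samples, "sample_id")
  if (anyNA(ids)) {
    ids <- sprintf("sample%05d", seq_along(samples))
    samples <- purrr::map2(samples, ids, function(s, id) {
      s$sample_id <- id
      s
    })
  }
  if (anyDuplicated(ids)) abort("sample_ids must be unique")
  manifest <- tibble(
    sample_id = ids,
    subject_id = purrr::map_chr(samples, ~ .x$care$subject_id),
    session_id = purrr::map_chr(samples, "session_id"),
    care_level = purrr::map_int(samples, ~ .x$care$care_level),
    label = purrr::map_int(samples, "label")
  )
  structure(list(samples = samples, manifest = manifest), class = "har_dataset")
}

#' @export
print.har_dataset <- function(x, ...) {
  cat(sprintf(
    "<har_dataset: %d samples, %d subjects, %d sessions>\n",
    nrow(x$manifest), dplyr::n_distinct(x$manifest$subject_id),
    dplyr::n_distinct(x$manifest$session_id)
  ))
  if (nrow(x$manifest) > 0) {
    print(dplyr::count(x$manifest, .data$care_level, .data$label))
  }
  invisible(x)
}

#' @export
length.har_dataset <- function(x) length(x$samples)

#' Save a dataset to a directory
#'
#' Writes the manifest, one keypoint CSV per sample and one 16-bit grayscale
#' TIFF per heatmap frame. The byte layout is deterministic given identical
#' input.
#'
#' @param d A `har_dataset`.
#' @param root_path Target directory (created if absent).
#' @return Invisibly, a tibble listing every file written.
#' @export
save_dataset <- function(d, root_path) {
  stopifnot(inherits(d, "har_dataset"))
  dir.create(root_path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root_path)) abort(paste("cannot create", root_path))
  dir.create(file.path(root_path, "keypoints"), showWarnings = FALSE)
  dir.create(file.path(root_path, "heatmaps"), showWarnings = FALSE)
  readr::write_csv(d$manifest, file.path(root_path, "manifest.csv"),
    progress = FALSE
  )
  files <- file.path(root_path, "manifest.csv")
  for (s in d$samples) {
    t_f <- n_frames(s)
    kp <- s$skeleton$keypoints
    kp_tbl <- tibble(
      frame = rep(0:(t_f - 1L), each = 17L),
      joint = rep(0:16, times = t_f),
      x = as.vector(t(kp[, , 1L, drop = TRUE])),
      y = as.vector(t(kp[, , 2L, drop = TRUE])),
      conf = as.vector(t(s$skeleton$confidences))
    )
    kp_path <- file.path(root_path, "keypoints", paste0(s$sample_id, ".csv"))
    readr::write_csv(kp_tbl, kp_path, progress = FALSE)
    files <- c(files, kp_path)
    for (t in seq_len(t_f)) {
      hp <- file.path(
        root_path, "heatmaps",
        sprintf("%s_%05d.tif", s$sample_id, t - 1L)
      )
      tiff::writeTIFF(s$heatmaps$maps[t, , ], hp, bits.per.sample = 16L)
      files <- c(files, hp)
    }
  }
  invisible(tibble(path = files))
}

#' Load a dataset from a directory
#'
#' Validates all invariants on load: care levels in 1..5, equal skeleton and
#' heatmap frame counts, and the absence of stand-up labels in the
#' high-assistance group. Malformed samples are rejected with an itemized
#' error report naming each offending sample.
#'
#' @param root_path Directory written by [save_dataset()].
#' @return A `har_dataset`.
#' @export
load_dataset <- function(root_path) {
  man_path <- file.path(root_path, "manifest.csv")
  if (!file.exists(man_path)) abort(paste("missing manifest:", man_path))
  manifest <- readr::read_csv(
    man_path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      subject_id = readr::col_character(),
      session_id = readr::col_character(),
      care_level = readr::col_integer(),
      label = readr::col_integer()
    ),
    progress = FALSE
  )
  errors <- character()
  samples <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    sid <- row$sample_id
    if (!(row$care_level %in% 1:5)) {
      errors <- c(errors, sprintf(
        "sample %s: care_level %s outside 1..5", sid, row$care_level
      ))
      next
    }
    if (!(row$label %in% 0:3)) {
      errors <- c(errors, sprintf("sample %s: label %s outside 0..3", sid, row$label))
      next
    }
    kp_path <- file.path(root_path, "keypoints", paste0(sid, ".csv"))
    if (!file.exists(kp_path)) {
      errors <- c(errors, sprintf("sample %s: missing keypoint file", sid))
      next
    }
    kp_tbl <- readr::read_csv(
      kp_path,
      col_types = readr::cols(
        frame = readr::col_integer(), joint = readr::col_integer(),
        x = readr::col_double(), y = readr::col_double(),
        conf = readr::col_double()
      ),
      progress = FALSE
    )
    t_f <- max(kp_tbl$frame) + 1L
    if (nrow(kp_tbl) != t_f * 17L) {
      errors <- c(errors, sprintf("sample %s: keypoint table is ragged", sid))
      next
    }
    kp_tbl <- dplyr::arrange(kp_tbl, .data$frame, .data$joint)
    kp <- array(0, c(t_f, 17L, 2L))
    kp[, , 1L] <- matrix(kp_tbl$x, t_f, 17L, byrow = TRUE)
    kp[, , 2L] <- matrix(kp_tbl$y, t_f, 17L, byrow = TRUE)
    conf <- matrix(kp_tbl$conf, t_f, 17L, byrow = TRUE)
    hm_files <- file.path(
      root_path, "heatmaps",
      sprintf("%s_%05d.tif", sid, 0:(t_f - 1L))
    )
    present <- file.exists(hm_files)
    extra <- file.exists(file.path(
      root_path, "heatmaps", sprintf("%s_%05d.tif", sid, t_f)
    ))
    if (!all(present) || extra) {
      n_hm <- length(list.files(file.path(root_path, "heatmaps"),
        pattern = paste0("^", sid, "_\\d{5}\\.tif$")
      ))
      errors <- c(errors, sprintf(
        "sample %s: %d skeleton frames but %d heatmap frames", sid, t_f, n_hm
      ))
      next
    }
    maps <- array(0, c(t_f, 64L, 64L))
    for (t in seq_len(t_f)) maps[t, , ] <- tiff::readTIFF(hm_files[t])
    sample <- tryCatch(
      labeled_sample(
        skeleton_sequence(kp, conf), heatmap_sequence(maps),
        care_record(row$subject_id, row$care_level),
        row$label, row$session_id, sid
      ),
      error = function(e) conditionMessage(e)
    )
    if (is.character(sample)) {
      errors <- c(errors, sprintf("sample %s: %s", sid, sample))
      next
    }
    samples <- c(samples, list(sample))
  }
  if (length(errors) > 0) {
    abort(c("dataset contains invalid samples:", setNames(errors, rep("x", length(errors)))))
  }
  har_dataset(samples)
}

#' Cut a sample into fixed-length windows
#'
#' Returns `floor((T_f - window_len) / stride) + 1` windows (or none when the
#' sequence is shorter than the window), each inheriting the label, care
#' record and session of its parent sample.
#'
#' @param s A [labeled_sample()].
#' @param window_len Window length in frames (>= 1).
#' @param stride Hop between window starts in frames (>= 1).
#' @return List of `labeled_sample` windows.
#' @export
window_sample <- function(s, window_len = 16L, stride = 8L) {
  stopifnot(inherits(s, "labeled_sample"), is_count(window_len), is_count(stride))
  t_f <- n_frames(s)
  if (t_f < window_len) {
    return(list())
  }
  starts <- seq(1L, t_f - window_len + 1L, by = stride)
  purrr::map(seq_along(starts), function(w) {
    idx <- starts[w]:(starts[w] + window_len - 1L)
    labeled_sample(
      skeleton_sequence(
        s$skeleton$keypoints[idx, , , drop = FALSE],
        s$skeleton$confidences[idx, , drop = FALSE]
      ),
      heatmap_sequence(s$heatmaps$maps[idx, , , drop = FALSE]),
      s$care, s$label, s$session_id,
      sample_id = sprintf("%s_w%02d", s$sample_id, w)
    )
  })
}

#' Window every sample of a dataset
#'
#' @param d A `har_dataset`.
#' @inheritParams window_sample
#' @return A `har_dataset` of windows; window ids extend the parent sample id.
#' @export
window_dataset <- function(d, window_len = 16L, stride = 8L) {
  stopifnot(inherits(d, "har_dataset"))
  wins <- purrr::flatten(purrr::map(d$samples, window_sample,
    window_len = window_len, stride = stride
  ))
  har_dataset(wins)
}
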