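# Domain types: skeleton sequences, heatmap sequences, care records and
# labeled samples. All sequences are frame-major numeric arrays; joints follow
# the COCO-17 convention throughout.

#' Activity classes
#'
#' Class indexing is fixed: 0 = sitting, 1 = eating, 2 = stand up,
#' 3 = trying to stand up.
#'
#' @return Character vector of the four activity names, in class-index order.
#' @export
activity_levels <- function() {
  c("sitting", "eating", "stand_up", "trying_to_stand_up")
}

#' COCO-17 joint names, in storage order
#' @return Character vector of length 17.
#' @export
coco_joints <- function() {
  c(
    "nose", "left_eye", "right_eye", "left_ear", "right_ear",
    "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
    "left_wrist", "right_wrist", "left_hip", "right_hip",
    "left_knee", "right_knee", "left_ankle", "right_ankle"
  )
}

#' COCO-17 bone list
#'
#' Edges between topologically adjacent joints, as 1-based (from, to) index
#' pairs. Used for joint-angle computation and for limb rendering in the
#' synthetic generator.
#'
#' @return Two-column integer matrix, one bone per row.
#' @export
coco_bones <- function() {
  m <- rbind(
    c(1L, 2L), c(1L, 3L), c(2L, 4L), c(3L, 5L), # head
    c(6L, 7L), # shoulders
    c(6L, 8L), c(8L, 10L), c(7L, 9L), c(9L, 11L), # arms
    c(6L, 12L), c(7L, 13L), c(12L, 13L), # trunk
    c(12L, 14L), c(14L, 16L), c(13L, 15L), c(15L, 17L) # legs
  )
  colnames(m) <- c("from", "to")
  m
}

label_code <- function(activity) {
  match(activity, activity_levels()) - 1L
}

label_name <- function(code) {
  activity_levels()[code + 1L]
}

#' Map a care level to its assistance group
#'
#' Care levels 1-2 form the low-assistance group, level 3 the mid group and
#' levels 4-5 the high group.
#'
#' @param care_level Integer vector with values in 1..5.
#' @return Character vector in `{"low","mid","high"}`.
#' @export
care_group <- function(care_level) {
  stopifnot(all(care_level %in% 1:5))
  c("low", "low", "mid", "high", "high")[care_level]
}

#' Construct a skeleton sequence
#'
#' @param keypoints `T x 17 x 2` numeric array of pixel coordinates
#'   (x right, y down, origin top-left).
#' @param confidences `T x 17` numeric matrix in `[0,1]`; defaults to 1.
#' @return A `skeleton_sequence` object.
#' @export
skeleton_sequence <- function(keypoints, confidences = NULL) {
  keypoints <- as_kp_array(keypoints)
  t_f <- dim(keypoints)[1L]
  if (t_f < 1L) abort("a skeleton sequence needs at least one frame")
  if (!all(is.finite(keypoints))) abort("keypoint coordinates must be finite")
  if (is.null(confidences)) {
    confidences <- matrix(1, t_f, 17L)
  }
  confidences <- as.matrix(confidences)
  stopifnot(identical(dim(confidences), c(t_f, 17L)))
  if (any(confidences < 0 | confidences > 1, na.rm = FALSE)) {
    abort("confidences must lie in [0, 1]")
  }
  structure(
    list(keypoints = keypoints, confidences = confidences),
    class = "skeleton_sequence"
  )
}

as_kp_array <- function(keypoints) {
  if (is.matrix(keypoints) && identical(dim(keypoints), c(17L, 2L))) {
    keypoints <- array(keypoints, c(1L, 17L, 2L))
  }
  if (!(is.array(keypoints) && length(dim(keypoints)) == 3L &&
    dim(keypoints)[2L] == 17L && dim(keypoints)[3L] == 2L)) {
    abort("keypoints must be a T x 17 x 2 array")
  }
  storage.mode(keypoints) <- "double"
  keypoints
}

#' Construct a heatmap sequence
#'
#' @param maps `T x 64 x 64` numeric array with values in `[0,1]`.
#' @return A `heatmap_sequence` object.
#' @export
heatmap_sequence <- function(maps) {
  if (is.matrix(maps)) maps <- array(maps, c(1L, dim(maps)))
  if (!(is.array(maps) && length(dim(maps)) == 3L &&
    dim(maps)[2L] == 64L && dim(maps)[3L] == 64L)) {
    abort("heatmaps must be a T x 64 x 64 array")
  }
  if (any(maps < 0 | maps > 1)) abort("heatmap values must lie in [0, 1]")
  storage.mode(maps) <- "double"
  structure(list(maps = maps), class = "heatmap_sequence")
}

#' Construct a care record
#'
#' @param subject_id Opaque subject identifier string.
#' @param care_level Integer in 1..5 (1 = minimal assistance, 5 = maximum).
#' @return A `care_record` object; the assistance group is derived.
#' @export
care_record <- function(subject_id, care_level) {
  if (!is_count(care_level) || !(care_level %in% 1:5)) {
    abort("care_level must be an integer in 1..5")
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      care_level = as.integer(care_level),
      group = care_group(as.integer(care_level))
    ),
    class = "care_record"
  )
}

#' Construct a labeled sample
#'
#' A labeled sample pairs a skeleton sequence with a depth-heatmap sequence of
#' the same frame count, the subject's care record, the activity label and a
#' session identifier used for cross-day train/test splitting. High-group
#' subjects never carry the stand-up or trying-to-stand labels.
#'
#' @param skeleton A [skeleton_sequence()].
#' @param heatmaps A [heatmap_sequence()].
#' @param care A [care_record()].
#' @param label Activity label: integer code 0..3 or one of
#'   [activity_levels()].
#' @param session_id Opaque session (day/site) identifier.
#' @param sample_id Optional sample identifier.
#' @return A `labeled_sample` object.
#' @export
labeled_sample <- function(skeleton, heatmaps, care, label, session_id,
                           sample_id = NULL) {
  stopifnot(
    inherits(skeleton, "skeleton_sequence"),
    inherits(heatmaps, "heatmap_sequence"),
    inherits(care, "care_record")
  )
  if (is.character(label)) label <- label_code(label)
  label <- as.integer(label)
  if (is.na(label) || !(label %in% 0:3)) abort("label must be in 0..3")
  if (dim(skeleton$keypoints)[1L] != dim(heatmaps$maps)[1L]) {
    abort("skeleton and heatmap frame counts differ")
  }
  if (care$group == "high" && label %in% c(2L, 3L)) {
    abort(paste0(
      "high-assistance subjects cannot carry label '",
      label_name(label), "': stand-up activities are absent in this group"
    ))
  }
  structure(
    list(
      skeleton = skeleton, heatmaps = heatmaps, care = care,
      label = label, session_id = as.character(session_id),
      sample_id = if (is.null(sample_id)) NA_character_ else as.character(sample_id)
    ),
    class = "labeled_sample"
  )
}

n_frames <- function(s) {
  if (inherits(s, "labeled_sample")) {
    return(dim(s$skeleton$keypoints)[1L])
  }
  if (inherits(s, "skeleton_sequence")) {
    return(dim(s$keypoints)[1L])
  }
  if (inherits(s, "heatmap_sequence")) {
    return(dim(s$maps)[1L])
  }
  abort("unsupported type")
}

#' @export
print.labeled_sample <- function(x, ...) {
  cat(sprintf(
    "<labeled_sample %s: %s, subject %s (CL %d, %s), session %s, %d frames>\n",
    x$sample_id, label_name(x$label), x$care$subject_id, x$care$care_level,
    x$care$group, x$session_id, n_frames(x)
  ))
  invisible(x)
}
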