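# Motion-sequence similarity statistics used for dataset validation:
# mean per-joint angle difference (MPJAD), cosine dissimilarity of flattened
# motion vectors, and HOG similarity of heatmaps, plus the pairwise
# care-group / activity tables built from them.

# Joints at which an angle is defined: (parent, joint, child) triples under
# the COCO-17 topology. Endpoint joints (nose, eyes, ears, wrists, ankles)
# have fewer than two incident limb bones and are masked NaN.
angle_triples <- function() {
  m <- rbind(
    c(12L, 6L, 8L), # left shoulder:  hip - shoulder - elbow
    c(13L, 7L, 9L), # right shoulder
    c(6L, 8L, 10L), # left elbow: shoulder - elbow - wrist
    c(7L, 9L, 11L), # right elbow
    c(6L, 12L, 14L), # left hip: shoulder - hip - knee
    c(7L, 13L, 15L), # right hip
    c(12L, 14L, 16L), # left knee: hip - knee - ankle
    c(13L, 15L, 17L) # right knee
  )
  colnames(m) <- c("parent", "joint", "child")
  m
}

#' Joint-angle sequence of a skeleton
#'
#' At every joint with both an inbound and an outbound bone (shoulders,
#' elbows, hips, knees) the angle is `arccos` of the normalized dot product
#' of the two bone vectors pointing away from the joint, in `[0, pi]`; a
#' fully extended limb therefore reads pi. Endpoint joints, and joints with a
#' zero-length bone, are `NaN` and are masked out of all averages.
#'
#' @param s A [skeleton_sequence()].
#' @return `T x 17` matrix of angles in radians (class
#'   `joint_angle_sequence`).
#' @export
joint_angles <- function(s) {
  stopifnot(inherits(s, "skeleton_sequence"))
  kp <- s$keypoints
  t_f <- dim(kp)[1L]
  ang <- matrix(NaN, t_f, 17L, dimnames = list(NULL, coco_joints()))
  tri <- angle_triples()
  for (r in seq_len(nrow(tri))) {
    p <- tri[r, 1L]
    j <- tri[r, 2L]
    ch <- tri[r, 3L]
    ux <- kp[, p, 1L] - kp[, j, 1L]
    uy <- kp[, p, 2L] - kp[, j, 2L]
    vx <- kp[, ch, 1L] - kp[, j, 1L]
    vy <- kp[, ch, 2L] - kp[, j, 2L]
    nu <- sqrt(ux^2 + uy^2)
    nv <- sqrt(vx^2 + vy^2)
    cosang <- (ux * vx + uy * vy) / (nu * nv) # 0-length bone -> NaN
    ang[, j] <- acos(clamp(cosang, -1, 1))
  }
  structure(ang, class = c("joint_angle_sequence", "matrix", "array"))
}

#' Mean per-joint angle difference between two sequences
#'
#' Average absolute joint-angle difference over the frames the two sequences
#' have in common and over all joints at which both angles are defined
#' (the denominator renormalizes to the unmasked entries). Lower values mean
#' more similar motions.
#'
#' @param a,b `T x 17` joint-angle matrices (see [joint_angles()]), or
#'   [skeleton_sequence()] objects.
#' @return Nonnegative scalar.
#' @export
mpjad_pair <- function(a, b) {
  a <- as_angles(a)
  b <- as_angles(b)
  t_common <- min(nrow(a), nrow(b))
  if (t_common < 1L) abort("sequences share no common frames")
  d <- abs(a[seq_len(t_common), , drop = FALSE] - b[seq_len(t_common), , drop = FALSE])
  ok <- is.finite(d)
  if (!any(ok)) abort("no jointly defined angles between the sequences")
  mean(d[ok])
}

as_angles <- function(x) {
  if (inherits(x, "skeleton_sequence")) {
    return(unclass(joint_angles(x)))
  }
  x <- as.matrix(x)
  stopifnot(ncol(x) == 17L)
  x
}

#' Mean per-joint angle difference over a set of sequences
#'
#' Mean of [mpjad_pair()] over all M unordered pairs of the input set.
#'
#' @param sequences List of two or more joint-angle matrices or skeleton
#'   sequences.
#' @return Nonnegative scalar.
#' @export
mpjad_set <- function(sequences) {
  n <- length(sequences)
  if (n < 2L) abort("mpjad_set needs at least two sequences")
  seqs <- lapply(sequences, as_angles)
  pairs <- utils::combn(n, 2L)
  mean(apply(pairs, 2L, function(ij) mpjad_pair(seqs[[ij[1L]]], seqs[[ij[2L]]])))
}

#' Cosine dissimilarity of two motion vectors
#'
#' `1 - (a . b) / (|a| |b|)`, in `[0, 2]`; 0 means the flattened motion
#' vectors are positively aligned (homogeneous motions).
#'
#' @param a,b Nonzero numeric vectors of equal length.
#' @return Scalar in `[0, 2]`.
#' @export
cosine_dissimilarity <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) abort("cosine dissimilarity is undefined for zero vectors")
  1 - sum(a * b) / (na * nb)
}

flatten_motion <- function(s, t_common = NULL) {
  kp <- if (inherits(s, "skeleton_sequence")) s$keypoints else s
  if (!is.null(t_common)) kp <- kp[seq_len(t_common), , , drop = FALSE]
  as.vector(kp)
}

#' Mean pairwise cosine dissimilarity within a class
#'
#' Sequences are truncated to the common minimum length, flattened to
#' vectors, and the cosine dissimilarity is averaged over all unordered
#' pairs. Lower values indicate higher within-class homogeneity.
#'
#' @param class_sequences List of two or more skeleton sequences (or
#'   `T x 17 x 2` arrays).
#' @return Scalar in `[0, 2]`.
#' @export
mean_pairwise_cosine_dissimilarity <- function(class_sequences) {
  n <- length(class_sequences)
  if (n < 2L) abort("need at least two class members")
  t_common <- min(vapply(
    class_sequences,
    function(s) if (inherits(s, "skeleton_sequence")) n_frames(s) else dim(s)[1L],
    integer(1)
  ))
  vecs <- lapply(class_sequences, flatten_motion, t_common = t_common)
  pairs <- utils::combn(n, 2L)
  mean(apply(pairs, 2L, function(ij) cosine_dissimilarity(vecs[[ij[1L]]], vecs[[ij[2L]]])))
}

#' Pairwise similarity tables across care groups or activities
#'
#' Reproduces the two dataset-validation views: `by_care_group` compares, for
#' each activity, the pools of the three care-group pairs (L-H, H-M, M-L);
#' `by_activity_within_groups` compares all 12 ordered activity pairs between
#' the mid-group pool (first activity) and the low-group pool (second
#' activity). Every cell carries three layers: the MPJAD of the pooled
#' cross-pairs, the mean cross-pair cosine dissimilarity of flattened
#' keypoint sequences, and the mean cross-pair HOG similarity of per-sample
#' temporal-mean heatmaps. Cells whose pools are empty (the high group lacks
#' the stand-up activities) are `NA`.
#'
#' @param d A `har_dataset`.
#' @param mode `"by_care_group"` or `"by_activity_within_groups"`.
#' @param max_per_pool Cap on samples per pool (pairs grow quadratically).
#' @param normalize If `TRUE`, min-max rescale each statistic layer over the
#'   non-`NA` cells of the table (off by default; raw statistic values are
#'   reported otherwise).
#' @return A tibble (class `similarity_table`) with one row per cell and
#'   columns `mpjad`, `cosine_dissimilarity`, `hog_similarity`.
#' @export
build_similarity_tables <- function(d,
                                    mode = c("by_care_group", "by_activity_within_groups"),
                                    max_per_pool = 25L,
                                    normalize = FALSE) {
  stopifnot(inherits(d, "har_dataset"))
  mode <- match.arg(mode)
  groups <- purrr::map_chr(d$samples, ~ .x$care$group)
  labels <- purrr::map_int(d$samples, "label")

  pool <- function(grp, act) {
    idx <- which(groups == grp & labels == label_code(act))
    head(idx, max_per_pool)
  }
  cell <- function(idx_a, idx_b) {
    if (length(idx_a) == 0L || length(idx_b) == 0L) {
      warn("empty pool for a requested cell; reporting NA")
      return(tibble(
        mpjad = NA_real_, cosine_dissimilarity = NA_real_,
        hog_similarity = NA_real_
      ))
    }
    ang_a <- lapply(d$samples[idx_a], function(s) unclass(joint_angles(s$skeleton)))
    ang_b <- lapply(d$samples[idx_b], function(s) unclass(joint_angles(s$skeleton)))
    t_common <- min(c(
      vapply(d$samples[idx_a], n_frames, integer(1)),
      vapply(d$samples[idx_b], n_frames, integer(1))
    ))
    vec_a <- lapply(d$samples[idx_a], function(s) flatten_motion(s$skeleton, t_common))
    vec_b <- lapply(d$samples[idx_b], function(s) flatten_motion(s$skeleton, t_common))
    hog_a <- lapply(d$samples[idx_a], function(s) hog_features(apply(s$heatmaps$maps, c(2, 3), mean)))
    hog_b <- lapply(d$samples[idx_b], function(s) hog_features(apply(s$heatmaps$maps, c(2, 3), mean)))
    mp <- cd <- hs <- 0
    n_pairs <- 0L
    for (i in seq_along(idx_a)) {
      for (j in seq_along(idx_b)) {
        mp <- mp + mpjad_pair(ang_a[[i]], ang_b[[j]])
        cd <- cd + cosine_dissimilarity(vec_a[[i]], vec_b[[j]])
        hs <- hs + hog_similarity(hog_a[[i]], hog_b[[j]])
        n_pairs <- n_pairs + 1L
      }
    }
    tibble(
      mpjad = mp / n_pairs, cosine_dissimilarity = cd / n_pairs,
      hog_similarity = hs / n_pairs
    )
  }

  acts <- c("eating", "sitting", "trying_to_stand_up", "stand_up")
  if (mode == "by_care_group") {
    pairs <- tibble(
      group_a = c("low", "high", "mid"),
      group_b = c("high", "mid", "low"),
      group_pair = c("L-H", "H-M", "M-L")
    )
    out <- tidyr::expand_grid(activity = acts, pairs)
    vals <- purrr::map(
      seq_len(nrow(out)),
      function(i) {
        cell(
          pool(out$group_a[i], out$activity[i]),
          pool(out$group_b[i], out$activity[i])
        )
      }
    )
    out <- dplyr::bind_cols(
      dplyr::select(out, "activity", "group_pair"),
      dplyr::bind_rows(vals)
    )
  } else {
    out <- tidyr::expand_grid(activity_mid = acts, activity_low = acts)
    out <- dplyr::filter(out, .data$activity_mid != .data$activity_low)
    vals <- purrr::map2(
      out$activity_mid, out$activity_low,
      function(a, b) cell(pool("mid", a), pool("low", b))
    )
    out <- dplyr::bind_cols(out, dplyr::bind_rows(vals))
  }
  if (normalize) {
    rescale <- function(x) {
      rng <- range(x, na.rm = TRUE)
      if (diff(rng) == 0) {
        return(x * 0)
      }
      (x - rng[1]) / diff(rng)
    }
    out <- dplyr::mutate(out, dplyr::across(
      c("mpjad", "cosine_dissimilarity", "hog_similarity"), rescale
    ))
  }
  class(out) <- c("similarity_table", class(out))
  out
}
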