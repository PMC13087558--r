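# Histogram-of-oriented-gradients descriptor and HOG similarity.
#
# Configuration is the canonical one: 8x8-pixel cells, 2x2-cell blocks with
# one-cell stride, 9 unsigned orientation bins over [0, 180) degrees with
# linear interpolation between the two nearest bin centers, and L2-Hys block
# normalization (L2-normalize, clip at 0.2, renormalize).

#' HOG descriptor of an image
#'
#' Gradients are central differences in the interior and one-sided at the
#' borders; orientations are unsigned (mod 180 degrees). A constant image has
#' no gradients and yields the all-zero descriptor, flagged with attribute
#' `zero_gradient`.
#'
#' @param img Numeric matrix (row = y, column = x); side lengths must be
#'   multiples of `cell_size`.
#' @param cell_size Cell side in pixels.
#' @param block_cells Block side in cells.
#' @param n_bins Number of unsigned orientation bins.
#' @param clip L2-Hys clipping threshold.
#' @return Numeric feature vector (7 x 7 x 2 x 2 x 9 = 1764 entries for a
#'   64 x 64 input at defaults).
#' @export
hog_features <- function(img, cell_size = 8L, block_cells = 2L, n_bins = 9L,
                         clip = 0.2) {
  img <- as.matrix(img)
  stopifnot(all(is.finite(img)))
  h <- nrow(img)
  w <- ncol(img)
  stopifnot(h %% cell_size == 0L, w %% cell_size == 0L)

  # gradients: gx along columns (x), gy along rows (y); one-sided at borders
  gx <- img
  gx[, 2:(w - 1)] <- (img[, 3:w] - img[, 1:(w - 2)]) / 2
  gx[, 1] <- img[, 2] - img[, 1]
  gx[, w] <- img[, w] - img[, w - 1]
  gy <- img
  gy[2:(h - 1), ] <- (img[3:h, ] - img[1:(h - 2), ]) / 2
  gy[1, ] <- img[2, ] - img[1, ]
  gy[h, ] <- img[h, ] - img[h - 1, ]

  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) * 180 / pi # (-180, 180]
  ang <- ang %% 180 # unsigned orientation [0, 180)

  # linear vote interpolation between the two nearest bin centers
  bin_width <- 180 / n_bins
  pos <- ang / bin_width - 0.5 # bin-center coordinates
  lo <- floor(pos)
  frac <- pos - lo
  bin_lo <- (as.vector(lo) %% n_bins) + 1L
  bin_hi <- (as.vector(lo + 1) %% n_bins) + 1L

  cy <- (row(img) - 1L) %/% cell_size + 1L
  cx <- (col(img) - 1L) %/% cell_size + 1L
  n_cy <- h %/% cell_size
  n_cx <- w %/% cell_size
  cell_of <- as.vector(cy + (cx - 1L) * n_cy)
  n_cells <- n_cy * n_cx

  hist <- matrix(0, n_cells, n_bins)
  idx_lo <- cbind(cell_of, bin_lo)
  idx_hi <- cbind(cell_of, bin_hi)
  v_lo <- as.vector(mag) * (1 - as.vector(frac))
  v_hi <- as.vector(mag) * as.vector(frac)
  # accumulate votes (duplicate indices summed via rowsum on flat index)
  flat <- c((idx_lo[, 2L] - 1L) * n_cells + idx_lo[, 1L],
            (idx_hi[, 2L] - 1L) * n_cells + idx_hi[, 1L])
  vals <- c(v_lo, v_hi)
  acc <- rowsum(vals, flat)
  hist[as.integer(rownames(acc))] <- acc

  cell_hist <- array(hist, c(n_cy, n_cx, n_bins))
  n_by <- n_cy - block_cells + 1L
  n_bx <- n_cx - block_cells + 1L
  feat <- numeric(0)
  out <- vector("list", n_by * n_bx)
  k <- 0L
  for (bx in seq_len(n_bx)) {
    for (by in seq_len(n_by)) {
      v <- as.vector(cell_hist[by:(by + block_cells - 1L), bx:(bx + block_cells - 1L), ])
      nrm <- sqrt(sum(v^2) + 1e-10)
      v <- pmin(v / nrm, clip)
      nrm2 <- sqrt(sum(v^2) + 1e-10)
      k <- k + 1L
      out[[k]] <- v / nrm2
    }
  }
  feat <- unlist(out, use.names = FALSE)
  if (all(mag == 0)) {
    feat <- feat * 0
    attr(feat, "zero_gradient") <- TRUE
  }
  feat
}

#' HOG similarity of two images
#'
#' Cosine similarity of the two HOG descriptors: 1 means near-identical edge
#' and gradient structure, 0 means none shared. Undefined (an error) when a
#' descriptor is the zero vector, as for a constant image.
#'
#' @param img1,img2 Images (matrices), or precomputed HOG feature vectors.
#' @param ... Passed on to [hog_features()] when images are given.
#' @return Scalar similarity; in `[0, 1]` on the nonnegative descriptors HOG
#'   produces.
#' @export
hog_similarity <- function(img1, img2, ...) {
  h1 <- if (is.matrix(img1)) hog_features(img1, ...) else as.numeric(img1)
  h2 <- if (is.matrix(img2)) hog_features(img2, ...) else as.numeric(img2)
  n1 <- sqrt(sum(h1^2))
  n2 <- sqrt(sum(h2^2))
  if (n1 == 0 || n2 == 0) {
    abort("HOG similarity is undefined for a constant image (zero descriptor)")
  }
  sum(h1 * h2) / (n1 * n2)
}
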