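#' Alternate sequential filter
#'
#' Morphological denoiser composing closings and openings with disks of
#' increasing radius 1, 2, ..., `order`. With `closing_first = TRUE`
#' (default) each stage applies the closing before the opening, which is
#' gentler on the dark, thin cell borders at small radii. `order = 0` is
#' the identity.
#'
#' @param img Gray image (numeric matrix).
#' @param order Filter order (integer >= 0).
#' @param closing_first Apply the closing before the opening at each radius?
#' @return Filtered gray image.
#' @export
alternate_sequential_filter <- function(img, order, closing_first = TRUE) {
  stopifnot(is.matrix(img))
  if (length(order) != 1L || is.na(order) || order < 0)
    stop("order must be a single integer >= 0")
  order <- as.integer(order)
  out <- img
  for (i in seq_len(order)) {
    k <- se_disk(i)
    if (closing_first) {
      out <- mm_open(mm_close(out, k), k)
    } else {
      out <- mm_close(mm_open(out, k), k)
    }
  }
  out
}

#' h-maxima markers
#'
#' Regional maxima of the grayscale reconstruction by dilation of
#' `img - h` under `img`: the maxima of `img` whose prominence exceeds
#' `h` gray levels. With `h = 0` these are the plain regional maxima.
#'
#' @param img Gray image.
#' @param h Prominence threshold in gray levels (>= 0).
#' @return Logical marker image.
#' @export
h_maxima_markers <- function(img, h) {
  stopifnot(is.matrix(img))
  if (length(h) != 1L || is.na(h) || h < 0) stop("h must be a single value >= 0")
  rec <- if (h > 0) cpp_reconstruct_dilate(img - h, img) else img
  m <- cpp_regional_maxima(rec) == 1L
  dim(m) <- dim(img)
  m
}

#' Morphological top-hat
#'
#' Residue of a closing (dark top-hat, extracts dark thin structures such
#' as cell borders) or of an opening (bright top-hat) with a disk.
#'
#' @param img Gray image.
#' @param size Disk radius in pixels (>= 1).
#' @param dark If `TRUE` (default) return `closing(img) - img`, else
#'   `img - opening(img)`.
#' @return Nonnegative gray image of the extracted structures.
#' @export
top_hat <- function(img, size, dark = TRUE) {
  stopifnot(is.matrix(img), size >= 1)
  k <- se_disk(size)
  if (dark) mm_close(img, k) - img else img - mm_open(img, k)
}

#' Euclidean distance map
#'
#' Exact Euclidean distance from every pixel to the nearest nonzero pixel
#' of a binary image (0 on the set itself).
#'
#' @param binary Binary image (logical or 0/1 matrix).
#' @param empty_error Error if the input has no foreground pixel?
#' @return Numeric matrix of distances.
#' @export
distance_map <- function(binary, empty_error = TRUE) {
  b <- as_binary(binary)
  if (!any(b)) {
    if (empty_error) stop("distance_map: input set is empty")
    return(matrix(Inf, nrow(b), ncol(b)))
  }
  unclass(EBImage::distmap(1 - (b * 1), metric = "euclidean"))
}

#' Marker-controlled watershed with watershed lines
#'
#' Meyer flooding of a relief from markers. Every pixel is assigned to
#' the region of one connected marker, so the labels partition the image
#' domain; the returned line set contains the 1-pixel-wide interfaces
#' separating distinct labels.
#'
#' @param relief Gray image to flood (catchment basins are its minima).
#' @param markers Logical marker image or integer label matrix
#'   (0 = unmarked).
#' @return A list with `labels` (integer matrix, one label per connected
#'   marker) and `lines` (logical matrix of separating pixels).
#' @export
watershed_lines <- function(relief, markers) {
  stopifnot(is.matrix(relief))
  check_same_dim(relief, markers)
  if (is.logical(markers) || all(markers %in% c(0, 1))) {
    m <- matrix(as.integer(as_binary(markers)), nrow(relief))
    lab0 <- cpp_label(m, 8L)
  } else {
    lab0 <- matrix(as.integer(markers), nrow(relief))
  }
  if (!any(lab0 > 0)) stop("watershed_lines: no markers")
  labels <- cpp_watershed(relief, lab0)
  list(labels = labels, lines = boundary_map(labels))
}

#' Interfaces separating distinct labels
#'
#' One-sided crack assignment: a pixel belongs to the boundary set when
#' its north or west 4-neighbour carries a different label. This yields
#' 1-pixel-wide closed interface curves and is the shared convention for
#' ground-truth and watershed contours.
#'
#' @param labels Integer label matrix.
#' @return Logical contour map.
#' @export
boundary_map <- function(labels) {
  nr <- nrow(labels)
  nc <- ncol(labels)
  b <- matrix(FALSE, nr, nc)
  if (nr > 1) b[-1, ] <- labels[-1, , drop = FALSE] != labels[-nr, , drop = FALSE]
  if (nc > 1) b[, -1] <- b[, -1] | (labels[, -1, drop = FALSE] != labels[, -nc, drop = FALSE])
  b
}

#' Supremum of openings by segments
#'
#' Pointwise supremum, over a set of equally spaced orientations, of
#' gray-level openings by a digital line segment. Retains bright
#' structures that contain a straight segment of the given length at
#' some orientation -- the linear cell contours.
#'
#' @param img Gray image.
#' @param length Segment length in pixels (>= 1).
#' @param orientations Number of orientations spanning [0, 180) (>= 2).
#' @return Gray image, pointwise <= `img`.
#' @export
sup_open_segments <- function(img, length, orientations = 8L) {
  stopifnot(is.matrix(img), length >= 1, orientations >= 2)
  angles <- seq(0, 180, length.out = orientations + 1L)[seq_len(orientations)]
  out <- matrix(-Inf, nrow(img), ncol(img))
  for (a in angles) {
    out <- pmax(out, mm_open(img, se_segment(length, a)))
  }
  out
}

#' Skeletonise and prune nonlinear parts
#'
#' Thins a binary image to a 1-pixel skeleton (Zhang-Suen), then keeps
#' only skeleton pixels covered by a foreground line segment of length
#' `t_s` lying entirely inside the skeleton (binary supremum of openings
#' by segments). Blobs and short spurs vanish; straight border runs
#' survive.
#'
#' @param binary Binary image.
#' @param t_s Segment length in pixels (>= 1).
#' @param orientations Number of segment orientations.
#' @return Logical contour map of the pruned skeleton.
#' @export
prune_nonlinear_skeleton <- function(binary, t_s, orientations = 8L) {
  b <- as_binary(binary)
  sk <- cpp_thin(matrix(as.integer(b), nrow(b)))
  # zero-pad so a retained pixel needs a full-length segment inside the
  # skeleton (set containment, not window-restricted filtering)
  pad <- as.integer(ceiling(t_s))
  skp <- matrix(0, nrow(b) + 2 * pad, ncol(b) + 2 * pad)
  skp[pad + seq_len(nrow(b)), pad + seq_len(ncol(b))] <- sk
  keepp <- sup_open_segments(skp, t_s, orientations) >= 0.5
  keep <- keepp[pad + seq_len(nrow(b)), pad + seq_len(ncol(b))]
  out <- (sk == 1L) & keep
  dim(out) <- dim(b)
  out
}

#' Regional maxima
#'
#' 8-connected plateaus with no strictly higher neighbour.
#'
#' @param img Gray image.
#' @return Logical matrix marking the maxima plateaus.
#' @export
regional_maxima <- function(img) {
  m <- cpp_regional_maxima(img) == 1L
  dim(m) <- dim(img)
  m
}

#' Connected-component labelling
#'
#' @param binary Binary image.
#' @param connectivity 4 or 8.
#' @return Integer label matrix (0 = background).
#' @export
label_components <- function(binary, connectivity = 8L) {
  b <- as_binary(binary)
  cpp_label(matrix(as.integer(b), nrow(b)), as.integer(connectivity))
}
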