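#' Disk structuring element
#'
#' Pixel set \{(dx, dy) : dx^2 + dy^2 <= r^2\}, the discretised Euclidean
#' ball used by all disk-based filters. `radius = 0` is the single-pixel
#' identity element.
#'
#' @param radius Disk radius in pixels (>= 0).
#' @return A 0/1 matrix of odd dimensions with the origin at its centre.
#' @export
#' @examples
#' se_disk(1)  # the 5-pixel cross
se_disk <- function(radius) {
  stopifnot(is.numeric(radius), length(radius) == 1L, radius >= 0)
  r <- floor(radius)
  xs <- -r:r
  k <- 1 * (outer(xs^2, xs^2, "+") <= radius^2 + 1e-9)
  storage.mode(k) <- "double"
  k
}

#' Line-segment structuring element
#'
#' A Bresenham-style digital segment of the given length centred on the
#' origin, at an orientation measured in degrees from the horizontal
#' (column) axis.
#'
#' @param length Segment length in pixels (>= 1).
#' @param orientation Orientation in degrees, in [0, 180).
#' @return A 0/1 matrix of odd dimensions with the origin at its centre.
#' @export
se_segment <- function(length, orientation) {
  stopifnot(length >= 1, orientation >= 0, orientation < 180)
  theta <- orientation * pi / 180
  dc <- cos(theta)
  dr <- -sin(theta)   # rows grow downwards
  t <- seq_len(length) - (length + 1) / 2
  rr <- round(t * dr)
  cc <- round(t * dc)
  mr <- max(abs(rr))
  mc <- max(abs(cc))
  k <- matrix(0, 2 * mr + 1, 2 * mc + 1)
  k[cbind(rr + mr + 1, cc + mc + 1)] <- 1
  k
}

# Flat grayscale erosion/dilation via EBImage. EBImage's grayscale
# morphology operates on [0,1]; rescale by the data range so arbitrary
# nonnegative images (e.g. distance maps) pass through exactly (flat
# morphology commutes with positive affine maps). Window-restricted
# border handling (EBImage's behaviour) coincides with mirror padding
# for flat structuring elements.
.mm_scale <- function(img) max(abs(img), 1)

mm_erode <- function(img, kern) {
  if (sum(kern) <= 1) return(img)
  s <- .mm_scale(img)
  unclass(EBImage::erode(img / s, kern)) * s
}

mm_dilate <- function(img, kern) {
  if (sum(kern) <= 1) return(img)
  s <- .mm_scale(img)
  unclass(EBImage::dilate(img / s, kern)) * s
}

mm_open <- function(img, kern) mm_dilate(mm_erode(img, kern), kern)
mm_close <- function(img, kern) mm_erode(mm_dilate(img, kern), kern)

# Gaussian smoothing with replicated-edge padding.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  brush <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  s <- .mm_scale(img)
  unclass(EBImage::filter2(img / s, brush, boundary = "replicate")) * s
}

# binary helpers -------------------------------------------------------

as_binary <- function(x) {
  if (is.logical(x)) return(x)
  m <- x != 0
  dim(m) <- dim(x)
  m
}

check_same_dim <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("image dimensions differ: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
  invisible(TRUE)
}
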