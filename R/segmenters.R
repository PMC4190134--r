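#' Control parameters of the three segmentation pipelines
#'
#' Constructors for the per-method control-parameter sets:
#' \describe{
#'   \item{`params_vm(o, h)`}{filter-and-h-maxima pipeline: `o` = order of
#'     the alternate sequential filter, `h` = h-maxima prominence (gray
#'     levels).}
#'   \item{`params_am(s1, g, s2, t, h)`}{distance-map pipeline: `s1` =
#'     opening radius, `g` = Gaussian smoothing sigma, `s2` = dark
#'     top-hat radius (0 bypasses the top-hat), `t` = border threshold
#'     (gray levels), `h` = h-maxima prominence on the distance map
#'     (0 uses the raw distance-map maxima).}
#'   \item{`params_gp(c, t_s, o, s)`}{linear-contour pipeline: `c` =
#'     closing radius on the rough border mask, `t_s` = segment length
#'     for the openings by segments and skeleton pruning, `o` = order of
#'     the alternate sequential filter, `s` = opening radius filtering
#'     the distance-map markers. Defaults are the tuned optimum
#'     `{2, 7, 4, 6}`.}
#' }
#'
#' @param o,h,s1,g,s2,t,c,t_s,s See description.
#' @return A named list of class `endo_params` with a `method` attribute.
#' @name parameter_sets
NULL

new_params <- function(method, values) {
  structure(values, method = method, class = "endo_params")
}

#' @rdname parameter_sets
#' @export
params_vm <- function(o = 2, h = 12) {
  stopifnot(o >= 0, h >= 0)
  new_params("vm", list(o = o, h = h))
}

#' @rdname parameter_sets
#' @export
params_am <- function(s1 = 4, g = 4, s2 = 1, t = 28, h = 1) {
  stopifnot(s1 >= 0, g >= 0, s2 >= 0, t >= 0, h >= 0)
  new_params("am", list(s1 = s1, g = g, s2 = s2, t = t, h = h))
}

#' @rdname parameter_sets
#' @export
params_gp <- function(c = 2, t_s = 7, o = 4, s = 6) {
  stopifnot(c >= 0, t_s >= 1, o >= 0, s >= 0)
  new_params("gp", list(c = c, t_s = t_s, o = o, s = s))
}

check_gray <- function(img) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (diff(range(img)) == 0)
    stop("segmentation requires a nonconstant image")
  invisible(img)
}

new_segmentation <- function(ws, method, params) {
  labs <- ws$labels
  frame <- sort(unique(c(labs[1, ], labs[nrow(labs), ],
                         labs[, 1], labs[, ncol(labs)])))
  structure(list(labels = labs, contours = ws$lines,
                 n_cells = max(labs), frame_labels = frame,
                 method = method, params = params),
            class = "endo_segmentation")
}

#' Segment by filtering and h-maxima markers
#'
#' Pipeline: alternate sequential filter of order `p$o`; h-maxima of the
#' filtered image (cell interiors are its bright regional maxima) as
#' markers; marker-controlled watershed of the complemented filtered
#' image, whose ridges are the dark cell borders.
#'
#' @param img Gray image in [0, 255].
#' @param p Parameters from [params_vm()].
#' @return An `endo_segmentation` with `labels` (partition of the
#'   domain), `contours` (watershed lines), `n_cells` and
#'   `frame_labels` (labels touching the image frame).
#' @export
segment_vincent_masters <- function(img, p = params_vm()) {
  check_gray(img)
  stopifnot(identical(attr(p, "method"), "vm"))
  f <- alternate_sequential_filter(img, p$o)
  markers <- h_maxima_markers(f, p$h)
  # h at or above the filtered dynamic range flattens the
  # reconstruction: every pixel becomes a "maximum" and no cell marker
  # remains distinguishable
  if (!any(markers) || all(markers))
    stop("no usable markers: the image is over-filtered (h too large)")
  ws <- watershed_lines(255 - f, markers)
  new_segmentation(ws, "vm", p)
}

#' Segment by border threshold and distance-map markers
#'
#' Pipeline: opening of radius `s1`, Gaussian smoothing of sigma `g`,
#' dark top-hat of radius `s2` (bypassed when `s2 = 0`, in which case
#' the threshold applies to the complemented smoothed image); threshold
#' at `t` gives a first border estimate; the Euclidean distance map of
#' its complement has one dome per cell, whose h-maxima (`h`; raw
#' maxima when `h = 0`) seed a watershed of the complemented distance
#' map.
#'
#' @param img Gray image in [0, 255].
#' @param p Parameters from [params_am()].
#' @inherit segment_vincent_masters return
#' @export
segment_angulo_matou <- function(img, p = params_am()) {
  check_gray(img)
  stopifnot(identical(attr(p, "method"), "am"))
  f <- img
  if (p$s1 > 0) f <- mm_open(f, se_disk(p$s1))
  if (p$g > 0) f <- gaussian_blur(f, p$g)
  resp <- if (p$s2 > 0) top_hat(f, p$s2, dark = TRUE) else 255 - f
  borders <- resp >= p$t
  if (!any(borders))
    stop("threshold produced an empty border set (t too large)")
  d <- distance_map(borders)
  markers <- h_maxima_markers(d, p$h)
  ws <- watershed_lines(-d, markers)
  new_segmentation(ws, "am", p)
}

#' Segment by linear contour extraction
#'
#' Pipeline: alternate sequential filter of order `p$o`; complement (so
#' borders are bright); supremum of openings by segments of length
#' `t_s` retains the linear border responses, binarised by Otsu's
#' threshold; closing of radius `c` reconnects gaps; the skeleton is
#' pruned of its nonlinear parts (segments of length `t_s` again),
#' giving rough linear contours; markers are the regional maxima of the
#' opened (radius `s`) distance map of the contour complement, and the
#' final closed contours come from a watershed of the complemented
#' distance map.
#'
#' @param img Gray image in [0, 255].
#' @param p Parameters from [params_gp()].
#' @param orientations Number of segment orientations in [0, 180).
#' @inherit segment_vincent_masters return
#' @export
segment_gavet_pinoli <- function(img, p = params_gp(), orientations = 8L) {
  check_gray(img)
  stopifnot(identical(attr(p, "method"), "gp"))
  f <- alternate_sequential_filter(img, p$o)
  comp <- 255 - f
  so <- sup_open_segments(comp, p$t_s, orientations)
  th <- EBImage::otsu(so / 255, range = c(0, 1)) * 255
  rough <- so > th
  if (p$c > 0) rough <- mm_close(rough * 1, se_disk(p$c)) >= 0.5
  contours <- prune_nonlinear_skeleton(rough, p$t_s, orientations)
  if (!any(contours))
    stop("skeleton pruning removed every contour (t_s too large)")
  d <- distance_map(contours)
  dm <- if (p$s > 0) mm_open(d, se_disk(p$s)) else d
  markers <- regional_maxima(dm)
  ws <- watershed_lines(-d, markers)
  new_segmentation(ws, "gp", p)
}

#' Run a segmentation pipeline by method id
#'
#' @param img Gray image.
#' @param method One of `"vm"`, `"am"`, `"gp"`.
#' @param p Matching `endo_params`; defaults to the method's defaults.
#' @return An `endo_segmentation`.
#' @export
segment <- function(img, method = c("vm", "am", "gp"), p = NULL) {
  method <- match.arg(method)
  switch(method,
         vm = segment_vincent_masters(img, if (is.null(p)) params_vm() else p),
         am = segment_angulo_matou(img, if (is.null(p)) params_am() else p),
         gp = segment_gavet_pinoli(img, if (is.null(p)) params_gp() else p))
}
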