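# Images are held as numeric matrices in (row, col) orientation with
# intensities in [0, 255]; EBImage stores (x, y), hence the transposes.

#' Read a gray image
#'
#' Reads an 8- or 16-bit single-channel PNG or TIFF and linearly maps
#' its intensities to [0, 255]. RGB inputs are converted by luminance
#' with a warning; multi-frame files are rejected.
#'
#' @param path Path to the image file.
#' @return Gray image (numeric matrix in [0, 255]).
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (EBImage::colorMode(img) == EBImage::Color) {
    if (length(d) > 3 || (length(d) == 3 && !d[3] %in% c(2, 3, 4)))
      stop("multi-frame image not supported: ", path)
    warning("colour image converted to grayscale by luminance: ", path)
    img <- EBImage::channel(img, "luminance")
  } else if (length(d) > 2) {
    stop("multi-frame image not supported: ", path)
  }
  t(EBImage::imageData(img)) * 255
}

#' Write a gray image
#'
#' @param img Gray image in [0, 255].
#' @param path Destination (.png or .tif/.tiff).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  EBImage::writeImage(EBImage::Image(t(img / 255)), path)
  invisible(path)
}

#' Read a binary contour map
#'
#' Nonzero pixels are contour pixels. Files with more than two distinct
#' gray values are rejected as ambiguous masks; an all-zero mask is
#' accepted with a warning.
#'
#' @param path Path to the mask file.
#' @return Logical contour map.
#' @export
read_contour_map <- function(path) {
  img <- read_gray_image(path)
  vals <- unique(as.vector(img))
  if (length(vals) > 2)
    stop("ambiguous mask (more than two gray values): ", path)
  m <- img != 0
  if (!any(m)) warning("contour map is empty: ", path)
  m
}

#' Write a binary contour map as a 0/255 PNG
#'
#' @param map Logical contour map.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_contour_map <- function(map, path) {
  write_gray_image(as_binary(map) * 255, path)
}

#' Read/write a label mosaic as 16-bit TIFF
#'
#' Labels are stored as 16-bit gray values (supports up to 65535
#' cells).
#'
#' @param labels Integer label matrix.
#' @param path File path.
#' @return `read_label_map`: integer matrix. `write_label_map`: `path`,
#'   invisibly.
#' @export
write_label_map <- function(labels, path) {
  if (max(labels) > 65535) stop("more than 65535 labels")
  EBImage::writeImage(EBImage::Image(t(labels / 65535)), path,
                      bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- t(EBImage::imageData(EBImage::readImage(path)))
  matrix(as.integer(round(m * 65535)), nrow(m))
}

#' Write evaluation rows as CSV
#'
#' @param rows Data frame (or list of lists) with columns `image_id`,
#'   `method`, `params`, `criterion`, `rho`, `value`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(rows, path) {
  cols <- c("image_id", "method", "params", "criterion", "rho", "value")
  if (!is.data.frame(rows)) {
    rows <- do.call(rbind, lapply(rows, function(r) as.data.frame(r[cols])))
  }
  if (length(rows) && !all(cols %in% names(rows)))
    stop("rows must have columns: ", paste(cols, collapse = ", "))
  if (is.null(rows) || nrow(rows) == 0) {
    rows <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  }
  write.csv(rows[cols], path, row.names = FALSE)
  invisible(path)
}

#' Write a report (tuning, CV, morphometry) as JSON
#'
#' @param report A list-like report object.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass_deep(report), path, auto_unbox = TRUE,
                       digits = 8)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    attr(x, "method") <- NULL
    lapply(x, unclass_deep)
  } else if (is.matrix(x)) {
    unname(x)
  } else {
    x
  }
}

#' Read a YAML or JSON configuration file
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
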