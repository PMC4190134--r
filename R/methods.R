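#' @export
print.endo_spec <- function(x, ...) {
  cat("Synthetic endothelium spec:", x$width, "x", x$height, "px,",
      "mean cell area", x$mean_cell_area, "px^2, jitter", x$jitter, "\n")
  cat("  border", x$border_intensity, "@", x$border_width, "px, interior",
      x$interior_intensity, ", illum +/-", x$illumination_amplitude,
      ", noise sd", x$noise_sigma, ", blur sd", x$blur_sigma,
      ", seed", x$seed, "\n")
  invisible(x)
}

#' @export
print.endo_truth <- function(x, ...) {
  cat("Ground-truth mosaic:", max(x$labels), "cells on",
      nrow(x$labels), "x", ncol(x$labels), "px,",
      sum(x$contours), "contour pixels\n")
  invisible(x)
}

#' @export
print.endo_params <- function(x, ...) {
  cat("Parameters [", attr(x, "method"), "]: ", param_label(x), "\n",
      sep = "")
  invisible(x)
}

#' @export
print.endo_segmentation <- function(x, ...) {
  cat("Segmentation [", x$method, "]: ", x$n_cells, " cells (",
      length(x$frame_labels), " touching the frame), ",
      sum(x$contours), " contour pixels\n", sep = "")
  cat("  params: ", param_label(x$params), "\n", sep = "")
  invisible(x)
}

#' Display a segmentation over its image
#'
#' Draws the gray image (if given) with the segmentation contours
#' overlaid, or the label mosaic alone.
#'
#' @param x An `endo_segmentation`.
#' @param img Optional underlying gray image.
#' @param ... Passed to [graphics::image()].
#' @export
plot.endo_segmentation <- function(x, img = NULL, ...) {
  flip <- function(m) t(m[nrow(m):1, , drop = FALSE])
  if (is.null(img)) {
    graphics::image(flip(x$labels), col = grDevices::hcl.colors(64, "Spectral"),
                    axes = FALSE, asp = ncol(x$labels) / nrow(x$labels), ...)
  } else {
    graphics::image(flip(img), col = grDevices::gray.colors(256, 0, 1),
                    axes = FALSE, asp = ncol(img) / nrow(img), ...)
    ov <- matrix(NA_real_, nrow(img), ncol(img))
    ov[x$contours] <- 1
    graphics::image(flip(ov), col = "red", add = TRUE)
  }
  invisible(x)
}

#' @export
print.endo_tolerance <- function(x, ...) {
  cat("Selected tolerance rho =", x$rho, "px\n")
  print(x$curve)
  invisible(x)
}

#' @export
print.endo_quality_table <- function(x, ...) {
  cat("Quality table [", x$method, ", ", x$criterion,
      if (x$criterion == "epsilon") paste0(" @ rho=", x$rho), "]: ",
      length(x$images), " images x ", length(x$params),
      " parameter sets\n", sep = "")
  invisible(x)
}

#' @export
print.endo_tuning <- function(x, ...) {
  cat("Learned parameters [", x$method, ", ", x$criterion, "]\n", sep = "")
  cat(sprintf("  mean:            %-28s Q_hat    = %.4f\n",
              param_label(x$p_hat), x$Q_hat))
  cat(sprintf("  trimmed (k=%.2g): %-28s Q_hat_k  = %.4f\n",
              x$k, param_label(x$p_hat_k), x$Q_hat_k))
  cat(sprintf("  median:          %-28s Q_tilde  = %.4f\n",
              param_label(x$p_tilde), x$Q_tilde))
  invisible(x)
}

#' @export
print.endo_cv <- function(x, ...) {
  cat(x$K, "-fold cross-validation [", x$method, ", ", x$criterion,
      "]\n", sep = "")
  for (f in x$folds) {
    cat(sprintf("  fold %d: %-28s Q_i_CV = %.4f  Q~_i_CV = %.4f\n",
                f$fold, param_label(f$p), f$Q_i_CV, f$Q_tilde_i_CV))
  }
  cat(sprintf("  mean: Q_CV = %.4f  Q~_CV = %.4f\n", x$Q_CV, x$Q_tilde_CV))
  invisible(x)
}

#' @export
print.endo_morphometry <- function(x, ...) {
  cat(sprintf("Endothelium morphometry (%d cells, %.4g mm/px):\n",
              x$n_cells, x$pixel_size))
  cat(sprintf("  ECD           %.1f cells/mm^2%s%s\n", x$ecd,
              if (x$below_transparency_threshold)
                "  [below 400: transparency at risk]" else "",
              if (x$below_implant_threshold)
                "  [below 1000: implant contraindicated]" else ""))
  cat(sprintf("  polymegathism %.1f %%\n", x$polymegathism))
  cat(sprintf("  pleomorphism  %.1f %%\n", x$pleomorphism))
  invisible(x)
}
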