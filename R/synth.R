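#' Synthetic endothelium specification
#'
#' Parameters of the synthetic specular-microscopy mosaic generator. The
#' defaults describe a healthy endothelium imaged at about 1 um/pixel:
#' a 256 x 256 field of ~400 px^2 cells (2500 cells/mm^2), moderately
#' jittered hexagonal packing, dark 3-px borders on brighter interiors,
#' a smooth illumination drift, slight optical blur and sensor noise.
#'
#' @param width,height Image size in pixels.
#' @param mean_cell_area Target mean cell area in px^2.
#' @param jitter Seed displacement as a fraction of the lattice spacing,
#'   in [0, 1]; 0 gives a perfect honeycomb.
#' @param border_width Drawn border width in pixels (>= 1; realised as
#'   the nearest odd width by Euclidean dilation of the 1-px contour).
#' @param border_intensity,interior_intensity Gray levels in [0, 255];
#'   borders must be darker than interiors.
#' @param illumination_amplitude Peak amplitude (gray levels) of the
#'   smooth illumination field, applied half multiplicatively (local
#'   gain, so shading also erodes local contrast) and half additively.
#' @param noise_sigma Additive Gaussian noise sigma in gray levels.
#' @param blur_sigma Gaussian blur sigma in pixels.
#' @param seed Integer seed governing all stochastic steps.
#' @return An object of class `endo_spec`.
#' @export
synthetic_spec <- function(width = 256L, height = 256L, mean_cell_area = 400,
                           jitter = 0.3, border_width = 3L,
                           border_intensity = 90, interior_intensity = 150,
                           illumination_amplitude = 30, noise_sigma = 20,
                           blur_sigma = 1.5, seed = 1L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               mean_cell_area = mean_cell_area, jitter = jitter,
               border_width = as.integer(border_width),
               border_intensity = border_intensity,
               interior_intensity = interior_intensity,
               illumination_amplitude = illumination_amplitude,
               noise_sigma = noise_sigma, blur_sigma = blur_sigma,
               seed = as.integer(seed))
  validate_spec(spec)
  structure(spec, class = "endo_spec")
}

validate_spec <- function(spec) {
  with(spec, {
    if (width < 1 || height < 1) stop("domain must be at least 1x1")
    if (mean_cell_area <= 0) stop("mean_cell_area must be positive")
    if (width * height < mean_cell_area)
      stop("domain too small to hold a single cell of the requested area")
    if (jitter < 0 || jitter > 1) stop("jitter must lie in [0, 1]")
    if (border_width < 1) stop("border_width must be >= 1")
    if (border_intensity >= interior_intensity)
      stop("cell borders must be darker than cell interiors")
    if (noise_sigma < 0 || blur_sigma < 0 || illumination_amplitude < 0)
      stop("noise_sigma, blur_sigma and illumination_amplitude must be >= 0")
  })
  invisible(spec)
}

# One seed per named stochastic substep, derived from the spec seed so
# fixtures are reproducible step by step.
substream_seed <- function(seed, step) {
  offsets <- c(jitter = 1L, illumination = 2L, noise = 3L, perturb = 4L,
               fold = 5L)
  if (!step %in% names(offsets)) stop("unknown substream: ", step)
  ((as.integer(seed) %% 1000003L) * 1009L + offsets[[step]]) %% 2147483647L
}

with_substream <- function(seed, step, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, step))
  expr
}

#' Generate a ground-truth cell mosaic
#'
#' Voronoi tessellation of seeds placed on a hexagonal lattice with
#' per-seed uniform jitter. Returns the label partition, the
#' 1-pixel-wide contour map separating adjacent cells, and the seed
#' coordinates. Deterministic given `spec$seed`.
#'
#' @param spec An [synthetic_spec()] object.
#' @return An object of class `endo_truth` with elements `labels`
#'   (integer matrix), `contours` (logical matrix), `cell_seeds`
#'   (matrix of (row, col) positions) and `spec`.
#' @export
generate_mosaic <- function(spec) {
  validate_spec(spec)
  w <- spec$width; h <- spec$height
  dx <- sqrt(2 * spec$mean_cell_area / sqrt(3))   # column spacing
  dy <- dx * sqrt(3) / 2                          # row spacing
  rows <- seq(-dy, h + dy, by = dy)
  cols <- seq(-dx, w + dx, by = dx)
  sr <- rep(rows, each = length(cols))
  sc <- rep(cols, times = length(rows))
  odd <- rep(seq_along(rows) %% 2 == 0, each = length(cols))
  sc[odd] <- sc[odd] + dx / 2
  if (spec$jitter > 0) {
    amp <- spec$jitter * dx / 2
    jit <- with_substream(spec$seed, "jitter", {
      n <- length(sr)
      cbind(runif(n, -amp, amp), runif(n, -amp, amp))
    })
    sr <- sr + jit[, 1]
    sc <- sc + jit[, 2]
  }
  raw <- cpp_nearest_seed(h, w, sr, sc)
  present <- sort(unique(as.vector(raw)))
  labels <- matrix(match(raw, present), h, w)
  structure(list(labels = labels,
                 contours = boundary_map(labels),
                 cell_seeds = cbind(row = sr[present], col = sc[present]),
                 spec = spec),
            class = "endo_truth")
}

#' Render a synthetic specular-microscopy image
#'
#' Paints the mosaic with dark borders (dilated to `border_width`) and
#' brighter interiors, adds a smooth two-sinusoid illumination field,
#' applies Gaussian blur, adds Gaussian noise, and clips to [0, 255].
#' A pure, deterministic function of `(truth, spec)`.
#'
#' @param truth A ground truth from [generate_mosaic()].
#' @param spec The matching [synthetic_spec()].
#' @return Gray image (numeric matrix in [0, 255]).
#' @export
render_specular <- function(truth, spec = truth$spec) {
  validate_spec(spec)
  check_same_dim(truth$labels, matrix(0, spec$height, spec$width))
  img <- matrix(spec$interior_intensity, spec$height, spec$width)
  border <- truth$contours
  if (spec$border_width > 1) {
    r <- (spec$border_width - 1) / 2
    border <- distance_map(truth$contours) <= r + 1e-9
  }
  img[border] <- spec$border_intensity
  if (spec$illumination_amplitude > 0) {
    ph <- with_substream(spec$seed, "illumination", runif(4, 0, 2 * pi))
    rr <- row(img) / spec$height
    cc <- col(img) / spec$width
    field <- (sin(2 * pi * (1.0 * cc + 0.5 * rr) + ph[1]) +
                sin(2 * pi * (0.5 * cc - 1.5 * rr) + ph[2])) / 2
    amp <- spec$illumination_amplitude
    img <- img * (1 + 0.5 * amp * field / 255) + 0.5 * amp * field
  }
  if (spec$blur_sigma > 0) img <- gaussian_blur(img, spec$blur_sigma)
  if (spec$noise_sigma > 0) {
    img <- img + with_substream(spec$seed, "noise",
                                matrix(rnorm(length(img), 0, spec$noise_sigma),
                                       nrow(img)))
  }
  img <- pmin(pmax(img, 0), 255)
  round(img)
}

#' Simulate expert redrawing variability
#'
#' Returns the contour map translated by an integer offset (pixels
#' shifted outside the domain are dropped) with a fraction `flip_rate`
#' of the contour pixels each moved to a free 8-neighbour position.
#' Deterministic given `seed`. Emulates an expert retracing the same
#' borders with small positional error.
#'
#' @param contours Nonempty logical contour map.
#' @param translation Integer (row, col) offset in pixels.
#' @param flip_rate Fraction in [0, 1] of contour pixels to displace.
#' @param seed Integer seed.
#' @return Logical contour map.
#' @export
perturb_contours <- function(contours, translation = c(0L, 0L),
                             flip_rate = 0, seed = 1L) {
  b <- as_binary(contours)
  if (!any(b)) stop("perturb_contours: input contour map is empty")
  stopifnot(length(translation) == 2L, flip_rate >= 0, flip_rate <= 1)
  nr <- nrow(b); nc <- ncol(b)
  out <- matrix(FALSE, nr, nc)
  idx <- which(b, arr.ind = TRUE)
  nr2 <- idx[, 1] + as.integer(translation[1])
  nc2 <- idx[, 2] + as.integer(translation[2])
  keep <- nr2 >= 1 & nr2 <= nr & nc2 >= 1 & nc2 <= nc
  out[cbind(nr2[keep], nc2[keep])] <- TRUE
  if (flip_rate > 0) {
    orig <- out
    pix <- which(out, arr.ind = TRUE)
    m <- round(flip_rate * nrow(pix))
    if (m > 0) {
      off <- cbind(rep(c(-1L, 0L, 1L), 3), rep(c(-1L, 0L, 1L), each = 3))
      off <- off[!(off[, 1] == 0 & off[, 2] == 0), , drop = FALSE]
      with_substream(seed, "perturb", {
        moved <- 0L
        # displace exactly m pixels; targets must be free both in the
        # original and the current map so each move changes 2 pixels
        for (i in sample(nrow(pix))) {
          if (moved >= m) break
          cand <- cbind(pix[i, 1] + off[, 1], pix[i, 2] + off[, 2])
          ok <- cand[, 1] >= 1 & cand[, 1] <= nr &
            cand[, 2] >= 1 & cand[, 2] <= nc
          cand <- cand[ok, , drop = FALSE]
          cand <- cand[!orig[cand] & !out[cand], , drop = FALSE]
          if (nrow(cand) == 0) next
          tgt <- cand[sample(nrow(cand), 1), , drop = FALSE]
          out[pix[i, 1], pix[i, 2]] <- FALSE
          out[tgt] <- TRUE
          moved <- moved + 1L
        }
        if (moved < m)
          warning("could only displace ", moved, " of ", m,
                  " contour pixels")
      })
    }
  }
  if (!any(out)) stop("perturb_contours: perturbation emptied the contour map")
  out
}

#' Generate a synthetic image database
#'
#' Renders `n` mosaics from one generating specification, differing only
#' in their seed. Each entry carries the gray image, the reference
#' contour map and the ground-truth labels.
#'
#' @param spec Base [synthetic_spec()].
#' @param n Number of images.
#' @return A list of class `endo_db`; each element has `id`, `image`,
#'   `ref` and `truth`.
#' @export
synthetic_database <- function(spec, n) {
  stopifnot(n >= 1)
  db <- lapply(seq_len(n), function(i) {
    si <- spec
    si$seed <- as.integer((spec$seed + 7919L * i) %% 2147483647L)
    tr <- generate_mosaic(si)
    list(id = sprintf("synth-%03d", i),
         image = render_specular(tr, si),
         ref = tr$contours,
         truth = tr)
  })
  structure(db, class = "endo_db")
}
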