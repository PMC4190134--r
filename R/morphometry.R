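#' Region adjacency of a label mosaic
#'
#' Pairs of distinct labels sharing a 4-adjacent pixel edge.
#'
#' @param labels Integer label matrix partitioning the domain.
#' @return Two-column matrix of label pairs (a < b).
#' @export
region_adjacency <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  h <- cbind(as.vector(labels[, -nc, drop = FALSE]),
             as.vector(labels[, -1, drop = FALSE]))
  v <- cbind(as.vector(labels[-nr, , drop = FALSE]),
             as.vector(labels[-1, , drop = FALSE]))
  pairs <- rbind(h, v)
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]),
                 pmax(pairs[, 1], pairs[, 2]))
  unique(pairs)
}

frame_labels <- function(labels) {
  sort(unique(c(labels[1, ], labels[nrow(labels), ],
                labels[, 1], labels[, ncol(labels)])))
}

included_labels <- function(labels, exclude_frame = TRUE) {
  all_lab <- sort(unique(as.vector(labels)))
  if (exclude_frame) setdiff(all_lab, frame_labels(labels)) else all_lab
}

#' Endothelial cell density
#'
#' Number of cells per mm^2: the count of included cells divided by the
#' sum of their areas. Cells touching the image frame are excluded by
#' default because their areas are truncated.
#'
#' @param labels Integer label mosaic.
#' @param pixel_size Pixel pitch in mm/pixel (> 0).
#' @param exclude_frame Exclude frame-touching cells?
#' @return Density in cells/mm^2.
#' @export
cell_density <- function(labels, pixel_size, exclude_frame = TRUE) {
  stopifnot(pixel_size > 0)
  inc <- included_labels(labels, exclude_frame)
  if (length(inc) == 0) stop("no included cells (all touch the frame)")
  areas <- tabulate(labels)[inc]
  length(inc) / (sum(areas) * pixel_size^2)
}

#' Polymegathism (cell-area variability)
#'
#' Coefficient of variation of the included cell areas, in percent,
#' using the population standard deviation.
#'
#' @inheritParams cell_density
#' @return Percentage (may exceed 100).
#' @export
polymegathism <- function(labels, exclude_frame = TRUE) {
  inc <- included_labels(labels, exclude_frame)
  if (length(inc) < 2) stop("polymegathism needs at least 2 included cells")
  areas <- tabulate(labels)[inc]
  pop_sd <- sqrt(mean((areas - mean(areas))^2))
  100 * pop_sd / mean(areas)
}

#' Pleomorphism (hexagon-like cell fraction)
#'
#' Percentage of included cells with exactly six neighbours in the
#' region adjacency graph (neighbours are counted among all cells,
#' including frame-touching ones).
#'
#' @inheritParams cell_density
#' @return Percentage in [0, 100].
#' @export
pleomorphism <- function(labels, exclude_frame = TRUE) {
  inc <- included_labels(labels, exclude_frame)
  if (length(inc) < 1) stop("pleomorphism needs at least 1 included cell")
  adj <- region_adjacency(labels)
  deg <- tabulate(c(adj[, 1], adj[, 2]), nbins = max(labels))
  100 * mean(deg[inc] == 6)
}

#' Morphometry report of a segmented endothelium
#'
#' Combines the three clinical indices and flags the cell-density
#' thresholds relevant to corneal transparency (400 cells/mm^2) and to
#' intraocular lens implantation (1000 cells/mm^2).
#'
#' @inheritParams cell_density
#' @return An object of class `endo_morphometry` with fields `ecd`,
#'   `polymegathism`, `pleomorphism`, `n_cells`, `pixel_size`,
#'   `below_transparency_threshold` and `below_implant_threshold`.
#' @export
morphometry_report <- function(labels, pixel_size, exclude_frame = TRUE) {
  ecd <- cell_density(labels, pixel_size, exclude_frame)
  structure(list(
    ecd = ecd,
    polymegathism = polymegathism(labels, exclude_frame),
    pleomorphism = pleomorphism(labels, exclude_frame),
    n_cells = length(included_labels(labels, exclude_frame)),
    pixel_size = pixel_size,
    below_transparency_threshold = ecd < 400,
    below_implant_threshold = ecd < 1000),
    class = "endo_morphometry")
}
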