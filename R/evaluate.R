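#' Symmetric difference of two contour maps
#'
#' Pixels belonging to exactly one of the two sets.
#'
#' @param R,X Binary images of identical dimensions.
#' @return Logical matrix.
#' @export
symmetric_difference <- function(R, X) {
  R <- as_binary(R); X <- as_binary(X)
  check_same_dim(R, X)
  xor(R, X)
}

#' Minkowski dilation by a Euclidean disk
#'
#' `X` dilated by the discrete Euclidean ball of radius `rho`:
#' the pixels at Euclidean distance <= `rho` from `X`. This is the
#' tolerance tube used by the epsilon criterion. `rho = 0` is the
#' identity; the dilation of an empty set is empty.
#'
#' @param X Binary image.
#' @param rho Tolerance radius in pixels (>= 0).
#' @return Logical matrix.
#' @export
minkowski_dilate <- function(X, rho) {
  stopifnot(rho >= 0)
  X <- as_binary(X)
  if (rho == 0 || !any(X)) return(X)
  distance_map(X) <= rho + 1e-9
}

#' The epsilon dissimilarity criterion
#'
#' Tolerance-aware normalised symmetric difference between a reference
#' contour map `R` and a candidate `X`:
#' \deqn{\epsilon_R^\rho(X) = \frac{\#\{(X \setminus (R \oplus \rho N))
#'   \cup (R \setminus (X \oplus \rho N))\}}{\#\{R \oplus \rho N\}}}
#' where \eqn{\oplus \rho N} dilates by the Euclidean disk of radius
#' \eqn{\rho}. It is 0 when the two sets agree within the tolerance
#' tube, tends to 0 as \eqn{\rho} grows, and is deliberately neither
#' symmetric nor a metric.
#'
#' @param R Nonempty reference contour map.
#' @param X Candidate contour map (may be empty: a total miss scores
#'   `#R / #(R %+% rho N)`).
#' @param rho Tolerance radius in pixels (>= 0).
#' @return Nonnegative dissimilarity value (0 = agreement).
#' @export
epsilon <- function(R, X, rho = 2) {
  R <- as_binary(R); X <- as_binary(X)
  check_same_dim(R, X)
  if (!any(R)) stop("epsilon: the reference R must be nonempty")
  stopifnot(rho >= 0)
  Rd <- minkowski_dilate(R, rho)
  Xd <- minkowski_dilate(X, rho)
  num <- sum((X & !Rd) | (R & !Xd))
  num / sum(Rd)
}

#' Pratt's figure of merit (dissimilarity orientation)
#'
#' \deqn{\mathrm{fom}_R(X) = 1 - \frac{1}{\max\{\#R, \#X\}}
#'   \sum_{p \in X} \frac{1}{1 + d^2(p, R)}}
#' with \eqn{d(p, R)} the Euclidean distance from a candidate pixel to
#' the nearest reference pixel. Values lie in [0, 1]; 0 is perfect
#' agreement, so the same argmin tuning machinery applies to both
#' criteria.
#'
#' @param R Nonempty reference contour map.
#' @param X Candidate contour map (empty scores 1, a total miss).
#' @return Value in [0, 1].
#' @export
fom <- function(R, X) {
  R <- as_binary(R); X <- as_binary(X)
  check_same_dim(R, X)
  if (!any(R)) stop("fom: the reference R must be nonempty")
  if (!any(X)) return(1)
  d <- distance_map(R)[X]
  1 - sum(1 / (1 + d^2)) / max(sum(R), sum(X))
}

#' Calibrate the tolerance from expert variability
#'
#' Given several contour maps drawn by experts for the same image,
#' computes the mean epsilon over all ordered pairs for each integer
#' tolerance in `rho_range`, and returns the smallest tolerance whose
#' mean dissimilarity does not exceed `epsilon_max` -- the tolerance at
#' which the experts agree with themselves.
#'
#' @param expert_maps List of >= 2 nonempty contour maps of one shape.
#' @param epsilon_max Acceptable mean dissimilarity (e.g. 0.05).
#' @param rho_range Integer tolerances to scan (default 0:10).
#' @return A list of class `endo_tolerance` with `rho` and `curve`
#'   (data frame of `rho` and `mean_epsilon`, non-increasing). If no
#'   tolerance satisfies the bound, an error condition of class
#'   `endoseg_tolerance_error` carrying the curve is signalled.
#' @export
select_tolerance <- function(expert_maps, epsilon_max, rho_range = 0:10) {
  stopifnot(length(expert_maps) >= 2, epsilon_max >= 0)
  maps <- lapply(expert_maps, as_binary)
  for (m in maps) {
    check_same_dim(maps[[1]], m)
    if (!any(m)) stop("select_tolerance: all expert maps must be nonempty")
  }
  n <- length(maps)
  pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
  pairs <- pairs[pairs$i != pairs$j, ]
  mean_eps <- vapply(rho_range, function(rho) {
    mean(mapply(function(i, j) epsilon(maps[[i]], maps[[j]], rho),
                pairs$i, pairs$j))
  }, numeric(1))
  curve <- data.frame(rho = rho_range, mean_epsilon = mean_eps)
  ok <- which(mean_eps <= epsilon_max)
  if (length(ok) == 0) {
    stop(errorCondition(
      sprintf("no tolerance in [%d, %d] reaches mean epsilon <= %g",
              min(rho_range), max(rho_range), epsilon_max),
      curve = curve, class = "endoseg_tolerance_error"))
  }
  structure(list(rho = rho_range[min(ok)], curve = curve),
            class = "endo_tolerance")
}
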