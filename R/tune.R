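#' Build a parameter grid for one method
#'
#' @param method One of `"vm"`, `"am"`, `"gp"`.
#' @param ... Named axes of candidate values; names must match the
#'   method's parameter fields (vm: o, h; am: s1, g, s2, t, h;
#'   gp: c, t_s, o, s). Every axis must be nonempty.
#' @return A list of class `endo_grid`: the method id and the list of
#'   `endo_params` on the full Cartesian product, ordered
#'   lexicographically by parameter tuple.
#' @export
parameter_grid <- function(method = c("vm", "am", "gp"), ...) {
  method <- match.arg(method)
  axes <- list(...)
  fields <- switch(method,
                   vm = c("o", "h"),
                   am = c("s1", "g", "s2", "t", "h"),
                   gp = c("c", "t_s", "o", "s"))
  if (!setequal(names(axes), fields))
    stop("grid axes must be exactly: ", paste(fields, collapse = ", "))
  if (any(lengths(axes) == 0)) stop("every axis must be nonempty")
  axes <- axes[fields]
  tuples <- expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE)
  tuples <- tuples[, rev(seq_along(axes)), drop = FALSE]
  tuples <- tuples[do.call(order, tuples), , drop = FALSE]
  params <- lapply(seq_len(nrow(tuples)), function(i) {
    new_params(method, as.list(tuples[i, , drop = FALSE]))
  })
  structure(list(method = method, params = params, axes = axes),
            class = "endo_grid")
}

param_label <- function(p) {
  paste(sprintf("%s=%g", names(p), unlist(p)), collapse = ";")
}

#' Quality of one segmentation against its reference
#'
#' Runs the requested pipeline on the image and scores its contour
#' output against the reference with the chosen criterion
#' (`Q_C(A_p, I) = C(A_p(I), R)`). A pipeline failure (e.g. no markers)
#' is scored as the worst value: 1 for fom, `fail_penalty` for epsilon.
#'
#' @param method Method id (`"vm"`, `"am"`, `"gp"`).
#' @param p `endo_params` for that method.
#' @param img Gray image.
#' @param ref Nonempty reference contour map.
#' @param criterion `"epsilon"` or `"fom"`.
#' @param rho Tolerance for the epsilon criterion.
#' @param fail_penalty Epsilon value assigned to a failed segmentation.
#' @return A single nonnegative quality value (lower is better).
#' @export
quality <- function(method, p, img, ref, criterion = c("epsilon", "fom"),
                    rho = 2, fail_penalty = 2) {
  criterion <- match.arg(criterion)
  seg <- tryCatch(segment(img, method, p), error = function(e) NULL)
  if (is.null(seg)) {
    return(if (criterion == "fom") 1 else fail_penalty)
  }
  if (criterion == "fom") fom(ref, seg$contours)
  else epsilon(ref, seg$contours, rho)
}

#' Quality table over an image database and a parameter grid
#'
#' Evaluates every (image, parameter set) pair of the grid on the
#' database, producing the matrix the tuning aggregators act on.
#'
#' @param db An `endo_db` (see [synthetic_database()]) or any list of
#'   elements with `id`, `image` and `ref`.
#' @param grid An [parameter_grid()] object.
#' @param criterion,rho,fail_penalty Passed to [quality()].
#' @return An object of class `endo_quality_table` with `images`,
#'   `params` and the `values` matrix (images x parameter sets).
#' @export
quality_table <- function(db, grid, criterion = c("epsilon", "fom"),
                          rho = 2, fail_penalty = 2) {
  criterion <- match.arg(criterion)
  stopifnot(length(db) >= 1, inherits(grid, "endo_grid"))
  vals <- vapply(grid$params, function(p) {
    vapply(db, function(entry) {
      quality(grid$method, p, entry$image, entry$ref, criterion,
              rho = rho, fail_penalty = fail_penalty)
    }, numeric(1))
  }, numeric(length(db)))
  vals <- matrix(vals, nrow = length(db))
  rownames(vals) <- vapply(db, function(e) e$id, character(1))
  colnames(vals) <- vapply(grid$params, param_label, character(1))
  structure(list(images = rownames(vals), params = grid$params,
                 method = grid$method, criterion = criterion, rho = rho,
                 values = vals),
            class = "endo_quality_table")
}

#' Trimmed mean discarding the worst values
#'
#' Mean after discarding the `floor(k * n)` largest values; with
#' `k = 0` it is the plain mean.
#'
#' @param x Numeric vector.
#' @param k Fraction in [0, 0.5] discarded at the high end.
#' @return The trimmed mean.
#' @export
trimmed_mean <- function(x, k) {
  stopifnot(k >= 0, k <= 0.5)
  n <- length(x)
  m <- floor(k * n)
  if (m == 0) return(mean(x))
  mean(sort(x)[seq_len(n - m)])
}

param_tuples <- function(params) {
  as.data.frame(do.call(rbind, lapply(params, function(p) unlist(p))))
}

# index of the minimising column; ties broken by the lexicographically
# smallest parameter tuple
argmin_lex <- function(vals, params) {
  cand <- which(vals <= min(vals) + 1e-12)
  if (length(cand) == 1) return(cand)
  tup <- param_tuples(params[cand])
  cand[do.call(order, tup)[1]]
}

#' Learn the best parameter set from a quality table
#'
#' Minimises, over the parameter sets of the table, three aggregates of
#' the per-image quality values: the mean (`p_hat`, `Q_hat`), the
#' trimmed mean at `k` (`p_hat_k`, `Q_hat_k`) and the median
#' (`p_tilde`, `Q_tilde`). At `k = 0` the trimmed-mean optimum equals
#' the mean optimum exactly.
#'
#' @param table An [quality_table()] object (or a subset of its rows).
#' @param k Trimming fraction in [0, 0.5]; default 0.5 as in the
#'   reported trimmed results.
#' @return An object of class `endo_tuning`.
#' @export
grid_search <- function(table, k = 0.5) {
  stopifnot(inherits(table, "endo_quality_table"),
            nrow(table$values) >= 1, k >= 0, k <= 0.5)
  v <- table$values
  agg_mean <- colMeans(v)
  agg_trim <- apply(v, 2, trimmed_mean, k = k)
  agg_med <- apply(v, 2, median)
  i_hat <- argmin_lex(agg_mean, table$params)
  i_trim <- argmin_lex(agg_trim, table$params)
  i_med <- argmin_lex(agg_med, table$params)
  structure(list(method = table$method, criterion = table$criterion,
                 k = k,
                 p_hat = table$params[[i_hat]], Q_hat = agg_mean[[i_hat]],
                 p_hat_k = table$params[[i_trim]], Q_hat_k = agg_trim[[i_trim]],
                 p_tilde = table$params[[i_med]], Q_tilde = agg_med[[i_med]]),
            class = "endo_tuning")
}

#' Projection of the quality on one control parameter
#'
#' Sweeps the named parameter along its grid axis with every other
#' parameter fixed at the anchor's value, reporting the trimmed-mean
#' quality -- the curves used to judge whether a parameter matters.
#'
#' @param table An [quality_table()] object.
#' @param anchor An `endo_params` lying on the table's grid (typically
#'   the learned optimum).
#' @param param_name Name of the swept parameter.
#' @param k Trimming fraction.
#' @return Data frame with columns `value` and `Q`.
#' @export
projection <- function(table, anchor, param_name, k = 0.5) {
  tup <- param_tuples(table$params)
  if (!param_name %in% names(tup)) stop("unknown parameter: ", param_name)
  fixed <- setdiff(names(tup), param_name)
  anchor_v <- unlist(anchor)
  sel <- rep(TRUE, nrow(tup))
  for (f in fixed) sel <- sel & tup[[f]] == anchor_v[[f]]
  if (!any(sel)) stop("anchor does not lie on the table's grid")
  idx <- which(sel)[order(tup[[param_name]][sel])]
  data.frame(value = tup[[param_name]][idx],
             Q = vapply(idx, function(i) trimmed_mean(table$values[, i], k),
                        numeric(1)))
}

subset_table <- function(table, rows) {
  out <- table
  out$values <- table$values[rows, , drop = FALSE]
  out$images <- table$images[rows]
  out
}

#' K-fold cross-validation of the parameter learning
#'
#' Shuffles the database into K near-equal folds (deterministically
#' from `seed`), learns the mean-optimal parameter set on each K-1
#' training folds, and scores it on the held-out fold (`Q_i_CV`). For
#' comparison it also reports the best mean quality attainable on the
#' test fold itself (`Q_tilde_i_CV`), which can never exceed the
#' learned score.
#'
#' @param db Image database (as for [quality_table()]).
#' @param grid An [parameter_grid()].
#' @param criterion,rho,fail_penalty Passed to [quality()].
#' @param K Number of folds (2 <= K <= number of images).
#' @param seed Integer seed for the fold shuffle.
#' @param table Optionally a precomputed [quality_table()] for `db` and
#'   `grid`, to avoid re-running the segmentations.
#' @return An object of class `endo_cv`: per-fold learned parameters
#'   and scores, the fold assignment, and the means `Q_CV` and
#'   `Q_tilde_CV`.
#' @export
kfold_cv <- function(db, grid, criterion = c("epsilon", "fom"), rho = 2,
                     fail_penalty = 2, K = 5, seed = 1L, table = NULL) {
  criterion <- match.arg(criterion)
  n <- length(db)
  if (K < 2) stop("K must be >= 2")
  if (K > n) stop("K exceeds the database size")
  if (is.null(table))
    table <- quality_table(db, grid, criterion, rho, fail_penalty)
  fold <- integer(n)
  perm <- with_substream(seed, "fold", sample(n))
  fold[perm] <- rep(seq_len(K), length.out = n)
  folds <- lapply(seq_len(K), function(i) {
    train <- subset_table(table, fold != i)
    test <- subset_table(table, fold == i)
    learned <- grid_search(train, k = 0)
    j <- match(param_label(learned$p_hat),
               vapply(table$params, param_label, character(1)))
    q_i <- mean(test$values[, j])
    test_means <- colMeans(test$values)
    j_best <- argmin_lex(test_means, table$params)
    list(fold = i, p = learned$p_hat, Q_i_CV = q_i,
         p_test_best = table$params[[j_best]],
         Q_tilde_i_CV = test_means[[j_best]])
  })
  structure(list(method = grid$method, criterion = criterion, rho = rho,
                 K = K, seed = seed, fold_of = fold, folds = folds,
                 Q_CV = mean(vapply(folds, `[[`, numeric(1), "Q_i_CV")),
                 Q_tilde_CV = mean(vapply(folds, `[[`, numeric(1),
                                          "Q_tilde_i_CV")),
                 table = table),
            class = "endo_cv")
}
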