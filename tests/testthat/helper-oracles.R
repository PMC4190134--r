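# Independent brute-force oracles: deliberately naive O(n^2)
# implementations used only to validate the package's fast paths.

# exact Euclidean distance of every pixel to the nearest TRUE pixel
bf_distance_map <- function(b) {
  idx <- which(b, arr.ind = TRUE)
  out <- matrix(Inf, nrow(b), ncol(b))
  for (r in seq_len(nrow(b))) {
    for (c in seq_len(ncol(b))) {
      out[r, c] <- sqrt(min((idx[, 1] - r)^2 + (idx[, 2] - c)^2))
    }
  }
  out
}

# epsilon via per-pixel distance thresholding rather than set dilation
bf_epsilon <- function(R, X, rho) {
  dR <- bf_distance_map(R)
  Rtube <- dR <= rho + 1e-9
  num <- sum(X & !Rtube)
  if (any(X)) {
    dX <- bf_distance_map(X)
    num <- num + sum(R & !(dX <= rho + 1e-9))
  } else {
    num <- num + sum(R)
  }
  num / sum(Rtube)
}

# grayscale reconstruction by iterated geodesic dilation (3x3 max)
bf_reconstruct <- function(marker, mask) {
  cur <- marker
  repeat {
    nxt <- cur
    nr <- nrow(cur); nc <- ncol(cur)
    for (dr in -1:1) for (dc in -1:1) {
      sh <- matrix(-Inf, nr, nc)
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      sh[rs, cs] <- cur[rs - dr, cs - dc]
      nxt <- pmax(nxt, sh)
    }
    nxt <- pmin(nxt, mask)
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
}

# flat min/max filtering over an arbitrary 0/1 kernel, window
# restricted to the image domain (mirror-padding equivalent)
bf_filter <- function(img, kern, fun) {
  kr <- (nrow(kern) - 1) / 2
  kc <- (ncol(kern) - 1) / 2
  out <- img
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      vals <- c()
      for (i in seq_len(nrow(kern))) {
        for (j in seq_len(ncol(kern))) {
          if (!kern[i, j]) next
          rr <- r + i - 1 - kr; cc <- c + j - 1 - kc
          if (rr >= 1 && rr <= nrow(img) && cc >= 1 && cc <= ncol(img))
            vals <- c(vals, img[rr, cc])
        }
      }
      out[r, c] <- fun(vals)
    }
  }
  out
}

bf_erode <- function(img, kern) bf_filter(img, kern, min)
bf_dilate <- function(img, kern) bf_filter(img, kern, max)

random_contour_map <- function(nr = 32, nc = 32, p = 0.05, nonempty = TRUE) {
  repeat {
    m <- matrix(runif(nr * nc) < p, nr, nc)
    if (!nonempty || any(m)) return(m)
  }
}

# a full-height vertical line at a given column (edge-effect-free
# translation fixture)
column_map <- function(nr, nc, col) {
  m <- matrix(FALSE, nr, nc)
  m[, col] <- TRUE
  m
}
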