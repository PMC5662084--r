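# Independent oracles and fixture builders used across the suite. These are
# deliberately written with different algorithms than the package code
# (recursive flood fill instead of graph components, explicit formulas
# instead of stats wrappers) so they can serve as cross-checks.

# Digital disk mask: pixel centers within `radius` of `center` (0-based).
disk_mask <- function(n, center, radius) {
  rr <- outer(0:(n - 1), rep(1, n))
  cc <- t(rr)
  sqrt((rr - center[1])^2 + (cc - center[2])^2) <= radius
}

# Digital axis-aligned ellipse mask with semi-axes (a, b).
ellipse_mask <- function(n, center, a, b) {
  rr <- outer(0:(n - 1), rep(1, n))
  cc <- t(rr)
  ((rr - center[1]) / a)^2 + ((cc - center[2]) / b)^2 <= 1
}

# Iterative flood-fill connected-components labelling (8-connectivity);
# independent of the package's graph-based labelling.
flood_label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nextlab <- 0L
  nr <- nrow(mask); nc <- ncol(mask)
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    stack <- start
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[p] != 0L) next
      lab[p] <- nextlab
      r <- ((p - 1L) %% nr) + 1L; c_ <- ((p - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr; c2 <- c_ + dc
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
          q <- (c2 - 1L) * nr + r2
          if (mask[q] && lab[q] == 0L) stack <- c(stack, q)
        }
      }
    }
  }
  lab
}

# Closed-form Welch t statistic and two-sided p value.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# Brute-force concordance category counting by enumerating votes per event.
concordance_oracle <- function(mat) {
  R <- ncol(mat)
  counts <- c(unanimous_positive = 0, unanimous_negative = 0,
              five_agree = 0, four_agree = 0, three_indifferent = 0)
  for (i in seq_len(nrow(mat))) {
    v <- 0
    for (j in seq_len(R)) if (mat[i, j]) v <- v + 1
    if (2 * v == R) counts["three_indifferent"] <-
        counts["three_indifferent"] + 1
    else if (v == R) counts["unanimous_positive"] <-
        counts["unanimous_positive"] + 1
    else if (v == 0) counts["unanimous_negative"] <-
        counts["unanimous_negative"] + 1
    else if (min(v, R - v) == 1) counts["five_agree"] <-
        counts["five_agree"] + 1
    else counts["four_agree"] <- counts["four_agree"] + 1
  }
  counts / nrow(mat)
}

# Normal-equations least squares (explicit matrix algebra).
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- X %*% beta
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2], r2 = r2)
}

# Ray-casting point-in-polygon (inclusive of boundary within eps).
sp_point_in_polygon <- function(points, ring) {
  n <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  apply(points, 1, function(p) {
    x <- p[1]; y <- p[2]
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      on_edge <- FALSE
      # boundary tolerance: distance to segment < 1e-9 counts as inside
      if ((ys[i] > y) != (ys[j] > y)) {
        xint <- xs[i] + (y - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i])
        if (abs(x - xint) < 1e-9) on_edge <- TRUE
        if (x < xint) inside <- !inside
      }
      if (on_edge) return(TRUE)
      j <- i
    }
    inside
  })
}

# Unweighted centroid of a segmented object's mask, 0-based.
mask_centroid_of <- function(object) {
  idx <- which(object$mask, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2])) - 1
}

# A rescaled frame wrapping a plain matrix (bypasses the archive path).
as_rescaled_frame <- function(pixels, channel = "MARKER1") {
  fluorescent_frame(pixels, channel, stored_bit_depth = 8L,
                    header_min = 0, header_max = 4095,
                    is_rescaled = TRUE)
}

# A segmented_object built directly from a mask via the package's public
# segmentation path is not available; tests that need one use the internal
# constructor through an exported-measure route: segment a synthetic frame
# whose thresholded support equals the wanted mask.
object_from_mask <- function(mask) {
  px <- matrix(0, nrow(mask), ncol(mask))
  px[mask] <- 1000
  segment_multiscale(as_rescaled_frame(px))[[1]]
}
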