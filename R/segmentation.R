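# Internal segmentation constants. All intensity cut-offs derive from the
# background model; none is a user-tunable threshold.
BG_EXCEEDANCE_K <- 3        # background exceedance, mu + k*sigma
MIN_OBJECT_AREA <- 4L       # px; suppresses single-pixel noise
SEG_SCALES <- c(3, 2, 1, 0) # Gaussian smoothing sigmas, coarse -> fine
AREA_STABILITY <- 0.2       # relative area change defining scale stability

#' Estimate a robust background model for a frame
#'
#' Location and scale of the non-object pixel population, estimated robustly
#' as the median and 1.4826 times the median absolute deviation so that a
#' bright object covering a minority of pixels does not bias the estimate.
#' A constant frame yields `(constant, 0)`.
#'
#' @param frame A rescaled [fluorescent_frame].
#' @return An object of class `background_model` with fields `mu`, `sigma`.
#' @export
estimate_background <- function(frame) {
  stopifnot(inherits(frame, "fluorescent_frame"))
  if (!frame$is_rescaled)
    stop("background is estimated on rescaled frames", call. = FALSE)
  px <- as.numeric(frame$pixels)
  structure(list(mu = stats::median(px), sigma = stats::mad(px)),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model mu=%.3f sigma=%.3f>\n", x$mu, x$sigma))
  invisible(x)
}

# Separable Gaussian smoothing with replicate boundary (preserves constants,
# so segmentation is invariant to a global intensity offset). sigma = 0
# returns the input unchanged.
gaussian_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  g <- stats::dnorm(-r:r, sd = sigma)
  k <- outer(g, g)
  k <- k / sum(k)
  out <- EBImage::filter2(mat, k, boundary = "replicate")
  matrix(as.numeric(out), nrow(mat), ncol(mat))
}

# 8-connected labelling of a logical mask via the pixel adjacency graph.
# Returns an integer matrix of labels (0 = background).
label_components_8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  nr <- nrow(mask)
  pos <- matrix(0L, nrow(mask), ncol(mask))
  pos[idx] <- seq_along(idx)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  edges <- NULL
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    r2 <- rr + d[1]; c2 <- cc + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    nb <- pos[cbind(r2[ok], c2[ok])]
    keep <- nb > 0L
    if (any(keep))
      edges <- rbind(edges, cbind(pos[idx[ok]][keep], nb[keep]))
  }
  if (is.null(edges)) {
    comp <- seq_along(idx)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  }
  lab[idx] <- as.integer(comp)
  lab
}

# Mid-crack contour(s) of a mask: the 0.5-level isoline of the zero-padded
# binary grid, whose vertices sit at pixel-boundary midpoints. Coordinates
# are 0-based (row, col) pixel centers. Rings are returned outer-first
# (longest first); orientation normalized counter-clockwise in (row, col)
# axes by signed area.
trace_contours <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask * 1
  cl <- grDevices::contourLines(x = seq_len(nr + 2L), y = seq_len(nc + 2L),
                                z = p, levels = 0.5)
  rings <- lapply(cl, function(s) {
    ring <- cbind(row = s$x - 2, col = s$y - 2)  # back to 0-based centers
    n <- nrow(ring)
    if (n >= 3) {
      a <- sum(ring[, 1] * c(ring[-1, 2], ring[1, 2]) -
               c(ring[-1, 1], ring[1, 1]) * ring[, 2]) / 2
      if (a < 0) ring <- ring[n:1, , drop = FALSE]
    }
    ring
  })
  lens <- vapply(rings, function(r) {
    d <- diff(rbind(r, r[1, , drop = FALSE]))
    sum(sqrt(rowSums(d^2)))
  }, numeric(1))
  list(rings = rings[order(-lens)], perimeter = sum(lens))
}

# Build a segmented_object from a labelled component mask.
make_segmented_object <- function(mask, channel, scale_index) {
  ct <- trace_contours(mask)
  structure(list(channel = channel, mask = mask,
                 contour = ct$rings[[1]], rings = ct$rings,
                 perimeter = ct$perimeter,
                 scale_index = as.integer(scale_index),
                 area_px = sum(mask)),
            class = "segmented_object")
}

#' @export
print.segmented_object <- function(x, ...) {
  cat(sprintf("<segmented_object %s area=%d px (scale %d)>\n",
              x$channel, x$area_px, x$scale_index))
  invisible(x)
}

# Detections at a single smoothing scale: threshold the smoothed frame at
# the raw frame's background level mu + k*sigma (strict; one threshold for
# all scales keeps areas comparable across scales so stability merging is
# meaningful), label 8-connected, drop small components, and require
# support in the raw frame (>= MIN_OBJECT_AREA raw pixels above the same
# threshold) so smoothing-induced noise clusters never pass.
detect_at_scale <- function(raw, smoothed, raw_thr, mu) {
  lab <- label_components_8(smoothed > raw_thr)
  n <- max(lab)
  if (n == 0L) return(list())
  out <- list()
  for (i in seq_len(n)) {
    m <- lab == i
    if (sum(m) < MIN_OBJECT_AREA) next
    if (sum(raw[m] > raw_thr) < MIN_OBJECT_AREA) next
    m <- refine_halfmax(smoothed, m, mu, raw_thr)
    if (is.null(m) || sum(m) < MIN_OBJECT_AREA) next
    out[[length(out) + 1L]] <- m
  }
  out
}

# Contour refinement at half maximum above background. Gaussian smoothing
# of a step edge leaves the half-maximum crossing at the edge position, so
# this contour is (approximately) invariant across smoothing scales — it is
# what makes cross-scale area stability meaningful — and it places the
# boundary at the object's intensity plateau rather than at the background
# noise floor. The level never drops below the background exceedance
# threshold; both cut-offs derive from the background model and the
# object's own peak, so no tunable parameter is introduced.
refine_halfmax <- function(smoothed, cand, mu, raw_thr) {
  vals <- smoothed[cand]
  peak <- max(vals)
  thr2 <- max(raw_thr, mu + (peak - mu) / 2)
  m2 <- (smoothed > thr2) & cand
  if (!any(m2)) return(NULL)
  lab <- label_components_8(m2)
  peak_pos <- which(cand)[which.max(vals)]
  keep <- lab[peak_pos]
  if (keep == 0L) keep <- max(1L, lab[which(m2)[1]])
  lab == keep
}

#' Multi-scale object segmentation of one channel
#'
#' Detects object outlines in a rescaled frame with a parameter-free
#' multi-scale procedure: the frame is evaluated at a monotone sequence of
#' Gaussian smoothing scales (coarse to fine, sigmas 3, 2, 1, 0 px); at
#' every scale, pixels exceeding the raw frame's robust background level by
#' three background standard deviations form candidate objects
#' (8-connected, minimum 4 px, and required to be supported by at least
#' 4 raw pixels above the same level); each candidate's contour is then
#' refined at half maximum above background, the level a Gaussian-blurred
#' edge preserves across scales. Candidates are merged across scales: an object found
#' at several scales is reported once, keeping the finest-scale contour
#' whose area is stable (relative change below 20%) against the next
#' coarser scale. All cut-offs derive from the background model; no user
#' threshold exists. A frame that is pure background returns an empty list —
#' this is the separating gap that encodes marker negativity as a mean
#' intensity of exactly zero downstream.
#'
#' @param frame A rescaled [fluorescent_frame].
#' @return List of `segmented_object`s (possibly empty); deterministic.
#' @export
segment_multiscale <- function(frame) {
  stopifnot(inherits(frame, "fluorescent_frame"))
  if (!frame$is_rescaled)
    stop("segment_multiscale requires a rescaled frame", call. = FALSE)
  raw <- frame$pixels
  bg0 <- estimate_background(frame)
  raw_thr <- bg0$mu + BG_EXCEEDANCE_K * bg0$sigma

  per_scale <- lapply(seq_along(SEG_SCALES), function(si) {
    sm <- gaussian_smooth(raw, SEG_SCALES[si])
    detect_at_scale(raw, sm, raw_thr, bg0$mu)
  })
  n_per <- lengths(per_scale)
  if (sum(n_per) == 0L) return(list())

  # flatten; id -> (scale, mask, area)
  masks <- do.call(c, per_scale)
  scale_of <- rep(seq_along(SEG_SCALES), n_per)
  areas <- vapply(masks, sum, numeric(1))
  nobj <- length(masks)

  # overlap links between consecutive scales; parent = best-overlap object
  # at the next coarser scale
  parent <- rep(NA_integer_, nobj)
  for (i in seq_len(nobj)) {
    s <- scale_of[i]
    if (s == 1L) next
    coarser <- which(scale_of == s - 1L)
    if (!length(coarser)) next
    ov <- vapply(coarser, function(j) sum(masks[[i]] & masks[[j]]), numeric(1))
    if (max(ov) > 0) parent[i] <- coarser[which.max(ov)]
  }

  # group tracks: connected components of the parent links plus any residual
  # mask overlap (so duplicates across non-consecutive scales still merge)
  edges <- cbind(which(!is.na(parent)), parent[!is.na(parent)])
  extra <- NULL
  for (i in seq_len(nobj)) for (j in seq_len(nobj)) {
    if (i < j && abs(scale_of[i] - scale_of[j]) > 1L &&
        sum(masks[[i]] & masks[[j]]) > 0)
      extra <- rbind(extra, c(i, j))
  }
  edges <- rbind(edges, extra)
  if (is.null(edges) || nrow(edges) == 0L) {
    grp <- seq_len(nobj)
  } else {
    g <- igraph::make_empty_graph(nobj, directed = FALSE)
    g <- igraph::add_edges(g, t(edges))
    grp <- igraph::components(g)$membership
  }

  stable <- vapply(seq_len(nobj), function(i) {
    if (is.na(parent[i])) return(TRUE)  # first appearance counts as stable
    abs(areas[i] - areas[parent[i]]) / areas[parent[i]] < AREA_STABILITY
  }, logical(1))

  chosen <- integer(0)
  for (gid in unique(grp)) {
    members <- which(grp == gid)
    finest <- members[scale_of[members] == max(scale_of[members])]
    for (leaf in finest) {
      # walk the chain towards coarser scales; pick the finest stable link
      chain <- leaf
      while (!is.na(parent[chain[length(chain)]]))
        chain <- c(chain, parent[chain[length(chain)]])
      pick <- chain[which(stable[chain])[1]]
      if (is.na(pick)) pick <- chain[length(chain)]
      chosen <- c(chosen, pick)
    }
  }
  chosen <- unique(chosen)

  # drop nested duplicates (a mask fully contained in another)
  if (length(chosen) > 1L) {
    drop <- logical(length(chosen))
    for (a in seq_along(chosen)) for (b in seq_along(chosen)) {
      if (a == b || drop[a]) next
      ma <- masks[[chosen[a]]]; mb <- masks[[chosen[b]]]
      if (all(!(ma & !mb)) && (sum(mb) > sum(ma) || b < a)) drop[a] <- TRUE
    }
    chosen <- chosen[!drop]
  }

  lapply(chosen, function(i)
    make_segmented_object(masks[[i]], frame$channel, scale_of[i]))
}

# Unweighted mask centroid, 0-based (row, col) pixel-center coordinates.
mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(row = mean(idx[, 1]) - 1, col = mean(idx[, 2]) - 1)
}

#' Select the event-defining object of a channel
#'
#' When a channel's segmentation yields several objects, the one belonging
#' to the event is chosen as the object with the largest pixel overlap with
#' the nuclear (DAPI) mask; ties break towards the larger object, then the
#' object whose centroid is closest to the thumbnail center.
#'
#' @param objects List of `segmented_object`s from one channel.
#' @param nucleus_mask Logical matrix: DAPI mask of the same thumbnail (may
#'   be all-`FALSE` when no nucleus was found).
#' @return A single `segmented_object`, or `NULL` when `objects` is empty.
#' @export
select_event_object <- function(objects, nucleus_mask) {
  if (!length(objects)) return(NULL)
  ov <- vapply(objects, function(o) sum(o$mask & nucleus_mask), numeric(1))
  ar <- vapply(objects, function(o) o$area_px, numeric(1))
  ctr <- (dim(nucleus_mask) - 1) / 2
  dc <- vapply(objects, function(o) {
    cen <- mask_centroid(o$mask)
    sqrt(sum((cen - ctr)^2))
  }, numeric(1))
  objects[[order(-ov, -ar, dc)[1]]]
}
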