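MEASUREMENT_FIELDS <- c("eccentricity", "perimeter", "mean_intensity",
                        "max_intensity", "size", "std_intensity", "mass",
                        "perimeter2area")

#' Measure one channel of an event
#'
#' Computes the per-object, per-channel feature vector: eccentricity
#' (moment-based, `sqrt(1 - (minor/major)^2)`), perimeter (length of the
#' mid-crack contour polygon, vertices at pixel-boundary midpoints),
#' mean / maximum / standard deviation of intensity inside the contour,
#' size (pixel count), mass (sum of intensities) and perimeter2area, the
#' circularity `perimeter^2 / (4 * pi * size)` normalized so a perfect disk
#' gives 1. Intensities are the rescaled values inside the mask with no
#' background subtraction: marker negativity is encoded purely by the
#' absence of a segmented object, in which case every field is zero.
#'
#' @param object A `segmented_object`, or `NULL` when the channel had no
#'   detectable signal.
#' @param frame The channel's rescaled [fluorescent_frame]; its dimensions
#'   must match the object's mask.
#' @return An object of class `channel_measurements` (a named list with the
#'   eight fields above).
#' @export
measure_channel <- function(object, frame) {
  if (is.null(object)) {
    m <- as.list(stats::setNames(numeric(length(MEASUREMENT_FIELDS)),
                                 MEASUREMENT_FIELDS))
    m$size <- 0L
    return(structure(m, class = "channel_measurements"))
  }
  stopifnot(inherits(object, "segmented_object"),
            inherits(frame, "fluorescent_frame"))
  if (!identical(dim(object$mask), dim(frame$pixels)))
    stop("object mask and frame dimensions differ", call. = FALSE)
  vals <- frame$pixels[object$mask]
  size <- length(vals)
  mom <- mask_moments(object$mask)
  per <- object$perimeter
  structure(list(
    eccentricity = mom$eccentricity,
    perimeter = per,
    mean_intensity = mean(vals),
    max_intensity = max(vals),
    size = size,
    std_intensity = if (size > 1L) stats::sd(vals) else 0,
    mass = sum(vals),
    perimeter2area = per^2 / (4 * pi * size)),
    class = "channel_measurements")
}

# Central second moments of a mask and the derived eccentricity. The 1/12
# term accounts for each pixel's own unit extent so a single pixel has the
# moments of a unit square (eccentricity 0).
mask_moments <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  r <- idx[, 1] - mean(idx[, 1])
  c_ <- idx[, 2] - mean(idx[, 2])
  mu20 <- mean(r^2) + 1 / 12
  mu02 <- mean(c_^2) + 1 / 12
  mu11 <- mean(r * c_)
  tr <- mu20 + mu02
  det_ <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(0, (tr / 2)^2 - det_))
  l1 <- tr / 2 + disc  # major-axis variance
  l2 <- tr / 2 - disc  # minor-axis variance
  ecc <- if (l1 <= 0) 0 else sqrt(max(0, 1 - l2 / l1))
  list(mu20 = mu20, mu02 = mu02, mu11 = mu11, eccentricity = ecc, n = n)
}

#' @export
print.channel_measurements <- function(x, ...) {
  cat(sprintf("<channel_measurements size=%d mean=%.2f mass=%.1f>\n",
              x$size, x$mean_intensity, x$mass))
  invisible(x)
}

#' Relative overlay of two channel masks
#'
#' Fraction of mask `a`'s area shared with mask `b`, `|a intersect b| / |a|`.
#' By convention `a` is the DAPI (nuclear) mask; an empty `a` gives 0.
#'
#' @param mask_a,mask_b Congruent logical matrices.
#' @return A fraction in `[0, 1]`.
#' @export
relative_overlay <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("overlay masks must have identical dimensions", call. = FALSE)
  na <- sum(mask_a)
  if (na == 0L) return(0)
  sum(mask_a & mask_b) / na
}

#' Measure all channels of a thumbnail
#'
#' Runs the full per-event pipeline: rescales every frame, segments each
#' channel independently with [segment_multiscale()], selects the
#' event-defining object per channel via the DAPI nucleus mask, measures
#' each channel with [measure_channel()], and computes the DAPI/CD45 and
#' DAPI/CK relative overlays. Deterministic for a given thumbnail.
#'
#' @param thumb An [event_thumbnail] (frames may be archived or rescaled).
#' @return An object of class `event_record`: identifiers, a
#'   `channel_measurements` per channel, both overlays, the median marker
#'   intensity inside the marker contour (`marker_median`), and a
#'   `her2_class` slot filled by the scoring step (`NA` until then).
#' @export
measure_event <- function(thumb) {
  stopifnot(inherits(thumb, "event_thumbnail"))
  thumb <- rescale_thumbnail(thumb)
  objects <- lapply(thumb$frames, segment_multiscale)
  d <- dim(thumb$frames$DAPI$pixels)
  empty <- matrix(FALSE, d[1], d[2])
  dapi_obj <- select_event_object(objects$DAPI, empty)
  nucleus <- if (is.null(dapi_obj)) empty else dapi_obj$mask
  selected <- lapply(CHANNELS, function(ch) {
    if (ch == "DAPI") dapi_obj
    else select_event_object(objects[[ch]], nucleus)
  })
  names(selected) <- CHANNELS
  meas <- lapply(CHANNELS, function(ch)
    measure_channel(selected[[ch]], thumb$frames[[ch]]))
  names(meas) <- CHANNELS
  mask_of <- function(o) if (is.null(o)) empty else o$mask
  marker_px <- thumb$frames$MARKER1$pixels[mask_of(selected$MARKER1)]
  structure(list(
    event_id = thumb$event_id, sample_id = thumb$sample_id,
    patient_id = thumb$patient_id,
    measurements = meas,
    dapi_cd45_overlay = relative_overlay(nucleus, mask_of(selected$CD45)),
    dapi_ck_overlay = relative_overlay(nucleus, mask_of(selected$CK)),
    marker_median = if (length(marker_px)) stats::median(marker_px) else 0,
    manual_score = thumb$manual_score,
    her2_class = NA_character_),
    class = "event_record")
}

#' @export
print.event_record <- function(x, ...) {
  cat(sprintf("<event_record %s marker mean=%.2f class=%s>\n", x$event_id,
              x$measurements$MARKER1$mean_intensity, x$her2_class))
  invisible(x)
}

#' Flatten event records to the tabular schema
#'
#' One row per event with columns `<channel>_<feature>` for all four
#' channels (channels `dapi, ck, cd45, marker1`; features
#' `ecc, perim, mean, max, size, std, mass, p2a`), the two overlays, and
#' the median marker intensity.
#'
#' @param records List of `event_record`s (or a single one).
#' @return A data.frame, one row per event.
#' @export
records_to_table <- function(records) {
  if (inherits(records, "event_record")) records <- list(records)
  feat_short <- c(eccentricity = "ecc", perimeter = "perim",
                  mean_intensity = "mean", max_intensity = "max",
                  size = "size", std_intensity = "std", mass = "mass",
                  perimeter2area = "p2a")
  rows <- lapply(records, function(r) {
    vals <- unlist(lapply(CHANNELS, function(ch) {
      m <- r$measurements[[ch]]
      stats::setNames(as.numeric(m[MEASUREMENT_FIELDS]),
                      paste0(tolower(ch), "_", feat_short[MEASUREMENT_FIELDS]))
    }))
    cbind(data.frame(event_id = r$event_id, sample_id = r$sample_id,
                     patient_id = r$patient_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(vals)),
          data.frame(dapi_cd45_overlay = r$dapi_cd45_overlay,
                     dapi_ck_overlay = r$dapi_ck_overlay,
                     marker1_median = r$marker_median))
  })
  do.call(rbind, rows)
}

#' Two-sided Welch test on two pixel-intensity samples
#'
#' Tests whether the in-contour marker intensities of two events differ in
#' mean, treating pixels as independent samples (spatial correlation within
#' a cell is ignored; see the methods vignette for the caveat).
#'
#' @param pixels_a,pixels_b Numeric vectors of in-contour pixel values, each
#'   of length at least 2.
#' @return List with `t_statistic`, `p_value`, `df`.
#' @export
intensity_difference_test <- function(pixels_a, pixels_b) {
  if (length(pixels_a) < 2L || length(pixels_b) < 2L)
    stop("both pixel samples need at least 2 values", call. = FALSE)
  if (stats::sd(pixels_a) == 0 && stats::sd(pixels_b) == 0) {
    d <- mean(pixels_a) - mean(pixels_b)
    if (d == 0) return(list(t_statistic = 0, p_value = 1, df = Inf))
    return(list(t_statistic = sign(d) * Inf, p_value = 0, df = Inf))
  }
  ht <- stats::t.test(pixels_a, pixels_b, var.equal = FALSE,
                      alternative = "two.sided")
  list(t_statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Fit the antigen calibration line
#'
#' Ordinary least-squares line relating measured marker intensity per cell
#' line to the antigen count determined by bead-calibrated flow cytometry,
#' turning instrument intensity units into antigens per cell.
#'
#' @param intensity Numeric vector of per-cell-line mean (or median) marker
#'   intensities; at least two distinct values.
#' @param antigens Numeric vector of matching antigen counts.
#' @return Object of class `calibration_line` with `slope` (antigens per
#'   intensity unit), `intercept` (antigens) and `r_squared`.
#' @export
fit_antigen_calibration <- function(intensity, antigens) {
  if (length(intensity) != length(antigens))
    stop("intensity and antigen vectors must be paired", call. = FALSE)
  if (length(intensity) < 2L)
    stop("calibration needs at least two points", call. = FALSE)
  if (diff(range(intensity)) == 0)
    stop("degenerate fit: all intensities identical", call. = FALSE)
  fit <- stats::lm(antigens ~ intensity)
  ss_tot <- sum((antigens - mean(antigens))^2)
  r2 <- if (ss_tot == 0) 1
        else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2),
            class = "calibration_line")
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf("<calibration_line antigens = %.1f + %.1f * intensity, r2 = %.4f>\n",
              x$intercept, x$slope, x$r_squared))
  invisible(x)
}
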