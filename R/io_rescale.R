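# Channel vocabulary used throughout: nuclear stain, cytokeratin, leukocyte
# marker, and the treatment-target marker channel.
CHANNELS <- c("DAPI", "CK", "CD45", "MARKER1")

# Full scale of the instrument's 12-bit dynamic range.
FULL_SCALE_12BIT <- 4095

#' Construct a single-channel fluorescence frame
#'
#' A frame holds one channel's pixel grid together with the archive metadata
#' needed to restore the native intensity scale: the stored bit depth and the
#' original per-channel minimum/maximum recorded when the acquisition was
#' archived to 8 bit.
#'
#' @param pixels Numeric matrix of non-negative pixel values (rows = image
#'   rows, 0-based pixel-center coordinates are used downstream).
#' @param channel One of `"DAPI"`, `"CK"`, `"CD45"`, `"MARKER1"`.
#' @param stored_bit_depth Integer; 8 for archived thumbnails, 12 for native.
#' @param header_min,header_max Original channel minimum/maximum on the
#'   12-bit scale (0 to 4095) recorded at archive time.
#' @param pixel_size_um Physical pixel pitch in micrometres (default 0.64).
#' @param is_rescaled Logical; `TRUE` once pixels are back on the native
#'   intensity scale.
#' @return An object of class `fluorescent_frame`.
#' @export
fluorescent_frame <- function(pixels, channel, stored_bit_depth = 8L,
                              header_min = 0, header_max = NULL,
                              pixel_size_um = 0.64, is_rescaled = FALSE) {
  channel <- match.arg(channel, CHANNELS)
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("frame pixels must be a non-empty rectangular matrix", call. = FALSE)
  if (anyNA(pixels) || any(pixels < 0))
    stop("frame pixels must be non-negative and free of NA", call. = FALSE)
  if (is.null(header_max))
    header_max <- 2^stored_bit_depth - 1
  if (header_min < 0 || header_max > FULL_SCALE_12BIT)
    stop("header min/max must lie within [0, ", FULL_SCALE_12BIT, "]",
         call. = FALSE)
  if (header_max < header_min)
    stop("header_max < header_min: malformed archive header", call. = FALSE)
  if (pixel_size_um <= 0)
    stop("pixel_size_um must be positive", call. = FALSE)
  structure(
    list(pixels = pixels, channel = channel,
         stored_bit_depth = as.integer(stored_bit_depth),
         header_min = header_min, header_max = header_max,
         pixel_size_um = pixel_size_um, is_rescaled = isTRUE(is_rescaled)),
    class = "fluorescent_frame")
}

#' @export
print.fluorescent_frame <- function(x, ...) {
  cat(sprintf("<fluorescent_frame %s %dx%d %d-bit %s header=[%g, %g]>\n",
              x$channel, nrow(x$pixels), ncol(x$pixels), x$stored_bit_depth,
              if (x$is_rescaled) "rescaled" else "archived",
              x$header_min, x$header_max))
  invisible(x)
}

#' Construct a per-event thumbnail bundle
#'
#' Bundles the four aligned channel frames of one candidate event together
#' with its identifiers and, optionally, a manual ordinal marker score.
#'
#' @param frames Named list of [fluorescent_frame] objects covering all four
#'   channels; identical dimensions and pixel size required.
#' @param event_id,sample_id,patient_id Identifier strings.
#' @param manual_score Optional manual ordinal score in `0:3` (0, 1+, 2+, 3+).
#' @return An object of class `event_thumbnail`.
#' @export
event_thumbnail <- function(frames, event_id, sample_id = event_id,
                            patient_id = sample_id, manual_score = NA_integer_) {
  if (!setequal(names(frames), CHANNELS))
    stop("thumbnail needs exactly the four channels ",
         paste(CHANNELS, collapse = ", "), call. = FALSE)
  frames <- frames[CHANNELS]
  dims <- vapply(frames, function(f) dim(f$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all channel frames must share identical dimensions", call. = FALSE)
  px <- vapply(frames, function(f) f$pixel_size_um, numeric(1))
  if (diff(range(px)) > 1e-12)
    stop("all channel frames must share pixel_size_um", call. = FALSE)
  if (!is.na(manual_score) && !(manual_score %in% 0:3))
    stop("manual_score must be in 0:3 (0, 1+, 2+, 3+)", call. = FALSE)
  structure(list(frames = frames, event_id = as.character(event_id),
                 sample_id = as.character(sample_id),
                 patient_id = as.character(patient_id),
                 manual_score = manual_score),
            class = "event_thumbnail")
}

#' @export
print.event_thumbnail <- function(x, ...) {
  d <- dim(x$frames[[1]]$pixels)
  cat(sprintf("<event_thumbnail %s (patient %s) %dx%d, 4 channels>\n",
              x$event_id, x$patient_id, d[1], d[2]))
  invisible(x)
}

#' Default archive-header parser
#'
#' Returns a parser function used by [load_thumbnail()] to recover the
#' original per-channel minimum and maximum written at archive time. The
#' default convention accepts either
#' \itemize{
#'   \item an ImageDescription string of the form `"min=<int>;max=<int>"`
#'     attached to the TIFF frame, or
#'   \item a sidecar JSON file `<tiff>.hdr.json` mapping each channel name to
#'     `{"min": <int>, "max": <int>}` (the convention the fixture writer
#'     emits).
#' }
#' Alternative parsers for other vendor dialects can be supplied to
#' [load_thumbnail()]; a parser is any `function(path, channel, frame_info)`
#' returning `c(min, max)` or `NULL` when the header is absent.
#'
#' @return A parser function.
#' @export
header_parser_default <- function() {
  function(path, channel, frame_info) {
    desc <- frame_info$description
    if (!is.null(desc) && grepl("min=", desc, fixed = TRUE)) {
      mn <- sub(".*min=([0-9.]+).*", "\\1", desc)
      mx <- sub(".*max=([0-9.]+).*", "\\1", desc)
      return(c(as.numeric(mn), as.numeric(mx)))
    }
    sidecar <- paste0(path, ".hdr.json")
    if (file.exists(sidecar)) {
      hdr <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      if (!is.null(hdr[[channel]]))
        return(c(hdr[[channel]]$min, hdr[[channel]]$max))
    }
    NULL
  }
}

#' Load an archived multi-frame thumbnail TIFF
#'
#' Reads a multi-frame grayscale TIFF holding the four channels of one
#' event. Pixels are returned on the stored (archived) scale; call
#' [rescale_frame()] or [measure_event()] to restore native intensities.
#' When a frame carries no archive header, the full stored range
#' `(0, 2^bits - 1)` is assumed and a warning is emitted.
#'
#' @param path Path to the TIFF file.
#' @param channel_map Named integer vector mapping each channel name to its
#'   frame index within the TIFF, e.g. `c(DAPI = 1, CK = 2, CD45 = 3,
#'   MARKER1 = 4)`. Channel order is configuration, never a positional
#'   assumption.
#' @param header_parser Archive-header parser; see [header_parser_default()].
#' @param pixel_size_um Pixel pitch in micrometres.
#' @param event_id,sample_id,patient_id Identifiers; default to the file stem.
#' @return An [event_thumbnail] with un-rescaled frames.
#' @export
load_thumbnail <- function(path,
                           channel_map = c(DAPI = 1L, CK = 2L, CD45 = 3L,
                                           MARKER1 = 4L),
                           header_parser = header_parser_default(),
                           pixel_size_um = 0.64,
                           event_id = NULL, sample_id = NULL,
                           patient_id = NULL) {
  if (!file.exists(path))
    stop("cannot read TIFF: file does not exist: ", path, call. = FALSE)
  if (!setequal(names(channel_map), CHANNELS))
    stop("channel_map must cover all four channels ",
         paste(CHANNELS, collapse = ", "), call. = FALSE)
  frames_raw <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE),
    error = function(e) stop("cannot read TIFF ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (!is.list(frames_raw)) frames_raw <- list(frames_raw)
  if (max(channel_map) > length(frames_raw))
    stop("channel_map refers to frame ", max(channel_map), " but ", path,
         " has only ", length(frames_raw), " frame(s)", call. = FALSE)

  stem <- sub("\\.tiff?$", "", basename(path), ignore.case = TRUE)
  if (is.null(event_id)) event_id <- stem
  if (is.null(sample_id)) sample_id <- event_id
  if (is.null(patient_id)) patient_id <- sample_id

  frames <- lapply(CHANNELS, function(ch) {
    img <- frames_raw[[channel_map[[ch]]]]
    if (is.null(dim(img)) || any(dim(img) == 0L))
      stop("frame ", channel_map[[ch]], " of ", path,
           " is not a non-empty rectangular image", call. = FALSE)
    if (length(dim(img)) == 3L) img <- img[, , 1L]  # grayscale stored as planes
    bits <- attr(img, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
    info <- attributes(img)
    hdr <- header_parser(path, ch, info)
    if (is.null(hdr)) {
      hdr <- c(0, 2^bits - 1)
      warning("no archive header for channel ", ch, " in ", path,
              "; assuming full stored range (", hdr[1], ", ", hdr[2], ")",
              call. = FALSE)
    }
    fluorescent_frame(matrix(as.numeric(img), nrow(img), ncol(img)),
                      channel = ch, stored_bit_depth = bits,
                      header_min = hdr[1], header_max = hdr[2],
                      pixel_size_um = pixel_size_um, is_rescaled = FALSE)
  })
  names(frames) <- CHANNELS
  event_thumbnail(frames, event_id, sample_id, patient_id)
}

#' Restore a frame to its native intensity scale
#'
#' Archived thumbnails are stored as 8-bit images whose brightness was
#' adjusted relative to the brightest pixel of the channel. The original
#' minimum and maximum recorded in the archive header invert that scaling:
#' each stored pixel `p` maps to
#' `header_min + p * (header_max - header_min) / 255`.
#' The map is affine and order-preserving; restored values are kept as
#' non-integer numbers (no re-quantization), so downstream thresholding on
#' means is not distorted.
#'
#' @param frame An un-rescaled 8-bit [fluorescent_frame].
#' @return The frame with pixels on the native scale and `is_rescaled = TRUE`.
#' @export
rescale_frame <- function(frame) {
  stopifnot(inherits(frame, "fluorescent_frame"))
  if (frame$is_rescaled)
    stop("frame is already rescaled", call. = FALSE)
  if (frame$stored_bit_depth != 8L)
    stop("only 8-bit archived frames are rescaled (got ",
         frame$stored_bit_depth, "-bit)", call. = FALSE)
  if (frame$header_max < frame$header_min)
    stop("header_max < header_min: malformed archive header", call. = FALSE)
  span <- frame$header_max - frame$header_min
  frame$pixels <- frame$header_min + frame$pixels * span / 255
  frame$is_rescaled <- TRUE
  frame
}

# Rescale every frame of a thumbnail (frames already rescaled are passed
# through unchanged).
rescale_thumbnail <- function(thumb) {
  thumb$frames <- lapply(thumb$frames, function(f)
    if (f$is_rescaled) f else rescale_frame(f))
  thumb
}

#' Read a per-event score table
#'
#' Reads a CSV with header `event_id,scorer_id,score` where `score` is
#' either an ordinal manual call (`0`, `1+`, `2+`, `3+`) or a binary call
#' (`positive` / `negative`). Ordinal tokens map to integers 0 to 3.
#'
#' @param path CSV path.
#' @return A data.frame with columns `event_id`, `scorer_id`, `score`
#'   (integer 0-3 for ordinal rows, `"positive"`/`"negative"` kept as
#'   character for binary rows) and `score_type` (`"ordinal"`/`"binary"`).
#' @export
read_score_table <- function(path) {
  if (!file.exists(path))
    stop("score table does not exist: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("event_id", "scorer_id", "score")
  if (!all(need %in% names(df)))
    stop("score table must have header columns ",
         paste(need, collapse = ","), call. = FALSE)
  ord_map <- c("0" = 0L, "1+" = 1L, "2+" = 2L, "3+" = 3L,
               "1" = 1L, "2" = 2L, "3" = 3L)
  tok <- trimws(df$score)
  is_ord <- tok %in% names(ord_map)
  is_bin <- tolower(tok) %in% c("positive", "negative")
  bad <- which(!is_ord & !is_bin)
  if (length(bad))
    stop("unknown score token '", tok[bad[1]], "' at data row ", bad[1],
         " of ", path, call. = FALSE)
  df$score_type <- ifelse(is_ord, "ordinal", "binary")
  df$score <- ifelse(is_ord, as.character(ord_map[tok]), tolower(tok))
  df[c("event_id", "scorer_id", "score", "score_type")]
}

#' Map an ordinal manual score to binary positivity
#'
#' Manual ordinal scores of 2+ or 3+ count as marker-positive.
#'
#' @param ordinal Integer vector of ordinal scores in 0:3.
#' @return Character vector `"positive"`/`"negative"`.
#' @export
ordinal_to_binary <- function(ordinal) {
  stopifnot(all(ordinal %in% 0:3))
  ifelse(ordinal >= 2L, "positive", "negative")
}
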