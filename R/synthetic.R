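# Reference background noise level: standard deviation of the background
# signal in archived thumbnails, used as the fixture default.
BG_SIGMA_DEFAULT <- 6.6

#' Specify a synthetic event thumbnail
#'
#' Describes one synthetic four-channel thumbnail: per-channel blob
#' descriptors (a flat-top disk of known plateau intensity whose edge
#' falls off as a Gaussian skirt, so the in-mask truth mean equals the
#' plateau exactly), Gaussian background noise, and the 12-bit to 8-bit
#' archiving step with recorded per-channel min/max headers.
#'
#' @param blobs Named list over channels; each entry is `NULL` (no signal in
#'   the channel) or a list with `center` (row, col; 0-based, defaults to
#'   the thumbnail center), `radius` (px, >= 2), `plateau` (the in-disk
#'   truth intensity in `[0, 4095]`, background included; 0 means no
#'   signal, otherwise it must exceed `bg_mu`), `softness` (edge Gaussian
#'   sd in px, default 0.25 — sub-pixel, so the half-maximum contour stays inside the true disk and the plateau oracle is exact).
#' @param size Thumbnail side length in px (default 80).
#' @param bg_mu,bg_sigma Background mean and standard deviation (defaults
#'   20 and 6.6).
#' @param pixel_size_um Pixel pitch (default 0.64).
#' @param seed Integer seed making the rendering deterministic.
#' @return Object of class `event_spec`.
#' @export
event_spec <- function(blobs = list(), size = 80L, bg_mu = 20,
                       bg_sigma = BG_SIGMA_DEFAULT, pixel_size_um = 0.64,
                       seed = 1L) {
  if (!all(names(blobs) %in% CHANNELS))
    stop("blob channels must be among ", paste(CHANNELS, collapse = ", "),
         call. = FALSE)
  for (ch in names(blobs)) {
    b <- blobs[[ch]]
    if (is.null(b)) next
    if (is.null(b$radius) || b$radius < 2)
      stop("blob radius must be >= 2 px (channel ", ch, ")", call. = FALSE)
    if (is.null(b$plateau) || b$plateau < 0 ||
        b$plateau > FULL_SCALE_12BIT)
      stop("blob plateau must lie in [0, ", FULL_SCALE_12BIT, "] (channel ",
           ch, ")", call. = FALSE)
    if (b$plateau > 0 && b$plateau <= bg_mu)
      stop("blob plateau must exceed the background mean bg_mu (channel ",
           ch, "); use plateau = 0 or drop the blob for a signal-free ",
           "channel", call. = FALSE)
    if (is.null(b$center)) blobs[[ch]]$center <- c((size - 1) / 2,
                                                   (size - 1) / 2)
    if (is.null(b$softness)) blobs[[ch]]$softness <- 0.25
  }
  if (bg_mu < 0 || bg_mu > FULL_SCALE_12BIT || bg_sigma < 0)
    stop("background must satisfy 0 <= mu <= 4095 and sigma >= 0",
         call. = FALSE)
  structure(list(blobs = blobs, size = as.integer(size), bg_mu = bg_mu,
                 bg_sigma = bg_sigma, pixel_size_um = pixel_size_um,
                 seed = as.integer(seed)),
            class = "event_spec")
}

# Render one channel at 12-bit. The plateau is the in-disk truth intensity
# (what the pipeline should measure, background included), so the blob
# amplitude above background is plateau - bg_mu: inside the disk the noise-
# free value is exactly the plateau, outside it decays to the background
# along a Gaussian skirt. Values are rounded to the 12-bit integer grid.
render_channel <- function(spec, ch) {
  n <- spec$size
  img <- matrix(spec$bg_mu, n, n)
  b <- spec$blobs[[ch]]
  if (!is.null(b) && b$plateau > 0) {
    rr <- outer(0:(n - 1), rep(1, n))
    cc <- t(rr)
    d <- sqrt((rr - b$center[1])^2 + (cc - b$center[2])^2)
    amp <- b$plateau - spec$bg_mu
    img <- spec$bg_mu +
      amp * ifelse(d <= b$radius, 1,
                   exp(-(d - b$radius)^2 / (2 * b$softness^2)))
  }
  img <- img + stats::rnorm(n * n, 0, spec$bg_sigma)
  matrix(pmin(pmax(round(img), 0), FULL_SCALE_12BIT), n, n)
}

#' Generate a synthetic archived thumbnail
#'
#' Renders the four channels at 12 bit, archives them to 8 bit scaled to
#' each channel's min/max (recorded as the archive header), writes a
#' multi-frame TIFF plus the sidecar header JSON the default header parser
#' reads, and writes a ground-truth manifest. Byte-identical output per
#' seed.
#'
#' @param spec An [event_spec].
#' @param path Output TIFF path (sidecar and manifest are derived from it).
#' @param event_id,sample_id,patient_id Identifiers stored in the manifest.
#' @return Invisibly, a list with `path`, `truth` (per-channel list with
#'   `mask` — the true in-plateau disk mask —, `mean` — the plateau —,
#'   `center`, `radius`) and `headers`.
#' @export
generate_thumbnail <- function(spec, path, event_id = NULL,
                               sample_id = NULL, patient_id = NULL) {
  stopifnot(inherits(spec, "event_spec"))
  stem <- sub("\\.tiff?$", "", basename(path), ignore.case = TRUE)
  if (is.null(event_id)) event_id <- stem
  if (is.null(sample_id)) sample_id <- event_id
  if (is.null(patient_id)) patient_id <- sample_id

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  native <- lapply(CHANNELS, function(ch) render_channel(spec, ch))
  names(native) <- CHANNELS

  headers <- lapply(native, function(img)
    list(min = as.integer(min(img)), max = as.integer(max(img))))
  stored <- lapply(CHANNELS, function(ch) {
    h <- headers[[ch]]
    span <- max(1L, h$max - h$min)
    round((native[[ch]] - h$min) / span * 255) / 255  # [0,1] for writeTIFF
  })
  tiff::writeTIFF(stored, path, bits.per.sample = 8L, compression = "none")
  jsonlite::write_json(headers, paste0(path, ".hdr.json"),
                       auto_unbox = TRUE)

  n <- spec$size
  truth <- lapply(CHANNELS, function(ch) {
    b <- spec$blobs[[ch]]
    if (is.null(b) || b$plateau == 0)
      return(list(mask = matrix(FALSE, n, n), mean = 0,
                  center = NULL, radius = 0))
    rr <- outer(0:(n - 1), rep(1, n)); cc <- t(rr)
    mask <- sqrt((rr - b$center[1])^2 + (cc - b$center[2])^2) <= b$radius
    list(mask = mask, mean = b$plateau, center = b$center,
         radius = b$radius)
  })
  names(truth) <- CHANNELS

  manifest <- list(
    event_id = event_id, sample_id = sample_id, patient_id = patient_id,
    size = n, bg_mu = spec$bg_mu, bg_sigma = spec$bg_sigma,
    pixel_size_um = spec$pixel_size_um, seed = spec$seed,
    channels = lapply(CHANNELS, function(ch) {
      b <- spec$blobs[[ch]]
      c(list(header = headers[[ch]]),
        if (is.null(b)) list(true_mean = 0)
        else list(true_mean = b$plateau, center = b$center,
                  radius = b$radius, softness = b$softness))
    }))
  names(manifest$channels) <- CHANNELS
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(path = path, truth = truth, headers = headers,
                 native = native))
}

# Save/restore the global RNG state so generators are seeded locally.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Truncated-normal sampler (lower truncation at 0) by inverse CDF.
rnorm_trunc_pos <- function(n, mean, sd) {
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, p0, 1), mean, sd)
}

#' Generate a labelled cell-line-like population
#'
#' Samples per-event mean marker intensities for three ground-truth
#' classes: negative events have a mean of exactly 0 (the no-object
#' encoding), dim and bright events draw from zero-truncated normal
#' distributions that straddle the bright cut-off of 100, emulating a
#' spiked cell-line validation run with imperfect class separation. The
#' closed-form expected accuracy of the 0/100 thresholds under these
#' distributions is returned as the analytic oracle.
#'
#' Defaults mirror a three-cell-line validation: class sizes 373 / 496 /
#' 361 and dim N(86.5, 15) / bright N(113.5, 15), whose analytic accuracy
#' is about 0.87.
#'
#' @param n_negative,n_dim,n_bright Class sizes (each >= 1).
#' @param dim_mean,dim_sd,bright_mean,bright_sd Generative parameters of
#'   the dim and bright intensity distributions.
#' @param seed Integer seed.
#' @return List with `records` (data.frame `event_id`, `true_class`,
#'   `mean_intensity`) and `analytic_accuracy`.
#' @export
generate_population <- function(n_negative = 373L, n_dim = 496L,
                                n_bright = 361L, dim_mean = 86.5,
                                dim_sd = 15, bright_mean = 113.5,
                                bright_sd = 15, seed = 1L) {
  if (min(n_negative, n_dim, n_bright) < 1L)
    stop("class sizes must be >= 1", call. = FALSE)
  if (dim_mean >= 100 || dim_mean <= 0)
    stop("dim distribution must be centred in (0, 100)", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  means <- c(rep(0, n_negative),
             rnorm_trunc_pos(n_dim, dim_mean, dim_sd),
             rnorm_trunc_pos(n_bright, bright_mean, bright_sd))
  cls <- rep(HER2_CLASSES, c(n_negative, n_dim, n_bright))
  n <- length(means)
  # closed-form per-class probability of landing in the correct band
  p_dim <- (stats::pnorm(100, dim_mean, dim_sd) -
            stats::pnorm(0, dim_mean, dim_sd)) /
           (1 - stats::pnorm(0, dim_mean, dim_sd))
  p_bright <- (1 - stats::pnorm(100, bright_mean, bright_sd)) /
              (1 - stats::pnorm(0, bright_mean, bright_sd))
  analytic <- (n_negative * 1 + n_dim * p_dim + n_bright * p_bright) / n
  list(records = data.frame(event_id = sprintf("cell%04d", seq_len(n)),
                            true_class = cls, mean_intensity = means,
                            stringsAsFactors = FALSE),
       analytic_accuracy = analytic)
}

#' Generate a synthetic patient cohort
#'
#' Emulates a metastatic-cohort marker study: each patient carries an
#' overdispersed number of tumor-cell events (1 plus a negative binomial)
#' and a latent marker-positive fraction drawn from a beta distribution;
#' positive events split between dim and bright. Defaults approximate a
#' 132-patient cohort of about 4000 events with a pooled positive fraction
#' near 0.39 and bright making up about 6% of positives.
#'
#' @param n_patients Number of patients.
#' @param events_mu,events_size Negative-binomial mean and size for the
#'   per-patient event count (count = 1 + NB).
#' @param pos_shape1,pos_shape2 Beta parameters of the per-patient positive
#'   fraction.
#' @param bright_given_positive Probability a positive event is bright.
#' @param dim_mean,dim_sd,bright_mean,bright_sd Intensity distributions of
#'   dim/bright events (zero-truncated normals; dim values above 100 or
#'   bright below are kept, so observed class follows intensity).
#' @param seed Integer seed.
#' @return data.frame with `patient_id`, `event_id`, `mean_intensity`, and
#'   the generative `true_positive` flag.
#' @export
generate_cohort <- function(n_patients = 132L, events_mu = 30,
                            events_size = 0.35, pos_shape1 = 1.2,
                            pos_shape2 = 1.9,
                            bright_given_positive = 0.0622,
                            dim_mean = 40, dim_sd = 20,
                            bright_mean = 150, bright_sd = 40,
                            seed = 1L) {
  stopifnot(n_patients >= 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rows <- lapply(seq_len(n_patients), function(p) {
    n_ev <- 1L + stats::rnbinom(1, size = events_size, mu = events_mu)
    theta <- stats::rbeta(1, pos_shape1, pos_shape2)
    pos <- stats::runif(n_ev) < theta
    bright <- pos & (stats::runif(n_ev) < bright_given_positive)
    mi <- numeric(n_ev)
    n_dim <- sum(pos & !bright)
    mi[pos & !bright] <- pmin(rnorm_trunc_pos(n_dim, dim_mean, dim_sd),
                              4095)
    mi[bright] <- pmin(rnorm_trunc_pos(sum(bright), bright_mean, bright_sd),
                       4095)
    data.frame(patient_id = sprintf("P%03d", p),
               event_id = sprintf("P%03d_ev%04d", p, seq_len(n_ev)),
               mean_intensity = mi, true_positive = pos,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a synthetic reader-score matrix
#'
#' Each reviewer's binary call is the event's true status flipped
#' independently with the reviewer's error probability — a fixture with a
#' closed-form concordance distribution (e.g. with all flip probabilities
#' 1/2 the expected tie fraction for six reviewers is
#' `choose(6,3)/2^6 = 0.3125`).
#'
#' @param true_positive Logical vector of true per-event status.
#' @param flip_prob Numeric vector of per-reviewer flip probabilities (its
#'   length sets the number of reviewers).
#' @param display_condition Condition label attached to the matrix.
#' @param seed Integer seed.
#' @return A [reader_score_matrix].
#' @export
generate_reader_scores <- function(true_positive, flip_prob,
                                   display_condition = "scaled",
                                   seed = 1L) {
  stopifnot(is.logical(true_positive), length(flip_prob) >= 2,
            all(flip_prob >= 0 & flip_prob <= 1))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- length(true_positive)
  calls <- vapply(flip_prob, function(p) {
    flip <- stats::runif(n) < p
    xor(true_positive, flip)
  }, logical(n))
  calls <- matrix(calls, nrow = n)
  dimnames(calls) <- list(sprintf("ev%04d", seq_len(n)),
                          sprintf("reviewer%d", seq_along(flip_prob)))
  reader_score_matrix(calls, display_condition)
}
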