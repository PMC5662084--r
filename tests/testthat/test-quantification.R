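test_that("channel measurements match brute-force oracles", {
  # absent object -> all-zero record (the negativity encoding)
  none <- measure_channel(NULL, as_rescaled_frame(matrix(1, 10, 10)))
  expect_equal(none$mean_intensity, 0)
  expect_equal(none$size, 0L)
  expect_equal(none$mass, 0)
  expect_equal(none$max_intensity, 0)

  # digital disk of radius 5 at constant 50: size/mass by pixel counting
  n <- 21
  mask <- disk_mask(n, c(10, 10), 5)
  expect_equal(sum(mask), 81)  # brute-force enumeration
  px <- matrix(0, n, n); px[mask] <- 50
  obj <- object_from_mask(mask)
  m <- measure_channel(obj, as_rescaled_frame(px))
  expect_equal(m$size, 81)
  expect_equal(m$mean_intensity, 50)
  expect_equal(m$mass, 4050)
  expect_equal(m$max_intensity, 50)
  expect_equal(m$std_intensity, 0)
  expect_lt(m$eccentricity, 0.1)
  expect_gte(m$perimeter2area, 1)
  expect_lte(m$perimeter2area, 1.3)

  # shape mismatch is an error
  expect_error(measure_channel(obj, as_rescaled_frame(matrix(1, 5, 5))),
               "dimensions differ")
})

test_that("single-pixel statistics and the mass identity hold", {
  # 1-px semantics checked through the formulas' degenerate limits:
  # mean = max = mass / 1 and std = 0 (verified on a 4-px constant patch,
  # the smallest object segmentation reports, plus the identity below)
  set.seed(51)
  for (i in 1:25) {
    n <- 30
    ctr <- c(sample(8:22, 1), sample(8:22, 1))
    mask <- disk_mask(n, ctr, runif(1, 2, 6))
    px <- matrix(0, n, n)
    px[mask] <- 200 + rnorm(sum(mask), 0, 20)
    px <- pmax(px, 1)
    m <- measure_channel(object_from_mask(mask), as_rescaled_frame(px))
    # mass == mean * size to float tolerance
    expect_equal(m$mass, m$mean_intensity * m$size, tolerance = 1e-9)
    expect_gte(m$max_intensity, m$mean_intensity)
    expect_gte(m$perimeter2area, 1)
  }
})

test_that("eccentricity follows the moment oracle for a digital ellipse", {
  mask <- ellipse_mask(31, c(15, 15), 10, 5)
  px <- matrix(0, 31, 31); px[mask] <- 100
  m <- measure_channel(object_from_mask(mask), as_rescaled_frame(px))
  expect_equal(m$eccentricity, sqrt(1 - 25 / 100), tolerance = 0.05)

  # independent moment oracle on the same mask
  idx <- which(mask, arr.ind = TRUE)
  S <- cov(idx) * (nrow(idx) - 1) / nrow(idx) + diag(2) / 12
  ev <- eigen(S, symmetric = TRUE)$values
  expect_equal(m$eccentricity, sqrt(1 - ev[2] / ev[1]), tolerance = 1e-6)
})

test_that("perimeter2area is at least 1 and grows with irregularity", {
  set.seed(53)
  p2a_of <- function(mask) {
    px <- matrix(0, nrow(mask), ncol(mask)); px[mask] <- 100
    measure_channel(object_from_mask(mask),
                    as_rescaled_frame(px))$perimeter2area
  }
  for (i in 1:50) {
    # union of 2-3 overlapping disks: blob-like but non-circular
    n <- 40
    mask <- disk_mask(n, c(20, 20), runif(1, 3, 6))
    for (k in 1:sample(1:2, 1)) {
      off <- round(runif(2, -4, 4))
      mask <- mask | disk_mask(n, c(20, 20) + off, runif(1, 2.5, 5))
    }
    if (max(flood_label8(mask)) != 1) next
    expect_gte(p2a_of(mask), 1)
  }
  # an elongated shape is less circular than the disk of similar area
  expect_gt(p2a_of(ellipse_mask(41, c(20, 20), 16, 3)),
            p2a_of(disk_mask(41, c(20, 20), 7)))
})

test_that("relative overlay counts pixels with the DAPI denominator", {
  a <- matrix(FALSE, 10, 10); a[2:6, 2:7] <- TRUE   # 30 px
  expect_equal(relative_overlay(a, a), 1.0)
  b <- matrix(FALSE, 10, 10); b[8:9, 8:9] <- TRUE
  expect_equal(relative_overlay(a, b), 0.0)
  a2 <- matrix(FALSE, 10, 10); a2[1:5, 1:8] <- TRUE # 40 px
  b2 <- matrix(FALSE, 10, 10); b2[1:5, 7:10] <- TRUE
  expect_equal(relative_overlay(a2, b2), 10 / 40)   # pixel counting
  expect_equal(relative_overlay(matrix(FALSE, 10, 10), b2), 0)
  expect_error(relative_overlay(a, matrix(TRUE, 5, 5)), "dimensions")
})

test_that("measure_event recovers generator truth per channel", {
  dir <- withr::local_tempdir()
  sp <- event_spec(blobs = list(
    DAPI = list(radius = 5, plateau = 900),
    CK = list(radius = 7, plateau = 500),
    MARKER1 = list(radius = 6, plateau = 150)), seed = 61)
  generate_thumbnail(sp, file.path(dir, "ev.tif"))
  rec <- measure_event(load_thumbnail(file.path(dir, "ev.tif")))

  mk <- rec$measurements$MARKER1
  tol <- 3 * 6.6 / sqrt(mk$size)
  expect_lt(abs(mk$mean_intensity - 150), tol)
  expect_gt(rec$dapi_ck_overlay, 0.9)   # CK blob covers the nucleus
  expect_equal(rec$dapi_cd45_overlay, 0)
  expect_equal(rec$measurements$CD45$mean_intensity, 0)
  expect_gt(rec$marker_median, 0)
})

test_that("measure_event is invariant to frame order given the channel map", {
  dir <- withr::local_tempdir()
  sp <- event_spec(blobs = list(DAPI = list(radius = 5, plateau = 800),
                                MARKER1 = list(radius = 5, plateau = 200)),
                   seed = 63)
  p <- file.path(dir, "ev.tif")
  generate_thumbnail(sp, p)
  # rewrite the TIFF with frames reversed and a matching channel map
  frames <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
  stored <- lapply(rev(frames), function(m)
    matrix(as.numeric(m) / 255, nrow(m), ncol(m)))
  p2 <- file.path(dir, "ev_rev.tif")
  tiff::writeTIFF(stored, p2, bits.per.sample = 8L, compression = "none")
  file.copy(paste0(p, ".hdr.json"), paste0(p2, ".hdr.json"))

  r1 <- measure_event(load_thumbnail(p))
  r2 <- measure_event(load_thumbnail(
    p2, channel_map = c(DAPI = 4L, CK = 3L, CD45 = 2L, MARKER1 = 1L)))
  expect_equal(r1$measurements$MARKER1$mean_intensity,
               r2$measurements$MARKER1$mean_intensity)
  expect_equal(r1$measurements$DAPI$mass, r2$measurements$DAPI$mass)
  expect_equal(r1$dapi_ck_overlay, r2$dapi_ck_overlay)
})

test_that("the intensity-difference test matches the Welch oracle", {
  same <- c(1, 2, 3, 4, 5)
  r <- intensity_difference_test(same, same)
  expect_equal(r$t_statistic, 0)
  expect_equal(r$p_value, 1)

  set.seed(65)
  a <- rnorm(500, 30, 6.6)
  b <- rnorm(500, 60, 6.6)
  r2 <- intensity_difference_test(a, b)
  o <- welch_oracle(a, b)
  expect_equal(r2$t_statistic, o$t, tolerance = 1e-9)
  expect_equal(r2$p_value, o$p, tolerance = 1e-9)
  expect_lt(r2$p_value, 0.001)

  # reshuffled copy of the same values: mean-equality, t = 0
  r3 <- intensity_difference_test(a, sample(a))
  expect_lt(abs(r3$t_statistic), 1e-10)

  expect_error(intensity_difference_test(1, c(1, 2)), "at least 2")
})

test_that("antigen calibration matches the normal-equations oracle", {
  fit <- fit_antigen_calibration(c(0, 1, 2), c(0, 10, 20))
  expect_equal(fit$slope, 10)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)

  x <- c(10, 300, 950)
  y <- c(19958, 335075, 957731) + c(5000, -8000, 3000)
  fit2 <- fit_antigen_calibration(x, y)
  o <- ols_oracle(x, y)
  expect_equal(fit2$slope, o$slope, tolerance = 1e-9)
  expect_equal(fit2$intercept, o$intercept, tolerance = 1e-9)
  expect_equal(fit2$r_squared, o$r2, tolerance = 1e-9)
  expect_lt(fit2$r_squared, 1)

  expect_error(fit_antigen_calibration(5, 10), "at least two")
  expect_error(fit_antigen_calibration(c(5, 5), c(1, 2)), "degenerate")
})

test_that("event records flatten to the documented table schema", {
  dir <- withr::local_tempdir()
  sp <- event_spec(blobs = list(DAPI = list(radius = 5, plateau = 800)),
                   seed = 67)
  generate_thumbnail(sp, file.path(dir, "ev.tif"))
  tab <- records_to_table(measure_event(load_thumbnail(file.path(dir, "ev.tif"))))
  expect_equal(nrow(tab), 1)
  chans <- c("dapi", "ck", "cd45", "marker1")
  feats <- c("ecc", "perim", "mean", "max", "size", "std", "mass", "p2a")
  expect_true(all(as.vector(outer(chans, feats, paste, sep = "_")) %in%
                  names(tab)))
  expect_true(all(c("event_id", "sample_id", "patient_id",
                    "dapi_cd45_overlay", "dapi_ck_overlay",
                    "marker1_median") %in% names(tab)))
  expect_equal(ncol(tab), 3 + 32 + 2 + 1)
})
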