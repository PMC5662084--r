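test_that("expression classes follow the documented boundary semantics", {
  th <- her2_thresholds()
  expect_equal(classify_her2(0, th), "negative")
  expect_equal(classify_her2(50, th), "dim")
  expect_equal(classify_her2(100, th), "bright")
  expect_equal(classify_her2(99.999999, th), "dim")
  expect_equal(classify_her2(1e-9, th), "dim")
  expect_equal(classify_her2(c(0, 12, 250), th),
               c("negative", "dim", "bright"))
  expect_error(classify_her2(-1, th), "non-negative")
  expect_error(her2_thresholds(100, 100), "t_dim < t_bright")
})

test_that("classification is monotone in mean intensity", {
  th <- her2_thresholds()
  rank_of <- c(negative = 1, dim = 2, bright = 3)
  set.seed(71)
  x <- sort(c(0, runif(200, 0, 300)))
  r <- rank_of[classify_her2(x, th)]
  expect_true(all(diff(r) >= 0))
})

test_that("population accuracy matches hand counts and the analytic rate", {
  # all negative, all correct
  r <- classify_population(rep(0, 10), rep("negative", 10))
  expect_equal(r$accuracy, 1.0)
  expect_equal(sum(r$confusion), 10)

  # constructed mixed list with a known hand count: 3 of 6 correct
  means <- c(0, 30, 150, 0, 120, 95)
  truth <- c("negative", "dim", "bright", "dim", "dim", "bright")
  r2 <- classify_population(means, truth)
  expect_equal(r2$accuracy, 3 / 6)
  expect_equal(sum(r2$confusion), 6)
  expect_equal(unname(r2$confusion["dim", "bright"]), 1)
  expect_equal(unname(r2$confusion["bright", "dim"]), 1)

  # generated cell-line populations: empirical accuracy within +-0.05 of
  # the generator's closed-form misclassification rate
  pop <- generate_population(n_negative = 400, n_dim = 400, n_bright = 400,
                             seed = 73)
  rc <- classify_population(pop$records$mean_intensity,
                            pop$records$true_class)
  expect_lt(abs(rc$accuracy - pop$analytic_accuracy), 0.05)

  expect_error(classify_population(numeric(0), character(0)), "empty")
})

test_that("patient summaries implement the all/none/mixed rule", {
  s1 <- summarize_patient(rep("dim", 3))
  expect_equal(s1$heterogeneity, "all_positive")
  s2 <- summarize_patient(rep("negative", 3))
  expect_equal(s2$heterogeneity, "none_positive")
  s3 <- summarize_patient(c("negative", "dim", "bright"))
  expect_equal(s3$heterogeneity, "mixed")
  expect_equal(s3$fraction_positive, 2 / 3)
  expect_equal(s3$n_total, s3$n_negative + s3$n_dim + s3$n_bright)
  # single-event patients follow the same rule; mixed impossible
  expect_equal(summarize_patient("bright")$heterogeneity, "all_positive")
  expect_equal(summarize_patient("negative")$heterogeneity, "none_positive")
  expect_error(summarize_patient(character(0)), "no classified events")
})

test_that("cohort breakdown equals an independent tally", {
  two <- cohort_breakdown(list(
    summarize_patient(rep("negative", 5), "p1"),
    summarize_patient(rep("dim", 5), "p2")))
  expect_equal(two$patients_all_positive, 1)
  expect_equal(two$patients_none_positive, 1)
  expect_equal(two$patients_mixed, 0)
  expect_equal(unname(two$pct), c(50, 50, 0))

  # constructed 10-patient cohort vs brute-force tally
  set.seed(75)
  patients <- lapply(1:10, function(p) {
    n <- sample(1:8, 1)
    sample(c("negative", "dim", "bright"), n, replace = TRUE,
           prob = c(0.6, 0.35, 0.05))
  })
  bd <- cohort_breakdown(lapply(seq_along(patients), function(i)
    summarize_patient(patients[[i]], paste0("p", i))))
  all_classes <- unlist(patients)
  expect_equal(bd$n_events, length(all_classes))
  expect_equal(unname(bd$pct["negative"]),
               100 * sum(all_classes == "negative") / length(all_classes))
  expect_equal(bd$patients_all_positive,
               sum(vapply(patients, function(x) !any(x == "negative"),
                          logical(1))))
  expect_equal(bd$patients_none_positive,
               sum(vapply(patients, function(x) all(x == "negative"),
                          logical(1))))
  expect_equal(bd$patients_all_positive + bd$patients_none_positive +
               bd$patients_mixed, 10)
  # percentages sum to 100 and the table is sorted by positive fraction
  expect_equal(sum(bd$pct), 100, tolerance = 1e-9)
  expect_true(all(diff(bd$patient_table$fraction_positive) <= 0))

  # pooling is invariant to patient grouping
  one <- cohort_breakdown(list(summarize_patient(all_classes, "pool")))
  expect_equal(unname(one$pct), unname(bd$pct))
})

test_that("manual-automatic correlation matches the covariance formula", {
  expect_equal(manual_auto_correlation(1:3, 1:3)$r, 1)
  expect_equal(manual_auto_correlation(1:3, 3:1)$r, -1)
  set.seed(77)
  a <- rpois(40, 20); b <- a + rpois(40, 5)
  r <- manual_auto_correlation(a, b)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(r$r, num / den, tolerance = 1e-12)
  expect_true(r$ci[1] < r$r && r$r < r$ci[2])
  expect_error(manual_auto_correlation(c(2, 2, 2), 1:3), "zero variance")
  expect_error(manual_auto_correlation(1:2, 1:2), "at least 3")
})

test_that("concordance categories follow the vote split exactly", {
  # all reviewers positive on every event
  m <- reader_score_matrix(matrix(TRUE, 10, 6))
  h <- concordance_histogram(m)
  expect_equal(h$unanimous_positive, 1.0)
  expect_equal(h$unanimous_negative + h$five_agree + h$four_agree +
               h$three_indifferent, 0)

  # constructed 12x6 matrix, two events per vote-count pattern 6,0,5,1,4,3
  votes <- c(6, 6, 0, 0, 5, 5, 1, 1, 4, 4, 3, 3)
  mm <- t(vapply(votes, function(v) c(rep(TRUE, v), rep(FALSE, 6 - v)),
                 logical(6)))
  h2 <- concordance_histogram(reader_score_matrix(mm))
  expect_equal(h2$unanimous_positive, 2 / 12)
  expect_equal(h2$unanimous_negative, 2 / 12)
  expect_equal(h2$five_agree, 4 / 12)
  expect_equal(h2$four_agree, 2 / 12)
  expect_equal(h2$three_indifferent, 2 / 12)
  expect_equal(unname(concordance_oracle(mm)),
               c(h2$unanimous_positive, h2$unanimous_negative,
                 h2$five_agree, h2$four_agree, h2$three_indifferent))

  # an odd reviewer panel cannot produce ties
  m5 <- matrix(c(TRUE, TRUE, FALSE, TRUE, FALSE), 8, 5, byrow = TRUE)
  h5 <- concordance_histogram(reader_score_matrix(m5))
  expect_equal(h5$three_indifferent, 0)

  expect_error(concordance_histogram(matrix(c(TRUE, NA), 1, 2)), "missing")
  expect_error(reader_score_matrix(matrix(TRUE, 4, 1)), "2 reviewers")
})

test_that("concordance fractions equal brute-force counts on random panels", {
  set.seed(79)
  for (i in 1:200) {
    R <- sample(c(4, 5, 6), 1)
    n <- sample(5:30, 1)
    m <- matrix(runif(n * R) < runif(1, 0.2, 0.8), n, R)
    h <- concordance_histogram(reader_score_matrix(m))
    frac <- c(h$unanimous_positive, h$unanimous_negative, h$five_agree,
              h$four_agree, h$three_indifferent)
    expect_equal(frac, unname(concordance_oracle(m)), tolerance = 1e-12)
    expect_equal(sum(frac), 1, tolerance = 1e-9)
  }
})
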