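HER2_CLASSES <- c("negative", "dim", "bright")

#' Marker expression thresholds
#'
#' The two cut-offs separating negative, dim and bright marker expression
#' on the restored 12-bit intensity scale. A mean of exactly `t_dim`
#' (default 0, the no-object encoding) is negative; a mean strictly between
#' `t_dim` and `t_bright` is dim; a mean at or above `t_bright` (default
#' 100) is bright. The cut-off of 0 suffices for negative-versus-dim
#' because the segmentation constructs a separating gap: undetectable
#' channels yield a mean of exactly 0.
#'
#' @param t_dim Lower cut-off (default 0).
#' @param t_bright Upper cut-off (default 100).
#' @return Object of class `her2_thresholds`.
#' @export
her2_thresholds <- function(t_dim = 0, t_bright = 100) {
  if (!(t_dim >= 0 && t_dim < t_bright))
    stop("thresholds must satisfy 0 <= t_dim < t_bright", call. = FALSE)
  structure(list(t_dim = t_dim, t_bright = t_bright),
            class = "her2_thresholds")
}

#' Classify marker expression from mean intensity
#'
#' @param mean_intensity Numeric vector of per-event mean marker
#'   intensities (non-negative).
#' @param thresholds An [her2_thresholds] object.
#' @return Character vector in `c("negative", "dim", "bright")`.
#' @export
classify_her2 <- function(mean_intensity, thresholds = her2_thresholds()) {
  stopifnot(inherits(thresholds, "her2_thresholds"))
  if (any(is.na(mean_intensity)) || any(mean_intensity < 0))
    stop("mean intensity must be non-negative", call. = FALSE)
  out <- ifelse(mean_intensity <= thresholds$t_dim, "negative",
         ifelse(mean_intensity >= thresholds$t_bright, "bright", "dim"))
  unname(out)
}

#' Validate thresholds against a labelled population
#'
#' Classifies every event and compares against ground-truth class labels
#' (for cell-line validation: MDA-MB 231 maps to negative, MDA-MB 453 to
#' dim, SKBR-3 to bright).
#'
#' @param mean_intensity Numeric vector of mean marker intensities.
#' @param true_class Character vector of matching ground-truth classes.
#' @param thresholds An [her2_thresholds].
#' @return List with `accuracy` (fraction correct), `confusion` (3x3 table,
#'   true class in rows), `n`.
#' @export
classify_population <- function(mean_intensity, true_class,
                                thresholds = her2_thresholds()) {
  if (!length(mean_intensity))
    stop("empty population", call. = FALSE)
  if (length(mean_intensity) != length(true_class))
    stop("intensities and labels must be paired", call. = FALSE)
  if (!all(true_class %in% HER2_CLASSES))
    stop("true_class values must be in ",
         paste(HER2_CLASSES, collapse = "/"), call. = FALSE)
  pred <- classify_her2(mean_intensity, thresholds)
  tc <- factor(true_class, levels = HER2_CLASSES)
  pc <- factor(pred, levels = HER2_CLASSES)
  conf <- table(true = tc, predicted = pc)
  list(accuracy = mean(pred == true_class), confusion = conf,
       n = length(pred))
}

#' Summarize marker heterogeneity for one patient
#'
#' Counts the patient's events per expression class and labels the patient
#' `all_positive` when no event is negative, `none_positive` when no event
#' is dim or bright, and `mixed` otherwise. A single-event patient follows
#' the same rule (mixed impossible).
#'
#' @param her2_class Character vector of the patient's per-event classes.
#' @param patient_id Identifier attached to the summary.
#' @return Object of class `patient_summary`.
#' @export
summarize_patient <- function(her2_class, patient_id = "patient") {
  if (!length(her2_class))
    stop("patient has no classified events", call. = FALSE)
  if (!all(her2_class %in% HER2_CLASSES))
    stop("classes must be in ", paste(HER2_CLASSES, collapse = "/"),
         call. = FALSE)
  n_neg <- sum(her2_class == "negative")
  n_dim <- sum(her2_class == "dim")
  n_bri <- sum(her2_class == "bright")
  het <- if (n_neg == 0L) "all_positive"
         else if (n_dim + n_bri == 0L) "none_positive"
         else "mixed"
  structure(list(patient_id = as.character(patient_id),
                 n_total = length(her2_class), n_negative = n_neg,
                 n_dim = n_dim, n_bright = n_bri, heterogeneity = het,
                 fraction_positive = (n_dim + n_bri) / length(her2_class)),
            class = "patient_summary")
}

#' @export
print.patient_summary <- function(x, ...) {
  cat(sprintf("<patient_summary %s n=%d (%d neg / %d dim / %d bright) %s>\n",
              x$patient_id, x$n_total, x$n_negative, x$n_dim, x$n_bright,
              x$heterogeneity))
  invisible(x)
}

#' Cohort-level breakdown of patient summaries
#'
#' Pools patient summaries into cohort statistics: counts of all-positive /
#' none-positive / mixed patients, pooled event-level class percentages,
#' and a patient table sorted by decreasing fraction of marker-positive
#' events (the standard heterogeneity-plot ordering).
#'
#' @param summaries List of [summarize_patient] results.
#' @return List with `n_patients`, `n_events`, `patients_all_positive`,
#'   `patients_none_positive`, `patients_mixed`, `pct` (named percentages
#'   negative/dim/bright summing to 100), and `patient_table` (data.frame
#'   sorted by `fraction_positive` descending).
#' @export
cohort_breakdown <- function(summaries) {
  if (!length(summaries))
    stop("empty cohort", call. = FALSE)
  stopifnot(all(vapply(summaries, inherits, logical(1), "patient_summary")))
  tab <- do.call(rbind, lapply(summaries, function(s)
    data.frame(patient_id = s$patient_id, n_total = s$n_total,
               n_negative = s$n_negative, n_dim = s$n_dim,
               n_bright = s$n_bright, heterogeneity = s$heterogeneity,
               fraction_positive = s$fraction_positive,
               stringsAsFactors = FALSE)))
  tab <- tab[order(-tab$fraction_positive, tab$patient_id), ]
  rownames(tab) <- NULL
  n_events <- sum(tab$n_total)
  pct <- 100 * c(negative = sum(tab$n_negative),
                 dim = sum(tab$n_dim),
                 bright = sum(tab$n_bright)) / n_events
  list(n_patients = nrow(tab), n_events = n_events,
       patients_all_positive = sum(tab$heterogeneity == "all_positive"),
       patients_none_positive = sum(tab$heterogeneity == "none_positive"),
       patients_mixed = sum(tab$heterogeneity == "mixed"),
       pct = pct, patient_table = tab)
}

#' Correlation of manual and automatic positive-event counts
#'
#' Pearson correlation between per-sample manual and automatic counts of
#' marker-positive events, with a 95% confidence interval by Fisher's z
#' transform.
#'
#' @param manual_counts,auto_counts Paired integer vectors (length >= 3,
#'   each with nonzero variance).
#' @return List with `r`, `ci` (length-2), `n`.
#' @export
manual_auto_correlation <- function(manual_counts, auto_counts) {
  if (length(manual_counts) != length(auto_counts))
    stop("count vectors must be paired", call. = FALSE)
  if (length(manual_counts) < 3L)
    stop("need at least 3 paired samples", call. = FALSE)
  if (stats::sd(manual_counts) == 0 || stats::sd(auto_counts) == 0)
    stop("undefined correlation: a count vector has zero variance",
         call. = FALSE)
  r <- stats::cor(manual_counts, auto_counts)
  n <- length(manual_counts)
  if (abs(r) < 1 && n > 3) {
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  } else ci <- c(r, r)
  list(r = r, ci = ci, n = n)
}

#' Build a reader-score matrix
#'
#' @param calls Matrix (events x reviewers) of binary calls, either logical
#'   (`TRUE` = positive) or character `"positive"`/`"negative"`; no missing
#'   cells, at least two reviewers.
#' @param display_condition `"scaled"` or `"quantitative"` — the display
#'   under which reviewers scored.
#' @return Logical matrix of class `reader_score_matrix` (`TRUE` =
#'   positive) with the condition attached as an attribute.
#' @export
reader_score_matrix <- function(calls, display_condition = c("scaled",
                                                             "quantitative")) {
  display_condition <- match.arg(display_condition)
  if (is.character(calls)) {
    if (!all(calls %in% c("positive", "negative")))
      stop("calls must be 'positive'/'negative'", call. = FALSE)
    calls <- matrix(calls == "positive", nrow(calls), ncol(calls),
                    dimnames = dimnames(calls))
  }
  if (!is.matrix(calls) || !is.logical(calls))
    stop("calls must be a logical events x reviewers matrix", call. = FALSE)
  if (anyNA(calls))
    stop("missing votes are not allowed (no imputation)", call. = FALSE)
  if (ncol(calls) < 2L)
    stop("need at least 2 reviewers", call. = FALSE)
  structure(calls, class = c("reader_score_matrix", class(calls)),
            display_condition = display_condition)
}

#' Inter-reader concordance histogram
#'
#' Categorizes every event by its vote split among `R` reviewers: all agree
#' (split by direction into `unanimous_positive` / `unanimous_negative`),
#' one dissenter (`five_agree` for the six-reviewer design), two or more
#' dissenters short of a tie (`four_agree`), and an exact tie
#' (`three_indifferent`, only possible for even `R`). Fractions are over
#' events and sum to 1. The majority direction of each non-unanimous
#' category is recorded alongside.
#'
#' @param mat A [reader_score_matrix] (or plain logical matrix).
#' @return Object of class `concordance_histogram`: the five category
#'   fractions, `n_events`, `n_reviewers`, and `direction`, a table of
#'   positive-majority counts within the non-unanimous categories.
#' @export
concordance_histogram <- function(mat) {
  if (!is.matrix(mat) || !is.logical(mat))
    stop("expected a logical events x reviewers matrix", call. = FALSE)
  if (anyNA(mat))
    stop("missing votes are not allowed (no imputation)", call. = FALSE)
  R <- ncol(mat)
  if (R < 2L) stop("need at least 2 reviewers", call. = FALSE)
  v <- rowSums(mat)              # positive votes per event
  dissent <- pmin(v, R - v)      # minority size
  tie <- (2 * v == R)
  cat_of <- ifelse(tie, "three_indifferent",
            ifelse(dissent == 0L, ifelse(v == R, "unanimous_positive",
                                         "unanimous_negative"),
            ifelse(dissent == 1L, "five_agree", "four_agree")))
  lv <- c("unanimous_positive", "unanimous_negative", "five_agree",
          "four_agree", "three_indifferent")
  frac <- as.numeric(table(factor(cat_of, levels = lv))) / nrow(mat)
  names(frac) <- lv
  dir_tab <- table(category = factor(cat_of, levels = lv),
                   majority_positive = factor(v > R - v,
                                              levels = c(FALSE, TRUE)))
  structure(c(as.list(frac),
              list(n_events = nrow(mat), n_reviewers = R,
                   direction = dir_tab,
                   display_condition = attr(mat, "display_condition"))),
            class = "concordance_histogram")
}

#' @export
print.concordance_histogram <- function(x, ...) {
  cat(sprintf(paste0("<concordance_histogram n=%d, R=%d: unanimous %.1f%% ",
                     "(+%.1f%% / -%.1f%%), 1-dissent %.1f%%, ",
                     ">=2-dissent %.1f%%, tie %.1f%%>\n"),
              x$n_events, x$n_reviewers,
              100 * (x$unanimous_positive + x$unanimous_negative),
              100 * x$unanimous_positive, 100 * x$unanimous_negative,
              100 * x$five_agree, 100 * x$four_agree,
              100 * x$three_indifferent))
  invisible(x)
}
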