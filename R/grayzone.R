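# Gray-zone abstention: threshold sweep, landscape, zone selection.

#' Construct a gray zone
#'
#' A Severity-Score interval \[lo, hi) inside which the classifier
#' abstains and reports `"unknown"`. `lo == hi` is the empty zone (no
#' abstention).
#'
#' @param lo,hi Bounds in \[0, 1\] with `lo <= hi`.
#' @return An object of class `gray_zone`.
#' @export
gray_zone <- function(lo, hi) {
  stopifnot(length(lo) == 1L, length(hi) == 1L, is.finite(lo), is.finite(hi))
  if (lo < 0 || hi > 1 || lo > hi) {
    stop("need 0 <= lo <= hi <= 1", call. = FALSE)
  }
  structure(list(lo = lo, hi = hi), class = "gray_zone")
}

#' @export
print.gray_zone <- function(x, ...) {
  cat(sprintf("Gray zone: scores in [%.2f, %.2f) are 'unknown'\n",
              x$lo, x$hi))
  invisible(x)
}

#' Ternary call under a gray zone
#'
#' Partitions \[0, 1\]: scores below `lo` are called mild/moderate,
#' scores in \[lo, hi) are unknown, scores at or above `hi` are severe.
#' Every score receives exactly one label; boundaries are half-open.
#'
#' @param scores Numeric Severity Scores in \[0, 1\].
#' @param zone A `gray_zone`.
#' @return Factor with levels `mild_moderate`, `unknown`, `severe`.
#' @export
classify_with_zone <- function(scores, zone) {
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  out <- ifelse(scores < zone$lo, "mild_moderate",
                ifelse(scores < zone$hi, "unknown", "severe"))
  factor(out, levels = c("mild_moderate", "unknown", "severe"))
}

#' Sweep gray-zone threshold pairs
#'
#' Evaluates every valid pair (lo <= hi) from the given grids: the
#' per-class accuracy on classified instances (the fraction of
#' true-severe instances called severe among the classified
#' true-severe, and likewise for mild/moderate), the coverage (fraction
#' of instances classified), and the number abstained. A class with no
#' classified instance gets `NA` accuracy, never 0.
#'
#' @param scores Severity Scores in \[0, 1\].
#' @param labels Binary truth (`severe` vs anything else).
#' @param lo_grid,hi_grid Candidate thresholds; default a 0.01-step
#'   grid over \[0, 1\].
#' @param positive Label counted as the severe class.
#' @return A tibble of class `threshold_landscape`: `lo`, `hi`,
#'   `acc_severe`, `acc_mild_moderate`, `coverage`, `n_unknown`.
#' @export
sweep_thresholds <- function(scores, labels,
                             lo_grid = seq(0, 1, by = 0.01),
                             hi_grid = seq(0, 1, by = 0.01),
                             positive = "severe") {
  if (any(scores < 0 | scores > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(all(lo_grid >= 0 & lo_grid <= 1),
            all(hi_grid >= 0 & hi_grid <= 1))
  is_sev <- as.character(labels) == positive
  n <- length(scores)
  s_sev <- sort(scores[is_sev])
  s_mm <- sort(scores[!is_sev])

  grid <- expand.grid(lo = sort(unique(lo_grid)),
                      hi = sort(unique(hi_grid)))
  grid <- grid[grid$lo <= grid$hi, , drop = FALSE]

  # counts of class scores strictly below a threshold, via sorted search
  below <- function(sorted, t) {
    findInterval(t, sorted, left.open = FALSE) -
      # findInterval counts <= t; subtract the ties at exactly t
      vapply(t, function(ti) sum(sorted == ti), numeric(1))
  }
  sev_below_lo <- below(s_sev, grid$lo)
  mm_below_lo <- below(s_mm, grid$lo)
  sev_ge_hi <- length(s_sev) - below(s_sev, grid$hi)
  mm_ge_hi <- length(s_mm) - below(s_mm, grid$hi)

  sev_classified <- sev_below_lo + sev_ge_hi
  mm_classified <- mm_below_lo + mm_ge_hi
  classified <- sev_classified + mm_classified

  out <- tibble::tibble(
    lo = grid$lo, hi = grid$hi,
    acc_severe = ifelse(sev_classified > 0, sev_ge_hi / sev_classified,
                        NA_real_),
    acc_mild_moderate = ifelse(mm_classified > 0,
                               mm_below_lo / mm_classified, NA_real_),
    coverage = classified / n,
    n_unknown = as.integer(n - classified)
  )
  class(out) <- c("threshold_landscape", class(out))
  out
}

#' Select a gray zone from the landscape
#'
#' Maximizes the selection criterion (default: the smaller of the two
#' per-class accuracies) over cells meeting the coverage floor. Ties
#' are broken by larger coverage, then by smaller interval width.
#'
#' @param landscape A `threshold_landscape`.
#' @param min_coverage Minimum fraction of instances that must remain
#'   classified.
#' @param criterion `"min_class_accuracy"` (default) or
#'   `"mean_class_accuracy"`.
#' @return A `gray_zone` with the selected cell's metrics attached as
#'   attribute `metrics`.
#' @export
select_gray_zone <- function(landscape, min_coverage = 0.5,
                             criterion = c("min_class_accuracy",
                                           "mean_class_accuracy")) {
  criterion <- match.arg(criterion)
  stopifnot(nrow(landscape) > 0)
  ok <- landscape$coverage >= min_coverage &
    !is.na(landscape$acc_severe) & !is.na(landscape$acc_mild_moderate)
  if (!any(ok)) {
    stop(sprintf(
      "no zone reaches coverage %.2f with both classes represented; best attainable coverage with both classes is %.2f",
      min_coverage,
      max(landscape$coverage[!is.na(landscape$acc_severe) &
                               !is.na(landscape$acc_mild_moderate)], 0)),
      call. = FALSE)
  }
  cand <- landscape[ok, , drop = FALSE]
  score <- if (criterion == "min_class_accuracy") {
    pmin(cand$acc_severe, cand$acc_mild_moderate)
  } else {
    (cand$acc_severe + cand$acc_mild_moderate) / 2
  }
  ord <- order(-score, -cand$coverage, cand$hi - cand$lo)
  pick <- cand[ord[1], ]
  z <- gray_zone(pick$lo, pick$hi)
  attr(z, "metrics") <- pick
  z
}
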