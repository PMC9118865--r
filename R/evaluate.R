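#' Match detected plants to ground-truth plants
#'
#' Greedy one-to-one matching by ascending pair distance in XY: the closest
#' unmatched (detection, truth) pair is matched repeatedly while the
#' distance is at most `max_dist`. A detection is counted correct iff it is
#' matched. Greedy matching is deterministic and, at plantation spacing,
#' agrees with the optimal assignment.
#'
#' @param seeds data frame of detected positions (columns `x`, `y`).
#' @param truth_bases data frame of true plant bases (columns `x`, `y`).
#' @param max_dist maximum match distance, metres (default 0.3).
#' @return Number of correct detections (integer).
#' @export
match_detections <- function(seeds, truth_bases, max_dist = 0.3) {
  stopifnot(max_dist > 0)
  ns <- nrow(seeds)
  nt <- nrow(truth_bases)
  if (ns == 0 || nt == 0) return(0L)
  dmat <- outer(seeds$x, truth_bases$x, "-")^2 +
    outer(seeds$y, truth_bases$y, "-")^2
  dmat <- sqrt(dmat)
  n_correct <- 0L
  repeat {
    mi <- which.min(dmat)
    if (length(mi) == 0 || !is.finite(dmat[mi]) || dmat[mi] > max_dist) break
    ij <- arrayInd(mi, dim(dmat))
    n_correct <- n_correct + 1L
    dmat[ij[1], ] <- Inf
    dmat[, ij[2]] <- Inf
    if (n_correct >= min(ns, nt)) break
  }
  n_correct
}

#' Counting evaluation metrics
#'
#' Precision, recall and percentage error of a plant count:
#' `P = 100 * n_correct / n_recognized`, `R = 100 * n_correct / n_true`,
#' `PE = 100 * |n_recognized - n_true| / n_true`. Values are returned at
#' full precision; round to two decimals (half-up) for reporting.
#'
#' @param n_true number of true plants (>= 1).
#' @param n_recognized number of detections.
#' @param n_correct number of correct detections.
#' @return One-row tibble: `n_true`, `n_recognized`, `n_correct`,
#'   `precision`, `recall`, `pe` (percentages).
#' @export
count_metrics <- function(n_true, n_recognized, n_correct) {
  if (n_true < 1) stop("count_metrics: n_true must be >= 1")
  if (n_recognized < 0) stop("count_metrics: n_recognized must be >= 0")
  if (n_correct > n_recognized || n_correct > n_true) {
    stop("count_metrics: n_correct cannot exceed n_true or n_recognized")
  }
  tibble::tibble(
    n_true = as.integer(n_true),
    n_recognized = as.integer(n_recognized),
    n_correct = as.integer(n_correct),
    precision = if (n_recognized == 0) 0 else 100 * n_correct / n_recognized,
    recall = 100 * n_correct / n_true,
    pe = 100 * abs(n_recognized - n_true) / n_true
  )
}

#' Regression evaluation metrics
#'
#' RMSE, MAPE and the coefficient of determination between measured and
#' true values: `rmse = sqrt(mean((m - t)^2))`,
#' `mape = 100 * mean(|m - t| / t)`,
#' `r2 = 1 - SS_res / SS_tot` about the truth mean. When all truth values
#' are equal `SS_tot = 0` and `r2` is returned as `NaN` with a warning.
#' An `r2_method = "pearson"` option computes the squared Pearson
#' correlation instead, since scatter-plot conventions vary.
#'
#' @param measured numeric vector of measured values.
#' @param truth numeric vector of true values (same length, non-zero for
#'   MAPE).
#' @return One-row tibble with `n`, `rmse`, `mape`, `r2`.
#' @param r2_method `"determination"` (default) or `"pearson"`.
#' @export
regression_metrics <- function(measured, truth,
                               r2_method = c("determination", "pearson")) {
  r2_method <- match.arg(r2_method)
  if (length(measured) != length(truth)) {
    stop("regression_metrics: measured and truth must have equal length")
  }
  if (length(measured) == 0) stop("regression_metrics: empty input")
  if (any(truth == 0)) {
    stop("regression_metrics: truth values must be non-zero for MAPE")
  }
  err <- measured - truth
  ss_tot <- sum((truth - mean(truth))^2)
  r2 <- if (r2_method == "pearson") {
    stats::cor(measured, truth)^2
  } else if (ss_tot == 0) {
    warning("regression_metrics: all truth values equal; r2 undefined")
    NaN
  } else {
    1 - sum(err^2) / ss_tot
  }
  tibble::tibble(
    n = length(measured),
    rmse = sqrt(mean(err^2)),
    mape = 100 * mean(abs(err) / abs(truth)),
    r2 = r2
  )
}

#' Evaluate a detection run against scene truth
#'
#' Convenience wrapper: matches seeds against true plant bases and computes
#' the counting metrics.
#'
#' @param seeds detected stem centroids (columns `x`, `y`).
#' @param truth scene truth (the `truth` element of [generate_scene()]), or
#'   any data frame of true bases with `x`, `y`.
#' @param max_dist matching distance, metres.
#' @return One-row tibble from [count_metrics()].
#' @export
evaluate_count <- function(seeds, truth, max_dist = 0.3) {
  bases <- if (is.data.frame(truth)) truth else truth$plants
  n_correct <- match_detections(seeds, bases, max_dist)
  count_metrics(nrow(bases), nrow(seeds), n_correct)
}
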