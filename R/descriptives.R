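#' Snodgrass-Corwin corrected hit and false-alarm rates
#'
#' Avoids extreme rates of 0 and 1 by adding 0.5 to the hit and
#' false-alarm counts and 1 to the old and new item totals before forming
#' proportions, so corrected rates always lie strictly inside (0, 1).
#'
#' @param hits,n_old,fas,n_new Counts (vectorized); `0 <= hits <= n_old`,
#'   `0 <= fas <= n_new`, totals >= 1.
#' @return A tibble with columns `hit_rate` and `fa_rate`.
#' @examples
#' corrected_rates(10, 10, 0, 10)
#' @export
corrected_rates <- function(hits, n_old, fas, n_new) {
  if (any(n_old < 1) || any(n_new < 1)) {
    abort("`n_old` and `n_new` must be >= 1.")
  }
  if (any(hits < 0) || any(hits > n_old)) {
    abort("`hits` must lie in 0..n_old.")
  }
  if (any(fas < 0) || any(fas > n_new)) {
    abort("`fas` must lie in 0..n_new.")
  }
  tibble::tibble(
    hit_rate = (hits + 0.5) / (n_old + 1),
    fa_rate = (fas + 0.5) / (n_new + 1)
  )
}

#' Sensitivity d-prime
#'
#' `qnorm(hit_rate) - qnorm(fa_rate)`. Rates must already be corrected
#' away from 0 and 1 (see [corrected_rates()]).
#'
#' @param hit_rate,fa_rate Rates strictly inside (0, 1); vectorized.
#' @return Numeric d-prime.
#' @export
dprime <- function(hit_rate, fa_rate) {
  if (any(hit_rate <= 0 | hit_rate >= 1) || any(fa_rate <= 0 | fa_rate >= 1)) {
    abort("rates must lie strictly inside (0, 1); correct them first.")
  }
  qnorm(hit_rate) - qnorm(fa_rate)
}

#' Assign memorability bins
#'
#' Scores above 0.75 are high memorability, scores in (0.55, 0.75] are
#' intermediate, and scores at or below 0.55 are low. Boundary scores go
#' to the lower bin, a fixed convention making the binning deterministic.
#'
#' @param score Memorability scores in `[0, 1]`.
#' @param thresholds Named vector `c(low = , high = )` of bin boundaries.
#' @return A factor with levels `low`, `mid`, `high`.
#' @export
bin_memorability <- function(score, thresholds = c(low = 0.55, high = 0.75)) {
  check_prob(score, "score")
  out <- ifelse(score > thresholds[["high"]], "high",
                ifelse(score > thresholds[["low"]], "mid", "low"))
  factor(out, levels = c("low", "mid", "high"))
}

#' Flag subjects performing no better than chance
#'
#' A subject is kept only when overall old/new accuracy exceeds 0.5 by a
#' one-sided exact binomial test at level `alpha`.
#'
#' @param trials Trial tibble (see [read_trials()] for the schema).
#' @param alpha One-sided significance level (default 0.05).
#' @param B Number of confidence bins.
#' @return A tibble with one row per subject: `subject`, `n_trials`,
#'   `n_correct`, `accuracy`, `p_value`, `keep`.
#' @export
exclude_at_chance <- function(trials, alpha = 0.05, B = 6) {
  check_trials(trials, B)
  trials |>
    dplyr::mutate(
      correct = (.data$status == "old") == is_old_response(.data$response, B)
    ) |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_correct = sum(.data$correct),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      accuracy = .data$n_correct / .data$n_trials,
      p_value = pbinom(.data$n_correct - 1, .data$n_trials, 0.5,
                       lower.tail = FALSE),
      keep = .data$p_value < alpha
    )
}

#' Tabulate confidence-rating counts
#'
#' The sufficient statistic for ROC fitting: a 2 x B matrix of response
#' counts with rows `old`, `new` and columns confidence bins 1..B.
#'
#' @inheritParams exclude_at_chance
#' @return An integer matrix of class `rating_counts`.
#' @export
rating_counts <- function(trials, B = 6) {
  stopifnot(is.data.frame(trials), all(c("status", "response") %in% names(trials)))
  if (any(trials$response < 1 | trials$response > B)) {
    abort(sprintf("`response` must be an integer in 1..%d.", B))
  }
  counts <- matrix(0L, nrow = 2, ncol = B,
                   dimnames = list(c("old", "new"), as.character(seq_len(B))))
  tab <- table(factor(trials$status, levels = c("old", "new")),
               factor(trials$response, levels = seq_len(B)))
  counts[] <- as.integer(tab)
  structure(counts, class = c("rating_counts", "matrix", "array"))
}

#' Empirical ROC points
#'
#' Cumulative hit and false-alarm rates from the most to the least
#' conservative criterion (response B downward), i.e. the `B - 1`
#' interior points of the ROC before appending the (0,0) and (1,1)
#' anchors.
#'
#' @param counts A [rating_counts()] matrix.
#' @return A tibble with columns `criterion` (the lowest response bin
#'   counted as "old" at that point), `fa` and `hit`, ordered from most
#'   conservative to most liberal.
#' @export
roc_points <- function(counts) {
  stopifnot(is.matrix(counts), nrow(counts) == 2)
  B <- ncol(counts)
  n_old <- sum(counts[1, ])
  n_new <- sum(counts[2, ])
  if (n_old == 0 || n_new == 0) {
    abort("both old and new trials are required to form ROC points.")
  }
  tail_sums_old <- rev(cumsum(rev(counts[1, ])))
  tail_sums_new <- rev(cumsum(rev(counts[2, ])))
  j <- seq(B, 2)
  tibble::tibble(criterion = j,
                 fa = unname(tail_sums_new[j]) / n_new,
                 hit = unname(tail_sums_old[j]) / n_old)
}

#' z-transformed ROC points
#'
#' Inverse-normal transform of the interior ROC points; points with a
#' cumulative rate of exactly 0 or 1, where the transform diverges, are
#' omitted.
#'
#' @param points A tibble from [roc_points()].
#' @return A tibble with columns `zfa` and `zhit`.
#' @export
z_transform <- function(points) {
  pts <- dplyr::filter(points,
                       .data$fa > 0, .data$fa < 1,
                       .data$hit > 0, .data$hit < 1)
  tibble::tibble(zfa = qnorm(pts$fa), zhit = qnorm(pts$hit))
}

#' Trapezoidal area under the ROC
#'
#' Appends the (0,0) and (1,1) anchors, sorts by false-alarm rate and
#' integrates by the trapezoidal rule. The chance diagonal gives 0.5 and
#' a perfect step (hit = 1 at fa = 0) gives 1.
#'
#' @inheritParams z_transform
#' @return A single number in `[0, 1]`.
#' @export
trapezoid_auc <- function(points) {
  fa <- c(0, points$fa, 1)
  hit <- c(0, points$hit, 1)
  ord <- order(fa, hit)
  fa <- fa[ord]
  hit <- hit[ord]
  sum(diff(fa) * (head(hit, -1) + tail(hit, -1)) / 2)
}

#' Per-subject recognition descriptives
#'
#' Corrected hit/false-alarm rates, d-prime and trapezoidal AUC per
#' subject, optionally split by memorability bin (rates are corrected
#' within each cell).
#'
#' @inheritParams exclude_at_chance
#' @param by_bin Split by [bin_memorability()] bins?
#' @return A tibble with one row per subject (x bin).
#' @export
subject_stats <- function(trials, B = 6, by_bin = FALSE) {
  check_trials(trials, B)
  trials <- dplyr::mutate(trials, .old_resp = is_old_response(.data$response, B))
  groups <- if (by_bin) {
    trials <- dplyr::mutate(trials, mem_bin = bin_memorability(.data$memorability))
    c("subject", "mem_bin")
  } else "subject"
  trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(
      n_old = sum(.data$status == "old"),
      n_new = sum(.data$status == "new"),
      hits = sum(.data$status == "old" & .data$.old_resp),
      fas = sum(.data$status == "new" & .data$.old_resp),
      auc = if (sum(.data$status == "old") > 0 && sum(.data$status == "new") > 0) {
        trapezoid_auc(roc_points(rating_counts(dplyr::pick(dplyr::everything()), B)))
      } else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      corrected_rates(.data$hits, .data$n_old, .data$fas, .data$n_new),
      dprime = dprime(.data$hit_rate, .data$fa_rate)
    )
}

#' Per-image recognition descriptives
#'
#' Pools responses over subjects for each image (each image is old for
#' some subjects and new for others), applies the count correction after
#' pooling, and computes corrected rates, d-prime and trapezoidal AUC per
#' image.
#'
#' @inheritParams exclude_at_chance
#' @return A tibble with one row per image: `image`, `memorability`,
#'   `mem_bin`, presentation counts, `hit_rate`, `fa_rate`, `dprime`,
#'   `auc`.
#' @export
image_stats <- function(trials, B = 6) {
  check_trials(trials, B)
  trials |>
    dplyr::mutate(.old_resp = is_old_response(.data$response, B)) |>
    dplyr::group_by(.data$image) |>
    dplyr::summarise(
      memorability = .data$memorability[1],
      n_old = sum(.data$status == "old"),
      n_new = sum(.data$status == "new"),
      hits = sum(.data$status == "old" & .data$.old_resp),
      fas = sum(.data$status == "new" & .data$.old_resp),
      auc = if (sum(.data$status == "old") > 0 && sum(.data$status == "new") > 0) {
        trapezoid_auc(roc_points(rating_counts(dplyr::pick(dplyr::everything()), B)))
      } else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mem_bin = bin_memorability(.data$memorability),
      corrected_rates(.data$hits, pmax(.data$n_old, 1),
                      .data$fas, pmax(.data$n_new, 1)),
      dprime = dprime(.data$hit_rate, .data$fa_rate)
    ) |>
    dplyr::relocate("mem_bin", .after = "memorability")
}

#' Correlate an image-level statistic with memorability
#'
#' @param stats An image-level tibble such as from [image_stats()],
#'   containing `memorability` and the target column.
#' @param field Name of the column to correlate with memorability.
#' @param method `"pearson"` or `"spearman"`.
#' @return A one-row tibble: `field`, `method`, `estimate`, `p_value`, `n`.
#' @export
image_level_association <- function(stats, field,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- stats$memorability
  y <- stats[[field]]
  if (is.null(y)) abort(sprintf("column `%s` not found.", field))
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) abort("need at least 3 images with defined values.")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) abort("constant vectors cannot be correlated.")
  ct <- cor.test(x[ok], y[ok], method = method, exact = FALSE)
  tibble::tibble(field = field, method = method,
                 estimate = unname(ct$estimate),
                 p_value = ct$p.value, n = sum(ok))
}
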