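#' Scaled difference of two statement proportions
#'
#' `(a - b) / (a + b)`, the contrast used for remember/know and
#' detailed/unfamiliar statements. Because a "know" statement implies
#' "not remember" (and vice versa), raw proportions are interdependent;
#' the scaled difference folds both into one outcome in `[-1, 1]`.
#' Positive values mean a propensity toward the first statement type,
#' zero means no propensity. Undefined (0/0) cells return `NA` rather
#' than raising an error; the statistic is scale invariant, so counts
#' and proportions give identical results.
#'
#' @param a,b Nonnegative counts or proportions (vectorized).
#' @return Numeric in `[-1, 1]`, `NA` where `a + b == 0`.
#' @examples
#' scaled_difference(0.52, 0.48)  # 0.04
#' @export
scaled_difference <- function(a, b) {
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE)) {
    abort("`a` and `b` must be nonnegative.")
  }
  tot <- a + b
  ifelse(tot > 0, (a - b) / tot, NA_real_)
}

# Response-class filter for the four statement bases.
basis_filter <- function(trials, basis, B) {
  old_resp <- is_old_response(trials$response, B)
  old_item <- trials$status == "old"
  keep <- switch(basis,
    hits = old_item & old_resp,
    false_alarms = !old_item & old_resp,
    correct_rejections = !old_item & !old_resp,
    false_rejections = old_item & !old_resp
  )
  trials[keep, , drop = FALSE]
}

basis_statements <- function(basis) {
  if (basis %in% c("hits", "false_alarms")) c("R", "K") else c("D", "U")
}

#' Per-subject scaled differences by memorability bin
#'
#' Restricts trials to one response class (basis), counts the two
#' relevant statement types per subject and memorability bin, and forms
#' the scaled difference (`Yold` for R/K bases, `Ynew` for D/U bases).
#' Cells with no trials in the basis are undefined (`NA` score) and are
#' expected to be dropped pairwise from group tests.
#'
#' @inheritParams exclude_at_chance
#' @param basis `"hits"`, `"false_alarms"`, `"correct_rejections"` or
#'   `"false_rejections"` (misses).
#' @return A tibble: `subject`, `mem_bin`, `basis`, `n_a`, `n_b` (counts
#'   of the first/second statement type), `prop_a`, `score`.
#' @export
subject_scaled_differences <- function(trials,
                                       basis = c("hits", "false_alarms",
                                                 "correct_rejections",
                                                 "false_rejections"),
                                       B = 6) {
  basis <- match.arg(basis)
  check_trials(trials, B, require_statement = TRUE)
  st <- basis_statements(basis)
  sel <- basis_filter(trials, basis, B)
  grid <- tidyr::expand_grid(
    subject = unique(trials$subject),
    mem_bin = factor(c("low", "mid", "high"), levels = c("low", "mid", "high"))
  )
  sel |>
    dplyr::mutate(mem_bin = bin_memorability(.data$memorability)) |>
    dplyr::group_by(.data$subject, .data$mem_bin) |>
    dplyr::summarise(
      n_a = sum(.data$statement == st[1]),
      n_b = sum(.data$statement == st[2]),
      .groups = "drop"
    ) |>
    dplyr::right_join(grid, by = c("subject", "mem_bin")) |>
    tidyr::replace_na(list(n_a = 0L, n_b = 0L)) |>
    dplyr::arrange(.data$subject, .data$mem_bin) |>
    dplyr::mutate(
      basis = basis,
      prop_a = ifelse(.data$n_a + .data$n_b > 0,
                      .data$n_a / (.data$n_a + .data$n_b), NA_real_),
      score = scaled_difference(.data$n_a, .data$n_b)
    )
}

#' One-sided JZS Bayes-factor t test
#'
#' One-sample (paired-difference) t test with a default Jeffreys-Zellner-
#' Siow prior: under H1 the standardized effect size follows a Cauchy
#' distribution with scale `prior_scale`, truncated to the hypothesized
#' direction for one-sided tests. The Bayes factor is computed by
#' numerical integration of the noncentral-t likelihood over the prior.
#' `bf10 > 1` favours the alternative; `bf01 = 1 / bf10`. The classical
#' paired t statistic and Cohen's `d_z` (mean difference / SD of
#' differences) are reported alongside.
#'
#' Zero-variance differences are only tolerated when the mean is also
#' zero (the t statistic is then taken as 0, i.e. data exactly at the
#' null); otherwise an error is raised.
#'
#' @param diffs Numeric vector of paired per-subject differences
#'   (`NA`s dropped), length >= 2 after removal.
#' @param direction `"greater"`, `"less"` or `"two-sided"` (direction of
#'   the H1 effect).
#' @param prior_scale Cauchy prior scale; defaults to `sqrt(2) / 2`, the
#'   conventional "medium" default.
#' @return A one-row tibble of class `bayes_t`: `t`, `n`, `df`,
#'   `prior_scale`, `direction`, `bf10`, `bf01`, `cohens_d`, `p_value`.
#' @export
bayes_t_test <- function(diffs, direction = c("greater", "less", "two-sided"),
                         prior_scale = sqrt(2) / 2) {
  direction <- match.arg(direction)
  diffs <- diffs[is.finite(diffs)]
  n <- length(diffs)
  if (n < 2) abort("need at least 2 finite differences.")
  s <- sd(diffs)
  m <- mean(diffs)
  if (s == 0) {
    if (m != 0) abort("zero-variance differences with nonzero mean.")
    tstat <- 0
  } else {
    tstat <- m / (s / sqrt(n))
  }
  df <- n - 1
  bf10 <- jzs_bf10(tstat, n, prior_scale, direction)
  p_value <- switch(direction,
    greater = stats::pt(tstat, df, lower.tail = FALSE),
    less = stats::pt(tstat, df),
    `two-sided` = 2 * stats::pt(-abs(tstat), df)
  )
  structure(
    tibble::tibble(
      t = tstat, n = n, df = df, prior_scale = prior_scale,
      direction = direction, bf10 = bf10, bf01 = 1 / bf10,
      cohens_d = if (s == 0) 0 else m / s, p_value = p_value
    ),
    class = c("bayes_t", "tbl_df", "tbl", "data.frame")
  )
}

# Marginal likelihood ratio: integral of the noncentral-t density over
# the (possibly truncated) Cauchy prior on delta, divided by the central
# density under H0.
jzs_bf10 <- function(tstat, n, prior_scale, direction) {
  df <- n - 1
  m0 <- dt(tstat, df)
  # prior mass doubles on the retained half-line for one-sided tests
  weight <- if (direction == "two-sided") 1 else 2
  # dt(ncp =) warns about full precision near the distribution tails;
  # the residual error is far below the quadrature tolerance
  f <- function(d) {
    suppressWarnings(dt(tstat, df, ncp = d * sqrt(n))) *
      weight * dcauchy(d, 0, prior_scale)
  }
  bounds <- switch(direction,
    greater = c(0, Inf),
    less = c(-Inf, 0),
    `two-sided` = c(-Inf, Inf)
  )
  # split at the likelihood peak so integrate() cannot miss a narrow mode
  dhat <- tstat / sqrt(n)
  knots <- sort(unique(c(bounds, max(min(dhat, bounds[2]), bounds[1]))))
  m1 <- sum(purrr::map_dbl(seq_len(length(knots) - 1), function(i) {
    integrate(f, knots[i], knots[i + 1], rel.tol = 1e-9,
              stop.on.error = FALSE)$value
  }))
  m1 / m0
}

#' Per-image statement scores
#'
#' Pools statements over subjects for each image: `yold` is the scaled
#' difference of R vs K statements among hits, `ynew` of D vs U
#' statements among correct rejections. Images with no defined score in
#' a column carry `NA`.
#'
#' @inheritParams exclude_at_chance
#' @return A tibble: `image`, `memorability`, `mem_bin`, pooled counts
#'   `r`, `k`, `d`, `u`, and `yold`, `ynew`.
#' @seealso [statement_correlations()] for the image-level correlations
#'   with memorability.
#' @export
image_statement_scores <- function(trials, B = 6) {
  check_trials(trials, B, require_statement = TRUE)
  hits <- basis_filter(trials, "hits", B)
  crs <- basis_filter(trials, "correct_rejections", B)
  count_by_image <- function(df, st) {
    df |>
      dplyr::group_by(.data$image) |>
      dplyr::summarise(a = sum(.data$statement == st[1]),
                       b = sum(.data$statement == st[2]),
                       .groups = "drop")
  }
  rk <- count_by_image(hits, c("R", "K"))
  du <- count_by_image(crs, c("D", "U"))
  trials |>
    dplyr::distinct(.data$image, .data$memorability) |>
    dplyr::left_join(dplyr::rename(rk, r = "a", k = "b"), by = "image") |>
    dplyr::left_join(dplyr::rename(du, d = "a", u = "b"), by = "image") |>
    tidyr::replace_na(list(r = 0L, k = 0L, d = 0L, u = 0L)) |>
    dplyr::mutate(
      mem_bin = bin_memorability(.data$memorability),
      yold = scaled_difference(.data$r, .data$k),
      ynew = scaled_difference(.data$d, .data$u)
    ) |>
    dplyr::relocate("mem_bin", .after = "memorability") |>
    dplyr::arrange(.data$image)
}

#' Correlations of image statement scores with memorability
#'
#' Pearson correlations (pairwise-complete) of per-image `yold` and
#' `ynew` with memorability, and of `yold` with `ynew`.
#'
#' @param scores A tibble from [image_statement_scores()].
#' @return A tibble with columns `pair`, `estimate`, `p_value`, `n`.
#' @export
statement_correlations <- function(scores) {
  if (sum(is.finite(scores$yold)) < 3 && sum(is.finite(scores$ynew)) < 3) {
    abort("need at least 3 images with defined scores.")
  }
  one <- function(x, y, label) {
    ok <- is.finite(x) & is.finite(y)
    ct <- cor.test(x[ok], y[ok])
    tibble::tibble(pair = label, estimate = unname(ct$estimate),
                   p_value = ct$p.value, n = sum(ok))
  }
  dplyr::bind_rows(
    one(scores$memorability, scores$yold, "memorability~yold"),
    one(scores$memorability, scores$ynew, "memorability~ynew"),
    one(scores$yold, scores$ynew, "yold~ynew")
  )
}

#' Statement summary table by memorability bin
#'
#' A compact summary mirroring the usual reporting layout: for each
#' memorability bin and each statement basis, the mean per-subject
#' statement proportions, the mean of per-subject scaled differences
#' (`mean_score`, each subject weighted equally) and the scaled
#' difference of the pooled statement counts (`score_of_means`,
#' trial-weighted). The two aggregates differ in general; both are
#' reported because published tables do not always say which was used.
#'
#' @inheritParams exclude_at_chance
#' @return A tibble: `basis`, `mem_bin`, `prop_a`, `prop_b`,
#'   `mean_score`, `score_of_means`, `n_subjects` (subjects with a
#'   defined cell).
#' @export
rk_summary <- function(trials, B = 6) {
  bases <- c("hits", "false_alarms", "correct_rejections", "false_rejections")
  purrr::map_dfr(bases, function(bs) {
    subject_scaled_differences(trials, bs, B) |>
      dplyr::group_by(.data$mem_bin) |>
      dplyr::summarise(
        basis = bs,
        prop_a = mean(.data$prop_a, na.rm = TRUE),
        mean_score = mean(.data$score, na.rm = TRUE),
        score_of_means = scaled_difference(sum(.data$n_a), sum(.data$n_b)),
        n_subjects = sum(is.finite(.data$score)),
        .groups = "drop"
      ) |>
      dplyr::mutate(prop_b = 1 - .data$prop_a, .after = "prop_a")
  }) |>
    dplyr::relocate("basis")
}
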