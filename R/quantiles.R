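#' Bin items into memorability quantiles of equal trial numbers
#'
#' Items are rank ordered by memorability (ties broken by image id, so
#' the assignment is stable under any input order) and packed greedily
#' into `Q` bins of approximately equal total trial counts; totals differ
#' by at most the largest single-item trial count.
#'
#' @param items A tibble with columns `image`, `memorability` and
#'   optionally `n_trials` (defaults to 1 per item).
#' @param Q Number of quantiles (>= 2, <= number of items).
#' @return `items` sorted by memorability with an integer `quantile`
#'   column (1 = least memorable).
#' @export
quantile_bin <- function(items, Q = 30) {
  Q <- check_scalar_count(Q, "Q", min = 2)
  stopifnot(is.data.frame(items),
            all(c("image", "memorability") %in% names(items)))
  if (Q > nrow(items)) abort("`Q` cannot exceed the number of items.")
  if (!"n_trials" %in% names(items)) items$n_trials <- 1L
  items <- dplyr::arrange(items, .data$memorability, .data$image)
  total <- sum(items$n_trials)
  q <- pmin(Q, ceiling(cumsum(items$n_trials) / (total / Q)))
  # guard against empty bins when trial counts are very unequal
  q <- as.integer(factor(q, levels = sort(unique(q))))
  if (max(q) < Q) {
    warn(sprintf("only %d non-empty quantiles could be formed (Q = %d).",
                 max(q), Q))
  }
  dplyr::mutate(items, quantile = q)
}

#' Fit both ROC models within each memorability quantile
#'
#' Pools trials over subjects within each quantile (pooling, rather than
#' averaging per-subject fits, is what gives each quantile enough trials
#' for a stable ROC) and fits the DPSD and UVSD models to each pooled
#' rating table.
#'
#' @inheritParams exclude_at_chance
#' @param assignment A tibble from [quantile_bin()] (`image`,
#'   `quantile`).
#' @param n_restarts Optimizer restarts per fit.
#' @return A tibble with one row per quantile x model: `quantile`,
#'   `n_trials`, fitted parameters, fit statistics and the `roc_fit`
#'   object in a list column. Unfittable quantiles are dropped with a
#'   warning.
#' @export
fit_quantiles <- function(trials, assignment, B = 6, n_restarts = 10) {
  check_trials(trials, B)
  stopifnot(all(c("image", "quantile") %in% names(assignment)))
  joined <- dplyr::inner_join(trials,
                              dplyr::select(assignment, "image", "quantile"),
                              by = "image")
  purrr::map_dfr(sort(unique(joined$quantile)), function(q) {
    df <- dplyr::filter(joined, .data$quantile == q)
    counts <- rating_counts(df, B)
    if (sum(counts[1, ]) == 0 || sum(counts[2, ]) == 0) {
      warn(sprintf("quantile %d has no old or no new trials; skipped.", q))
      return(NULL)
    }
    purrr::map_dfr(c("dpsd", "uvsd"), function(m) {
      f <- fit_rating_counts(counts, m, n_restarts)
      dplyr::bind_cols(tibble::tibble(quantile = q), glance(f),
                       tibble::tibble(fit = list(f)))
    })
  })
}

# ---- cumulative-logit (proportional odds) maximum likelihood -----------

ord_nll <- function(theta, X, y, Q) {
  k <- Q - 1
  zeta <- cumsum(c(theta[1], exp(pmin(theta[2:k], 20))))
  beta <- theta[(k + 1):length(theta)]
  eta <- drop(X %*% beta)
  lower <- c(-Inf, zeta)[y]
  upper <- c(zeta, Inf)[y]
  p <- plogis(upper - eta) - plogis(lower - eta)
  -sum(log(pmax(p, 1e-300)))
}

#' Ordinal (proportional-odds) regression by maximum likelihood
#'
#' Cumulative-logit model for ordered outcomes `1..Q` with `Q - 1`
#' ordered intercepts, fitted by direct likelihood maximization (the
#' intercepts are parameterized as first threshold plus log-gaps, so
#' ordering is enforced). Predictors are standardized internally for
#' numerical stability and the coefficients mapped back to the raw
#' scale; the standardized coefficients (raw coefficient times predictor
#' SD, a latent-scale standardization) are reported alongside.
#'
#' The model chi-square is the likelihood ratio against the
#' intercepts-only model; `r2_nagelkerke` is Nagelkerke's rescaled
#' Cox-Snell pseudo-R2 and `r2_adjusted` applies the usual
#' degrees-of-freedom adjustment `1 - (1 - R2)(n - 1)/(n - p - 1)`.
#' With one observation per rank (e.g. 30 quantiles) the model is
#' heavily parameterized and can diverge under perfect separation; the
#' `converged` flag is honest about optimizer status.
#'
#' @param data A data frame containing the outcome and predictors.
#' @param outcome Name of the ordered-rank column (integer 1..Q or an
#'   ordered factor).
#' @param predictors Character vector of predictor column names (finite,
#'   non-constant).
#' @param n_restarts Optimizer restarts.
#' @return An object of class `ordinal_fit` with a coefficient table
#'   (`estimate`, `std_error`, `z`, `p_value`, `std_coef`), `chi2`,
#'   `df`, `p_model`, `logLik`, `logLik_null`, `r2_nagelkerke`,
#'   `r2_adjusted`, `n`, `converged`. [tidy()] and [glance()] methods
#'   are provided.
#' @export
ordinal_fit <- function(data, outcome, predictors, n_restarts = 5) {
  stopifnot(is.data.frame(data), outcome %in% names(data),
            all(predictors %in% names(data)))
  y_raw <- data[[outcome]]
  y <- if (is.factor(y_raw)) as.integer(y_raw) else as.integer(factor(y_raw))
  Q <- max(y)
  if (Q < 3) abort("the outcome needs at least 3 ordered levels.")
  X_raw <- as.matrix(data[, predictors, drop = FALSE])
  if (any(!is.finite(X_raw))) abort("predictors must be finite.")
  sds <- apply(X_raw, 2, sd)
  if (any(sds == 0)) abort("predictors must be non-constant.")
  mus <- colMeans(X_raw)
  X <- sweep(sweep(X_raw, 2, mus), 2, sds, "/")
  n <- nrow(X)
  p <- length(predictors)
  k <- Q - 1

  # start: thresholds at logit of empirical cumulative proportions
  cum <- cumsum(tabulate(y, Q))[1:k] / n
  cum <- pmin(pmax(cum, 1 / (2 * n)), 1 - 1 / (2 * n))
  zeta0 <- qlogis(cum)
  for (i in seq_len(k)[-1]) zeta0[i] <- max(zeta0[i], zeta0[i - 1] + 1e-3)
  theta0 <- c(zeta0[1], log(diff(zeta0)), rep(0, p))

  jitter <- withr::with_seed(20260918L, {
    matrix(rnorm((n_restarts - 1) * length(theta0), sd = 0.3),
           ncol = length(theta0))
  })
  starts <- rbind(theta0, sweep(jitter, 2, theta0, `+`))
  best <- NULL
  for (r in seq_len(nrow(starts))) {
    opt <- tryCatch(
      optim(starts[r, ], ord_nll, X = X, y = y, Q = Q, method = "BFGS",
            control = list(maxit = 1000, reltol = 1e-12), hessian = FALSE),
      error = function(e) NULL
    )
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value - 1e-9) best <- opt
  }
  if (is.null(best)) abort("ordinal regression failed to optimize.")
  H <- tryCatch(
    stats::optimHess(best$par, ord_nll, X = X, y = y, Q = Q),
    error = function(e) NULL
  )
  se_std <- rep(NA_real_, p)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      dv <- diag(V)[(k + 1):(k + p)]
      se_std[dv > 0] <- sqrt(dv[dv > 0])
    }
  }
  beta_std <- unname(best$par[(k + 1):(k + p)])
  beta_raw <- beta_std / unname(sds)
  se_raw <- se_std / unname(sds)
  logL <- -best$value

  # intercepts-only null model (beta fixed at zero)
  opt0 <- optim(theta0[1:k], function(th) ord_nll(c(th, rep(0, p)), X, y, Q),
                method = "BFGS", control = list(maxit = 1000, reltol = 1e-12))
  logL0 <- -opt0$value

  chi2 <- max(2 * (logL - logL0), 0)
  r2_cs <- 1 - exp(-chi2 / n)
  r2_max <- 1 - exp(2 * logL0 / n)
  r2_n <- if (r2_max > 0) r2_cs / r2_max else NA_real_
  r2_adj <- if (n - p - 1 > 0) 1 - (1 - r2_n) * (n - 1) / (n - p - 1) else NA_real_

  coefs <- tibble::tibble(
    term = predictors,
    estimate = beta_raw,
    std_error = se_raw,
    z = beta_raw / se_raw,
    p_value = 2 * pnorm(-abs(beta_raw / se_raw)),
    std_coef = beta_std
  )
  structure(
    list(coefficients = coefs, zeta = NULL,
         chi2 = chi2, df = p, p_model = pchisq(chi2, p, lower.tail = FALSE),
         logLik = logL, logLik_null = logL0,
         r2_nagelkerke = r2_n, r2_adjusted = r2_adj,
         n = n, Q = Q, converged = best$convergence == 0),
    class = "ordinal_fit"
  )
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf("<ordinal_fit: %d obs, %d levels>\n", x$n, x$Q))
  print(x$coefficients)
  cat(sprintf("  chi2(%d) = %.2f (p = %.4g)  R2[Nagelkerke] = %.3f (adj %.3f)\n",
              x$df, x$chi2, x$p_model, x$r2_nagelkerke, x$r2_adjusted))
  if (!x$converged) cat("  [not converged]\n")
  invisible(x)
}

#' @export
tidy.ordinal_fit <- function(x, ...) x$coefficients

#' @export
glance.ordinal_fit <- function(x, ...) {
  tibble::tibble(
    chi2 = x$chi2, df = x$df, p_model = x$p_model,
    logLik = x$logLik, logLik_null = x$logLik_null,
    r2_nagelkerke = x$r2_nagelkerke, r2_adjusted = x$r2_adjusted,
    n = x$n, converged = x$converged
  )
}

#' Predict memorability quantile rank from model parameters
#'
#' The exploratory stage: for each ROC model, regress quantile rank
#' (1..Q, ordered) on that model's two signal parameters (`Ro` and `d'`
#' for DPSD; `d'` and `Vo` for UVSD) with [ordinal_fit()], and compare
#' how much rank variance each parameter set explains.
#'
#' @param quantile_fits A tibble from [fit_quantiles()].
#' @return A list with one `ordinal_fit` per model (`dpsd`, `uvsd`) and
#'   a `summary` tibble of per-model fit statistics.
#' @export
memorability_rank_regression <- function(quantile_fits) {
  wide <- quantile_fits |>
    dplyr::select("quantile", "model", "ro", "dprime", "vo")
  dpsd_df <- wide |>
    dplyr::filter(.data$model == "dpsd") |>
    dplyr::select("quantile", "ro", "dprime")
  uvsd_df <- wide |>
    dplyr::filter(.data$model == "uvsd") |>
    dplyr::select("quantile", "dprime", "vo")
  if (nrow(dpsd_df) < 5 || nrow(uvsd_df) < 5) {
    abort("need fits for at least 5 quantiles per model.")
  }
  fits <- list(
    dpsd = ordinal_fit(dpsd_df, "quantile", c("ro", "dprime")),
    uvsd = ordinal_fit(uvsd_df, "quantile", c("dprime", "vo"))
  )
  fits$summary <- purrr::imap_dfr(fits[c("dpsd", "uvsd")], function(f, m) {
    dplyr::bind_cols(tibble::tibble(model = m), glance(f))
  })
  fits
}
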