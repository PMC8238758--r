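#' Predicted response probabilities of the DPSD model
#'
#' Under the dual-process model an old item is recollected with
#' probability `Ro`, which loads all its mass on the most-confident "old"
#' bin; otherwise (and for new items) responses come from binning a
#' Gaussian familiarity signal by the criteria. The cumulative form is
#' \deqn{P(\ge j \mid old) = Ro + (1 - Ro)(1 - \Phi(c_{j-1} - d')),\quad
#'       P(\ge j \mid new) = 1 - \Phi(c_{j-1}).}
#'
#' @param ro Recollection probability in `[0, 1]`.
#' @param dprime Familiarity sensitivity (>= 0).
#' @param criteria `B - 1` strictly increasing thresholds.
#' @return A 2 x B matrix of bin probabilities, rows `old` and `new`,
#'   each summing to 1.
#' @export
dpsd_response_probs <- function(ro, dprime, criteria) {
  check_prob(ro, "ro")
  check_criteria(criteria)
  B <- length(criteria) + 1L
  fam_old <- diff(c(0, pnorm(criteria - dprime), 1))
  p_old <- (1 - ro) * fam_old
  p_old[B] <- p_old[B] + ro
  p_new <- diff(c(0, pnorm(criteria), 1))
  out <- rbind(old = p_old, new = p_new)
  colnames(out) <- as.character(seq_len(B))
  out
}

#' Predicted response probabilities of the UVSD model
#'
#' Single-dimension signal detection where the old-item strength
#' distribution is `Normal(d', Vo)` and the new-item distribution is
#' standard normal:
#' \deqn{P(\ge j \mid old) = 1 - \Phi((c_{j-1} - d') / Vo).}
#' With `Vo = 1` this reduces to the equal-variance model, identical to
#' DPSD with `Ro = 0`.
#'
#' @param dprime Mean old-item strength (unconstrained).
#' @param vo Old-item standard deviation (> 0).
#' @inheritParams dpsd_response_probs
#' @return A 2 x B matrix of bin probabilities.
#' @export
uvsd_response_probs <- function(dprime, vo, criteria) {
  if (vo <= 0) abort("`vo` must be > 0.")
  check_criteria(criteria)
  B <- length(criteria) + 1L
  p_old <- diff(c(0, pnorm((criteria - dprime) / vo), 1))
  p_new <- diff(c(0, pnorm(criteria), 1))
  out <- rbind(old = p_old, new = p_new)
  colnames(out) <- as.character(seq_len(B))
  out
}

#' Product-multinomial log-likelihood of a rating table
#'
#' Old and new rows are independent multinomials given the model's bin
#' probabilities; the multinomial coefficient is omitted (it is constant
#' across models and cancels in all comparisons used here).
#'
#' @param counts A 2 x B [rating_counts()] matrix.
#' @param probs A 2 x B probability matrix from [dpsd_response_probs()]
#'   or [uvsd_response_probs()].
#' @return The log-likelihood (a scalar).
#' @export
roc_loglik <- function(counts, probs) {
  stopifnot(dim(counts) == dim(probs))
  sum(counts * log(pmax(probs, 1e-300)))
}

#' Likelihood-ratio goodness-of-fit statistic
#'
#' `G = 2 * sum(O * log(O / E))` over cells with positive observed
#' counts. Expected counts are not floored; cells with `O = 0`
#' contribute 0.
#'
#' @param observed,expected Nonnegative count arrays of matching shape;
#'   `expected` must be positive wherever `observed` is.
#' @return The G statistic (>= 0 up to rounding of expected counts).
#' @export
g_statistic <- function(observed, expected) {
  if (any(observed < 0) || any(expected < 0)) {
    abort("counts must be nonnegative.")
  }
  stopifnot(length(observed) == length(expected))
  pos <- observed > 0
  if (any(expected[pos] <= 0)) {
    abort("`expected` must be positive wherever `observed` is.")
  }
  2 * sum(observed[pos] * log(observed[pos] / expected[pos]))
}

# ---- internal fitting machinery ----------------------------------------

# theta packing: DPSD  = (qlogis(ro), softplus_inv(dprime), c1, log gaps)
#                UVSD  = (dprime,     log(vo),              c1, log gaps)
unpack_theta <- function(theta, model) {
  k <- length(theta)
  # clamp log-gaps so criteria stay strictly increasing in finite arithmetic
  crit <- unname(cumsum(c(theta[3], exp(pmin(pmax(theta[4:k], -20), 20)))))
  if (model == "dpsd") {
    list(ro = unname(plogis(theta[1])), dprime = unname(softplus(theta[2])),
         vo = NA_real_, criteria = crit)
  } else {
    list(ro = NA_real_, dprime = unname(theta[1]),
         vo = unname(exp(pmin(theta[2], 20))), criteria = crit)
  }
}

model_probs <- function(params, model) {
  if (model == "dpsd") {
    dpsd_response_probs(params$ro, params$dprime, params$criteria)
  } else {
    uvsd_response_probs(params$dprime, params$vo, params$criteria)
  }
}

neg_loglik <- function(theta, counts, model) {
  if (any(!is.finite(theta))) return(1e10)
  params <- unpack_theta(theta, model)
  v <- tryCatch(-roc_loglik(counts, model_probs(params, model)),
                error = function(e) 1e10)
  if (!is.finite(v)) 1e10 else v
}

# Analytic gradient of neg_loglik in the unconstrained parameterization;
# BFGS with finite differences is ~8x slower and less reliable here.
grad_neg_loglik <- function(theta, counts, model) {
  params <- unpack_theta(theta, model)
  crit <- params$criteria
  B <- length(crit) + 1L
  p <- tryCatch(model_probs(params, model), error = function(e) NULL)
  if (is.null(p)) return(rep(0, length(theta)))
  w1 <- -counts[1, ] / pmax(p[1, ], 1e-12)
  w2 <- -counts[2, ] / pmax(p[2, ], 1e-12)
  # derivative of each row's NLL wrt the cumulative probs at the criteria
  gr_new <- (w2[-B] - w2[-1])
  phi_new <- dnorm(crit)
  if (model == "dpsd") {
    ro <- params$ro
    q <- pnorm(crit - params$dprime)
    fam <- diff(c(0, q, 1))
    phi_old <- dnorm(crit - params$dprime)
    gq_old <- (1 - ro) * (w1[-B] - w1[-1])
    g_ro <- sum(w1 * (-fam)) + w1[B]
    g_d <- sum(gq_old * (-phi_old))
    gc <- gq_old * phi_old + gr_new * phi_new
    g1 <- g_ro * ro * (1 - ro)
    g2 <- g_d * plogis(theta[2])
  } else {
    vo <- params$vo
    s <- (crit - params$dprime) / vo
    phi_old <- dnorm(s)
    gq_old <- (w1[-B] - w1[-1])
    g_d <- sum(gq_old * (-phi_old / vo))
    g_vo <- sum(gq_old * (-phi_old * s / vo))
    gc <- gq_old * phi_old / vo + gr_new * phi_new
    g1 <- g_d
    g2 <- g_vo * vo
  }
  gaps <- exp(pmin(pmax(theta[4:length(theta)], -20), 20))
  g_gap <- gaps * rev(cumsum(rev(gc)))[-1]
  c(g1, g2, sum(gc), g_gap)
}

# Moment-based start: criteria from corrected cumulative false-alarm
# rates, d' from mean z-difference, Vo from the zROC slope.
start_theta <- function(counts, model) {
  B <- ncol(counts)
  n_old <- sum(counts[1, ])
  n_new <- sum(counts[2, ])
  cum_old <- rev(cumsum(rev(counts[1, ])))[-1]
  cum_new <- rev(cumsum(rev(counts[2, ])))[-1]
  h <- (cum_old + 0.5) / (n_old + 1)
  f <- (cum_new + 0.5) / (n_new + 1)
  crit <- qnorm(1 - f)
  # ties from empty bins would break the log-gap transform
  for (i in seq_len(B - 1)[-1]) {
    crit[i] <- max(crit[i], crit[i - 1] + 1e-3)
  }
  zh <- qnorm(h)
  zf <- qnorm(f)
  d0 <- max(mean(zh - zf), 0.05)
  slope <- if (sd(zf) > 0) sd(zh) / sd(zf) else 1
  vo0 <- min(max(1 / max(slope, 1e-3), 0.5), 3)
  gaps <- pmax(diff(crit), 1e-3)
  if (model == "dpsd") {
    c(qlogis(0.15), softplus_inv(d0), crit[1], log(gaps))
  } else {
    c(d0, log(vo0), crit[1], log(gaps))
  }
}

fit_one_model <- function(counts, model, n_restarts = 10) {
  B <- ncol(counts)
  theta0 <- start_theta(counts, model)
  k <- length(theta0)
  jitter <- withr::with_seed(20260917L, {
    matrix(rnorm((n_restarts - 1) * k, sd = 0.4), ncol = k)
  })
  starts <- rbind(theta0, sweep(jitter, 2, theta0, `+`))
  best <- NULL
  used <- 0L
  for (r in seq_len(nrow(starts))) {
    used <- used + 1L
    opt <- tryCatch(
      optim(starts[r, ], neg_loglik, gr = grad_neg_loglik,
            counts = counts, model = model,
            method = "BFGS", control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value - 1e-9) best <- opt
  }
  list(opt = best, n_restarts_used = used)
}

#' Fit a DPSD or UVSD model to a rating table by maximum likelihood
#'
#' Maximizes the product-multinomial likelihood over the model parameters
#' and `B - 1` ordered criteria, using an unconstrained
#' reparameterization (logit for `Ro`, softplus for the DPSD `d'`, log
#' for `Vo`, first-threshold plus log-gaps for the criteria) and multiple
#' deterministically-jittered restarts from a moment-based start. Both
#' models carry `B + 1` free parameters, so BIC comparisons reflect fit
#' alone; the goodness-of-fit G-test has `2(B - 1) - (B + 1) = B - 3`
#' degrees of freedom.
#'
#' @param counts A 2 x B [rating_counts()] matrix with positive row
#'   totals and at least two nonzero bins per row.
#' @param model `"dpsd"` or `"uvsd"`.
#' @param n_restarts Number of optimizer starts (first is unjittered).
#' @return An object of class `roc_fit`: parameters, `logLik`, `G`,
#'   `df`, `p_value`, `bic`, `n_params`, `n_trials`, `converged`,
#'   `identifiable`, `n_restarts_used`. Degenerate tables (all mass in
#'   one bin for both rows) are flagged `identifiable = FALSE` rather
#'   than raising an error.
#' @seealso [fit_roc()] for the data-frame interface.
#' @export
fit_rating_counts <- function(counts, model = c("dpsd", "uvsd"),
                              n_restarts = 10) {
  model <- match.arg(model)
  stopifnot(is.matrix(counts), nrow(counts) == 2)
  B <- ncol(counts)
  if (B < 3) abort("need at least 3 confidence bins to fit these models.")
  n_old <- sum(counts[1, ])
  n_new <- sum(counts[2, ])
  if (n_old == 0 || n_new == 0) {
    abort("both rows of `counts` must have positive totals.")
  }
  identifiable <- sum(counts[1, ] > 0) >= 2 && sum(counts[2, ] > 0) >= 2

  fit <- fit_one_model(counts, model, n_restarts)
  opt <- fit$opt
  if (is.null(opt)) {
    opt <- list(par = start_theta(counts, model), convergence = 99L)
    opt$value <- neg_loglik(opt$par, counts, model)
  }
  params <- unpack_theta(opt$par, model)
  probs <- model_probs(params, model)
  logL <- -opt$value
  n_params <- B + 1L
  n_trials <- n_old + n_new
  expected <- probs * c(n_old, n_new)
  G <- g_statistic(counts, expected)
  df <- 2L * (B - 1L) - n_params
  p <- pchisq(G, df, lower.tail = FALSE)
  structure(
    list(model = model,
         ro = params$ro, dprime = params$dprime, vo = params$vo,
         criteria = params$criteria,
         logLik = logL, G = G, df = df, p_value = p,
         bic = -2 * logL + n_params * log(n_trials),
         n_params = n_params, n_trials = n_trials,
         converged = !is.null(opt) && opt$convergence == 0 && identifiable,
         identifiable = identifiable,
         n_restarts_used = fit$n_restarts_used,
         counts = counts),
    class = "roc_fit"
  )
}

#' @export
print.roc_fit <- function(x, ...) {
  cat(sprintf("<roc_fit: %s>\n", toupper(x$model)))
  if (x$model == "dpsd") {
    cat(sprintf("  Ro = %.3f  d' = %.3f\n", x$ro, x$dprime))
  } else {
    cat(sprintf("  d' = %.3f  Vo = %.3f\n", x$dprime, x$vo))
  }
  cat(sprintf("  criteria: %s\n", paste(sprintf("%.2f", x$criteria), collapse = " ")))
  cat(sprintf("  logL = %.2f  G(%d) = %.2f (p = %.3f)  BIC = %.1f\n",
              x$logLik, x$df, x$G, x$p_value, x$bic))
  if (!x$converged) cat("  [not converged / not identifiable]\n")
  invisible(x)
}

#' @export
tidy.roc_fit <- function(x, ...) {
  pars <- if (x$model == "dpsd") {
    c(Ro = x$ro, dprime = x$dprime)
  } else {
    c(dprime = x$dprime, Vo = x$vo)
  }
  tibble::tibble(
    term = c(names(pars), paste0("c", seq_along(x$criteria))),
    estimate = c(unname(pars), x$criteria)
  )
}

#' @export
glance.roc_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, ro = x$ro, dprime = x$dprime, vo = x$vo,
    logLik = x$logLik, G = x$G, df = x$df, p_value = x$p_value,
    bic = x$bic, n_params = x$n_params, n_trials = x$n_trials,
    converged = x$converged, n_restarts_used = x$n_restarts_used
  )
}

#' Fit ROC models across subjects
#'
#' Tabulates each subject's rating counts and fits the requested
#' model(s), returning one row per subject x model with the fitted
#' parameters, fit statistics and the full `roc_fit` object in a list
#' column.
#'
#' @inheritParams exclude_at_chance
#' @param model `"both"` (default), `"dpsd"` or `"uvsd"`.
#' @param n_restarts Optimizer restarts per fit.
#' @return A tibble with columns `subject`, `model`, `ro`, `dprime`,
#'   `vo`, `logLik`, `G`, `df`, `p_value`, `bic`, `converged`, `fit`.
#' @export
fit_roc <- function(trials, model = c("both", "dpsd", "uvsd"), B = 6,
                    n_restarts = 10) {
  model <- match.arg(model)
  check_trials(trials, B)
  models <- if (model == "both") c("dpsd", "uvsd") else model
  trials |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_map(function(df, key) {
      counts <- rating_counts(df, B)
      purrr::map_dfr(models, function(m) {
        f <- fit_rating_counts(counts, m, n_restarts)
        dplyr::bind_cols(tibble::tibble(subject = key$subject),
                         glance(f), tibble::tibble(fit = list(f)))
      })
    }) |>
    purrr::list_rbind()
}

#' Declare a winning model across subjects
#'
#' A model wins when it attains the lower BIC in at least 80% of
#' subjects *and* its G-test is non-rejected (p >= `alpha`) in more than
#' 80% of subjects; otherwise the comparison is inconclusive.
#'
#' @param fits A tibble from [fit_roc()] containing both models for
#'   every subject.
#' @param bic_prop Required proportion of subjects with lower BIC
#'   (default 0.8).
#' @param fit_prop Required proportion of subjects with an acceptable
#'   G-test (strictly exceeded; default 0.8).
#' @param alpha G-test significance level (default 0.05).
#' @return A list of class `model_selection`: `winner` (`"dpsd"`,
#'   `"uvsd"` or `"inconclusive"`), the per-model support proportions,
#'   and a per-subject summary tibble.
#' @export
select_winning_model <- function(fits, bic_prop = 0.8, fit_prop = 0.8,
                                 alpha = 0.05) {
  needed <- c("subject", "model", "bic", "p_value")
  stopifnot(all(needed %in% names(fits)))
  wide <- fits |>
    dplyr::select(dplyr::all_of(needed)) |>
    tidyr::pivot_wider(names_from = "model",
                       values_from = c("bic", "p_value"))
  if (!all(c("bic_dpsd", "bic_uvsd") %in% names(wide)) ||
      anyNA(wide$bic_dpsd) || anyNA(wide$bic_uvsd)) {
    abort("both models must be fitted for every subject.")
  }
  wide <- wide |>
    dplyr::mutate(
      dpsd_lower_bic = .data$bic_dpsd < .data$bic_uvsd,
      dpsd_acceptable = .data$p_value_dpsd >= alpha,
      uvsd_acceptable = .data$p_value_uvsd >= alpha
    )
  prop_lower <- c(dpsd = mean(wide$dpsd_lower_bic),
                  uvsd = mean(!wide$dpsd_lower_bic))
  prop_accept <- c(dpsd = mean(wide$dpsd_acceptable),
                   uvsd = mean(wide$uvsd_acceptable))
  winner <- "inconclusive"
  for (m in c("dpsd", "uvsd")) {
    if (prop_lower[[m]] >= bic_prop && prop_accept[[m]] > fit_prop) {
      winner <- m
    }
  }
  structure(
    list(winner = winner, prop_lower_bic = prop_lower,
         prop_acceptable = prop_accept, n_subjects = nrow(wide),
         per_subject = wide),
    class = "model_selection"
  )
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection over %d subjects>\n", x$n_subjects))
  cat(sprintf("  lower BIC:    DPSD %.0f%%  UVSD %.0f%%\n",
              100 * x$prop_lower_bic[["dpsd"]], 100 * x$prop_lower_bic[["uvsd"]]))
  cat(sprintf("  G acceptable: DPSD %.0f%%  UVSD %.0f%%\n",
              100 * x$prop_acceptable[["dpsd"]], 100 * x$prop_acceptable[["uvsd"]]))
  cat(sprintf("  winner: %s\n", toupper(x$winner)))
  invisible(x)
}
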