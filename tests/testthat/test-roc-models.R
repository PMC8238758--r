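test_that("model probability tables obey their structural identities", {
  crit <- c(-1, -0.5, 0, 0.5, 1)
  # null DPSD: old and new rows coincide
  p <- dpsd_response_probs(0, 0, crit)
  expect_equal(p["old", ], p["new", ])
  # recollection ceiling: all old mass in the top bin
  expect_equal(unname(dpsd_response_probs(1, 0.7, crit)["old", 6]), 1)
  # EVSD reduction: UVSD(Vo = 1) equals DPSD(Ro = 0)
  expect_equal(uvsd_response_probs(1.3, 1, crit),
               dpsd_response_probs(0, 1.3, crit))
  # null UVSD
  pu <- uvsd_response_probs(0, 1, crit)
  expect_equal(pu["old", ], pu["new", ])
  expect_error(dpsd_response_probs(0.5, 1, c(0, -1)), "increasing")
  expect_error(uvsd_response_probs(1, -0.2, crit), "vo")
})

test_that("rows are proper probability vectors for random parameters", {
  withr::local_seed(2)
  for (i in 1:50) {
    d <- random_dpsd()
    p1 <- dpsd_response_probs(d$ro, d$dprime, d$criteria)
    u <- random_uvsd()
    p2 <- uvsd_response_probs(u$dprime, u$vo, u$criteria)
    for (p in list(p1, p2)) {
      expect_true(all(p >= 0))
      expect_equal(unname(rowSums(p)), c(1, 1))
    }
  }
})

test_that("G statistic matches hand arithmetic", {
  expect_equal(g_statistic(c(10, 20, 30), c(10, 20, 30)), 0)
  expect_equal(g_statistic(c(10, 20, 30), c(20, 20, 20)),
               2 * (10 * log(0.5) + 30 * log(1.5)))
  expect_equal(g_statistic(c(10, 20, 30), c(20, 20, 20)), 10.46,
               tolerance = 0.001)
  # zero observed cells contribute nothing
  expect_equal(g_statistic(c(0, 30), c(10, 20)), 2 * 30 * log(30 / 20))
  expect_error(g_statistic(c(-1, 2), c(1, 2)), "nonnegative")
})

test_that("fitting recovers known parameters from near-expected counts", {
  crit <- c(-1, -0.4, 0.3, 0.9, 1.6)
  p <- dpsd_response_probs(0.35, 1.1, crit)
  cts <- round(p * 50000)
  f <- fit_rating_counts(cts, "dpsd")
  expect_true(f$converged)
  expect_equal(f$ro, 0.35, tolerance = 0.02)
  expect_equal(f$dprime, 1.1, tolerance = 0.05)
  expect_equal(f$criteria, crit, tolerance = 0.05)
  expect_lt(f$G, 0.5)
  expect_equal(f$df, 3)
  expect_equal(f$bic, -2 * f$logLik + f$n_params * log(f$n_trials))

  pu <- uvsd_response_probs(1.2, 1.4, crit)
  fu <- fit_rating_counts(round(pu * 50000), "uvsd")
  expect_equal(fu$dprime, 1.2, tolerance = 0.05)
  expect_equal(fu$vo, 1.4, tolerance = 0.05)
})

test_that("a chance observer yields null parameter estimates", {
  crit <- c(-1, -0.5, 0, 0.5, 1)
  cts <- round(dpsd_response_probs(0, 0, crit) * 20000)
  f <- fit_rating_counts(cts, "dpsd")
  expect_lt(f$ro, 0.03)
  expect_lt(abs(f$dprime), 0.05)
})

test_that("fitted likelihood dominates the generating parameters", {
  withr::local_seed(7)
  for (i in 1:8) {
    d <- random_dpsd()
    p <- dpsd_response_probs(d$ro, d$dprime, d$criteria)
    cts <- sim_counts(300, 300, p)
    f <- fit_rating_counts(cts, "dpsd")
    expect_gte(f$logLik + 1e-6, roc_loglik(cts, p))
    u <- random_uvsd()
    pu <- uvsd_response_probs(u$dprime, u$vo, u$criteria)
    ctsu <- sim_counts(300, 300, pu)
    fu <- fit_rating_counts(ctsu, "uvsd")
    expect_gte(fu$logLik + 1e-6, roc_loglik(ctsu, pu))
  }
})

test_that("high-recollection ROCs are asymmetric with zROC slope below 1", {
  crit <- c(-1, -0.5, 0, 0.5, 1)
  p <- dpsd_response_probs(0.5, 1, crit)
  cum_old <- rev(cumsum(rev(p["old", ])))[-1]
  cum_new <- rev(cumsum(rev(p["new", ])))[-1]
  slope <- coef(lm(qnorm(cum_old) ~ qnorm(cum_new)))[2]
  expect_lt(unname(slope), 1)
})

test_that("degenerate tables are flagged, not thrown", {
  cts <- matrix(c(100L, 0L, 0L, 0L, 0L, 0L, 100L, 0L, 0L, 0L, 0L, 0L), 2,
                byrow = TRUE)
  f <- fit_rating_counts(cts, "dpsd")
  expect_false(f$identifiable)
  expect_false(f$converged)
})

test_that("the winning-model rule needs both the BIC and the G condition", {
  mk_fits <- function(n, prop_dpsd_lower, dpsd_ok = 1, uvsd_ok = 1) {
    n_lower <- round(n * prop_dpsd_lower)
    tibble::tibble(
      subject = rep(sprintf("s%02d", 1:n), 2),
      model = rep(c("dpsd", "uvsd"), each = n),
      bic = c(ifelse(1:n <= n_lower, 100, 110),
              ifelse(1:n <= n_lower, 105, 105)),
      p_value = c(ifelse(1:n <= round(n * dpsd_ok), 0.5, 0.01),
                  ifelse(1:n <= round(n * uvsd_ok), 0.5, 0.01))
    )
  }
  expect_equal(select_winning_model(mk_fits(20, 0))$winner, "uvsd")
  expect_equal(select_winning_model(mk_fits(20, 0.6))$winner, "inconclusive")
  # 85% lower BIC but acceptable fit in only 70% of subjects
  expect_equal(select_winning_model(mk_fits(20, 0.85, dpsd_ok = 0.7))$winner,
               "inconclusive")
  expect_equal(select_winning_model(mk_fits(20, 1))$winner, "dpsd")
  expect_error(select_winning_model(mk_fits(20, 1)[1:20, ]), "both models")
})

test_that("fit_roc returns tidy per-subject results with methods attached", {
  obs <- const_observer("dpsd", ro = 0.3, dprime = 1,
                        criteria = c(-1, -0.3, 0.8, 1.4, 2))
  tr <- dplyr::bind_rows(
    dplyr::mutate(simulate_observer(obs, make_items(180, 180), seed = 1),
                  subject = "s01"),
    dplyr::mutate(simulate_observer(obs, make_items(180, 180), seed = 2),
                  subject = "s02")
  )
  fits <- fit_roc(tr, "both")
  expect_equal(nrow(fits), 4)
  expect_setequal(unique(fits$model), c("dpsd", "uvsd"))
  f <- fits$fit[[1]]
  td <- tidy(f)
  expect_equal(td$term[1:2], c("Ro", "dprime"))
  expect_equal(nrow(td), 7)
  gl <- glance(f)
  expect_equal(gl$n_trials, 360)
  expect_s3_class(autoplot(f), "ggplot")
})
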