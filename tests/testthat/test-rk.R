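test_that("scaled difference follows its algebraic identities", {
  expect_equal(scaled_difference(6, 4), 0.2)
  expect_equal(scaled_difference(0.5, 0.5), 0)
  expect_equal(scaled_difference(1, 0), 1)
  expect_true(is.na(scaled_difference(0, 0)))
  expect_error(scaled_difference(-1, 2), "nonnegative")

  withr::local_seed(3)
  for (i in 1:30) {
    a <- runif(1, 0, 5); b <- runif(1, 0, 5); c <- runif(1, 0.1, 10)
    expect_equal(scaled_difference(a, b), -scaled_difference(b, a))
    expect_equal(scaled_difference(c * a, c * b), scaled_difference(a, b))
  }
})

test_that("per-subject scaled differences compute within basis and flag 0/0", {
  trials <- tibble::tibble(
    subject = "a",
    image = sprintf("i%02d", 1:14),
    status = c(rep("old", 10), rep("new", 4)),
    memorability = c(rep(0.9, 10), rep(0.9, 4)),
    response = c(rep(5L, 10), rep(2L, 4)),
    statement = c(rep("R", 6), rep("K", 4), rep("D", 3), "U")
  )
  y <- subject_scaled_differences(trials, "hits")
  expect_equal(y$score[y$mem_bin == "high"], 0.2)
  expect_true(is.na(y$score[y$mem_bin == "low"]))
  # no false alarms anywhere: every cell of that basis is undefined
  yf <- subject_scaled_differences(trials, "false_alarms")
  expect_true(all(is.na(yf$score)))
  # D/U basis
  yn <- subject_scaled_differences(trials, "correct_rejections")
  expect_equal(yn$score[yn$mem_bin == "high"], 0.5)
})

test_that("JZS Bayes factor matches an independent grid quadrature", {
  bf_grid <- function(t, n, r, direction) {
    lo <- if (direction == "greater") 0 else -15
    hi <- if (direction == "less") 0 else 15
    d <- seq(lo, hi, length.out = 60001)
    w <- if (direction == "two-sided") 1 else 2
    f <- suppressWarnings(dt(t, n - 1, ncp = d * sqrt(n))) *
      w * dcauchy(d, 0, r)
    h <- d[2] - d[1]
    (sum(f) - (f[1] + f[length(f)]) / 2) * h / dt(t, n - 1)
  }
  r <- sqrt(2) / 2
  cases <- list(c(0, 42), c(2.5, 42), c(1.5, 20))
  for (cs in cases) {
    for (dir in c("greater", "two-sided")) {
      expect_equal(memroc:::jzs_bf10(cs[1], cs[2], r, dir),
                   bf_grid(cs[1], cs[2], r, dir), tolerance = 1e-3)
    }
  }
  expect_equal(memroc:::jzs_bf10(-1.2, 30, r, "less"),
               bf_grid(-1.2, 30, r, "less"), tolerance = 1e-3)
})

test_that("null data favour H0 and bf10/bf01 are reciprocal", {
  res <- bayes_t_test(rep(0, 42))
  expect_lt(res$bf10, 1)
  expect_equal(res$t, 0)

  withr::local_seed(5)
  for (i in 1:10) {
    x <- rnorm(20, runif(1, -0.5, 0.5))
    b <- bayes_t_test(x, sample(c("greater", "less", "two-sided"), 1))
    expect_equal(b$bf10 * b$bf01, 1)
  }
  expect_error(bayes_t_test(rep(2, 10)), "zero-variance")
  expect_error(bayes_t_test(1), "at least 2")
})

test_that("the Bayes factor is monotone in t for fixed n", {
  bfs <- sapply(seq(0, 5, by = 0.5),
                function(t) memroc:::jzs_bf10(t, 30, sqrt(2) / 2, "greater"))
  expect_true(all(diff(bfs) > 0))
})

test_that("under a true null the Bayes factor shrinks with sample size", {
  withr::local_seed(11)
  mean_log_bf <- sapply(c(20, 80, 320), function(n) {
    mean(replicate(60, {
      log(bayes_t_test(rnorm(n), "two-sided")$bf10)
    }))
  })
  expect_true(all(diff(mean_log_bf) < 0))
})

test_that("Cohen's d_z and the classical paired t are reported", {
  x <- c(0.2, 0.5, 0.1, 0.4, 0.3, 0.6, 0.2, 0.1)
  res <- bayes_t_test(x, "greater")
  expect_equal(res$cohens_d, mean(x) / sd(x))
  tt <- t.test(x, alternative = "greater")
  expect_equal(res$t, unname(tt$statistic))
  expect_equal(res$p_value, tt$p.value)
  expect_gt(res$bf10, 10)
})

test_that("memorability-linked recollection raises Yold for memorable items", {
  des <- sim_design(12, 90, 90, mem_dist = dist_bins())
  pop <- observer_population(12, "dpsd", ro_link = c(-2.1, 2.5),
                             dprime_link = c(0.9, 0), seed = 4)
  tr <- simulate_experiment(des, pop, seed = 23)
  y <- subject_scaled_differences(tr, "hits")
  agg <- tapply(y$score, y$mem_bin, mean, na.rm = TRUE)
  expect_gt(agg[["high"]], agg[["low"]])
})

test_that("image statement scores handle unanimity and permutation nulls", {
  unanimous <- tibble::tibble(
    subject = rep(c("a", "b", "c"), 2),
    image = rep(c("x", "y"), each = 3),
    status = "old",
    memorability = rep(c(0.9, 0.3), each = 3),
    response = 5L,
    statement = rep(c("R", "K"), each = 3)
  )
  sc <- image_statement_scores(unanimous)
  expect_equal(sc$yold[sc$image == "x"], 1)
  expect_equal(sc$yold[sc$image == "y"], -1)
  expect_true(all(is.na(sc$ynew)))

  des <- sim_design(12, 90, 90, mem_dist = dist_bins())
  pop <- observer_population(12, "dpsd", dprime_link = c(0.9, 0), seed = 4)
  tr <- simulate_experiment(des, pop, seed = 29)
  scores <- image_statement_scores(tr)
  cors <- statement_correlations(scores)
  expect_gt(cors$estimate[cors$pair == "memorability~yold"], 0)
  expect_gt(cors$estimate[cors$pair == "memorability~ynew"], 0)

  withr::local_seed(12)
  shuffled <- scores
  shuffled$memorability <- sample(shuffled$memorability)
  cors_null <- statement_correlations(shuffled)
  expect_lt(abs(cors_null$estimate[cors_null$pair == "memorability~yold"]),
            0.2)
})

test_that("rk_summary reports both subject-mean and pooled aggregates", {
  des <- sim_design(6, 60, 60, mem_dist = dist_bins())
  pop <- observer_population(6, "dpsd", seed = 8)
  tr <- simulate_experiment(des, pop, seed = 31)
  s <- rk_summary(tr)
  expect_setequal(unique(s$basis),
                  c("hits", "false_alarms", "correct_rejections",
                    "false_rejections"))
  hits <- s[s$basis == "hits", ]
  expect_equal(hits$prop_a + hits$prop_b, rep(1, nrow(hits)))
  expect_true(all(abs(hits$mean_score) <= 1, na.rm = TRUE))
  expect_true(all(abs(hits$score_of_means) <= 1, na.rm = TRUE))
})
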