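test_that("count correction matches hand arithmetic and stays interior", {
  # (10 + 0.5)/11 and (0 + 0.5)/11
  r <- corrected_rates(10, 10, 0, 10)
  expect_equal(r$hit_rate, 10.5 / 11)
  expect_equal(r$fa_rate, 0.5 / 11)
  expect_equal(corrected_rates(5, 10, 5, 10),
               tibble::tibble(hit_rate = 0.5, fa_rate = 0.5))
  expect_error(corrected_rates(11, 10, 0, 10), "hits")
  expect_error(corrected_rates(2, 10, 11, 10), "fas")
  expect_error(corrected_rates(2, 0, 0, 10), "n_old")

  # property: full count range maps into the open interval, monotone in hits
  withr::local_seed(1)
  for (i in 1:50) {
    n_old <- sample(1:200, 1); n_new <- sample(1:200, 1)
    h <- sample(0:n_old, 1); f <- sample(0:n_new, 1)
    r <- corrected_rates(h, n_old, f, n_new)
    expect_true(r$hit_rate > 0 && r$hit_rate < 1)
    expect_true(r$fa_rate > 0 && r$fa_rate < 1)
    if (h < n_old) {
      expect_gt(corrected_rates(h + 1, n_old, f, n_new)$hit_rate, r$hit_rate)
    }
  }
})

test_that("dprime is the difference of inverse normals", {
  expect_equal(dprime(0.5, 0.5), 0)
  expect_equal(dprime(0.8413, 0.5), 1, tolerance = 1e-3)
  expect_equal(dprime(0.9545, 0.0455), qnorm(0.9545) - qnorm(0.0455))
  expect_equal(dprime(0.9545, 0.0455), 3.38, tolerance = 0.005)
  expect_error(dprime(1, 0.5), "strictly")
  expect_error(dprime(0.5, 0), "strictly")
})

test_that("memorability binning follows the thresholds, boundaries downward", {
  expect_equal(as.character(bin_memorability(0.87)), "high")
  expect_equal(as.character(bin_memorability(0.45)), "low")
  expect_equal(as.character(bin_memorability(0.75)), "mid")
  expect_equal(as.character(bin_memorability(0.55)), "low")
  expect_equal(as.character(bin_memorability(c(0.76, 0.56))), c("high", "mid"))
  expect_error(bin_memorability(1.2), "\\[0, 1\\]")
})

test_that("chance-level subjects are excluded by the exact binomial rule", {
  mk <- function(subject, correct, n = 360) {
    status <- rep(c("old", "new"), each = n / 2)
    resp_correct <- ifelse(status == "old", 6L, 1L)
    resp_wrong <- ifelse(status == "old", 1L, 6L)
    ok <- seq_len(n) <= correct
    tibble::tibble(subject = subject, image = sprintf("i%03d", seq_len(n)),
                   status = status, memorability = 0.5,
                   response = ifelse(ok, resp_correct, resp_wrong))
  }
  trials <- dplyr::bind_rows(mk("at_chance", 180), mk("ceiling", 360),
                             mk("above", 200))
  res <- exclude_at_chance(trials)
  expect_equal(res$keep[res$subject == "at_chance"], FALSE)
  expect_equal(res$keep[res$subject == "ceiling"], TRUE)
  expect_equal(res$keep[res$subject == "above"], TRUE)
  # one-sided exact binomial oracle
  oracle <- binom.test(200, 360, 0.5, alternative = "greater")$p.value
  expect_equal(res$p_value[res$subject == "above"], oracle)
  expect_lt(oracle, 0.05)
})

test_that("rating counts and ROC points behave at the extremes", {
  perfect <- tibble::tibble(
    subject = "s", image = sprintf("i%02d", 1:20),
    status = rep(c("old", "new"), each = 10), memorability = 0.5,
    response = rep(c(6L, 1L), each = 10)
  )
  cts <- rating_counts(perfect)
  expect_equal(unname(rowSums(cts)), c(10, 10))
  pts <- roc_points(cts)
  expect_equal(pts$hit, rep(1, 5))
  expect_equal(pts$fa, rep(0, 5))
  expect_equal(trapezoid_auc(pts), 1)

  # identical old and new response distributions sit on the diagonal
  chance <- matrix(rep(c(3L, 4L, 3L, 4L, 3L, 3L), 2), nrow = 2, byrow = TRUE)
  rownames(chance) <- c("old", "new")
  pc <- roc_points(chance)
  expect_equal(pc$hit, pc$fa)
  expect_equal(trapezoid_auc(pc), 0.5)

  empty <- matrix(c(0L, 0L, 0L, 0L, 0L, 0L, 1L, 2L, 3L, 1L, 2L, 3L), 2,
                  byrow = TRUE)
  expect_error(roc_points(empty), "old and new")
})

test_that("cumulative ROC vectors are nondecreasing for random count tables", {
  withr::local_seed(4)
  for (i in 1:50) {
    cts <- matrix(rpois(12, sample(1:30, 1)), 2, 6)
    cts[1, sample(6, 1)] <- cts[1, sample(6, 1)] + 5L
    if (sum(cts[1, ]) == 0 || sum(cts[2, ]) == 0) next
    pts <- roc_points(cts)
    expect_true(all(diff(pts$hit) >= 0))
    expect_true(all(diff(pts$fa) >= 0))
    expect_true(all(pts$hit >= 0 & pts$hit <= 1))
  }
})

test_that("z-transform drops diverging endpoints", {
  pts <- tibble::tibble(fa = c(0, 0.2, 1), hit = c(0.4, 0.8, 1))
  z <- z_transform(pts)
  expect_equal(nrow(z), 1)
  expect_equal(z$zfa, qnorm(0.2))
  expect_equal(z$zhit, qnorm(0.8))
})

test_that("trapezoidal AUC matches hand geometry and merges collinear points", {
  # single interior point: triangle up to it plus a trapezoid to (1,1)
  one <- tibble::tibble(fa = 0.32, hit = 0.65)
  expect_equal(trapezoid_auc(one), 0.32 * 0.65 / 2 + 0.68 * (0.65 + 1) / 2)
  two <- tibble::tibble(fa = c(0.2, 0.6), hit = c(0.3, 0.7))
  with_mid <- tibble::tibble(fa = c(0.2, 0.4, 0.6), hit = c(0.3, 0.5, 0.7))
  expect_equal(trapezoid_auc(two), trapezoid_auc(with_mid))
})

test_that("d-prime from corrected rates recovers an EVSD observer", {
  obs <- const_observer("dpsd", ro = 0, dprime = 1.5)
  tr <- simulate_observer(obs, make_items(50000, 50000), seed = 8)
  hits <- sum(tr$status == "old" & tr$response > 3)
  fas <- sum(tr$status == "new" & tr$response > 3)
  r <- corrected_rates(hits, 50000, fas, 50000)
  expect_equal(dprime(r$hit_rate, r$fa_rate), 1.5, tolerance = 0.05)
})

test_that("image-level association recovers a memorability-linked d-prime", {
  des <- sim_design(10, 150, 150, mem_dist = dist_uniform(0.2, 0.95))
  pop <- observer_population(10, "dpsd", dprime_link = c(0.2, 1.5), seed = 2)
  tr <- simulate_experiment(des, pop, seed = 17)
  img <- image_stats(tr)
  expect_equal(nrow(img), 300)

  self <- image_level_association(dplyr::mutate(img, m2 = memorability), "m2")
  expect_equal(self$estimate, 1)

  assoc <- image_level_association(img, "dprime", "pearson")
  expect_gt(assoc$estimate, 0.2)
  expect_lt(assoc$p_value, 0.01)

  # permutation null: shuffling memorability destroys the association
  withr::local_seed(6)
  img_perm <- dplyr::mutate(img, memorability = sample(memorability))
  perm <- image_level_association(img_perm, "dprime", "pearson")
  expect_lt(abs(perm$estimate), 0.15)

  expect_error(image_level_association(img, "nope"), "not found")
  expect_error(
    image_level_association(dplyr::mutate(img, k = 1), "k"), "constant"
  )
})

test_that("subject_stats splits by bin and applies the correction per cell", {
  des <- sim_design(4, 30, 30, mem_dist = dist_bins())
  pop <- observer_population(4, "dpsd", seed = 3)
  tr <- simulate_experiment(des, pop, seed = 19)
  s <- subject_stats(tr, by_bin = TRUE)
  expect_equal(nrow(s), 4 * 3)
  expect_true(all(s$hit_rate > 0 & s$hit_rate < 1))
  expect_true(all(s$fa_rate > 0 & s$fa_rate < 1))
  s_all <- subject_stats(tr)
  expect_equal(nrow(s_all), 4)
  expect_true(all(s_all$n_old == 30 & s_all$n_new == 30))
})
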