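#' Memorability score distributions
#'
#' Constructors for the item-memorability distributions understood by
#' [simulate_memorability()]. Memorability is an image's hit rate in
#' large-sample online recognition experiments, so scores live in
#' \eqn{[0, 1]}.
#'
#' `dist_bins()` draws equal numbers of images uniformly from a low, a
#' middle and a high memorability range. The default ranges bracket the
#' binning thresholds used throughout the package (low <= 0.55,
#' 0.55 < mid <= 0.75, high > 0.75) and give bin means close to the
#' 0.45 / 0.66 / 0.87 means of the stimulus sets the analysis was designed
#' around.
#'
#' @param min,max Bounds of a uniform distribution on `[min, max]` within
#'   `[0, 1]`.
#' @param shape1,shape2 Positive shape parameters of a beta distribution.
#' @param values Explicit numeric scores in `[0, 1]`, used verbatim.
#' @param low,mid,high Length-2 ranges for the three memorability bins.
#' @return An object of class `mem_dist`.
#' @name mem_dist
#' @examples
#' simulate_memorability(3, dist_explicit(c(0.87, 0.66, 0.45)))
NULL

#' @rdname mem_dist
#' @export
dist_uniform <- function(min = 0.3, max = 0.95) {
  if (!is.numeric(min) || !is.numeric(max) || min >= max ||
      min < 0 || max > 1) {
    abort("uniform memorability distribution needs 0 <= min < max <= 1.")
  }
  structure(list(type = "uniform", min = min, max = max), class = "mem_dist")
}

#' @rdname mem_dist
#' @export
dist_beta <- function(shape1, shape2) {
  if (!is.numeric(shape1) || !is.numeric(shape2) ||
      shape1 <= 0 || shape2 <= 0) {
    abort("beta memorability distribution needs positive shape parameters.")
  }
  structure(list(type = "beta", shape1 = shape1, shape2 = shape2),
            class = "mem_dist")
}

#' @rdname mem_dist
#' @export
dist_explicit <- function(values) {
  check_prob(values, "values")
  structure(list(type = "explicit", values = values), class = "mem_dist")
}

#' @rdname mem_dist
#' @export
dist_bins <- function(low = c(0.30, 0.55), mid = c(0.55, 0.75),
                      high = c(0.75, 0.95)) {
  for (r in list(low, mid, high)) {
    if (length(r) != 2 || r[1] >= r[2] || r[1] < 0 || r[2] > 1) {
      abort("each bin range must be c(lo, hi) with 0 <= lo < hi <= 1.")
    }
  }
  structure(list(type = "bins", low = low, mid = mid, high = high),
            class = "mem_dist")
}

#' Simulate per-image memorability scores
#'
#' @param n_images Number of images (> 0). For [dist_explicit()] it must
#'   equal the number of supplied values.
#' @param dist A [mem_dist] object; defaults to three equal memorability
#'   bins, `dist_bins()`.
#' @param seed Optional integer seed; draws are reproducible under a fixed
#'   seed and do not disturb the caller's RNG state.
#' @return A tibble with columns `image` and `memorability`.
#' @export
simulate_memorability <- function(n_images, dist = dist_bins(), seed = NULL) {
  n_images <- check_scalar_count(n_images, "n_images")
  if (!inherits(dist, "mem_dist")) {
    abort("`dist` must be created with dist_uniform(), dist_beta(), dist_explicit() or dist_bins().")
  }
  draw <- function() {
    switch(dist$type,
      uniform = runif(n_images, dist$min, dist$max),
      beta = rbeta(n_images, dist$shape1, dist$shape2),
      explicit = {
        if (length(dist$values) != n_images) {
          abort("dist_explicit(): number of values must equal `n_images`.")
        }
        dist$values
      },
      bins = {
        per <- ceiling(n_images / 3)
        m <- c(runif(per, dist$low[1], dist$low[2]),
               runif(per, dist$mid[1], dist$mid[2]),
               runif(per, dist$high[1], dist$high[2]))
        m[seq_len(n_images)]
      }
    )
  }
  m <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble::tibble(
    image = sprintf("img%04d", seq_len(n_images)),
    memorability = m
  )
}

#' Specify a generative DPSD or UVSD observer
#'
#' An observer turns items into confidence responses (1 = sure new ...
#' B = sure old) and remember/know-style statements. Memorability `m`
#' modulates the model parameters through simple links:
#' recollection \eqn{Ro(m) = \mathrm{logit}^{-1}(a_r + b_r m)},
#' familiarity \eqn{d'(m) = a_d + b_d m} (floored at 0 for DPSD), and the
#' probability of a "detailed" statement given a "new" response
#' \eqn{P(D\mid m) = \mathrm{logit}^{-1}(a_p + b_p m)}.
#'
#' The default links were chosen once to emulate the qualitative regime of
#' a memorability experiment with facilitated encoding: hit rates rising
#' from ~0.57 (low mem) to ~0.78 (high mem), false-alarm rate ~0.21, and a
#' recollection share among hits rising from ~0.43 to ~0.57.
#'
#' @param model `"dpsd"` or `"uvsd"`.
#' @param ro_link `(intercept, slope)` on the logit scale mapping
#'   memorability to `Ro` (DPSD only; ignored for UVSD).
#' @param dprime_link `(intercept, slope)` of the linear memorability ->
#'   d-prime map.
#' @param vo Old-item standard deviation (> 0; UVSD only).
#' @param criteria `B - 1` strictly increasing decision thresholds on the
#'   memory-strength axis.
#' @param p_detailed_link `(intercept, slope)` on the logit scale mapping
#'   memorability to P(D | "new" response).
#' @param subject Optional subject id attached to simulated trials.
#' @return An object of class `observer_spec`.
#' @export
observer_spec <- function(model = c("dpsd", "uvsd"),
                          ro_link = c(-2.1, 2.2),
                          dprime_link = c(0.2, 1.0),
                          vo = 1.3,
                          criteria = c(-1.0, -0.3, 0.8, 1.4, 2.0),
                          p_detailed_link = c(-2.0, 2.5),
                          subject = NULL) {
  model <- match.arg(model)
  check_criteria(criteria)
  if (model == "uvsd" && (!is.numeric(vo) || vo <= 0)) {
    abort("`vo` must be > 0 for a UVSD observer.")
  }
  stopifnot(length(ro_link) == 2, length(dprime_link) == 2,
            length(p_detailed_link) == 2)
  structure(
    list(model = model, ro_link = ro_link, dprime_link = dprime_link,
         vo = vo, criteria = criteria, p_detailed_link = p_detailed_link,
         subject = subject),
    class = "observer_spec"
  )
}

ro_of <- function(obs, m) plogis(obs$ro_link[1] + obs$ro_link[2] * m)

dprime_of <- function(obs, m) {
  d <- obs$dprime_link[1] + obs$dprime_link[2] * m
  if (obs$model == "dpsd") pmax(d, 0) else d
}

p_detailed_of <- function(obs, m) {
  plogis(obs$p_detailed_link[1] + obs$p_detailed_link[2] * m)
}

#' Simulate one observer's test-phase responses
#'
#' Old DPSD trials recollect with probability `Ro(m)`; a recollection event
#' forces the most-confident "old" response and an "R" statement (the
#' classical high-confidence recollection assumption). Otherwise a
#' familiarity draw `Normal(d'(m), 1)` is binned by the criteria and any
#' "old"-classified response carries a "K" statement. UVSD old draws are
#' `Normal(d'(m), Vo)` and, lacking a latent recollection event, emit "R"
#' only at the maximal confidence bin. New-item draws are `Normal(0, 1)`.
#' Every "new"-classified response (correct rejection or miss) carries a
#' "D" statement with probability `P(D | m)`, else "U".
#'
#' Each trial consumes one recollection uniform, one normal and one
#' statement uniform in a fixed order, so DPSD(`Ro = 0`) and
#' UVSD(`Vo = 1`) observers produce identical response columns from the
#' same RNG state.
#'
#' @param obs An [observer_spec()].
#' @param items Tibble with columns `image`, `memorability`, `status`.
#' @param B Number of confidence bins (>= 2).
#' @param seed Optional integer seed (local; caller's RNG untouched).
#' @return A trial tibble: `subject`, `image`, `status`, `memorability`,
#'   `response`, `statement`.
#' @export
simulate_observer <- function(obs, items, B = 6, seed = NULL) {
  stopifnot(inherits(obs, "observer_spec"))
  B <- check_scalar_count(B, "B", min = 2)
  if (length(obs$criteria) != B - 1) {
    abort(sprintf("observer has %d criteria but B = %d needs %d.",
                  length(obs$criteria), B, B - 1))
  }
  if (!is.data.frame(items) || nrow(items) == 0) {
    abort("`items` must be a nonempty data frame.")
  }
  check_prob(items$memorability, "memorability")

  run <- function() {
    n <- nrow(items)
    m <- items$memorability
    old <- items$status == "old"
    u_rec <- runif(n)
    z <- rnorm(n)
    u_stmt <- runif(n)

    d <- dprime_of(obs, m)
    strength <- ifelse(old,
                       d + z * (if (obs$model == "uvsd") obs$vo else 1),
                       z)
    response <- findInterval(strength, obs$criteria) + 1L
    recollect <- rep(FALSE, n)
    if (obs$model == "dpsd") {
      recollect <- old & (u_rec < ro_of(obs, m))
      response[recollect] <- B
    }
    old_resp <- is_old_response(response, B)
    statement <- character(n)
    if (obs$model == "dpsd") {
      statement[old_resp] <- ifelse(recollect[old_resp], "R", "K")
    } else {
      statement[old_resp] <- ifelse(response[old_resp] == B, "R", "K")
    }
    statement[!old_resp] <- ifelse(u_stmt[!old_resp] < p_detailed_of(obs, m[!old_resp]),
                                   "D", "U")
    tibble::tibble(
      subject = obs$subject %||% "s01",
      image = items$image,
      status = items$status,
      memorability = m,
      response = as.integer(response),
      statement = statement
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulation designs
#'
#' `sim_design()` describes an experiment layout; `design_exp1()` and
#' `design_exp2()` preset the two layouts the package emulates: a large
#' shallow-encoding design (45 subjects, 330 old + 330 foil images) and a
#' smaller deep-encoding remember/know design (42 subjects, 180 + 180).
#'
#' @param n_subjects,n_old,n_new Positive counts; `n_old`/`n_new` are per
#'   subject. When equal, the item pool holds `n_old + n_new` images and
#'   each image is a target for one half of subjects and a foil for the
#'   other half (counterbalanced).
#' @param B Number of confidence bins (default 6).
#' @param mem_dist A [mem_dist] object for the item pool.
#' @return A `sim_design` list.
#' @export
sim_design <- function(n_subjects, n_old, n_new, B = 6,
                       mem_dist = dist_bins()) {
  structure(
    list(n_subjects = check_scalar_count(n_subjects, "n_subjects"),
         n_old = check_scalar_count(n_old, "n_old"),
         n_new = check_scalar_count(n_new, "n_new"),
         B = check_scalar_count(B, "B", min = 2),
         mem_dist = mem_dist),
    class = "sim_design"
  )
}

#' @rdname sim_design
#' @export
design_exp1 <- function() sim_design(45, 330, 330)

#' @rdname sim_design
#' @export
design_exp2 <- function() sim_design(42, 180, 180)

#' Build a population of observers
#'
#' One [observer_spec()] per subject. Between-subject heterogeneity is
#' introduced by jittering the link intercepts (normal, sd
#' `sd_intercept`) and the criteria (common shift, sd `sd_criteria`);
#' both default to modest values typical of individual differences in
#' confidence usage.
#'
#' @inheritParams observer_spec
#' @param n_subjects Number of observers.
#' @param sd_intercept,sd_criteria Between-subject jitter SDs (0 disables).
#' @param seed Integer seed for the jitters.
#' @return A list of `observer_spec` objects with subject ids
#'   `"s01", "s02", ...`.
#' @export
observer_population <- function(n_subjects,
                                model = c("dpsd", "uvsd"),
                                ro_link = c(-2.1, 2.2),
                                dprime_link = c(0.2, 1.0),
                                vo = 1.3,
                                criteria = c(-1.0, -0.3, 0.8, 1.4, 2.0),
                                p_detailed_link = c(-2.0, 2.5),
                                sd_intercept = 0.25,
                                sd_criteria = 0.1,
                                seed = 1L) {
  model <- match.arg(model)
  n_subjects <- check_scalar_count(n_subjects, "n_subjects")
  jit <- withr::with_seed(seed, {
    list(ro = rnorm(n_subjects, 0, sd_intercept),
         dp = rnorm(n_subjects, 0, sd_intercept / 2),
         pd = rnorm(n_subjects, 0, sd_intercept),
         cr = rnorm(n_subjects, 0, sd_criteria))
  })
  purrr::map(seq_len(n_subjects), function(s) {
    observer_spec(
      model = model,
      ro_link = c(ro_link[1] + jit$ro[s], ro_link[2]),
      dprime_link = c(dprime_link[1] + jit$dp[s], dprime_link[2]),
      vo = vo,
      criteria = criteria + jit$cr[s],
      p_detailed_link = c(p_detailed_link[1] + jit$pd[s], p_detailed_link[2]),
      subject = sprintf("s%02d", s)
    )
  })
}

#' Simulate a full experiment
#'
#' Draws one item pool of `n_old + n_new` images, assigns old/foil status
#' per subject (counterbalanced when `n_old == n_new`: half the subjects
#' study the first image set, half the second), and concatenates each
#' observer's simulated trials. Each subject uses an independent RNG
#' stream seeded from `(seed, subject index)`, so per-subject data are
#' reproducible in isolation.
#'
#' @param design A [sim_design()].
#' @param population List of [observer_spec()]s, length `n_subjects`.
#' @param seed Master integer seed.
#' @return A trial tibble; the full simulation configuration is attached
#'   as `attr(x, "config")` (see [write_sim_config()]).
#' @export
simulate_experiment <- function(design, population, seed = 1L) {
  stopifnot(inherits(design, "sim_design"))
  if (length(population) != design$n_subjects) {
    abort(sprintf("population has %d observers but design needs %d.",
                  length(population), design$n_subjects))
  }
  n_items <- design$n_old + design$n_new
  items <- simulate_memorability(n_items, design$mem_dist, seed = seed)

  counterbalanced <- design$n_old == design$n_new
  trials <- purrr::map_dfr(seq_along(population), function(s) {
    obs <- population[[s]]
    obs$subject <- obs$subject %||% sprintf("s%02d", s)
    sseed <- subject_seed(seed, s)
    it <- items
    if (counterbalanced) {
      # odd/even item sets interleave the memorability spectrum, so both
      # counterbalancing groups see old and foil items in every bin
      odd_set_old <- s %% 2 == 1
      odd_item <- seq_len(n_items) %% 2 == 1
      it$status <- ifelse(odd_item == odd_set_old, "old", "new")
    } else {
      it$status <- withr::with_seed(sseed + 1L, {
        st <- rep("new", n_items)
        st[sample.int(n_items, design$n_old)] <- "old"
        st
      })
    }
    simulate_observer(obs, it, B = design$B, seed = sseed)
  })

  attr(trials, "config") <- list(
    design = list(n_subjects = design$n_subjects, n_old = design$n_old,
                  n_new = design$n_new, B = design$B,
                  mem_dist = unclass(design$mem_dist)),
    observers = purrr::map(population, function(o) {
      list(model = o$model, ro_link = o$ro_link,
           dprime_link = o$dprime_link, vo = o$vo,
           criteria = o$criteria, p_detailed_link = o$p_detailed_link,
           subject = o$subject)
    }),
    seed = seed
  )
  trials
}
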