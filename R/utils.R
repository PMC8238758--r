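# Internal helpers shared across modules.

# Responses above the scale midpoint are classified "old"
# (1 = sure new ... B = sure old).
is_old_response <- function(response, B) {
  response > B / 2
}

# Softplus keeps DPSD d' >= 0 while the optimizer works unconstrained.
softplus <- function(x) {
  ifelse(x > 30, x, log1p(exp(x)))
}

softplus_inv <- function(y) {
  ifelse(y > 30, y, log(expm1(pmax(y, 1e-10))))
}

check_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  x
}

check_criteria <- function(criteria) {
  if (!is.numeric(criteria) || length(criteria) < 1L || anyNA(criteria)) {
    abort("`criteria` must be a numeric vector of finite thresholds.")
  }
  if (any(diff(criteria) <= 0)) {
    abort("`criteria` must be strictly increasing.")
  }
  criteria
}

check_trials <- function(trials, B = 6, require_statement = FALSE) {
  stopifnot(is.data.frame(trials))
  needed <- c("subject", "image", "status", "memorability", "response")
  missing <- setdiff(needed, names(trials))
  if (length(missing) > 0) {
    abort(paste0("trial table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!all(trials$status %in% c("old", "new"))) {
    abort("`status` must be 'old' or 'new'.")
  }
  if (any(trials$response < 1 | trials$response > B)) {
    abort(sprintf("`response` must be an integer in 1..%d.", B))
  }
  if (require_statement && !"statement" %in% names(trials)) {
    abort("trial table needs a `statement` column for this analysis.")
  }
  invisible(trials)
}

# Per-subject stream seed; kept < 2^31 and double-precision exact.
subject_seed <- function(master_seed, subject_index) {
  as.integer((as.double(master_seed %% 2147483647L) * 1000003 +
                subject_index) %% 2147483647)
}
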