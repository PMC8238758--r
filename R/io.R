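#' Read a trial table
#'
#' Reads and validates a comma-separated trial table. The native schema
#' (`dialect = "confidence6"`) has columns `subject`, `image`, `status`
#' (`old`/`new`), `memorability` (in `[0, 1]`), `response` (1 = sure new
#' ... B = sure old) and `statement` (`R`/`K` for "old"-classified
#' responses, `D`/`U` for "new", or `none`). The `oldnew3` dialect maps
#' an old/new decision plus a 3-point confidence rating onto the 6-point
#' scale: `("new", c) -> 4 - c`, `("old", c) -> 3 + c`.
#'
#' @param path Path to a CSV file with a header row.
#' @param dialect `"confidence6"` (native) or `"oldnew3"`.
#' @param B Number of confidence bins of the target scale.
#' @return A validated trial tibble.
#' @export
read_trials <- function(path, dialect = c("confidence6", "oldnew3"), B = 6) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (dialect == "oldnew3") {
    needed <- c("subject", "image", "status", "memorability", "decision",
                "confidence")
    missing <- setdiff(needed, names(raw))
    if (length(missing) > 0) {
      abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
    }
    if (!all(raw$confidence %in% 1:3)) {
      abort("`confidence` must be in 1..3 for the oldnew3 dialect.")
    }
    raw <- raw |>
      dplyr::mutate(response = ifelse(.data$decision == "new",
                                      4L - .data$confidence,
                                      3L + .data$confidence)) |>
      dplyr::select(-"decision", -"confidence")
  }
  if (!"statement" %in% names(raw)) raw$statement <- "none"
  validate_trials(raw, B)
}

#' Validate a trial table
#'
#' Checks the schema row by row and reports offending row numbers:
#' required columns, `status` values, memorability range, responses in
#' `1..B`, and statement/response-class consistency (`R`/`K` only on
#' "old"-classified responses, `D`/`U` only on "new"; `none` anywhere).
#'
#' @param trials A data frame in the native schema.
#' @param B Number of confidence bins.
#' @return The validated tibble (invisibly usable in pipes).
#' @export
validate_trials <- function(trials, B = 6) {
  needed <- c("subject", "image", "status", "memorability", "response",
              "statement")
  missing <- setdiff(needed, names(trials))
  if (length(missing) > 0) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  bad_row <- function(cond, what) {
    if (any(cond)) {
      abort(sprintf("%s in row(s): %s", what,
                    paste(utils::head(which(cond), 5), collapse = ", ")))
    }
  }
  bad_row(!trials$status %in% c("old", "new"), "invalid `status`")
  bad_row(!is.finite(trials$memorability) | trials$memorability < 0 |
            trials$memorability > 1, "memorability outside [0, 1]")
  bad_row(!trials$response %in% seq_len(B),
          sprintf("response outside 1..%d", B))
  old_resp <- is_old_response(trials$response, B)
  bad_row(old_resp & !trials$statement %in% c("R", "K", "none"),
          "statement must be R/K/none for an 'old' response")
  bad_row(!old_resp & !trials$statement %in% c("D", "U", "none"),
          "statement must be D/U/none for a 'new' response")
  tibble::as_tibble(trials) |>
    dplyr::mutate(response = as.integer(.data$response))
}

#' Write a trial table
#'
#' Writes the six native columns as UTF-8 CSV with a header.
#'
#' @param trials A trial tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  cols <- c("subject", "image", "status", "memorability", "response",
            "statement")
  if (!"statement" %in% names(trials)) trials$statement <- "none"
  readr::write_csv(dplyr::select(trials, dplyr::all_of(cols)), path)
  invisible(path)
}

#' Write the simulation sidecar configuration
#'
#' Serializes the full simulation configuration attached by
#' [simulate_experiment()] (design, per-observer parameters, seeds) as
#' YAML next to the trial table, so a simulation is reproducible from
#' its outputs alone.
#'
#' @param trials A trial tibble from [simulate_experiment()].
#' @param path Output path (YAML).
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(trials, path) {
  config <- attr(trials, "config")
  if (is.null(config)) abort("`trials` carries no simulation config attribute.")
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Assemble a pipeline configuration
#'
#' @param input Optional path to a trial CSV (alternatively pass trials
#'   to [run_pipeline()] directly).
#' @param out_dir Output directory for tables and the manifest.
#' @param B Number of confidence bins.
#' @param Q Number of memorability quantiles.
#' @param bin_thresholds Memorability bin boundaries `c(low =, high =)`.
#' @param prior_scale JZS Cauchy prior scale for the Bayes-factor tests.
#' @param alpha Significance level for subject exclusion and G-tests.
#' @param seed Master seed recorded in the manifest.
#' @return A validated `run_config` list.
#' @export
run_config <- function(input = NULL, out_dir = tempfile("memroc_run_"),
                       B = 6, Q = 30,
                       bin_thresholds = c(low = 0.55, high = 0.75),
                       prior_scale = sqrt(2) / 2, alpha = 0.05, seed = 1L) {
  B <- check_scalar_count(B, "B", min = 2)
  Q <- check_scalar_count(Q, "Q", min = 2)
  check_prob(unname(bin_thresholds), "bin_thresholds")
  if (prior_scale <= 0) abort("`prior_scale` must be positive.")
  structure(
    list(input = input, out_dir = out_dir, B = B, Q = Q,
         bin_thresholds = bin_thresholds, prior_scale = prior_scale,
         alpha = alpha, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [run_config()] fields.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  vals <- yaml::read_yaml(path)
  allowed <- c("input", "out_dir", "B", "Q", "bin_thresholds",
               "prior_scale", "alpha", "seed")
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(vals$bin_thresholds)) {
    vals$bin_thresholds <- unlist(vals$bin_thresholds)
  }
  do.call(run_config, vals)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: chance-level subject exclusion, per-subject and
#' per-image descriptives, per-subject DPSD/UVSD fits and the
#' winning-model verdict, scaled differences with one-sided Bayes-factor
#' tests (high vs low memorability, per basis), per-image statement
#' scores and correlations, and the quantile ordinal regression. All
#' tables are written as CSV under `config$out_dir` together with a JSON
#' manifest recording the package version, configuration, seed and a
#' config hash; two runs with equal config hashes produce identical
#' outputs. A failure in any stage aborts with the stage name; tables
#' written by earlier stages are preserved.
#'
#' @param trials A trial tibble; omit to read `config$input`.
#' @param config A [run_config()].
#' @return A list of class `memroc_run` with all stage results and the
#'   manifest.
#' @export
run_pipeline <- function(trials = NULL, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  out <- function(name) file.path(config$out_dir, name)
  B <- config$B

  if (is.null(trials)) {
    if (is.null(config$input)) abort("no trials and no `input` in config.")
    trials <- stage("read", read_trials(config$input, B = B))
  } else {
    trials <- stage("read", validate_trials(trials, B))
  }

  exclusion <- stage("exclusion", exclude_at_chance(trials, config$alpha, B))
  kept <- dplyr::filter(exclusion, .data$keep)$subject
  trials_kept <- dplyr::filter(trials, .data$subject %in% kept)
  readr::write_csv(exclusion, out("subject_exclusion.csv"))

  subj <- stage("descriptives", subject_stats(trials_kept, B, by_bin = TRUE))
  img <- stage("descriptives", image_stats(trials_kept, B))
  readr::write_csv(subj, out("subject_stats.csv"))
  readr::write_csv(img, out("image_stats.csv"))

  fits <- stage("roc_fits", fit_roc(trials_kept, "both", B))
  selection <- stage("model_selection", select_winning_model(fits,
                                                             alpha = config$alpha))
  readr::write_csv(dplyr::select(fits, -"fit"), out("roc_fits.csv"))
  readr::write_csv(selection$per_subject, out("model_selection.csv"))

  has_statements <- any(trials_kept$statement != "none")
  rk <- bf <- img_scores <- score_cors <- NULL
  if (has_statements) {
    rk <- stage("rk", rk_summary(trials_kept, B))
    bf <- stage("rk", purrr::map_dfr(
      c("hits", "false_alarms", "correct_rejections", "false_rejections"),
      function(bs) {
        sd_tab <- subject_scaled_differences(trials_kept, bs, B) |>
          dplyr::filter(.data$mem_bin %in% c("low", "high")) |>
          dplyr::select("subject", "mem_bin", "score") |>
          tidyr::pivot_wider(names_from = "mem_bin", values_from = "score")
        d <- sd_tab$high - sd_tab$low
        d <- d[is.finite(d)]
        if (length(d) < 2 || sd(d) == 0) return(NULL)
        dplyr::bind_cols(tibble::tibble(basis = bs, contrast = "high - low"),
                         bayes_t_test(d, "greater", config$prior_scale))
      }))
    img_scores <- stage("rk", image_statement_scores(trials_kept, B))
    score_cors <- stage("rk", statement_correlations(img_scores))
    readr::write_csv(rk, out("rk_summary.csv"))
    readr::write_csv(bf, out("bayes_factors.csv"))
    readr::write_csv(img_scores, out("image_statement_scores.csv"))
    readr::write_csv(score_cors, out("statement_correlations.csv"))
  }

  qreg <- qfits <- NULL
  items <- trials_kept |>
    dplyr::count(.data$image, .data$memorability, name = "n_trials")
  if (config$Q <= nrow(items)) {
    assignment <- stage("quantiles", quantile_bin(items, config$Q))
    qfits <- stage("quantiles", fit_quantiles(trials_kept, assignment, B))
    qreg <- stage("quantile_regression", memorability_rank_regression(qfits))
    readr::write_csv(dplyr::select(qfits, -"fit"), out("quantile_fits.csv"))
    readr::write_csv(qreg$summary, out("quantile_regression.csv"))
    readr::write_csv(
      dplyr::bind_rows(dpsd = tidy(qreg$dpsd), uvsd = tidy(qreg$uvsd),
                       .id = "model"),
      out("quantile_regression_coefficients.csv"))
  }

  manifest <- list(
    package = "memroc",
    version = as.character(utils::packageVersion("memroc")),
    config = unclass(config),
    # hash covers the analysis parameters only, so identical analyses in
    # different output directories share a hash
    config_hash = rlang::hash(unclass(config)[setdiff(names(config),
                                                      c("out_dir", "input"))]),
    seed = config$seed,
    n_subjects_in = dplyr::n_distinct(trials$subject),
    excluded_subjects = setdiff(unique(trials$subject), kept),
    winner = selection$winner,
    stages = c("exclusion", "descriptives", "roc_fits", "model_selection",
               if (has_statements) "rk", "quantiles", "quantile_regression"),
    exploratory_stages = c("quantiles", "quantile_regression")
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  structure(
    list(trials = trials_kept, exclusion = exclusion,
         subject_stats = subj, image_stats = img,
         fits = fits, selection = selection,
         rk_summary = rk, bayes_factors = bf,
         image_statement_scores = img_scores,
         statement_correlations = score_cors,
         quantile_fits = qfits, quantile_regression = qreg,
         manifest = manifest, out_dir = config$out_dir),
    class = "memroc_run"
  )
}

#' @export
print.memroc_run <- function(x, ...) {
  cat("<memroc_run>\n")
  cat(sprintf("  subjects kept: %d (excluded: %d)\n",
              sum(x$exclusion$keep), sum(!x$exclusion$keep)))
  cat(sprintf("  winning model: %s\n", toupper(x$selection$winner)))
  if (!is.null(x$bayes_factors)) {
    hit <- dplyr::filter(x$bayes_factors, .data$basis == "hits")
    if (nrow(hit) == 1) {
      cat(sprintf("  Yold high vs low (hits): BF10 = %.3g, d = %.2f\n",
                  hit$bf10, hit$cohens_d))
    }
  }
  cat(sprintf("  outputs: %s\n", x$out_dir))
  invisible(x)
}
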