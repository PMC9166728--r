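#' Read a long-format ratings CSV
#'
#' Ingests the canonical rating table: UTF-8, comma-separated, with header
#' `expert_id,case_id,session,decision,confidence_level,truth`. Decisions
#' and truth are 0/1 with 1 the positive label (recall / significant
#' abnormality). Every row is validated (session in \{1, 2\}, confidence
#' within the declared scale, binary decision/truth); offending rows are
#' reported with their line numbers and abort the read unless
#' `permissive = TRUE`, in which case they are dropped and counted.
#'
#' @param path CSV file path.
#' @param n_levels Number of confidence levels the scale declares.
#' @param permissive Drop invalid rows instead of failing.
#' @return A tibble of rating records; attribute `n_dropped` counts rows
#'   dropped under `permissive`.
#' @export
read_ratings <- function(path, n_levels = 5L, permissive = FALSE) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           expert_id = readr::col_character(),
                           case_id = readr::col_character(),
                           session = readr::col_integer(),
                           decision = readr::col_integer(),
                           confidence_level = readr::col_integer(),
                           truth = readr::col_integer()
                         ))
  needed <- c("expert_id", "case_id", "session", "decision",
              "confidence_level", "truth")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("Missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  problems <- character(0)
  bad <- rep(FALSE, nrow(raw))
  flag <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0) {
      problems <<- c(problems, sprintf("row %d: %s", idx, what))
      bad[idx] <<- TRUE
    }
  }
  flag(is.na(raw$session) | !raw$session %in% c(1L, 2L),
       "session must be 1 or 2")
  flag(is.na(raw$decision) | !raw$decision %in% c(0L, 1L),
       "decision must be 0 or 1")
  flag(is.na(raw$truth) | !raw$truth %in% c(0L, 1L), "truth must be 0 or 1")
  flag(is.na(raw$confidence_level) | raw$confidence_level < 1 |
         raw$confidence_level > n_levels,
       sprintf("confidence_level outside 1..%d", n_levels))
  if (any(bad)) {
    if (!permissive) {
      stop("Invalid rating rows:\n  ",
           paste(utils::head(problems, 10), collapse = "\n  "),
           if (length(problems) > 10) sprintf("\n  ... and %d more",
                                              length(problems) - 10),
           call. = FALSE)
    }
    message(sum(bad), " invalid row(s) dropped.")
    raw <- raw[!bad, ]
  }
  attr(raw, "n_dropped") <- sum(bad)
  raw
}

#' Write the canonical ratings CSV
#'
#' @param ratings Tibble of rating records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(ratings, path) {
  validate_ratings(ratings)
  readr::write_csv(
    ratings[, c("expert_id", "case_id", "session", "decision",
                "confidence_level", "truth")], path)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects everything one analysis run depends on. `generate` may be
#' `NULL`, in which case `input` must point to an existing ratings CSV.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Global seed, stamped into every artifact.
#' @param input Optional path to a ratings CSV.
#' @param generate Optional named list of [simulate_reader_study()]
#'   arguments for synthetic input.
#' @param n_levels Confidence-scale size of the input data.
#' @param kindness_lower,kindness_upper Kind/wicked thresholds.
#' @param tie_policy Tie policy for the confidence rule.
#' @param sampler MCMC settings for the regression stage.
#' @param run_models Fit the hierarchical models (`M1`, `M2`, `M4`, `M5`,
#'   `M7`) and the effect-size test; disable for summaries only.
#' @param method Regression engine, `"mcmc"` or `"ml"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, input = NULL, generate = NULL,
                       n_levels = 2L, kindness_lower = 0.4,
                       kindness_upper = 0.6, tie_policy = "random",
                       sampler = default_sampler(), run_models = TRUE,
                       method = "mcmc") {
  if (is.null(input) && is.null(generate)) {
    stop("Provide `input` (ratings CSV) or `generate` (simulation settings).",
         call. = FALSE)
  }
  if (kindness_lower > kindness_upper) {
    stop("`kindness_lower` must not exceed `kindness_upper`.", call. = FALSE)
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), input = input,
         generate = generate, n_levels = as.integer(n_levels),
         kindness_lower = kindness_lower, kindness_upper = kindness_upper,
         tie_policy = tie_policy, sampler = sampler,
         run_models = isTRUE(run_models), method = method),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes generate (optional) -> pair -> summarize -> evaluate-rule ->
#' analyze, writing every artifact as CSV into `config$out_dir` together
#' with a YAML run log (seed, package version, per-stage record counts,
#' stage timings). Deterministic stages are byte-stable for identical
#' configurations; the MCMC stage is seed-stable.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory artifacts (`ratings`,
#'   `pairs`, `case_summaries`, `expert_summaries`, `rule_evaluations`,
#'   `fits`, `delta_test`, `log`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = config$seed,
              package_version = as.character(utils::packageVersion("scmdiag")),
              started = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
              stages = list())
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("Pipeline stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  mark <- function(name, count) {
    log$stages[[name]] <<- list(records = count,
                                elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
  }

  ratings <- stage("input", {
    if (!is.null(config$generate)) {
      args <- utils::modifyList(list(seed = config$seed),
                                as.list(config$generate))
      if (!is.null(args$n_levels)) {
        args$scale <- confidence_scale(args$n_levels)
        args$n_levels <- NULL
      }
      study <- do.call(simulate_reader_study, args)
      readr::write_csv(study$cases, file.path(config$out_dir, "cases.csv"))
      study$ratings
    } else {
      read_ratings(config$input, n_levels = config$n_levels)
    }
  })
  write_ratings(ratings, file.path(config$out_dir, "ratings.csv"))
  mark("input", nrow(ratings))

  pairs <- stage("pair", pair_sessions(ratings, quiet = TRUE))
  mark("pair", nrow(pairs))
  log$stages$pair$dropped <- attr(pairs, "n_dropped")

  case_summaries <- stage("summarize", summarize_cases(
    ratings, pairs, lower = config$kindness_lower,
    upper = config$kindness_upper))
  expert_summaries <- stage("summarize", summarize_experts(pairs))
  readr::write_csv(case_summaries,
                   file.path(config$out_dir, "case_summaries.csv"))
  readr::write_csv(expert_summaries,
                   file.path(config$out_dir, "expert_summaries.csv"))
  mark("summarize", nrow(case_summaries))

  scored <- stage("evaluate-rule", mcs_choice(
    pairs, tie_policy = config$tie_policy, seed = config$seed))
  evaluations <- stage("evaluate-rule", lapply(
    stats::setNames(nm = c("first", "second", "random")),
    function(b) evaluate_rule(scored, case_summaries, baseline = b)))
  for (b in names(evaluations)) {
    readr::write_csv(evaluations[[b]]$per_case,
                     file.path(config$out_dir,
                               sprintf("rule_vs_%s_per_case.csv", b)))
    readr::write_csv(evaluations[[b]]$per_expert,
                     file.path(config$out_dir,
                               sprintf("rule_vs_%s_per_expert.csv", b)))
  }
  mark("evaluate-rule", evaluations$random$n_conflicts)
  log$stages$`evaluate-rule`$ties <- evaluations$random$n_ties
  log$stages$`evaluate-rule`$tie_policy <- config$tie_policy

  fits <- list()
  delta_test <- NULL
  if (config$run_models) {
    dat <- stage("analyze", regression_data(
      scored, case_summaries, apply_rule = FALSE))
    for (mname in c("M1", "M2", "M4", "M5", "M7")) {
      mdat <- if (mname == "M7") dplyr::filter(dat, .data$changed == 1L) else dat
      fits[[mname]] <- stage("analyze", fit_mixed_model(
        mdat, model_spec(mname), sampler = config$sampler,
        method = config$method, seed = config$seed))
    }
    delta_test <- stage("analyze", bayes_one_sample_ttest(
      dplyr::filter(evaluations$random$per_expert,
                    .data$stratum == "all")$improvement))
    results <- dplyr::bind_rows(lapply(names(fits), function(m) {
      dplyr::mutate(fits[[m]]$terms, model = m, .before = 1)
    }))
    readr::write_csv(results, file.path(config$out_dir, "model_terms.csv"))
    log$stages$analyze <- list(
      models = names(fits),
      converged = vapply(fits, function(f) f$diagnostics$converged,
                         logical(1)),
      delta_median = delta_test$delta_median
    )
  }

  log$finished <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  yaml::write_yaml(log, file.path(config$out_dir, "run_log.yaml"))
  invisible(list(ratings = ratings, pairs = pairs,
                 case_summaries = case_summaries,
                 expert_summaries = expert_summaries,
                 rule_evaluations = evaluations, fits = fits,
                 delta_test = delta_test, log = log))
}
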