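#' Maximum-confidence slating over an expert's two decisions
#'
#' Given an expert's two decisions on the same case, adopt the one held with
#' higher confidence (the "confidence rule"). When the decisions agree, the
#' shared decision is kept regardless of confidence. Equal confidences on
#' conflicting decisions are a tie; the tie policy decides (seeded random by
#' default) and the tie is flagged so downstream summaries can count it.
#'
#' @param pairs Tibble of paired decisions from [pair_sessions()].
#' @param tie_policy `"random"`, `"first"` or `"second"`.
#' @param seed Seed for random tie-breaking.
#' @return The input tibble with added columns `chosen`, `rule_correct`,
#'   `first_correct`, `second_correct`, `tie`.
#' @examples
#' study <- simulate_reader_study(n_experts = 3, n_cases = 30, seed = 1)
#' mcs_choice(pair_sessions(study$ratings), seed = 1)
#' @export
mcs_choice <- function(pairs, tie_policy = c("random", "first", "second"),
                       seed = 1L) {
  tie_policy <- match.arg(tie_policy)
  stopifnot(is.data.frame(pairs),
            all(c("decision_1", "decision_2", "confidence_1", "confidence_2",
                  "truth", "changed") %in% names(pairs)))
  n <- nrow(pairs)
  tie <- pairs$changed & pairs$confidence_1 == pairs$confidence_2
  take_first <- !pairs$changed | pairs$confidence_1 > pairs$confidence_2
  if (any(tie)) {
    take_first[tie] <- switch(
      tie_policy,
      first = TRUE,
      second = FALSE,
      random = {
        set.seed(seed)
        stats::runif(n)[tie] < 0.5
      }
    )
  }
  pairs |>
    dplyr::mutate(
      chosen = ifelse(take_first, .data$decision_1, .data$decision_2),
      rule_correct = .data$chosen == .data$truth,
      first_correct = .data$decision_1 == .data$truth,
      second_correct = .data$decision_2 == .data$truth,
      tie = tie
    )
}

#' Evaluate the confidence rule against baselines
#'
#' Among the conflicting pairs (the expert changed their diagnosis between
#' sessions — consistent pairs carry no contrast), compares the accuracy of
#' maximum-confidence slating to a baseline strategy: the first diagnosis,
#' the second diagnosis, or choosing at random between the two. On a binary
#' conflict the random baseline is exactly 0.5, so it enters analytically
#' rather than by simulation. Improvements are `rule_correct -
#' baseline_correct` per pair, aggregated to weighted means per case and per
#' expert; when stratifying, intermediate-kindness cases are excluded from
#' the kind/wicked strata but kept in the `"all"` stratum.
#'
#' @param pairs Paired decisions (with or without [mcs_choice()] columns;
#'   the rule is applied if absent).
#' @param summaries Case summaries from [summarize_cases()], required when
#'   `stratify_by_kindness = TRUE`.
#' @param baseline `"first"`, `"second"` or `"random"`.
#' @param stratify_by_kindness Add kind/wicked strata next to `"all"`.
#' @param tie_policy,seed Passed to [mcs_choice()].
#' @return A list of class `rule_evaluation` with tibbles `per_case`
#'   (`stratum`, `case_id`, `improvement`, `weight`), `per_expert`, a
#'   `summary` tibble of weighted box statistics per stratum, and counters
#'   `n_conflicts`, `n_ties`.
#' @examples
#' study <- simulate_reader_study(n_experts = 5, n_cases = 50, seed = 1)
#' pairs <- pair_sessions(study$ratings)
#' evaluate_rule(pairs, summarize_cases(study$ratings), baseline = "random")
#' @export
evaluate_rule <- function(pairs, summaries = NULL,
                          baseline = c("first", "second", "random"),
                          stratify_by_kindness = !is.null(summaries),
                          tie_policy = "random", seed = 1L) {
  baseline <- match.arg(baseline)
  if (!"rule_correct" %in% names(pairs)) {
    pairs <- mcs_choice(pairs, tie_policy = tie_policy, seed = seed)
  }
  conflicts <- dplyr::filter(pairs, .data$changed)
  if (nrow(conflicts) == 0) {
    stop("No conflicting pairs: the confidence rule has nothing to resolve.",
         call. = FALSE)
  }
  baseline_correct <- switch(
    baseline,
    first = as.numeric(conflicts$first_correct),
    second = as.numeric(conflicts$second_correct),
    random = 0.5
  )
  conflicts$improvement <- as.numeric(conflicts$rule_correct) - baseline_correct

  if (stratify_by_kindness) {
    if (is.null(summaries)) {
      stop("`summaries` with a `kindness` column is required to stratify.",
           call. = FALSE)
    }
    missing_cases <- setdiff(conflicts$case_id, summaries$case_id)
    if (length(missing_cases) > 0) {
      stop("No kindness classification for case(s): ",
           paste(utils::head(missing_cases, 5), collapse = ", "),
           call. = FALSE)
    }
    conflicts <- dplyr::left_join(
      conflicts, dplyr::select(summaries, "case_id", "kindness"),
      by = "case_id"
    )
  }

  aggregate_by <- function(df, id_col, stratum) {
    df |>
      dplyr::group_by(.data[[id_col]]) |>
      dplyr::summarise(improvement = mean(.data$improvement),
                       weight = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(stratum = stratum, .before = 1)
  }
  strata <- list(all = conflicts)
  if (stratify_by_kindness) {
    for (k in c("kind", "wicked")) {
      sub <- dplyr::filter(conflicts, .data$kindness == k)
      if (nrow(sub) > 0) strata[[k]] <- sub
    }
  }
  per_case <- dplyr::bind_rows(
    lapply(names(strata), function(s) aggregate_by(strata[[s]], "case_id", s)))
  per_expert <- dplyr::bind_rows(
    lapply(names(strata), function(s) aggregate_by(strata[[s]], "expert_id", s)))

  summary <- per_case |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      n_cases = dplyr::n(),
      stats = list(weighted_box_stats(.data$improvement, .data$weight)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("stats")

  structure(
    list(baseline = baseline, per_case = per_case, per_expert = per_expert,
         summary = summary, n_conflicts = nrow(conflicts),
         n_ties = sum(conflicts$tie)),
    class = "rule_evaluation"
  )
}

#' @export
print.rule_evaluation <- function(x, ...) {
  cat(sprintf(
    "Confidence rule vs %s baseline: %d conflicting pairs (%d ties)\n",
    x$baseline, x$n_conflicts, x$n_ties))
  print(x$summary)
  invisible(x)
}

#' Weighted box statistics
#'
#' Quartiles of values carrying positive integer weights (numbers of
#' contributing observations), computed by cumulative-weight interpolation.
#' The result is identical to expanding each weight-`w` point into `w`
#' unit-weight copies and taking ordinary sample quantiles, without
#' materializing the expansion.
#'
#' @param values Numeric vector.
#' @param weights Positive integer weights, same length.
#' @return A named list: `q1`, `median`, `q3`, `n_obs` (total weight).
#' @examples
#' weighted_box_stats(c(0, 1), c(3, 1)) # median 0, as for c(0, 0, 0, 1)
#' @export
weighted_box_stats <- function(values, weights = rep(1, length(values))) {
  if (length(values) == 0) stop("Empty input.", call. = FALSE)
  if (length(weights) != length(values) || any(weights <= 0) ||
      any(weights != round(weights))) {
    stop("`weights` must be positive integers matching `values`.",
         call. = FALSE)
  }
  ord <- order(values)
  v <- values[ord]
  w <- weights[ord]
  cum <- cumsum(w)
  n <- cum[length(cum)]
  # sample quantile (type 7) of the conceptually expanded vector
  qtype7 <- function(prob) {
    h <- (n - 1) * prob + 1
    lo <- findInterval(floor(h), cum, left.open = TRUE) + 1L
    hi <- findInterval(ceiling(h), cum, left.open = TRUE) + 1L
    v[lo] + (h - floor(h)) * (v[hi] - v[lo])
  }
  list(q1 = qtype7(0.25), median = qtype7(0.5), q3 = qtype7(0.75), n_obs = n)
}
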