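#' Pair the two sessions of a reader study
#'
#' Joins each expert's session-1 and session-2 ratings of the same case into
#' one paired record; expert x case combinations rated in only one session
#' are dropped (their count is attached as an attribute and reported).
#' Duplicate expert x case x session records are a hard error, since they
#' make the pairing ambiguous.
#'
#' @param ratings Tibble of rating records (`expert_id`, `case_id`,
#'   `session`, `decision`, `confidence_level`, `truth`).
#' @param quiet Suppress the dropped-singleton message.
#' @return A tibble of paired decisions: `expert_id`, `case_id`,
#'   `decision_1`, `decision_2`, `confidence_1`, `confidence_2`, `truth`,
#'   `changed`. Attribute `n_dropped` counts unpaired records.
#' @examples
#' study <- simulate_reader_study(n_experts = 2, n_cases = 10, seed = 1)
#' pair_sessions(study$ratings)
#' @export
pair_sessions <- function(ratings, quiet = FALSE) {
  validate_ratings(ratings)
  dup <- ratings |>
    dplyr::count(.data$expert_id, .data$case_id, .data$session) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("Duplicate expert x case x session records: ",
         paste(sprintf("%s/%s/s%d", dup$expert_id, dup$case_id, dup$session),
               collapse = ", "), call. = FALSE)
  }
  wide <- ratings |>
    tidyr::pivot_wider(
      id_cols = c("expert_id", "case_id", "truth"),
      names_from = "session",
      values_from = c("decision", "confidence_level")
    )
  paired <- wide |>
    dplyr::filter(!is.na(.data$decision_1), !is.na(.data$decision_2)) |>
    dplyr::transmute(
      expert_id = .data$expert_id, case_id = .data$case_id,
      decision_1 = .data$decision_1, decision_2 = .data$decision_2,
      confidence_1 = .data$confidence_level_1,
      confidence_2 = .data$confidence_level_2,
      truth = .data$truth,
      changed = .data$decision_1 != .data$decision_2
    )
  n_dropped <- nrow(ratings) - 2L * nrow(paired)
  if (!quiet && n_dropped > 0) {
    message(n_dropped, " unpaired rating(s) dropped (present in one session only).")
  }
  attr(paired, "n_dropped") <- n_dropped
  paired
}

#' Per-case consensus, confidence and inconsistency
#'
#' For each case: the proportion of experts whose initial diagnosis was
#' correct (`P_hat`, the case's consensus level), the mean elicited
#' confidence, the proportion of paired experts who changed their diagnosis
#' between sessions (`I_hat`), and the kind/wicked classification of the
#' case. `P_hat` and `mean_confidence` use session-1 ratings by default; set
#' `session = 2` to reproduce second-reading summaries. Cases with no paired
#' ratings get `I_hat = NA` and are flagged, never silently zeroed.
#'
#' @param ratings Tibble of rating records.
#' @param pairs Paired decisions from [pair_sessions()]; computed from
#'   `ratings` when omitted.
#' @param session Which session feeds `P_hat` and `mean_confidence` (1 or 2).
#' @param lower,upper Kindness thresholds passed to [classify_kindness()].
#' @param min_raters Cases with fewer session ratings than this are flagged
#'   `low_precision` (consensus estimates from few readers are noisy).
#' @return A tibble with one row per case: `case_id`, `truth`, `n_raters`,
#'   `P_hat`, `mean_confidence`, `n_pairs`, `I_hat`, `kindness`,
#'   `low_precision`.
#' @examples
#' study <- simulate_reader_study(n_experts = 5, n_cases = 20, seed = 1)
#' summarize_cases(study$ratings)
#' @export
summarize_cases <- function(ratings, pairs = NULL, session = 1L,
                            lower = 0.4, upper = 0.6, min_raters = 5L) {
  validate_ratings(ratings)
  stopifnot(session %in% c(1L, 2L))
  if (is.null(pairs)) pairs <- pair_sessions(ratings, quiet = TRUE)

  unknown <- setdiff(pairs$case_id, ratings$case_id)
  if (length(unknown) > 0) {
    stop("Pairs reference unknown case ids: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }

  per_session <- ratings |>
    dplyr::filter(.data$session == !!session) |>
    dplyr::group_by(.data$case_id, .data$truth) |>
    dplyr::summarise(
      n_raters = dplyr::n(),
      P_hat = mean(.data$decision == .data$truth),
      mean_confidence = mean(.data$confidence_level),
      .groups = "drop"
    )
  if (nrow(per_session) == 0) {
    stop("No session-", session, " ratings to summarize.", call. = FALSE)
  }
  per_pairs <- pairs |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(n_pairs = dplyr::n(), I_hat = mean(.data$changed),
                     .groups = "drop")

  per_session |>
    dplyr::left_join(per_pairs, by = "case_id") |>
    dplyr::mutate(
      n_pairs = dplyr::coalesce(.data$n_pairs, 0L),
      I_hat = dplyr::if_else(.data$n_pairs > 0, .data$I_hat, NA_real_),
      kindness = classify_kindness(.data$P_hat, lower = lower, upper = upper),
      low_precision = .data$n_raters < min_raters
    )
}

#' Per-expert inconsistency and session accuracies
#'
#' For each expert, over the cases they rated in both sessions: the
#' proportion of diagnoses changed between sessions, per-session accuracy,
#' and per-session mean confidence.
#'
#' @param pairs Paired decisions from [pair_sessions()].
#' @return A tibble with one row per expert: `expert_id`, `n_pairs`,
#'   `inconsistency`, `accuracy_1`, `accuracy_2`, `mean_confidence_1`,
#'   `mean_confidence_2`.
#' @examples
#' study <- simulate_reader_study(n_experts = 5, n_cases = 50, seed = 1)
#' summarize_experts(pair_sessions(study$ratings))
#' @export
summarize_experts <- function(pairs) {
  if (!is.data.frame(pairs) || nrow(pairs) == 0) {
    stop("`pairs` must be a non-empty tibble of paired decisions.",
         call. = FALSE)
  }
  pairs |>
    dplyr::group_by(.data$expert_id) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      inconsistency = mean(.data$changed),
      accuracy_1 = mean(.data$decision_1 == .data$truth),
      accuracy_2 = mean(.data$decision_2 == .data$truth),
      mean_confidence_1 = mean(.data$confidence_1),
      mean_confidence_2 = mean(.data$confidence_2),
      .groups = "drop"
    )
}

#' Classify cases as kind, wicked or intermediate
#'
#' A case is *kind* when the observed consensus `P_hat` exceeds the upper
#' threshold (the expert majority tends to be right) and *wicked* when it
#' falls below the lower threshold (the majority tends to be wrong). The
#' band in between — where the consensus classification would rest on a
#' handful of readings — is *intermediate*: such cases are excluded from
#' kindness-stratified contrasts but retained everywhere else. The inclusive
#' band matches the strict inequalities defining kind (`P_hat > upper`) and
#' wicked (`P_hat < lower`).
#'
#' @param P_hat Consensus proportion(s) in `[0, 1]`.
#' @param lower,upper Thresholds, `0 <= lower <= upper <= 1` (defaults 0.4
#'   and 0.6).
#' @return Factor with levels `wicked`, `intermediate`, `kind`.
#' @examples
#' classify_kindness(c(0.3, 0.5, 0.6, 0.7))
#' @export
classify_kindness <- function(P_hat, lower = 0.4, upper = 0.6) {
  if (any(is.na(P_hat)) || any(P_hat < 0) || any(P_hat > 1)) {
    stop("`P_hat` must lie in [0, 1].", call. = FALSE)
  }
  if (lower > upper || lower < 0 || upper > 1) {
    stop("Thresholds must satisfy 0 <= lower <= upper <= 1.", call. = FALSE)
  }
  factor(
    dplyr::case_when(P_hat > upper ~ "kind",
                     P_hat < lower ~ "wicked",
                     TRUE ~ "intermediate"),
    levels = c("wicked", "intermediate", "kind")
  )
}

#' Local-linear smooth of a case-level scatter
#'
#' Presentation-only diagnostic smoother (degree-1 local regression with a
#' configurable span) for plots such as inconsistency against consensus.
#' It plays no role in any statistical test.
#'
#' @param x,y Numeric vectors.
#' @param span Smoothing span in `(0, 1]`.
#' @param n_out Number of evaluation points.
#' @return A tibble with columns `x` and `y_smooth`.
#' @export
smooth_trend <- function(x, y, span = 0.75, n_out = 100L) {
  keep <- stats::complete.cases(x, y)
  df <- data.frame(x = x[keep], y = y[keep])
  fit <- stats::loess(y ~ x, data = df, span = span, degree = 1,
                      family = "gaussian")
  grid <- seq(min(df$x), max(df$x), length.out = n_out)
  tibble::tibble(x = grid,
                 y_smooth = stats::predict(fit, newdata = data.frame(x = grid)))
}

validate_ratings <- function(ratings) {
  needed <- c("expert_id", "case_id", "session", "decision",
              "confidence_level", "truth")
  if (!is.data.frame(ratings) || !all(needed %in% names(ratings))) {
    stop("`ratings` must contain columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  invisible(ratings)
}
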