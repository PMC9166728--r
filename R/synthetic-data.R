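#' Specify a synthetic case population
#'
#' Describes the pool of cases in a synthetic reader study: how many cases,
#' what fraction of them are "kind" (cue validity above 0.5, so the expert
#' majority tends to be right), the distributions the kind and wicked cue
#' validities are drawn from, and the prevalence of truth-positive cases.
#'
#' Defaults emulate a lumbosacral-spine-style study: 300 cases of which 50
#' are positive (significant abnormality), and a kind environment in which
#' 80% of cases are kind. Cue-validity distributions are Beta shapes mapped
#' onto the kind half `(0.5, 1]` and the wicked half `[0, 0.5)`; the default
#' `Beta(2, 2)` puts most mass at moderate ambiguity on either side.
#'
#' @param n_cases Number of cases.
#' @param kind_fraction Proportion of cases with cue validity above 0.5.
#'   A kind environment (`> 0.5`) encodes the assumption that the expert
#'   population has at least some skill.
#' @param prevalence Proportion of truth-positive cases. Truth is assigned
#'   independently of cue validity unless `wicked_positive_bias` is set.
#' @param p_kind,p_wicked Length-2 numeric vectors `c(shape1, shape2)` of the
#'   Beta distributions generating cue validities, rescaled to `(0.5, 1]` for
#'   kind and `[0, 0.5)` for wicked cases. A degenerate point mass can be
#'   requested with `list(point = value)`.
#' @param wicked_positive_bias Optional coupling in `[-1, 1]` between
#'   wickedness and truth class: positive values make wicked cases more
#'   likely to be truth-negative (some repeated-reading designs use only
#'   disease-free cases, where misleading cues all push toward recall).
#'   `0` (default) keeps truth independent of cue validity.
#'
#' @return A list of class `population_spec`.
#' @examples
#' population_spec(n_cases = 300, prevalence = 50 / 300)
#' @export
population_spec <- function(n_cases = 300L,
                            kind_fraction = 0.8,
                            prevalence = 50 / 300,
                            p_kind = c(2, 2),
                            p_wicked = c(2, 2),
                            wicked_positive_bias = 0) {
  stopifnot(n_cases >= 1, kind_fraction >= 0, kind_fraction <= 1,
            prevalence >= 0, prevalence <= 1,
            wicked_positive_bias >= -1, wicked_positive_bias <= 1)
  check_p_dist <- function(d, label) {
    ok <- (is.numeric(d) && length(d) == 2L && all(d > 0)) ||
      (is.list(d) && identical(names(d), "point") &&
         d$point >= 0 && d$point <= 1)
    if (!ok) stop(sprintf(
      "`%s` must be Beta shapes c(shape1, shape2) or list(point = value).",
      label), call. = FALSE)
  }
  check_p_dist(p_kind, "p_kind")
  check_p_dist(p_wicked, "p_wicked")
  structure(
    list(n_cases = as.integer(n_cases), kind_fraction = kind_fraction,
         prevalence = prevalence, p_kind = p_kind, p_wicked = p_wicked,
         wicked_positive_bias = wicked_positive_bias),
    class = "population_spec"
  )
}

draw_half_validity <- function(n, dist, half) {
  u <- if (is.list(dist)) rep(dist$point, n) else stats::rbeta(n, dist[1], dist[2])
  if (is.list(dist)) return(u)  # point mass is taken as the validity itself
  if (half == "kind") 0.5 + 0.5 * u else 0.5 * u
}

#' Generate a synthetic case pool
#'
#' Draws one cue validity `p_i` per case from the kind/wicked mixture of a
#' [population_spec()] and assigns binary ground truth at the specified
#' prevalence. The cue validity is a property of the case, shared by all
#' experts who read it.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed.
#' @return A tibble with columns `case_id`, `truth` (0/1), `p_i`, and
#'   `kind` (logical, `p_i > 0.5`).
#' @examples
#' generate_cases(population_spec(n_cases = 10), seed = 1)
#' @export
generate_cases <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(seed)
  n <- spec$n_cases
  kind <- stats::runif(n) < spec$kind_fraction
  p_i <- numeric(n)
  p_i[kind] <- draw_half_validity(sum(kind), spec$p_kind, "kind")
  p_i[!kind] <- draw_half_validity(sum(!kind), spec$p_wicked, "wicked")
  # point-mass specs may place p_i on either side; recompute the class label
  kind <- p_i > 0.5

  # optional coupling: shift positive-truth probability down for wicked cases
  # and renormalize so the marginal prevalence is preserved
  pr <- rep(spec$prevalence, n)
  b <- spec$wicked_positive_bias
  if (b != 0 && any(!kind) && any(kind)) {
    w <- mean(!kind)
    pr[!kind] <- spec$prevalence * (1 - b)
    pr[kind] <- (spec$prevalence - w * pr[!kind][1]) / (1 - w)
    pr <- pmin(pmax(pr, 0), 1)
  }
  truth <- as.integer(stats::runif(n) < pr)
  tibble::tibble(
    case_id = sprintf("case_%04d", seq_len(n)),
    truth = truth, p_i = p_i, kind = kind
  )
}

#' Expert design for a synthetic reader study
#'
#' One row per expert: an id, the (odd) number of cues the expert samples,
#' and which cases the expert reads in each session. By default every expert
#' samples the same number of cues and reads every case in both sessions;
#' incomplete designs are expressed by restricting `cases_1` / `cases_2`.
#'
#' @param n_experts Number of experts.
#' @param n_cues Odd cue count, recycled or length `n_experts` for
#'   heterogeneous experts.
#' @param cases_1,cases_2 Optional list of character vectors of case ids per
#'   expert (defaults to all cases at rating time).
#' @return A tibble with columns `expert_id`, `n_cues`, `cases_1`, `cases_2`.
#' @examples
#' expert_design(13, n_cues = 9)
#' @export
expert_design <- function(n_experts, n_cues = 9L, cases_1 = NULL,
                          cases_2 = NULL) {
  stopifnot(n_experts >= 1)
  n_cues <- rep_len(as.integer(n_cues), n_experts)
  if (any(n_cues < 1) || any(n_cues %% 2 == 0)) {
    stop("`n_cues` must be positive odd integers.", call. = FALSE)
  }
  as_case_col <- function(x) {
    if (is.null(x)) rep(list(NULL), n_experts) else rep_len(x, n_experts)
  }
  tibble::tibble(
    expert_id = sprintf("expert_%03d", seq_len(n_experts)),
    n_cues = n_cues,
    cases_1 = as_case_col(cases_1),
    cases_2 = as_case_col(cases_2)
  )
}

#' Discrete confidence elicitation scale
#'
#' Partitions the continuous SCM confidence range `[0.5, 1]` into ordered
#' response levels, emulating the scales used in reader studies (a 5-point
#' mammography-style scale, a 2-point spine-style scale). Default bin edges
#' are equal-width; the mapping from model confidence to elicited level is a
#' design choice of the generator, not an empirical fact.
#'
#' @param n_levels Number of levels (>= 2).
#' @param bin_edges Optional `n_levels - 1` strictly increasing interior cut
#'   points in `(0.5, 1)`.
#' @return A list of class `confidence_scale`.
#' @examples
#' confidence_scale(5)
#' confidence_scale(2, bin_edges = 0.8)
#' @export
confidence_scale <- function(n_levels, bin_edges = NULL) {
  stopifnot(length(n_levels) == 1L, n_levels >= 2, n_levels == round(n_levels))
  n_levels <- as.integer(n_levels)
  if (is.null(bin_edges)) {
    bin_edges <- 0.5 + 0.5 * seq_len(n_levels - 1L) / n_levels
  }
  if (length(bin_edges) != n_levels - 1L || is.unsorted(bin_edges, strictly = TRUE) ||
      any(bin_edges <= 0.5) || any(bin_edges >= 1)) {
    stop("`bin_edges` must be ", n_levels - 1L,
         " strictly increasing values in (0.5, 1).", call. = FALSE)
  }
  structure(list(n_levels = n_levels, bin_edges = as.numeric(bin_edges)),
            class = "confidence_scale")
}

#' Map continuous confidence to a scale level
#'
#' Monotone binning of SCM confidence onto a [confidence_scale()]: level `k`
#' covers `[edge_{k-1}, edge_k)`, with the bottom bin closed at 0.5 and the
#' top bin closed at 1.
#'
#' @param confidence Numeric vector in `[0.5, 1]`.
#' @param scale A [confidence_scale()].
#' @return Integer levels in `1:n_levels`.
#' @examples
#' discretize_confidence(c(0.5, 0.74, 1), confidence_scale(5))
#' @export
discretize_confidence <- function(confidence, scale) {
  stopifnot(inherits(scale, "confidence_scale"))
  if (any(is.na(confidence)) || any(confidence < 0.5) || any(confidence > 1)) {
    stop("`confidence` must lie in [0.5, 1].", call. = FALSE)
  }
  findInterval(confidence, scale$bin_edges) + 1L
}

# Deterministic per-record seed stream: depends only on the global seed and
# the (expert, case, session) indices, so enlarging the design never
# perturbs records already generated. Index terms are spread with large
# multipliers (and the first uniform after reseeding is discarded at the
# draw site) so that the streams of neighbouring records are uncorrelated.
record_seed <- function(seed, expert_idx, case_idx, session) {
  (as.double(seed) * 2654435761 + expert_idx * 40503 +
     case_idx * 9973 + session * 1301081) %% 2147483647
}

#' Generate two-session expert ratings under the SCM
#'
#' For every expert x case x session cell of the design, draws an
#' independent SCM decision: `h ~ Binomial(n_cues, p_i)` cues point to the
#' correct option, the diagnosis is the correct label iff `h` reaches the
#' majority threshold, and the elicited confidence is the discretized
#' sampled-proportion confidence. The two sessions are conditionally
#' independent given `(p_i, n_cues)` — re-reading a case is drawing a fresh
#' cue sample.
#'
#' @param cases Tibble from [generate_cases()] (columns `case_id`, `truth`,
#'   `p_i`).
#' @param experts Tibble from [expert_design()].
#' @param scale A [confidence_scale()].
#' @param seed Integer seed; record-level draws use a deterministic stream
#'   split per expert x case x session.
#' @return A tibble of rating records: `expert_id`, `case_id`, `session`,
#'   `decision` (0/1 label), `confidence_level`, `truth`.
#' @examples
#' cases <- generate_cases(population_spec(n_cases = 5), seed = 1)
#' generate_ratings(cases, expert_design(2, 9), confidence_scale(5), seed = 1)
#' @export
generate_ratings <- function(cases, experts, scale, seed = 1L) {
  stopifnot(is.data.frame(cases), all(c("case_id", "truth", "p_i") %in% names(cases)),
            is.data.frame(experts), inherits(scale, "confidence_scale"))
  if (nrow(cases) == 0 || nrow(experts) == 0) {
    stop("Empty design: need at least one case and one expert.", call. = FALSE)
  }
  case_idx <- stats::setNames(seq_len(nrow(cases)), cases$case_id)

  out <- vector("list", nrow(experts) * 2L)
  k <- 0L
  for (e in seq_len(nrow(experts))) {
    n_cues <- experts$n_cues[e]
    m <- (n_cues + 1L) %/% 2L
    for (s in 1:2) {
      ids <- experts[[paste0("cases_", s)]][[e]]
      if (is.null(ids)) ids <- cases$case_id
      if (!all(ids %in% cases$case_id)) {
        stop("Expert design references unknown case ids.", call. = FALSE)
      }
      ci <- unname(case_idx[ids])
      h <- vapply(ci, function(i) {
        set.seed(record_seed(seed, e, i, s))
        stats::runif(1L)  # burn one draw to decorrelate nearby streams
        stats::rbinom(1L, n_cues, cases$p_i[i])
      }, integer(1))
      correct <- h >= m
      conf <- confidence_from_sample(h / n_cues)
      k <- k + 1L
      out[[k]] <- tibble::tibble(
        expert_id = experts$expert_id[e],
        case_id = ids,
        session = s,
        decision = ifelse(correct, cases$truth[ci], 1L - cases$truth[ci]),
        confidence_level = discretize_confidence(conf, scale),
        truth = cases$truth[ci]
      )
    }
  }
  dplyr::bind_rows(out[seq_len(k)])
}

#' Simulate a complete synthetic reader study
#'
#' Convenience wrapper tying [generate_cases()], [expert_design()] and
#' [generate_ratings()] together. Defaults emulate a spine-style study: 13
#' experts reading 300 cases twice on a 2-point confidence scale, giving
#' 3900 repeated assessments.
#'
#' @param n_experts,n_cases Design size.
#' @param n_cues Odd cue count per expert.
#' @param kind_fraction,prevalence,p_kind,p_wicked,wicked_positive_bias
#'   Passed to [population_spec()].
#' @param scale A [confidence_scale()] (default 2-point).
#' @param seed Integer seed.
#' @return A list with `cases` (includes the latent `p_i`, for
#'   parameter-recovery checks) and `ratings`.
#' @examples
#' study <- simulate_reader_study(n_experts = 3, n_cases = 20, seed = 1)
#' nrow(study$ratings) # 3 * 20 * 2
#' @export
simulate_reader_study <- function(n_experts = 13L, n_cases = 300L,
                                  n_cues = 9L,
                                  kind_fraction = 0.8,
                                  prevalence = 50 / 300,
                                  p_kind = c(2, 2), p_wicked = c(2, 2),
                                  wicked_positive_bias = 0,
                                  scale = confidence_scale(2),
                                  seed = 1L) {
  spec <- population_spec(n_cases = n_cases, kind_fraction = kind_fraction,
                          prevalence = prevalence, p_kind = p_kind,
                          p_wicked = p_wicked,
                          wicked_positive_bias = wicked_positive_bias)
  cases <- generate_cases(spec, seed = seed)
  experts <- expert_design(n_experts, n_cues = n_cues)
  ratings <- generate_ratings(cases, experts, scale, seed = seed)
  list(cases = cases, ratings = ratings)
}
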