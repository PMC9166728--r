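#' Self-consistency model parameters
#'
#' Bundle the two parameters of the self-consistency model (SCM): the cue
#' validity `p` (probability that a single sampled cue points to the correct
#' option) and the number of sampled cues `n`. The SCM describes an expert
#' facing a two-alternative choice who samples a fixed, odd number of cues
#' and decides by cue majority; the majority threshold `m = (n + 1) / 2` is
#' derived and stored alongside.
#'
#' @param p Cue validity, a probability in `[0, 1]`.
#' @param n Number of sampled cues; a positive odd integer. Even values are
#'   rejected rather than tie-broken, which keeps the binomial accuracy
#'   expression exact.
#'
#' @return An object of class `scm_params`: a list with elements `p`, `n`
#'   and `m`.
#' @examples
#' scm_params(p = 0.6, n = 9)
#' @export
scm_params <- function(p, n) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("`p` must be a single probability in [0, 1].", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 ||
      n != round(n) || n %% 2 == 0) {
    stop("`n` must be a positive odd integer.", call. = FALSE)
  }
  n <- as.integer(n)
  structure(list(p = p, n = n, m = (n + 1L) %/% 2L), class = "scm_params")
}

#' @export
print.scm_params <- function(x, ...) {
  cat(sprintf("SCM parameters: p = %g, n = %d (majority threshold m = %d)\n",
              x$p, x$n, x$m))
  invisible(x)
}

as_scm_params <- function(params) {
  if (inherits(params, "scm_params")) return(params)
  if (is.list(params) && all(c("p", "n") %in% names(params))) {
    return(scm_params(params$p, params$n))
  }
  stop("`params` must be an `scm_params` object (see `scm_params()`).",
       call. = FALSE)
}

#' Probability of a correct majority decision
#'
#' Accuracy of an SCM decision maker: the upper binomial tail
#' \deqn{P(p, n) = \sum_{h = m}^{n} \binom{n}{h} p^h (1 - p)^{n - h},}
#' with majority threshold \eqn{m = (n + 1) / 2}. Computed through the
#' binomial survival function (`pbinom(..., lower.tail = FALSE)`) so the
#' tail does not degrade for large `n`; vectorized over `p`.
#'
#' @param params An [scm_params()] object, or `p` and `n` given directly.
#' @param p,n Alternative scalar/vector interface: cue validity (vectorized)
#'   and odd cue count. Ignored when `params` is supplied.
#'
#' @return Probability (vector) of a correct decision.
#' @examples
#' prob_correct(scm_params(0.6, 3)) # 0.648
#' prob_correct(p = c(0.4, 0.5, 0.6), n = 9)
#' @export
prob_correct <- function(params = NULL, p = NULL, n = NULL) {
  if (!is.null(params)) {
    params <- as_scm_params(params)
    p <- params$p
    n <- params$n
  } else {
    if (is.null(p) || is.null(n)) {
      stop("Supply either `params` or both `p` and `n`.", call. = FALSE)
    }
    if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
      stop("`p` must lie in [0, 1].", call. = FALSE)
    }
    if (length(n) != 1L || is.na(n) || n < 1 || n != round(n) || n %% 2 == 0) {
      stop("`n` must be a positive odd integer.", call. = FALSE)
    }
  }
  m <- (n + 1) / 2
  stats::pbinom(m - 1, size = n, prob = p, lower.tail = FALSE)
}

#' SCM confidence from a sampled cue proportion
#'
#' Confidence is the complement of the sample standard deviation of the
#' sampled cue proportion: \eqn{C = 1 - \sqrt{\hat p (1 - \hat p)}}. It is
#' symmetric in \eqn{\hat p \leftrightarrow 1 - \hat p} (an expert who saw
#' 8/9 cues for the *wrong* option is just as confident), minimal (0.5) at
#' \eqn{\hat p = 0.5} and maximal (1) at 0 and 1.
#'
#' @param p_hat Sampled cue proportion(s) in `[0, 1]`.
#' @return Confidence value(s) in `[0.5, 1]`.
#' @examples
#' confidence_from_sample(c(0.5, 0.8, 1)) # 0.5, 0.6, 1
#' @export
confidence_from_sample <- function(p_hat) {
  if (any(is.na(p_hat)) || any(p_hat < 0) || any(p_hat > 1)) {
    stop("`p_hat` must lie in [0, 1].", call. = FALSE)
  }
  1 - sqrt(p_hat * (1 - p_hat))
}

#' Test-retest inconsistency implied by decision accuracy
#'
#' If a decision is correct with probability `P` and two readings of the same
#' case are independent samples, the probability that they disagree is
#' \eqn{I = 2 P (1 - P)}: maximal (0.5) at chance-level accuracy and zero for
#' perfectly correct or perfectly incorrect decisions.
#'
#' @param P Probability (or vector of probabilities) of a correct decision.
#' @return Inconsistency probability in `[0, 0.5]`.
#' @examples
#' inconsistency_from_P(c(0.5, 0.7, 1)) # 0.5, 0.42, 0
#' @export
inconsistency_from_P <- function(P) {
  if (any(is.na(P)) || any(P < 0) || any(P > 1)) {
    stop("`P` must lie in [0, 1].", call. = FALSE)
  }
  2 * P * (1 - P)
}

#' Simulate one SCM decision
#'
#' Draws the number `h` of cues pointing to the correct option from
#' `Binomial(n, p)`, decides by majority, and attaches the SCM confidence of
#' the sampled proportion. Note the model's signature property: a perfectly
#' wicked case (`p = 0`) yields a *wrong* decision held with *maximal*
#' confidence.
#'
#' @param params An [scm_params()] object.
#' @param seed Optional integer seed for a reproducible draw.
#' @return A list of class `scm_decision` with `h`, `p_hat`, `correct`
#'   and `confidence`.
#' @examples
#' simulate_decision(scm_params(0.6, 9), seed = 1)
#' @export
simulate_decision <- function(params, seed = NULL) {
  params <- as_scm_params(params)
  if (!is.null(seed)) set.seed(seed)
  h <- stats::rbinom(1L, size = params$n, prob = params$p)
  p_hat <- h / params$n
  structure(
    list(h = h, p_hat = p_hat, correct = h >= params$m,
         confidence = confidence_from_sample(p_hat)),
    class = "scm_decision"
  )
}

#' @export
print.scm_decision <- function(x, ...) {
  cat(sprintf("SCM decision: h = %d, p_hat = %.3f, %s, confidence = %.3f\n",
              x$h, x$p_hat, if (x$correct) "correct" else "incorrect",
              x$confidence))
  invisible(x)
}

#' Model predictions over a grid of cue validities and cue counts
#'
#' Evaluates the three SCM quantities — accuracy `P`, expected confidence `C`
#' (cue validity plugged into the confidence function, the construction used
#' for the model's theoretical curves) and inconsistency `I = 2P(1-P)` — on
#' the Cartesian grid of `p_grid` and `n_values`. With
#' `expectation = "exact"`, `C` is instead the exact expectation of the
#' sampled-proportion confidence over the binomial distribution of `h`.
#'
#' @param p_grid Numeric vector of cue validities in `[0, 1]`.
#' @param n_values Vector of odd cue counts (defaults chosen to span small,
#'   moderate and large samples; the model's qualitative shape does not
#'   depend on the particular values).
#' @param expectation `"plugin"` (default) or `"exact"` for the confidence
#'   column.
#' @return A tibble with columns `p`, `n`, `P`, `C`, `I`, one row per
#'   combination; write it with [readr::write_csv()] to export the curves.
#' @examples
#' prediction_grid(seq(0, 1, 0.25), n_values = c(3, 9))
#' @export
prediction_grid <- function(p_grid, n_values = c(3L, 9L, 33L),
                            expectation = c("plugin", "exact")) {
  expectation <- match.arg(expectation)
  if (length(p_grid) == 0 || length(n_values) == 0) {
    stop("`p_grid` and `n_values` must be non-empty.", call. = FALSE)
  }
  if (any(is.na(p_grid)) || any(p_grid < 0) || any(p_grid > 1)) {
    stop("`p_grid` values must lie in [0, 1].", call. = FALSE)
  }
  if (any(n_values < 1) || any(n_values != round(n_values)) ||
      any(n_values %% 2 == 0)) {
    stop("`n_values` must be positive odd integers.", call. = FALSE)
  }
  grid <- tidyr::expand_grid(p = as.numeric(p_grid), n = as.integer(n_values))
  grid$P <- mapply(function(p, n) prob_correct(p = p, n = n), grid$p, grid$n)
  grid$C <- switch(
    expectation,
    plugin = confidence_from_sample(grid$p),
    exact = mapply(expected_confidence_exact, grid$p, grid$n)
  )
  grid$I <- inconsistency_from_P(grid$P)
  grid
}

# E[1 - sqrt(h/n (1 - h/n))] with h ~ Binomial(n, p)
expected_confidence_exact <- function(p, n) {
  h <- 0:n
  sum(stats::dbinom(h, n, p) * confidence_from_sample(h / n))
}

#' Condorcet amplification of cue validity
#'
#' With three or more cues, majority voting amplifies the cue validity:
#' group-of-cues accuracy `P` exceeds `p` when `p > 0.5`, falls below it when
#' `p < 0.5`, and equals it at `p = 0.5`. This is the Condorcet jury theorem
#' applied to cues rather than voters, and it is why the observed expert
#' consensus on a case is a more extreme version of the case's cue validity.
#'
#' @param params An [scm_params()] object with `n >= 3`.
#' @return A list of class `condorcet_report` with `p`, `n`, `P` and
#'   `relation` (one of `"P>p"`, `"P<p"`, `"P=p"`).
#' @examples
#' condorcet_relation(scm_params(0.6, 3)) # P > p: 0.648 > 0.6
#' @export
condorcet_relation <- function(params) {
  params <- as_scm_params(params)
  if (params$n < 3) {
    stop("Condorcet amplification requires `n >= 3`.", call. = FALSE)
  }
  P <- prob_correct(params)
  relation <- if (isTRUE(all.equal(P, params$p, tolerance = 1e-12))) {
    "P=p"
  } else if (P > params$p) "P>p" else "P<p"
  structure(list(p = params$p, n = params$n, P = P, relation = relation),
            class = "condorcet_report")
}

#' @export
print.condorcet_report <- function(x, ...) {
  cat(sprintf("Condorcet relation at p = %g, n = %d: P = %.6f (%s)\n",
              x$p, x$n, x$P, x$relation))
  invisible(x)
}
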