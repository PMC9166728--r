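make_pairs <- function(d1, d2, c1, c2, truth) {
  n <- length(d1)
  tibble::tibble(
    expert_id = sprintf("e%02d", seq_len(n)), case_id = sprintf("c%02d", seq_len(n)),
    decision_1 = d1, decision_2 = d2, confidence_1 = c1, confidence_2 = c2,
    truth = truth, changed = d1 != d2
  )
}

test_that("the rule adopts the more confident of two conflicting decisions", {
  pairs <- make_pairs(d1 = c(1L, 0L), d2 = c(0L, 1L),
                      c1 = c(4L, 2L), c2 = c(2L, 5L), truth = c(1L, 1L))
  out <- mcs_choice(pairs, seed = 1)
  expect_equal(out$chosen, c(1L, 1L))
  expect_true(all(out$rule_correct))
  expect_false(any(out$tie))
})

test_that("consistent pairs keep their shared decision regardless of confidence", {
  pairs <- make_pairs(d1 = 1L, d2 = 1L, c1 = 3L, c2 = 5L, truth = 0L)
  out <- mcs_choice(pairs, seed = 1)
  expect_equal(out$chosen, 1L)
  expect_false(out$rule_correct)
  expect_false(out$tie)
})

test_that("confidence ties on conflicts follow the tie policy and are flagged", {
  pairs <- make_pairs(d1 = 1L, d2 = 0L, c1 = 3L, c2 = 3L, truth = 1L)
  first <- mcs_choice(pairs, tie_policy = "first")
  expect_equal(first$chosen, 1L)
  expect_true(first$tie)
  second <- mcs_choice(pairs, tie_policy = "second")
  expect_equal(second$chosen, 0L)
  expect_identical(mcs_choice(pairs, tie_policy = "random", seed = 5),
                   mcs_choice(pairs, tie_policy = "random", seed = 5))
})

test_that("random tie-breaking is unbiased", {
  n <- 4000
  pairs <- tibble::tibble(
    expert_id = "e1", case_id = sprintf("c%04d", seq_len(n)),
    decision_1 = 1L, decision_2 = 0L, confidence_1 = 2L, confidence_2 = 2L,
    truth = 1L, changed = TRUE
  )
  out <- mcs_choice(pairs, tie_policy = "random", seed = 31)
  expect_lt(abs(mean(out$chosen) - 0.5), 3 * sqrt(0.25 / n))
  expect_true(all(out$tie))
})

test_that("improvements against baselines have the stated arithmetic", {
  # rule resolves every conflict correctly
  pairs <- make_pairs(d1 = c(1L, 0L), d2 = c(0L, 1L),
                      c1 = c(5L, 1L), c2 = c(1L, 5L), truth = c(1L, 1L))
  ev <- evaluate_rule(pairs, baseline = "random", stratify_by_kindness = FALSE)
  expect_equal(ev$per_case$improvement, c(0.5, 0.5))
  expect_equal(ev$n_conflicts, 2L)

  # rule always sides with the first decision -> zero improvement vs first
  pairs2 <- make_pairs(d1 = c(1L, 0L), d2 = c(0L, 1L),
                       c1 = c(5L, 4L), c2 = c(1L, 2L), truth = c(1L, 0L))
  ev2 <- evaluate_rule(pairs2, baseline = "first", stratify_by_kindness = FALSE)
  expect_equal(ev2$per_case$improvement, c(0, 0))
})

test_that("consistent pairs contribute nothing to any contrast", {
  conflict <- make_pairs(d1 = 1L, d2 = 0L, c1 = 5L, c2 = 1L, truth = 1L)
  consistent <- make_pairs(d1 = 0L, d2 = 0L, c1 = 5L, c2 = 5L, truth = 1L)
  consistent$expert_id <- "e99"
  consistent$case_id <- "c99"
  with_consistent <- dplyr::bind_rows(conflict, consistent)
  for (b in c("first", "second", "random")) {
    ev_a <- evaluate_rule(conflict, baseline = b, stratify_by_kindness = FALSE)
    ev_b <- evaluate_rule(with_consistent, baseline = b,
                          stratify_by_kindness = FALSE)
    expect_equal(ev_a$per_case, ev_b$per_case, label = b)
  }
})

test_that("rule-vs-random improvement equals the per-expert tabulation", {
  study <- tiny_study(n_experts = 8, n_cases = 80, seed = 32,
                      scale = confidence_scale(5))
  pairs <- mcs_choice(pair_sessions(study$ratings), seed = 32)
  ev <- evaluate_rule(pairs, baseline = "random",
                      stratify_by_kindness = FALSE)
  conf <- pairs[pairs$changed, ]
  for (eid in unique(ev$per_expert$expert_id)) {
    sub <- conf[conf$expert_id == eid, ]
    expect_equal(
      ev$per_expert$improvement[ev$per_expert$expert_id == eid],
      mean(sub$rule_correct) - 0.5)
    expect_equal(ev$per_expert$weight[ev$per_expert$expert_id == eid],
                 nrow(sub))
  }
})

test_that("stratified evaluation excludes intermediate cases but 'all' keeps them", {
  study <- tiny_study(n_experts = 20, n_cases = 100, seed = 33,
                      scale = confidence_scale(5))
  pairs <- pair_sessions(study$ratings)
  cs <- summarize_cases(study$ratings, pairs)
  ev <- evaluate_rule(pairs, cs, baseline = "first", seed = 33)
  inter <- cs$case_id[cs$kindness == "intermediate"]
  strat <- ev$per_case[ev$per_case$stratum != "all", ]
  expect_false(any(strat$case_id %in% inter))
  changed_cases <- unique(pairs$case_id[pairs$changed])
  expect_setequal(ev$per_case$case_id[ev$per_case$stratum == "all"],
                  changed_cases)
  expect_error(evaluate_rule(pairs, cs[0, ], baseline = "first"),
               "kindness|case")
})

test_that("under SCM synthesis the rule helps kind cases and hurts wicked ones", {
  study <- simulate_reader_study(n_experts = 400, n_cases = 60,
                                 kind_fraction = 0.5, n_cues = 9,
                                 scale = confidence_scale(5), seed = 34)
  pairs <- pair_sessions(study$ratings)
  cs <- summarize_cases(study$ratings, pairs)
  ev <- evaluate_rule(pairs, cs, baseline = "first", seed = 34)
  agg <- function(s) {
    sub <- ev$per_case[ev$per_case$stratum == s, ]
    sum(sub$improvement * sub$weight) / sum(sub$weight)
  }
  expect_gt(agg("kind"), 0)
  expect_lt(agg("wicked"), 0)
})

test_that("a kind environment gives a positive pooled rule-vs-random effect", {
  study <- simulate_reader_study(n_experts = 30, n_cases = 150,
                                 kind_fraction = 0.8,
                                 scale = confidence_scale(5), seed = 35)
  pairs <- pair_sessions(study$ratings)
  ev <- evaluate_rule(pairs, baseline = "random", stratify_by_kindness = FALSE,
                      seed = 35)
  tt <- bayes_one_sample_ttest(
    ev$per_expert$improvement[ev$per_expert$stratum == "all"])
  expect_gt(tt$delta_median, 0)
})

test_that("weighted box statistics match the expanded-vector quantiles", {
  expect_equal(weighted_box_stats(c(1, 3), c(1, 1))$median, 2)
  expect_equal(weighted_box_stats(c(0, 1), c(3, 1))$median, 0)
  one <- weighted_box_stats(5, 7)
  expect_equal(c(one$q1, one$median, one$q3), c(5, 5, 5))
  expect_equal(one$n_obs, 7)
  expect_error(weighted_box_stats(numeric(0)), "Empty")
  expect_error(weighted_box_stats(1:2, c(1, 0.5)), "positive integers")

  set.seed(36)
  for (rep in 1:20) {
    v <- rnorm(sample(2:12, 1))
    w <- sample(1:5, length(v), replace = TRUE)
    got <- weighted_box_stats(v, w)
    want <- unname(quantile(rep(v, w), c(0.25, 0.5, 0.75), type = 7))
    expect_equal(c(got$q1, got$median, got$q3), want, tolerance = 1e-12)
  }
})
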