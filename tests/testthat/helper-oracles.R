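# Exhaustive enumeration of all 2^n cue outcomes: independent oracle for the
# binomial-tail accuracy. Feasible for n <= 11.
enum_prob_correct <- function(p, n) {
  m <- (n + 1) / 2
  outcomes <- expand.grid(rep(list(c(0L, 1L)), n))
  pr <- apply(outcomes, 1, function(x) prod(ifelse(x == 1L, p, 1 - p)))
  sum(pr[rowSums(outcomes) >= m])
}

# Small two-session study reused across test files.
tiny_study <- function(n_experts = 6, n_cases = 40, seed = 11, ...) {
  simulate_reader_study(n_experts = n_experts, n_cases = n_cases,
                        seed = seed, ...)
}
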