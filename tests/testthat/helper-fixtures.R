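# Shared fixtures and independent oracles for the test suite.

tiny_meta <- function(ids, mch = rep(FALSE, length(ids)),
                      gbd = rep("Group A", length(ids))) {
  tibble::tibble(condition_id = ids,
                 name = paste("Condition", ids),
                 gbd_level2 = gbd,
                 mch_flag = mch)
}

# score_matrix whose condition means are exactly `means` (given as sums/28
# is awkward; instead each condition column is a constant = its mean, with
# one expert): for mean patterns needing fractional values use sum_column().
const_matrix <- function(means, n_experts = 1) {
  m <- matrix(rep(means, each = n_experts), nrow = n_experts)
  score_matrix(m,
               expert_ids = sprintf("E%02d", seq_len(n_experts)),
               condition_ids = sprintf("C%02d", seq_along(means)))
}

# one 28-expert score column with a prescribed total sum (28..112):
# deterministic greedy fill over scores {1,4} plus one remainder expert.
sum_column <- function(total, n_experts = 28L) {
  stopifnot(total >= n_experts, total <= 4 * n_experts)
  extra <- as.integer(total - n_experts)
  scores <- rep(1L, n_experts)
  n4 <- extra %/% 3L
  scores[seq_len(n4)] <- 4L
  r <- extra %% 3L
  if (r > 0) scores[n4 + 1L] <- 1L + r
  scores
}

# Kendall tau-b by explicit pairwise concordance/discordance counting.
kendall_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[i] - x[j])
      dy <- sign(y[i] - y[j])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - count_tie_pairs(x)) * (n0 - count_tie_pairs(y)))
}

count_tie_pairs <- function(v) {
  t <- table(v)
  sum(t * (t - 1) / 2)
}

# random small league table for oracle checks
random_league <- function(n, seed) {
  withr::with_seed(seed, {
    w <- tibble::tibble(
      intervention_id = sprintf("I%02d", seq_len(n)),
      name = sprintf("Intervention %02d", seq_len(n)),
      cer = round(stats::rlnorm(n, log(50), 1), 1),
      equity_weight = round(stats::runif(n, 1, 2), 2)
    )
    build_league(w)
  })
}
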