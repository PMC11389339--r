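summaries_from_means <- function(means) {
  tibble::tibble(condition_id = sprintf("C%02d", seq_along(means)),
                 mean_score = means)
}

test_that("categorize splits sorted conditions into near-equal tertiles", {
  cat3 <- categorize(summaries_from_means(c(4, 3, 2)))
  expect_identical(cat3$category, c("high", "medium", "low"))

  cat9 <- categorize(summaries_from_means(c(3.9, 3.1, 2.8, 2.2, 1.9, 1.5, 3.5, 2.5, 1.2)))
  expect_identical(as.vector(table(cat9$category)[c("high", "medium", "low")]),
                   c(3L, 3L, 3L))
  # blocks are contiguous in the descending sort
  ord <- order(-cat9$mean_score)
  expect_identical(rle(cat9$category[ord])$values, c("high", "medium", "low"))

  expect_error(categorize(summaries_from_means(c(3, 2))),
               class = "equileague_domain_error")
})

test_that("tied means never straddle a category boundary", {
  # frozen from the tie-respecting enumeration: valid boundaries for
  # [3,3,3,2,1,1] are {0,3,4,6}; sizes (3,1,2) uniquely minimise the total
  # deviation from an equal 2/2/2 split
  res <- categorize(summaries_from_means(c(3, 3, 3, 2, 1, 1)))
  expect_identical(res$category, c("high", "high", "high", "medium", "low", "low"))

  for (seed in 1:25) {
    means <- withr::with_seed(seed, sample(seq(1, 4, by = 0.5),
                                           sample(5:20, 1), replace = TRUE))
    res <- categorize(summaries_from_means(means))
    for (v in unique(means)) {
      expect_length(unique(res$category[means == v]), 1)
    }
    # ordering constraint: every high mean >= every medium mean >= every low
    if (any(res$category == "high") && any(res$category == "medium")) {
      expect_gte(min(means[res$category == "high"]),
                 max(means[res$category == "medium"]))
    }
    if (any(res$category == "medium") && any(res$category == "low")) {
      expect_gte(min(means[res$category == "medium"]),
                 max(means[res$category == "low"]))
    }
    # invariant to input order
    perm <- withr::with_seed(seed + 100, sample(length(means)))
    res_perm <- categorize(summaries_from_means(means)[perm, ])
    expect_identical(res_perm$category, res$category[perm])
  }
})

test_that("explicit score cutpoints override the tertile split", {
  res <- categorize(summaries_from_means(c(3.6, 2.4, 1.3, 2.9)),
                    cutpoints = c(3, 2))
  expect_identical(res$category, c("high", "medium", "low", "medium"))
  expect_error(categorize(summaries_from_means(c(3, 2, 1)), cutpoints = c(2, 3)),
               class = "equileague_config_error")
})

test_that("MCH conditions in medium/low are lifted to the high-category minimum", {
  # high-category minimum engineered to the study's realized value 2.25:
  # nine 28-expert columns with distinct sums; the high tertile holds sums
  # 106, 87, 63 (means 3.786, 3.107, 2.25)
  sums <- c(106L, 87L, 63L, 56L, 50L, 45L, 42L, 36L, 31L)
  m <- score_matrix(vapply(sums, sum_column, integer(28)),
                    expert_ids = sprintf("E%02d", 1:28),
                    condition_ids = sprintf("C%02d", 1:9))
  s <- mean_scores(m)
  cats <- categorize(s[, c("condition_id", "mean_score")])
  expect_equal(min(s$mean_score[cats$category == "high"]), 2.25)

  meta <- tiny_meta(s$condition_id,
                    mch = c(FALSE, TRUE, FALSE, FALSE, TRUE,
                            FALSE, FALSE, FALSE, TRUE))
  lifted <- mch_reassign(cats, meta)
  expect_equal(lifted$post_mch_score[5], 2.25)          # MCH, medium -> lifted
  expect_equal(lifted$post_mch_score[9], 2.25)          # MCH, low -> lifted
  expect_equal(lifted$post_mch_score[2], lifted$mean_score[2])  # MCH already high
  expect_equal(lifted$post_mch_score[8], lifted$mean_score[8])  # non-MCH low
  expect_true(all(lifted$post_mch_score >= lifted$mean_score))
  expect_true(all(lifted$post_mch_score[meta$mch_flag] >= 2.25))
})

test_that("standardization maps the score range onto [1, 2] affinely", {
  expect_equal(standardize_weights(c(1.11, 3.79)), c(1, 2))
  expect_equal(standardize_weights(c(1.11, 2.45, 3.79))[2], 1.5)

  w <- standardize_weights(c(2.8, 1.4, 3.3, 2.1))
  expect_identical(order(w), order(c(2.8, 1.4, 3.3, 2.1)))
  expect_equal(min(w), 1)
  expect_equal(max(w), 2)

  # idempotence: standardizing already-standardized weights returns them
  expect_equal(standardize_weights(w), w)

  expect_warning(w0 <- standardize_weights(c(3, 3, 3)),
                 class = "equileague_degenerate_warning")
  expect_equal(w0, c(1, 1, 1))
})

test_that("full equity table composes the stages in order", {
  # noiseless panel, integer latent means, no MCH: weights are exactly the
  # min-max standardized latent means
  lat <- c(1, 3, 2, 4, 2, 3, 1, 4)
  cfg <- synth_config(n_experts = 6, n_conditions = 8, expert_noise_sd = 0,
                      mch_fraction = 0, seed = 11)
  panel <- gen_panel(cfg, latent_means = lat)
  eq <- build_equity_table(panel$scores, panel$meta)
  expect_equal(eq$equity_weight, 1 + (lat - min(lat)) / (max(lat) - min(lat)))
  expect_equal(eq$raw_mean, lat, ignore_attr = TRUE)

  # MCH flag on the lowest-mean condition: its weight equals the weight of
  # the high-category minimum (hand-traced on the 9-condition fixture)
  sums <- c(106L, 87L, 63L, 56L, 50L, 45L, 42L, 36L, 31L)
  m <- score_matrix(vapply(sums, sum_column, integer(28)),
                    expert_ids = sprintf("E%02d", 1:28),
                    condition_ids = sprintf("C%02d", 1:9))
  meta <- tiny_meta(colnames(m), mch = c(rep(FALSE, 8), TRUE))
  eq2 <- build_equity_table(m, meta)
  expect_equal(eq2$equity_weight[9], eq2$equity_weight[3])
  expect_equal(eq2$post_mch_score[9], 2.25)

  # degenerate panel: every expert scores every condition 3
  m3 <- score_matrix(matrix(3L, 4, 5), expert_ids = sprintf("E%d", 1:4),
                     condition_ids = sprintf("C%d", 1:5))
  expect_warning(eq3 <- build_equity_table(m3, tiny_meta(colnames(m3))),
                 class = "equileague_degenerate_warning")
  expect_equal(eq3$equity_weight, rep(1, 5))
})

test_that("equity weights increase strictly with raw means for non-MCH conditions", {
  panel <- gen_panel(synth_config(n_experts = 10, n_conditions = 40,
                                  mch_fraction = 0.3, seed = 7))
  eq <- build_equity_table(panel$scores, panel$meta)
  non_mch <- eq[!eq$mch_flag, ]
  ord <- order(non_mch$raw_mean)
  expect_true(all(diff(non_mch$equity_weight[ord]) >= 0))
  distinct <- diff(non_mch$raw_mean[ord]) > 0
  expect_true(all(diff(non_mch$equity_weight[ord])[distinct] > 0))
})
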