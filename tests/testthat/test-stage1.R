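test_that("normalized rank maps top to 1, bottom to 0, midpoint to 0.5", {
  expect_equal(normalized_rank(1, 5), 1.0)
  expect_equal(normalized_rank(5, 5), 0.0)
  expect_equal(normalized_rank(3, 5), 0.5)
  expect_equal(normalized_rank(1, 1), 1.0) # singleton list: sole item is top
  expect_error(normalized_rank(6, 5), "out of range")
})

test_that("allocation fraction counts only experts who placed the variable", {
  resp <- data.frame(
    expert_id = sprintf("E%02d", 1:10), variable = "v",
    category = c(rep("RISK_FACTOR", 9), "JUDGEMENT_FACTOR"),
    position = 1, list_length = 1, stringsAsFactors = FALSE)
  expect_equal(allocation_fraction(resp, "v", "RISK_FACTOR"), 0.9)
  resp$category <- "RISK_FACTOR"
  expect_equal(allocation_fraction(resp, "v", "RISK_FACTOR"), 1.0)
  expect_error(allocation_fraction(resp, "unseen", "RISK_FACTOR"), "no expert")
})

test_that("the 80% allocation rule is strictly greater-than", {
  resp <- do.call(rbind, lapply(1:10, function(i)
    data.frame(expert_id = sprintf("E%02d", i), variable = "v",
               category = if (i <= 8) "RISK_FACTOR" else "JUDGEMENT_FACTOR",
               position = 1, list_length = 1, stringsAsFactors = FALSE)))
  out <- aggregate_stage1(resp)
  expect_equal(out$results$fraction, 0.8)
  expect_false(out$results$included) # exactly 80% is not "more than 80%"
  # push one expert over: 9/10 > 0.8 -> included
  resp$category[9] <- "RISK_FACTOR"
  out2 <- aggregate_stage1(resp)
  expect_true(out2$results$included)
})

test_that("unanimous panels score the common rank with zero penalty", {
  out <- aggregate_stage1(unanimous_stage1())
  res <- out$results[order(out$results$variable), ]
  expect_true(all(res$fraction == 1))
  expect_true(all(res$ipr80 == 0))
  expect_equal(res$adjusted_score, normalized_rank(1:3, 3))
  expect_equal(out$selected, c("v1", "v2", "v3"))
})

test_that("adjusted score equals median minus lambda * IPR80 of ranks", {
  # ranks {0.2, 0.5, 0.8} on a 6-long list (positions 5, 3.5 -> use 11-long)
  # construct positions giving normalized ranks 0.2, 0.5, 0.8 on length 6
  resp <- data.frame(
    expert_id = c("E01", "E02", "E03"), variable = "v",
    category = "RISK_FACTOR", position = c(5L, 3L, 2L), list_length = 6L,
    stringsAsFactors = FALSE)
  nr <- normalized_rank(c(5, 3, 2), 6)
  expect_equal(nr, c(0.2, 0.6, 0.8))
  out <- aggregate_stage1(resp, lambda_penalty = 0.5)
  expect_equal(out$results$adjusted_score,
               max(0, stats::median(nr) - 0.5 * oracle_ipr80(nr)))
})

test_that("aggregation is invariant to expert and row order", {
  set.seed(3)
  truth <- make_ground_truth(3, 2, 2, seed = 5)
  resp <- simulate_stage1(truth, panel_config(n_experts = 6, seed = 9,
                                              rank_noise_sd = 0.3,
                                              category_confusion = 0.1))
  a <- aggregate_stage1(resp)
  b <- aggregate_stage1(resp[sample(nrow(resp)), ])
  expect_equal(a$results[order(a$results$variable), ],
               b$results[order(b$results$variable), ],
               ignore_attr = TRUE)
  expect_equal(a$selected, b$selected)
})

test_that("adding a median-repeating expert never lowers adjusted scores", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    L <- 5L
    resp <- do.call(rbind, lapply(seq_len(n), function(i)
      data.frame(expert_id = sprintf("E%02d", i), variable = paste0("v", 1:L),
                 category = "RISK_FACTOR", position = sample(L),
                 list_length = L, stringsAsFactors = FALSE)))
    before <- aggregate_stage1(resp)$results
    for (v in before$variable) {
      ranks <- normalized_rank(
        resp$position[resp$variable == v], L)
      med <- stats::median(ranks)
      # a new expert echoing the median rank for every variable; use v1's
      # ordering scaffold by direct rank injection per variable is not a
      # valid placement list, so test the scalar property directly instead
      expect_gte(max(0, stats::median(c(ranks, med)) -
                       0.5 * ipr80(c(ranks, med))),
                 max(0, med - 0.5 * ipr80(ranks)) - 1e-12)
    }
  }
})

test_that("alias mapping rewrites, merges and recompacts", {
  resp <- data.frame(
    expert_id = "E01",
    variable = c("low mood", "depression", "bmi", "smoking", "age"),
    category = c(rep("RISK_FACTOR", 5)),
    position = c(2L, 4L, 1L, 3L, 5L), list_length = 5L,
    stringsAsFactors = FALSE)
  expect_warning(
    out <- apply_alias_map(resp, c("low mood" = "depression")),
    "merged duplicate")
  expect_false("low mood" %in% out$variable)
  dep <- out[out$variable == "depression", ]
  expect_equal(dep$position, 2L)          # the better rank survives
  expect_equal(unique(out$list_length), 4L)
  expect_equal(sort(out$position), 1:4)   # recompacted
  # identity map leaves responses untouched
  expect_equal(apply_alias_map(resp, c()), resp)
  expect_error(apply_alias_map(resp, c(a = "b", b = "c")), "chains")
})

test_that("conflicting duplicate placements are rejected as malformed", {
  resp <- rbind(unanimous_stage1(2),
                data.frame(expert_id = "E01", variable = "v1",
                           category = "SIGN_SYMPTOM", position = 1,
                           list_length = 1, stringsAsFactors = FALSE))
  expect_error(aggregate_stage1(resp), "more than once")
})

test_that("the cap truncates by adjusted score with documented tie-breaks", {
  resp <- unanimous_stage1(4)
  out <- aggregate_stage1(resp, cap = 2L)
  expect_equal(out$selected, c("v1", "v2"))
  expect_equal(sum(out$results$included), 2L)
})
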