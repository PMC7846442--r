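test_that("ground truth generation is deterministic and well-formed", {
  t1 <- make_ground_truth(3, 2, 3, edge_density = 0.5, seed = 4)
  t2 <- make_ground_truth(3, 2, 3, edge_density = 0.5, seed = 4)
  expect_equal(t1$network$edges, t2$network$edges)
  expect_equal(t1$importances, t2$importances)
  for (nm in names(t1$network$cpts))
    expect_equal(t1$network$cpts[[nm]]$prob, t2$network$cpts[[nm]]$prob)
  # constructive invariants: skeleton-conformant DAG, normalized CPTs
  expect_true(check_dag(t1$network$edges, t1$network$variables))
  for (cpt in t1$network$cpts)
    expect_true(all(abs(colSums(cpt$prob) - 1) < 1e-9))
  # density 1 gives the complete bipartite layering
  tc <- make_ground_truth(2, 2, 2, edge_density = 1, seed = 1)
  expect_equal(nrow(tc$network$edges), 2 * 2 + 2 * 2)
})

test_that("noise-free experts reproduce categories and importance order", {
  truth <- make_ground_truth(3, 2, 3, seed = 6)
  resp <- simulate_stage1(truth, panel_config(n_experts = 5, seed = 3))
  vars <- truth$network$variables
  for (i in seq_len(nrow(resp))) {
    expect_equal(resp$category[i], vars[[resp$variable[i]]]$category)
  }
  # within each expert and category, order follows true importance
  one <- resp[resp$expert_id == "E01" & resp$category == "RISK_FACTOR", ]
  one <- one[order(one$position), ]
  expect_equal(one$variable,
               one$variable[order(-truth$importances[one$variable])])
  # total confusion: nobody places correctly
  resp_bad <- simulate_stage1(truth, panel_config(n_experts = 5, seed = 3,
                                                  category_confusion = 1))
  for (i in seq_len(nrow(resp_bad)))
    expect_false(resp_bad$category[i] == vars[[resp_bad$variable[i]]]$category)
})

test_that("category confusion hits at the configured binomial rate", {
  truth <- make_ground_truth(4, 3, 4, seed = 10)
  vars <- truth$network$variables
  miss <- 0L; total <- 0L
  for (seed in 1:12) {
    resp <- simulate_stage1(truth, panel_config(n_experts = 10, seed = seed,
                                                category_confusion = 0.1))
    wrong <- vapply(seq_len(nrow(resp)), function(i)
      resp$category[i] != vars[[resp$variable[i]]]$category, logical(1))
    miss <- miss + sum(wrong); total <- total + length(wrong)
  }
  rate <- miss / total
  se <- sqrt(0.1 * 0.9 / total)
  expect_lt(abs(rate - 0.1), 4 * se)
})

test_that("zero-noise grids equal true strengths and recover the edge set", {
  truth <- make_ground_truth(3, 2, 3, edge_density = 0.5, seed = 14)
  resp <- simulate_stage2(truth, panel_config(n_experts = 6, seed = 2))
  key <- paste(resp$source, resp$target)
  tkey <- paste(truth$strengths$source, truth$strengths$target)
  expect_equal(resp$score, truth$strengths$strength[match(key, tkey)])
  dag <- build_dag(aggregate_grid(resp), truth$network$variables)
  expect_equal(structure_recovery(dag$edges, truth$network$edges)$f1, 1)
})

test_that("moderate stage-2 noise still recovers most of the structure", {
  truth <- make_ground_truth(4, 3, 4, edge_density = 0.5, seed = 20)
  resp <- simulate_stage2(truth, panel_config(n_experts = 15, seed = 5,
                                              strength_noise_sd = 0.7))
  dag <- build_dag(suppressWarnings(aggregate_grid(resp)),
                   truth$network$variables)
  f1 <- structure_recovery(dag$edges, truth$network$edges)$f1
  expect_gt(f1, 0.8)
})

test_that("zero-noise slider answers equal the true CPT entries", {
  truth <- make_ground_truth(3, 2, 3, edge_density = 0.6, seed = 16)
  q <- generate_questions(truth$network$edges, truth$network$variables)
  ans <- simulate_stage3(truth, panel_config(n_experts = 3, seed = 4),
                         q$questions)
  for (i in seq_len(min(nrow(ans$sliders), 50))) {
    row <- ans$sliders[i, ]
    cpt <- truth$network$cpts[[row$child]]
    want <- elicitbn:::cpt_column(cpt, string_to_config(row$config))
    expect_equal(row$prob, unname(want[row$state]), tolerance = 1e-12)
  }
})

test_that("logit-noised slider answers still sum to one", {
  truth <- make_ground_truth(3, 2, 3, edge_density = 0.6, seed = 16)
  q <- generate_questions(truth$network$edges, truth$network$variables)
  ans <- simulate_stage3(truth, panel_config(n_experts = 5, seed = 4,
                                             prob_noise_sd = 0.5),
                         q$questions)
  sums <- tapply(ans$sliders$prob,
                 paste(ans$sliders$expert_id, ans$sliders$child,
                       ans$sliders$config), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("same seed reproduces every simulated response file", {
  truth <- make_ground_truth(3, 2, 3, seed = 22)
  cfg <- panel_config(n_experts = 5, seed = 17, prob_noise_sd = 0.2,
                      rank_noise_sd = 0.2, strength_noise_sd = 0.5,
                      category_confusion = 0.1, outlier_rate = 0.1)
  q <- generate_questions(truth$network$edges, truth$network$variables)
  expect_equal(simulate_stage1(truth, cfg), simulate_stage1(truth, cfg))
  expect_equal(simulate_stage2(truth, cfg), simulate_stage2(truth, cfg))
  expect_equal(simulate_stage3(truth, cfg, q$questions),
               simulate_stage3(truth, cfg, q$questions))
})

test_that("a biased minority barely moves the median aggregate", {
  truth <- make_ground_truth(3, 2, 3, edge_density = 0.6, seed = 33)
  q <- generate_questions(truth$network$edges, truth$network$variables)
  bias <- stats::setNames(c(2, 2, rep(0, 7)), sprintf("E%02d", 1:9))
  cfg <- panel_config(n_experts = 9, seed = 11, bias = bias)
  ans <- simulate_stage3(truth, cfg, q$questions)
  pooled <- pool_answers(q$questions, ans$sliders, ans$spreads,
                         truth$network$variables)
  cpts <- build_cpts(truth$network$edges, truth$network$variables, pooled)
  net <- eb_network(truth$network$variables, truth$network$edges, cpts)
  rec <- cpt_recovery(net, truth$network)
  expect_lt(rec$max_abs_error, 1e-6) # median ignores a 2-of-9 biased bloc
})
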