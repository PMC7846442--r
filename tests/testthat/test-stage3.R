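three_parent_child <- function() {
  vars <- list(
    eb_variable("j", "JUDGEMENT_FACTOR", "BINARY", c("absent", "present")))
  for (i in 1:3)
    vars[[length(vars) + 1L]] <-
      eb_variable(paste0("x", i), "RISK_FACTOR", "RANKED",
                  c("low", "mid", "high"))
  eb_varset(vars)
}

test_that("question counts follow the noisy-OR economy formula", {
  vars <- three_parent_child()
  edges <- data.frame(from = paste0("x", 1:3), to = "j")
  # noisy-OR: 1 baseline + sum(|states| - 1) = 1 + 3*2 = 7, plus 3 priors
  q_nor <- generate_questions(edges, vars, mode = "noisy_or")
  expect_equal(sum(q_nor$questions$child == "j"), 7L)
  # full factorial: 3^3 = 27 configurations
  q_full <- generate_questions(edges, vars, mode = "full")
  expect_equal(sum(q_full$questions$child == "j"), 27L)
  # a prior binary variable alone yields one question
  solo <- eb_varset(list(eb_variable("p", "RISK_FACTOR", "BINARY",
                                     c("no", "yes"))))
  expect_equal(generate_questions(NULL, solo)$count, 1L)
})

test_that("question counts match brute-force enumeration on random nets", {
  for (seed in 1:5) {
    truth <- make_ground_truth(3, 2, 3, edge_density = 0.6, seed = seed)
    vars <- truth$network$variables
    edges <- truth$network$edges
    q <- generate_questions(edges, vars, mode = "full")
    brute <- sum(vapply(names(vars), function(nm) {
      parents <- edges$from[edges$to == nm]
      if (length(parents) == 0L) 1 else
        prod(vapply(parents, function(p) length(vars[[p]]$states), numeric(1)))
    }, numeric(1)))
    expect_equal(q$count, brute)
    # noisy-OR mode never asks more than full-factorial
    expect_lte(generate_questions(edges, vars, "noisy_or")$count, q$count)
  }
})

test_that("outlier screening follows the leave-one-out IPR band", {
  # three identical answers: nothing rejected
  r <- remove_outliers(cbind(rep(0.4, 3)))
  expect_equal(length(r$rejected), 0L)
  # the aberrant 0.9 among a tight cluster is rejected
  m <- cbind(c(0.1, 0.12, 0.11, 0.9))
  rownames(m) <- paste0("E", 1:4)
  r <- remove_outliers(m, k = 1.5)
  expect_equal(r$rejected, "E4")
  # two answers only: both retained regardless of disagreement
  r <- remove_outliers(cbind(c(0, 1)))
  expect_equal(length(r$rejected), 0L)
})

test_that("outlier removal never exceeds half the panel", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    m <- cbind(stats::runif(n), stats::runif(n))
    r <- remove_outliers(m, k = 1.5)
    expect_lte(length(r$rejected), floor(n / 2))
  }
})

test_that("pooling takes per-state medians and renormalizes", {
  expect_equal(pool_discrete(rbind(c(0.7, 0.3))), c(0.7, 0.3))
  expect_equal(pool_discrete(rbind(c(0.6, 0.4), c(0.8, 0.2))), c(0.7, 0.3))
  expect_equal(pool_discrete(rbind(c(0.5, 0.5), c(0.5, 0.5), c(0.9, 0.1))),
               c(0.5, 0.5))
  expect_error(pool_discrete(matrix(numeric(), 0, 2)), "no retained")
})

test_that("noisy-OR probability follows the leak-survival product", {
  ps <- list(a = c("base", "hi"), b = c("base", "hi"))
  spec <- noisy_or_spec("c", c("a", "b"), ps, leak = 0.05,
                        p = list(a = c(hi = 0.6), b = c(hi = 0.5)))
  expect_equal(noisy_or_probability(spec, c(a = "base", b = "base")), 0.05)
  spec0 <- noisy_or_spec("c", c("a", "b"), ps, leak = 0,
                         p = list(a = c(hi = 0.6), b = c(hi = 0.5)))
  expect_equal(noisy_or_probability(spec0, c(a = "hi", b = "base")), 0.6)
  spec55 <- noisy_or_spec("c", c("a", "b"), ps, leak = 0,
                          p = list(a = c(hi = 0.5), b = c(hi = 0.5)))
  expect_equal(noisy_or_probability(spec55, c(a = "hi", b = "hi")), 0.75)
  expect_error(noisy_or_probability(spec, c(a = "nope", b = "base")),
               "unknown state")
})

test_that("noisy-OR probability is monotone in activations and leak", {
  ps <- list(a = c("base", "hi"))
  grid <- seq(0, 1, 0.1)
  vals <- vapply(grid, function(p)
    noisy_or_probability(noisy_or_spec("c", "a", ps, 0.1, list(a = c(hi = p))),
                         c(a = "hi")), numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
  leaks <- vapply(seq(0, 0.9, 0.1), function(l)
    noisy_or_probability(noisy_or_spec("c", "a", ps, l, list(a = c(hi = 0.3))),
                         c(a = "base")), numeric(1))
  expect_true(all(diff(leaks) >= -1e-12))
})

test_that("noisy-OR closed-form fit inverts single-active elicitations", {
  ps <- list(a = c("base", "hi"))
  elic <- data.frame(config = c("a=base", "a=hi"), q = c(0.05, 0.6),
                     stringsAsFactors = FALSE)
  fit <- fit_noisy_or(elic, "c", "a", ps)
  expect_equal(fit$spec$leak, 0.05)
  expect_equal(unname(fit$spec$p$a["hi"]), (0.6 - 0.05) / 0.95)
  expect_equal(noisy_or_probability(fit$spec, c(a = "hi")), 0.6)
  expect_lt(fit$max_residual, 1e-12)
  # non-monotone data clamps at zero with a warning
  elic_bad <- data.frame(config = c("a=base", "a=hi"), q = c(0.3, 0.1))
  expect_warning(fbad <- fit_noisy_or(elic_bad, "c", "a", ps), "clamped")
  expect_equal(unname(fbad$spec$p$a["hi"]), 0)
})

test_that("noise-free noisy-OR recovery is exact, noisy within tolerance", {
  ps <- list(a = c("b0", "b1", "b2"), b = c("b0", "b1"))
  true_spec <- noisy_or_spec("c", c("a", "b"), ps, 0.08,
                             list(a = c(b1 = 0.4, b2 = 0.7), b = c(b1 = 0.55)))
  grid <- cpt_config_grid(ps)
  cfgs <- apply(grid, 1L, function(r)
    config_to_string(stats::setNames(as.character(r), names(ps))))
  q_true <- vapply(seq_len(nrow(grid)), function(j)
    noisy_or_probability(true_spec,
                         stats::setNames(as.character(grid[j, ]), names(ps))),
    numeric(1))
  fit <- fit_noisy_or(data.frame(config = cfgs, q = q_true), "c",
                      c("a", "b"), ps)
  expect_lt(fit$max_residual, 1e-6)
  expect_equal(fit$spec$leak, 0.08, tolerance = 1e-5)
  expect_equal(fit$spec$p$a, true_spec$p$a, tolerance = 1e-4)
  # with N(0, 0.01^2) observation noise, parameters land within 0.05
  set.seed(99)
  q_noisy <- elicitbn:::clamp(q_true + stats::rnorm(length(q_true), 0, 0.01),
                              0, 1)
  fitn <- fit_noisy_or(data.frame(config = cfgs, q = q_noisy), "c",
                       c("a", "b"), ps)
  expect_lt(abs(fitn$spec$leak - 0.08), 0.05)
  expect_lt(max(abs(fitn$spec$p$a - true_spec$p$a)), 0.05)
  expect_lt(max(abs(fitn$spec$p$b - true_spec$p$b)), 0.05)
})

test_that("spread answers convert to sigma via the normal quantile", {
  spec <- fit_tnormal(0.5, 0.1645)
  expect_equal(spec$mu, 0.5)
  expect_equal(spec$sigma, 0.1, tolerance = 1e-3)
  # boundary mode is retained; truncation handles it downstream
  expect_equal(fit_tnormal(0, 0.2)$mu, 0)
  # vanishing spread concentrates the discretized mass
  tight <- fit_tnormal(0.5, 1e-9)
  expect_equal(discretize_tnormal(tight, 5), c(0, 0, 1, 0, 0))
})

test_that("truncated-normal discretization matches numerical integration", {
  flat <- discretize_tnormal(list(mu = 0.5, sigma = 10), 5)
  expect_true(all(abs(flat - 0.2) < 0.01))
  # numerical oracle: fine-grid Riemann integration of the truncated density
  grid_oracle <- function(mu, sigma, n_states) {
    x <- seq(0, 1, length.out = 200001)
    d <- stats::dnorm(x, mu, sigma)
    d <- d / (sum(d) * (x[2] - x[1]))
    idx <- pmin(floor(x * n_states) + 1L, n_states)
    tapply(d * (x[2] - x[1]), idx, sum)
  }
  for (mu in c(0.1, 0.5, 0.9)) for (sigma in c(0.05, 0.2, 1)) {
    got <- discretize_tnormal(list(mu = mu, sigma = sigma), 4)
    want <- as.numeric(grid_oracle(mu, sigma, 4))
    expect_equal(sum(got), 1, tolerance = 1e-9)
    expect_true(max(abs(got - want)) < 1e-4)
  }
  # sigma -> 0 puts all mass in the mode's interval
  expect_equal(discretize_tnormal(list(mu = 0.9, sigma = 0), 5),
               c(0, 0, 0, 0, 1))
})

test_that("raising mu shifts the discretized distribution upward", {
  for (sigma in c(0.05, 0.2, 0.5)) {
    mus <- seq(0.05, 0.95, 0.1)
    means <- vapply(mus, function(mu) {
      p <- discretize_tnormal(list(mu = mu, sigma = sigma), 5)
      sum(p * seq_len(5))
    }, numeric(1))
    expect_true(all(diff(means) >= -1e-12))
    # first-order stochastic dominance of successive mus
    for (i in seq_len(length(mus) - 1L)) {
      lo <- cumsum(discretize_tnormal(list(mu = mus[i], sigma = sigma), 5))
      hi <- cumsum(discretize_tnormal(list(mu = mus[i + 1], sigma = sigma), 5))
      expect_true(all(hi <= lo + 1e-12))
    }
  }
})

test_that("ranked child mean is the weighted parent midpoint", {
  expect_equal(ranked_child_mean(0.9, 1), 0.9)
  expect_equal(ranked_child_mean(c(0.1, 0.9), c(1, 1)), 0.5)
  expect_equal(ranked_child_mean(c(0.1, 0.5, 0.9), c(1, 2, 1)), 0.5)
  expect_error(ranked_child_mean(c(0.1, 0.9), c(0, 0)), "all-zero")
})

test_that("build_cpts reproduces priors, noisy-OR columns and ranked CPTs", {
  truth <- make_ground_truth(3, 2, 3, edge_density = 0.6, seed = 31)
  vars <- truth$network$variables
  edges <- truth$network$edges
  q <- generate_questions(edges, vars)
  ans <- simulate_stage3(truth, panel_config(n_experts = 4, seed = 8),
                         q$questions)
  pooled <- pool_answers(q$questions, ans$sliders, ans$spreads, vars)
  cpts <- build_cpts(edges, vars, pooled)
  net <- eb_network(vars, edges, cpts)
  rec <- cpt_recovery(net, truth$network)
  expect_lt(rec$max_abs_error, 1e-6)
  # every noisy-OR child column reproduces the closed form by construction
  for (nm in names(vars)) {
    cpt <- cpts[[nm]]
    expect_true(all(abs(colSums(cpt$prob) - 1) < 1e-9))
  }
  # a missing question is reported as a gap
  pooled_gap <- pooled
  pooled_gap$vectors <- pooled$vectors[-(1:2), ]
  expect_error(build_cpts(edges, vars, pooled_gap), "missing pooled")
})
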