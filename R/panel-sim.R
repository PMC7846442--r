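# Simulated expert panels. A known ground-truth network (with the latent
# quantities a real elicitation would tap: variable importances, 0-3
# relationship strengths, noisy-OR and ranked-node generators) is answered
# by a configurable panel of noisy experts, producing exactly the response
# tables the stage 1-3 aggregators consume. All randomness flows from one
# seed through named substreams, so any single response file is
# independently reproducible.

#' Panel configuration for simulated elicitations
#'
#' @param n_experts Panel size (>= 2; workshops typically field 7-15).
#' @param seed Master seed.
#' @param category_confusion Probability an expert mis-places a variable's
#'   category.
#' @param rank_noise_sd SD of Gaussian noise added to true importance before
#'   an expert sorts a category list.
#' @param strength_noise_sd SD of the (rounded, clipped) noise on 0-3 grid
#'   scores.
#' @param prob_noise_sd SD of logit-scale noise on probability answers.
#' @param outlier_rate Probability an answer is replaced by a random
#'   aberrant one.
#' @param bias Optional named numeric vector of per-expert systematic
#'   logit/rank-scale offsets (names = expert IDs `E01`, `E02`, ...).
#' @return List of class `eb_panel_config`.
#' @export
panel_config <- function(n_experts = 10L, seed = 1L, category_confusion = 0,
                         rank_noise_sd = 0, strength_noise_sd = 0,
                         prob_noise_sd = 0, outlier_rate = 0, bias = NULL) {
  stopifnot(n_experts >= 2L, category_confusion >= 0, category_confusion <= 1,
            outlier_rate >= 0, outlier_rate <= 1,
            rank_noise_sd >= 0, strength_noise_sd >= 0, prob_noise_sd >= 0)
  structure(list(n_experts = as.integer(n_experts), seed = as.integer(seed),
                 category_confusion = category_confusion,
                 rank_noise_sd = rank_noise_sd,
                 strength_noise_sd = strength_noise_sd,
                 prob_noise_sd = prob_noise_sd,
                 outlier_rate = outlier_rate, bias = bias),
            class = "eb_panel_config")
}

expert_ids <- function(config) sprintf("E%02d", seq_len(config$n_experts))

expert_bias <- function(config, id) {
  if (is.null(config$bias) || !(id %in% names(config$bias))) 0
  else config$bias[[id]]
}

# random point on the simplex (uniform Dirichlet)
runif_simplex <- function(n) {
  g <- stats::rexp(n)
  g / sum(g)
}

#' Generate a ground-truth network and its latent elicitation targets
#'
#' Builds a random layered DAG honouring the skeleton (risk factors ->
#' judgement factors -> signs and symptoms). Judgement factors are binary
#' with leaky noisy-OR CPTs; risk factors are a mix of binary, ranked and
#' labeled priors; signs alternate between binary (noisy-OR) and ranked
#' (truncated-normal weighted-mean construction). Relationship strengths:
#' present edges score 2-3, absent allowed pairs 0-1, so the stage 2 keep
#' rule (strength >= 2) recovers the edge set exactly. Variable importances
#' are uniform on \[0, 1\].
#'
#' @param n_risk,n_judgement,n_sign Layer sizes (>= 1).
#' @param edge_density Probability an allowed pair carries an edge, in
#'   (0, 1\]; every child is guaranteed at least one parent.
#' @param seed Seed.
#' @param n_ranked_states States for ranked variables (default 3).
#' @return List of class `eb_ground_truth`: `network`, `importances`,
#'   `strengths` (data frame `source`, `target`, `strength`), `specs`
#'   (per-child generators: noisy-OR specs, ranked weights and sigma).
#' @export
make_ground_truth <- function(n_risk, n_judgement, n_sign, edge_density = 0.5,
                              seed = 1L, n_ranked_states = 3L) {
  stopifnot(n_risk >= 1L, n_judgement >= 1L, n_sign >= 1L,
            edge_density > 0, edge_density <= 1)
  with_stream(seed, "truth", {
    risk_kinds <- rep(c("BINARY", "RANKED", "LABELED"), length.out = n_risk)
    vars <- list()
    for (i in seq_len(n_risk)) {
      k <- risk_kinds[i]
      states <- switch(k,
        BINARY = c("no", "yes"),
        RANKED = paste0("level", seq_len(n_ranked_states)),
        LABELED = c("typeA", "typeB", "typeC"))
      vars[[length(vars) + 1L]] <-
        eb_variable(sprintf("risk%02d", i), "RISK_FACTOR", k, states)
    }
    for (i in seq_len(n_judgement))
      vars[[length(vars) + 1L]] <-
        eb_variable(sprintf("judge%02d", i), "JUDGEMENT_FACTOR", "BINARY",
                    c("absent", "present"))
    sign_kinds <- rep(c("BINARY", "RANKED"), length.out = n_sign)
    for (i in seq_len(n_sign)) {
      k <- sign_kinds[i]
      states <- if (k == "BINARY") c("no", "yes") else
        paste0("grade", seq_len(n_ranked_states))
      vars[[length(vars) + 1L]] <-
        eb_variable(sprintf("sign%02d", i), "SIGN_SYMPTOM", k, states)
    }
    varset <- eb_varset(vars)
    risks <- sprintf("risk%02d", seq_len(n_risk))
    judges <- sprintf("judge%02d", seq_len(n_judgement))
    signs <- sprintf("sign%02d", seq_len(n_sign))

    # allowed pairs and their true strengths; edge iff strength >= 2
    pairs <- rbind(expand.grid(source = risks, target = judges,
                               stringsAsFactors = FALSE),
                   expand.grid(source = judges, target = signs,
                               stringsAsFactors = FALSE))
    present <- stats::runif(nrow(pairs)) < edge_density
    # guarantee each child at least one parent and each risk at least one
    # child, so no ground-truth variable is isolated (stage 2 would
    # legitimately discard it, and the recovery target is the full truth)
    for (tg in c(judges, signs)) {
      rows <- which(pairs$target == tg)
      if (!any(present[rows]))
        present[rows[sample.int(length(rows), 1L)]] <- TRUE
    }
    for (src in risks) {
      rows <- which(pairs$source == src)
      if (!any(present[rows]))
        present[rows[sample.int(length(rows), 1L)]] <- TRUE
    }
    strength <- ifelse(present, sample(2:3, nrow(pairs), replace = TRUE),
                       sample(0:1, nrow(pairs), replace = TRUE))
    strengths <- data.frame(pairs, strength = strength,
                            stringsAsFactors = FALSE)
    edges <- data.frame(from = pairs$source[present],
                        to = pairs$target[present], stringsAsFactors = FALSE)

    cpts <- list()
    specs <- list()
    for (nm in names(varset)) {
      v <- varset[[nm]]
      parents <- sort(edges$from[edges$to == nm])
      pstates <- stats::setNames(
        lapply(parents, function(p) varset[[p]]$states), parents)
      if (length(parents) == 0L) {
        if (v$kind == "RANKED") {
          spec <- structure(list(mu = stats::runif(1, 0.2, 0.8),
                                 sigma = stats::runif(1, 0.1, 0.3)),
                            class = "eb_tnormal")
          cpts[[nm]] <- eb_cpt(nm, v$states,
                               prob = cbind(discretize_tnormal(spec, length(v$states))))
          specs[[nm]] <- list(kind = "tnormal_prior", spec = spec)
        } else {
          p <- runif_simplex(length(v$states))
          p <- clamp(p, 0.05, 0.95); p <- p / sum(p)
          cpts[[nm]] <- eb_cpt(nm, v$states, prob = cbind(p))
          specs[[nm]] <- list(kind = "table")
        }
      } else if (v$kind == "BINARY") {
        leak <- stats::runif(1, 0.02, 0.15)
        p <- lapply(parents, function(pa) {
          nonbase <- pstates[[pa]][-1L]
          stats::setNames(sort(stats::runif(length(nonbase), 0.2, 0.9)), nonbase)
        })
        names(p) <- parents
        spec <- noisy_or_spec(nm, parents, pstates, leak, p)
        grid <- cpt_config_grid(pstates)
        p_true <- vapply(seq_len(nrow(grid)), function(j)
          noisy_or_probability(spec, stats::setNames(as.character(grid[j, ]),
                                                     parents)),
          numeric(1))
        cpts[[nm]] <- eb_cpt(nm, v$states, parents, pstates,
                             rbind(1 - p_true, p_true))
        specs[[nm]] <- list(kind = "noisy_or", spec = spec)
      } else { # RANKED child: weighted-mean truncated normal
        w <- stats::setNames(stats::runif(length(parents), 0.5, 2), parents)
        sigma <- stats::runif(1, 0.1, 0.25)
        grid <- cpt_config_grid(pstates)
        prob <- matrix(0, length(v$states), nrow(grid))
        mus <- numeric(nrow(grid))
        for (j in seq_len(nrow(grid))) {
          mids <- vapply(parents, function(pa) {
            k <- match(grid[j, pa], pstates[[pa]])
            state_midpoints(length(pstates[[pa]]))[k]
          }, numeric(1))
          mus[j] <- ranked_child_mean(mids, w)
          prob[, j] <- discretize_tnormal(
            structure(list(mu = mus[j], sigma = sigma), class = "eb_tnormal"),
            length(v$states))
        }
        cpts[[nm]] <- eb_cpt(nm, v$states, parents, pstates, prob)
        specs[[nm]] <- list(kind = "tnormal_child", weights = w, sigma = sigma,
                            mus = mus)
      }
    }
    network <- eb_network(varset, edges, cpts)
    importances <- stats::setNames(stats::runif(length(varset)), names(varset))
    structure(list(network = network, importances = importances,
                   strengths = strengths, specs = specs),
              class = "eb_ground_truth")
  })
}

#' Simulate Stage 1 placement-and-ranking responses
#'
#' Each expert places each variable in its true category with probability
#' `1 - category_confusion` (otherwise a random other category) and orders
#' each category list by true importance plus Gaussian rank noise (plus any
#' per-expert bias).
#'
#' @param truth An `eb_ground_truth`.
#' @param config An `eb_panel_config`.
#' @return Stage 1 response data frame (`expert_id`, `variable`, `category`,
#'   `position`, `list_length`).
#' @export
simulate_stage1 <- function(truth, config) {
  vars <- truth$network$variables
  out <- list()
  for (id in expert_ids(config)) {
    out[[id]] <- with_stream(config$seed, paste0("stage1/", id), {
      cat_choice <- vapply(names(vars), function(nm) {
        true_cat <- vars[[nm]]$category
        if (stats::runif(1) < config$category_confusion)
          sample(setdiff(EB_CATEGORIES, true_cat), 1L)
        else true_cat
      }, character(1))
      score <- truth$importances[names(vars)] +
        stats::rnorm(length(vars), expert_bias(config, id),
                     config$rank_noise_sd)
      rows <- list()
      for (cat in EB_CATEGORIES) {
        members <- names(vars)[cat_choice == cat]
        if (length(members) == 0L) next
        ord <- members[order(-score[members], members)]
        rows[[cat]] <- data.frame(
          expert_id = id, variable = ord, category = cat,
          position = seq_along(ord), list_length = length(ord),
          stringsAsFactors = FALSE)
      }
      do.call(rbind, rows)
    })
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate Stage 2 relationship-strength grids
#'
#' Each expert reports the true 0-3 strength of every allowed pair plus
#' integer-rounded Gaussian noise, clipped to 0..3.
#'
#' @inheritParams simulate_stage1
#' @return Stage 2 response data frame (`expert_id`, `source`, `target`,
#'   `score`).
#' @export
simulate_stage2 <- function(truth, config) {
  out <- list()
  for (id in expert_ids(config)) {
    out[[id]] <- with_stream(config$seed, paste0("stage2/", id), {
      noise <- round(stats::rnorm(nrow(truth$strengths),
                                  expert_bias(config, id),
                                  config$strength_noise_sd))
      data.frame(expert_id = id,
                 source = truth$strengths$source,
                 target = truth$strengths$target,
                 score = as.integer(clamp(truth$strengths$strength + noise, 0, 3)),
                 stringsAsFactors = FALSE)
    })
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

perturb_logit <- function(p, eps) {
  stats::plogis(stats::qlogis(clamp(p, 1e-6, 1 - 1e-6)) + eps)
}

#' Simulate Stage 3 probability answers
#'
#' Slider answers are the true conditional distributions perturbed on the
#' log scale and renormalized; mode-and-spread answers perturb the true
#' mode on the logit scale and the half-width on the log scale. With
#' probability `outlier_rate` an answer is replaced by a uniform-random
#' aberrant one. Returns, alongside the answers, the injected-outlier
#' labels so detection can be scored.
#'
#' @param truth An `eb_ground_truth`.
#' @param config An `eb_panel_config`.
#' @param questions Question data frame from [generate_questions()].
#' @return List: `sliders`, `spreads` (answer data frames) and `outliers`
#'   (data frame `expert_id`, `child`, `config` of injected aberrant
#'   answers).
#' @export
simulate_stage3 <- function(truth, config, questions) {
  vars <- truth$network$variables
  sliders <- list(); spreads <- list(); outliers <- list()
  z90 <- stats::qnorm(0.95)
  for (id in expert_ids(config)) {
    res <- with_stream(config$seed, paste0("stage3/", id), {
      sl <- list(); sp <- list(); ol <- list()
      for (i in seq_len(nrow(questions))) {
        ch <- questions$child[i]; cf <- questions$config[i]
        cfg <- string_to_config(cf)
        aberrant <- stats::runif(1) < config$outlier_rate
        if (questions$format[i] == "STATE_SLIDERS") {
          cpt <- truth$network$cpts[[ch]]
          p <- cpt_column(cpt, cfg)
          if (aberrant) {
            p <- runif_simplex(length(p))
          } else if (config$prob_noise_sd > 0 || expert_bias(config, id) != 0) {
            lp <- log(clamp(p, 1e-6, 1)) +
              stats::rnorm(length(p), expert_bias(config, id),
                           config$prob_noise_sd)
            p <- exp(lp) / sum(exp(lp))
          }
          sl[[length(sl) + 1L]] <- data.frame(
            expert_id = id, child = ch, config = cf,
            state = vars[[ch]]$states, prob = unname(p),
            stringsAsFactors = FALSE)
        } else {
          spec <- truth$specs[[ch]]
          if (spec$kind == "tnormal_prior") {
            mu <- spec$spec$mu; sigma <- spec$spec$sigma
          } else {
            grid <- cpt_config_grid(truth$network$cpts[[ch]]$parent_states)
            j <- cpt_config_index(truth$network$cpts[[ch]], cfg)
            mu <- spec$mus[j]; sigma <- spec$sigma
          }
          m <- mu; h <- z90 * sigma
          if (aberrant) {
            m <- stats::runif(1); h <- stats::runif(1, 0.01, 1)
          } else if (config$prob_noise_sd > 0 || expert_bias(config, id) != 0) {
            m <- perturb_logit(mu, stats::rnorm(1, expert_bias(config, id),
                                                config$prob_noise_sd))
            h <- clamp(h * exp(stats::rnorm(1, 0, config$prob_noise_sd)),
                       1e-4, 1)
          }
          sp[[length(sp) + 1L]] <- data.frame(
            expert_id = id, child = ch, config = cf, mode = m, halfwidth = h,
            stringsAsFactors = FALSE)
        }
        if (aberrant)
          ol[[length(ol) + 1L]] <- data.frame(
            expert_id = id, child = ch, config = cf, stringsAsFactors = FALSE)
      }
      list(sl = sl, sp = sp, ol = ol)
    })
    sliders <- c(sliders, res$sl)
    spreads <- c(spreads, res$sp)
    outliers <- c(outliers, res$ol)
  }
  bind0 <- function(l, proto) {
    out <- if (length(l)) do.call(rbind, l) else proto
    rownames(out) <- NULL
    out
  }
  list(
    sliders = bind0(sliders, data.frame(expert_id = character(),
                                        child = character(), config = character(),
                                        state = character(), prob = numeric())),
    spreads = bind0(spreads, data.frame(expert_id = character(),
                                        child = character(), config = character(),
                                        mode = numeric(), halfwidth = numeric())),
    outliers = bind0(outliers, data.frame(expert_id = character(),
                                          child = character(),
                                          config = character())))
}
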