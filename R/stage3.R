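# Stage 3: probability elicitation. Questions are generated from the
# stage-2 structure; per-expert answers are screened with an IPR-based
# outlier rule, pooled by per-state medians, and turned into CPTs via leaky
# generalized noisy-OR (binary children), full tables (labeled children) or
# truncated-normal ranked-node discretization (ordinal children).
#
# Answer files are tabular:
#   sliders:  expert_id, child, config, state, prob      (STATE_SLIDERS)
#   spreads:  expert_id, child, config, mode, halfwidth  (MODE_AND_SPREAD)
# `config` is the config_to_string() serialization; "" for prior variables.

#' Generate the Stage 3 question list and elicitation burden count
#'
#' One question per prior variable. For conditional children: ranked
#' children get one mode-and-spread question per parent configuration;
#' binary children get either the full factorial (`mode = "full"`) or the
#' noisy-OR economy set (`mode = "noisy_or"`: one baseline question plus one
#' question per parent per non-baseline parent state); labeled children are
#' always full-factorial. The count drives burden estimates — the factorial
#' explosion is what made real panels face hundreds of questions.
#'
#' @param edges Edge data frame (`from`, `to`) from [build_dag()].
#' @param variables An `eb_varset` restricted to the network's variables.
#' @param mode `"noisy_or"` (default) or `"full"`, or a named character
#'   vector giving a per-child mode.
#' @return List: `questions` (data frame `child`, `config`, `format`) and
#'   `count`.
#' @export
generate_questions <- function(edges, variables, mode = "noisy_or") {
  edges <- as_edge_df(edges)
  mode_for <- function(child) {
    m <- if (length(mode) > 1L || !is.null(names(mode)))
      mode[[child]] else mode
    match.arg(m, c("noisy_or", "full"))
  }
  qs <- list()
  for (nm in names(variables)) {
    v <- variables[[nm]]
    if (length(v$states) == 0L)
      stop("variable '", nm, "' has no states", call. = FALSE)
    parents <- sort(edges$from[edges$to == nm])
    fmt <- if (v$kind == "RANKED") "MODE_AND_SPREAD" else "STATE_SLIDERS"
    if (length(parents) == 0L) {
      qs[[length(qs) + 1L]] <- data.frame(child = nm, config = "",
                                          format = fmt, stringsAsFactors = FALSE)
      next
    }
    pstates <- lapply(parents, function(p) variables[[p]]$states)
    names(pstates) <- parents
    if (v$kind == "BINARY" && mode_for(nm) == "noisy_or") {
      # baseline (all parents at first state) + each single-parent-active
      base <- vapply(pstates, `[`, character(1), 1L)
      cfgs <- list(base)
      for (p in parents) for (s in pstates[[p]][-1L]) {
        cfg <- base
        cfg[p] <- s
        cfgs[[length(cfgs) + 1L]] <- cfg
      }
      strs <- vapply(cfgs, config_to_string, character(1))
    } else {
      grid <- cpt_config_grid(pstates)
      strs <- apply(grid, 1L, function(r)
        config_to_string(stats::setNames(as.character(r), names(pstates))))
    }
    qs[[length(qs) + 1L]] <- data.frame(child = nm, config = strs,
                                        format = fmt, stringsAsFactors = FALSE)
  }
  questions <- do.call(rbind, qs)
  rownames(questions) <- NULL
  list(questions = questions, count = nrow(questions))
}

# Rows of a scalar matrix (experts x elicited scalars) falling outside the
# leave-one-out band [median - k*IPR80, median + k*IPR80] of the remaining
# retained experts on any scalar. The band is leave-one-out so an aberrant
# answer cannot widen its own acceptance band, and screening is iterative
# (the worst offender is removed and the bands recomputed) so one aberrant
# answer cannot mask another. With fewer than 3 answers nothing is removed;
# identical panels reject nothing; never more than floor(n/2) answers are
# removed in total.
outlier_rows <- function(m, k) {
  n <- nrow(m)
  if (n < 3L) return(integer())
  cap <- floor(n / 2)
  removed <- integer()
  keep <- seq_len(n)
  # screening needs a reference set of >= 3 other answers, so peeling stops
  # once only 3 retained answers would remain to judge against
  while (length(removed) < cap && length(keep) >= 4L) {
    excess <- vapply(keep, function(i) {
      rest_rows <- setdiff(keep, i)
      max(vapply(seq_len(ncol(m)), function(j) {
        rest <- m[rest_rows, j]
        abs(m[i, j] - stats::median(rest)) - k * ipr80(rest)
      }, numeric(1)))
    }, numeric(1))
    if (max(excess) <= 1e-12) break
    worst <- keep[which.max(excess)]
    removed <- c(removed, worst)
    keep <- setdiff(keep, worst)
  }
  sort(removed)
}

#' Remove outlying answers for one question
#'
#' Each elicited scalar (a state's probability, or the mode and half-width)
#' is screened against the band `median ± k * IPR80` of the *other*
#' experts' answers (leave-one-out, so an aberrant answer cannot widen its
#' own acceptance band); the whole answer is rejected if any scalar falls
#' outside, and screening repeats (worst offender first) so aberrant
#' answers cannot mask each other. A unanimous panel rejects nothing; the
#' reference set must keep at least three answers, so panels smaller than
#' four are retained wholesale; at most `floor(n/2)` answers are ever
#' removed.
#'
#' @param answers Numeric matrix, one row per expert (rownames = expert
#'   IDs), one column per elicited scalar.
#' @param k Band width multiplier (default 1.5).
#' @return List: `retained` (matrix) and `rejected` (expert IDs).
#' @export
remove_outliers <- function(answers, k = 1.5) {
  m <- as.matrix(answers)
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  bad <- outlier_rows(m, k)
  list(retained = m[setdiff(seq_len(nrow(m)), bad), , drop = FALSE],
       rejected = rownames(m)[bad])
}

#' Pool retained slider answers into one distribution
#'
#' Per-state median across the retained experts, renormalized to sum to 1.
#'
#' @param answers Numeric matrix, rows = experts, columns = child states.
#' @return Probability vector over the child states.
#' @export
pool_discrete <- function(answers) {
  m <- as.matrix(answers)
  if (nrow(m) == 0L)
    stop("elicitation failure: no retained answers for question", call. = FALSE)
  med <- apply(m, 2L, stats::median)
  s <- sum(med)
  if (s <= 0) stop("pooled answer sums to zero", call. = FALSE)
  med / s
}

#' Leaky generalized noisy-OR specification
#'
#' The child (binary; its second listed state is the "present" state) is
#' caused independently by each parent in a non-baseline state, with
#' activation probability `p[parent][state]`, plus a background leak `leak`
#' active even when every parent sits at its baseline (first listed) state.
#'
#' @param child Child variable name.
#' @param parents Ordered parent names.
#' @param parent_states Named list of parent state vectors.
#' @param leak Leak probability in \[0, 1).
#' @param p Named list: parent -> named numeric vector of activation
#'   probabilities for each non-baseline state.
#' @return Object of class `eb_noisy_or`.
#' @export
noisy_or_spec <- function(child, parents, parent_states, leak, p) {
  stopifnot(leak >= 0, leak < 1)
  for (pa in parents) {
    nonbase <- parent_states[[pa]][-1L]
    if (!setequal(names(p[[pa]]), nonbase))
      stop("activation probabilities for '", pa,
           "' must cover exactly its non-baseline states", call. = FALSE)
    if (any(p[[pa]] < 0 | p[[pa]] > 1))
      stop("activation probability outside [0,1]", call. = FALSE)
  }
  structure(list(child = child, parents = parents,
                 parent_states = parent_states, leak = leak, p = p),
            class = "eb_noisy_or")
}

#' Noisy-OR probability of the child being present
#'
#' `P(present | config) = 1 - (1 - leak) * prod over active parents of
#' (1 - p[parent][state])`, where "active" means any non-baseline state.
#'
#' @param spec An `eb_noisy_or`.
#' @param config Named character vector covering all parents.
#' @return Probability in \[0, 1\].
#' @export
noisy_or_probability <- function(spec, config) {
  surv <- 1 - spec$leak
  for (pa in spec$parents) {
    s <- config[[pa]]
    if (is.null(s) || is.na(s))
      stop("configuration missing parent '", pa, "'", call. = FALSE)
    if (!(s %in% spec$parent_states[[pa]]))
      stop("unknown state '", s, "' for parent '", pa, "'", call. = FALSE)
    if (s != spec$parent_states[[pa]][1L]) surv <- surv * (1 - spec$p[[pa]][[s]])
  }
  1 - surv
}

#' Fit a leaky noisy-OR to pooled elicited probabilities
#'
#' `elicited` maps parent configurations to the pooled probability of the
#' child's present (second) state. The baseline configuration gives the leak
#' directly. When only single-parent-active configurations were elicited the
#' fit is exact: `p = (q - leak) / (1 - leak)`. With a fuller configuration
#' set, those closed-form values seed a bounded least-squares refinement
#' over all elicited configurations. Elicited values below the baseline
#' (non-monotone data) are clamped to activation 0 with a warning.
#'
#' @param elicited Data frame: `config` (serialized), `q` (pooled
#'   probability of the present state).
#' @param child Child name.
#' @param parents Ordered parent names.
#' @param parent_states Named list of parent state vectors.
#' @return List: `spec` (an `eb_noisy_or`), `residuals` (per-config fitted
#'   minus elicited) and `max_residual`.
#' @export
fit_noisy_or <- function(elicited, child, parents, parent_states) {
  cfgs <- lapply(elicited$config, string_to_config)
  base <- vapply(parent_states, `[`, character(1), 1L)
  names(base) <- parents
  is_base <- vapply(cfgs, function(cf) all(cf[parents] == base), logical(1))
  if (!any(is_base))
    stop("baseline configuration was not elicited for '", child, "'",
         call. = FALSE)
  leak <- elicited$q[which(is_base)[1L]]
  if (leak >= 1) stop("elicited baseline probability must be < 1", call. = FALSE)
  # closed-form from single-active configs where available
  p <- lapply(parents, function(pa)
    stats::setNames(rep(NA_real_, length(parent_states[[pa]]) - 1L),
                    parent_states[[pa]][-1L]))
  names(p) <- parents
  n_active <- vapply(cfgs, function(cf) sum(cf[parents] != base), integer(1))
  clamped <- FALSE
  for (i in which(n_active == 1L)) {
    pa <- parents[which(cfgs[[i]][parents] != base)]
    s <- cfgs[[i]][[pa]]
    val <- (elicited$q[i] - leak) / (1 - leak)
    if (val < 0) { clamped <- TRUE; val <- 0 }
    p[[pa]][s] <- min(val, 1)
  }
  if (clamped)
    warning("elicited value below baseline for '", child,
            "'; activation clamped at 0", call. = FALSE)
  # parameters never pinned by a single-active config start at 0.5
  for (pa in parents) p[[pa]][is.na(p[[pa]])] <- 0.5
  spec <- noisy_or_spec(child, parents, parent_states, leak, p)
  if (any(n_active > 1L)) {
    # refine over all elicited configs by bounded least squares
    flat <- unlist(p, use.names = FALSE)
    theta0 <- c(leak, flat)
    unpack <- function(theta) {
      l <- theta[1L]
      k <- 1L
      pp <- p
      for (pa in parents) for (s in names(pp[[pa]])) {
        k <- k + 1L
        pp[[pa]][s] <- theta[k]
      }
      noisy_or_spec(child, parents, parent_states, l, pp)
    }
    sse <- function(theta) {
      sp <- unpack(theta)
      sum(vapply(seq_along(cfgs), function(i)
        (noisy_or_probability(sp, cfgs[[i]]) - elicited$q[i])^2, numeric(1)))
    }
    opt <- stats::optim(theta0, sse, method = "L-BFGS-B",
                        lower = rep(0, length(theta0)),
                        upper = c(1 - 1e-9, rep(1, length(theta0) - 1L)))
    spec <- unpack(opt$par)
  }
  fitted <- vapply(cfgs, function(cf) noisy_or_probability(spec, cf), numeric(1))
  res <- fitted - elicited$q
  list(spec = spec, residuals = res, max_residual = max(abs(res)))
}

# Logistic-link fallback for binary children where the noisy-OR fit is poor:
# P(present) = plogis(intercept + sum of per-(parent, non-baseline state)
# coefficients), least squares on logit-transformed pooled values clamped to
# [0.01, 0.99]. Returns a function(config) -> probability.
fit_logistic_link <- function(elicited, parents, parent_states) {
  cfgs <- lapply(elicited$config, string_to_config)
  terms <- unlist(lapply(parents, function(pa)
    paste(pa, parent_states[[pa]][-1L], sep = "\r")), use.names = FALSE)
  X <- matrix(0, length(cfgs), length(terms),
              dimnames = list(NULL, terms))
  for (i in seq_along(cfgs)) for (pa in parents) {
    s <- cfgs[[i]][[pa]]
    if (s != parent_states[[pa]][1L]) X[i, paste(pa, s, sep = "\r")] <- 1
  }
  y <- stats::qlogis(clamp(elicited$q, 0.01, 0.99))
  fit <- stats::lm.fit(cbind(1, X), y)
  beta <- stats::setNames(fit$coefficients, c("(intercept)", terms))
  beta[is.na(beta)] <- 0
  function(config) {
    eta <- beta[["(intercept)"]]
    for (pa in parents) {
      s <- config[[pa]]
      if (s != parent_states[[pa]][1L])
        eta <- eta + beta[[paste(pa, s, sep = "\r")]]
    }
    stats::plogis(eta)
  }
}

#' Truncated-normal spec from an elicited mode and spread
#'
#' The expert's most-likely value becomes the (pre-truncation) mean; the
#' elicited half-width is read as the half-width of a central
#' `confidence` interval, so `sigma = h / z` with
#' `z = qnorm((1 + confidence)/2)` (1.645 at the default 90\%). The
#' distribution is doubly truncated to \[0, 1\].
#'
#' @param m Most likely value in \[0, 1\].
#' @param h Half-width of the variation interval, in (0, 1\].
#' @param confidence Central-interval mass the half-width represents
#'   (default 0.90).
#' @return List of class `eb_tnormal`: `mu`, `sigma` (`sigma = 0` flags a
#'   degenerate point mass).
#' @export
fit_tnormal <- function(m, h, confidence = 0.90) {
  stopifnot(m >= 0, m <= 1, h >= 0)
  z <- stats::qnorm((1 + confidence) / 2)
  structure(list(mu = m, sigma = h / z), class = "eb_tnormal")
}

#' Discretize a \[0,1\]-truncated normal over ranked states
#'
#' State `i` of the equal-width partition of \[0, 1\] receives the
#' truncated-normal mass of its sub-interval. A degenerate (sigma = 0) spec
#' puts all mass in the interval containing the mode.
#'
#' @param spec An `eb_tnormal` (fields `mu`, `sigma`).
#' @param n_states Number of ordered states (>= 2).
#' @return Probability vector of length `n_states` summing to 1.
#' @export
discretize_tnormal <- function(spec, n_states) {
  stopifnot(n_states >= 2L)
  breaks <- seq(0, 1, length.out = n_states + 1L)
  if (spec$sigma <= 1e-12) {
    i <- min(max(1L, findInterval(spec$mu, breaks, rightmost.closed = TRUE)),
             n_states)
    out <- numeric(n_states)
    out[i] <- 1
    return(out)
  }
  cdf <- stats::pnorm((breaks - spec$mu) / spec$sigma)
  mass <- diff(cdf)
  total <- cdf[n_states + 1L] - cdf[1L]
  if (total <= 0) { # numerically degenerate: all mass outside, fall back
    i <- if (spec$mu >= 1) n_states else 1L
    out <- numeric(n_states)
    out[i] <- 1
    return(out)
  }
  mass / total
}

#' Weighted mean of parent positions on the ranked scale
#'
#' The ranked-node construction: a child's truncated-normal mean for a
#' parent configuration is the weighted mean of the parents' state-interval
#' midpoints on \[0, 1\].
#'
#' @param values Parent state midpoints in \[0, 1\].
#' @param weights Non-negative weights, not all zero.
#' @return Number in \[0, 1\].
#' @export
ranked_child_mean <- function(values, weights) {
  stopifnot(length(values) == length(weights))
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (sum(weights) == 0) stop("all-zero weights", call. = FALSE)
  sum(weights * values) / sum(weights)
}

#' Screen and pool per-expert Stage 3 answers
#'
#' Applies [remove_outliers()] per question and pools the retained answers:
#' per-state medians (renormalized) for slider questions, medians of the
#' mode and half-width for spread questions.
#'
#' @param questions Question data frame from [generate_questions()].
#' @param sliders Data frame `expert_id`, `child`, `config`, `state`, `prob`.
#' @param spreads Data frame `expert_id`, `child`, `config`, `mode`,
#'   `halfwidth`.
#' @param variables An `eb_varset` (for state ordering).
#' @param k Outlier band multiplier (default 1.5).
#' @return List: `vectors` (data frame `child`, `config`, `state`, `prob`),
#'   `spreads` (data frame `child`, `config`, `mode`, `halfwidth`),
#'   `rejections` (data frame `child`, `config`, `expert_id`).
#' @export
pool_answers <- function(questions, sliders, spreads, variables, k = 1.5) {
  vec_out <- list(); spr_out <- list(); rej <- list()
  for (i in seq_len(nrow(questions))) {
    ch <- questions$child[i]; cf <- questions$config[i]
    if (questions$format[i] == "STATE_SLIDERS") {
      rows <- sliders[sliders$child == ch & sliders$config == cf, , drop = FALSE]
      if (nrow(rows) == 0L)
        stop("no answers for question ", ch, " [", cf, "]", call. = FALSE)
      states <- variables[[ch]]$states
      experts <- unique(rows$expert_id)
      m <- matrix(NA_real_, length(experts), length(states),
                  dimnames = list(experts, states))
      m[cbind(rows$expert_id, rows$state)] <- rows$prob
      if (anyNA(m)) stop("incomplete slider answer for ", ch, call. = FALSE)
      bad_sum <- abs(rowSums(m) - 1) > 1e-6
      if (any(bad_sum))
        stop("slider answers not summing to 1 (expert ",
             paste(experts[bad_sum], collapse = ", "), ", question ", ch, ")",
             call. = FALSE)
      kept <- remove_outliers(m, k)
      pooled <- pool_discrete(kept$retained)
      vec_out[[length(vec_out) + 1L]] <- data.frame(
        child = ch, config = cf, state = states, prob = unname(pooled),
        stringsAsFactors = FALSE)
      if (length(kept$rejected))
        rej[[length(rej) + 1L]] <- data.frame(
          child = ch, config = cf, expert_id = kept$rejected,
          stringsAsFactors = FALSE)
    } else {
      rows <- spreads[spreads$child == ch & spreads$config == cf, , drop = FALSE]
      if (nrow(rows) == 0L)
        stop("no answers for question ", ch, " [", cf, "]", call. = FALSE)
      m <- cbind(mode = rows$mode, halfwidth = rows$halfwidth)
      rownames(m) <- rows$expert_id
      kept <- remove_outliers(m, k)
      spr_out[[length(spr_out) + 1L]] <- data.frame(
        child = ch, config = cf,
        mode = stats::median(kept$retained[, "mode"]),
        halfwidth = stats::median(kept$retained[, "halfwidth"]),
        stringsAsFactors = FALSE)
      if (length(kept$rejected))
        rej[[length(rej) + 1L]] <- data.frame(
          child = ch, config = cf, expert_id = kept$rejected,
          stringsAsFactors = FALSE)
    }
  }
  rbind0 <- function(l, proto) if (length(l)) do.call(rbind, l) else proto
  list(
    vectors = rbind0(vec_out, data.frame(child = character(), config = character(),
                                         state = character(), prob = numeric())),
    spreads = rbind0(spr_out, data.frame(child = character(), config = character(),
                                         mode = numeric(), halfwidth = numeric())),
    rejections = rbind0(rej, data.frame(child = character(), config = character(),
                                        expert_id = character())))
}

#' Build all CPTs from pooled Stage 3 answers
#'
#' Priors come straight from pooled vectors (or a discretized
#' truncated normal for ranked priors). Binary conditional children under
#' noisy-OR mode are fitted with [fit_noisy_or()], whose fitted model populates the
#' full table, falling back to a logistic-link regression when the noisy-OR
#' max residual exceeds `logistic_tolerance`; full-mode and labeled children
#' take their columns directly from pooled vectors; ranked children get a
#' per-configuration truncated normal, discretized.
#'
#' @param edges Edge data frame of the final structure.
#' @param variables An `eb_varset` restricted to the network's variables.
#' @param pooled Output of [pool_answers()].
#' @param mode `"noisy_or"` (default) or `"full"`, or named per-child vector.
#' @param confidence Central-interval mass for spread conversion.
#' @param logistic_tolerance Max absolute noisy-OR residual above which the
#'   logistic-link fallback is used (default 0.1).
#' @return Named list of `eb_cpt`, one per variable.
#' @export
build_cpts <- function(edges, variables, pooled, mode = "noisy_or",
                       confidence = 0.90, logistic_tolerance = 0.1) {
  edges <- as_edge_df(edges)
  qinfo <- generate_questions(edges, variables, mode)
  missing_q <- NULL
  have <- c(paste(pooled$vectors$child, pooled$vectors$config, sep = "\r"),
            paste(pooled$spreads$child, pooled$spreads$config, sep = "\r"))
  need <- paste(qinfo$questions$child, qinfo$questions$config, sep = "\r")
  gap <- setdiff(need, have)
  if (length(gap))
    stop("missing pooled answers for question(s): ",
         paste(gsub("\r", " | ", gap), collapse = "; "), call. = FALSE)
  cpts <- list()
  for (nm in names(variables)) {
    v <- variables[[nm]]
    parents <- sort(edges$from[edges$to == nm])
    pstates <- stats::setNames(lapply(parents, function(p) variables[[p]]$states),
                               parents)
    grid <- cpt_config_grid(pstates)
    n_cfg <- nrow(grid)
    cfg_strings <- if (length(parents) == 0L) "" else
      apply(grid, 1L, function(r)
        config_to_string(stats::setNames(as.character(r), parents)))
    if (v$kind == "RANKED") {
      prob <- matrix(0, length(v$states), n_cfg)
      for (j in seq_len(n_cfg)) {
        row <- pooled$spreads[pooled$spreads$child == nm &
                                pooled$spreads$config == cfg_strings[j], ,
                              drop = FALSE]
        spec <- fit_tnormal(row$mode[1L], row$halfwidth[1L], confidence)
        prob[, j] <- discretize_tnormal(spec, length(v$states))
      }
      cpts[[nm]] <- eb_cpt(nm, v$states, parents, pstates, prob)
      next
    }
    use_noisy <- v$kind == "BINARY" && length(parents) > 0L &&
      (if (length(mode) > 1L || !is.null(names(mode))) mode[[nm]] else mode) == "noisy_or"
    if (use_noisy) {
      elic_cfgs <- unique(qinfo$questions$config[qinfo$questions$child == nm])
      q <- vapply(elic_cfgs, function(cf) {
        rows <- pooled$vectors[pooled$vectors$child == nm &
                                 pooled$vectors$config == cf, , drop = FALSE]
        rows$prob[match(v$states[2L], rows$state)]
      }, numeric(1))
      fit <- fit_noisy_or(data.frame(config = elic_cfgs, q = q,
                                     stringsAsFactors = FALSE),
                          nm, parents, pstates)
      if (fit$max_residual > logistic_tolerance) {
        pr <- fit_logistic_link(data.frame(config = elic_cfgs, q = q,
                                           stringsAsFactors = FALSE),
                                parents, pstates)
        p_true <- vapply(seq_len(n_cfg), function(j)
          pr(string_to_config(cfg_strings[j])), numeric(1))
      } else {
        p_true <- vapply(seq_len(n_cfg), function(j)
          noisy_or_probability(fit$spec, string_to_config(cfg_strings[j])),
          numeric(1))
      }
      prob <- rbind(1 - p_true, p_true)
      cpts[[nm]] <- eb_cpt(nm, v$states, parents, pstates, prob)
      next
    }
    # full table from pooled vectors (priors, labeled, full-mode binary)
    prob <- matrix(0, length(v$states), n_cfg)
    for (j in seq_len(n_cfg)) {
      rows <- pooled$vectors[pooled$vectors$child == nm &
                               pooled$vectors$config == cfg_strings[j], ,
                             drop = FALSE]
      if (nrow(rows) == 0L)
        stop("missing pooled vector for ", nm, " [", cfg_strings[j], "]",
             call. = FALSE)
      prob[, j] <- rows$prob[match(v$states, rows$state)]
    }
    cpts[[nm]] <- eb_cpt(nm, v$states, parents, pstates, prob)
  }
  cpts
}
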