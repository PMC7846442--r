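# Stage 1: per-expert placement of variables into skeleton categories and
# within-category ranking, aggregated by allocation fraction and
# IPR-penalized median normalized rank.
#
# Responses travel as a data frame with one row per
# (expert_id, variable, category, position, list_length): `position` is the
# 1-based rank in that expert's list for the chosen category, `list_length`
# the length of that list.

#' Normalized rank of a list position
#'
#' Maps position 1 (top of an expert's list) to 1 and the bottom position to
#' 0, linearly in between. A singleton list scores 1: its sole item is the
#' top item.
#'
#' @param position Integer rank, 1 = most important.
#' @param list_length Length of the list the position refers to.
#' @return Number in \[0, 1\].
#' @examples
#' normalized_rank(1, 5)  # 1
#' normalized_rank(5, 5)  # 0
#' @export
normalized_rank <- function(position, list_length) {
  ll <- rep(list_length, length.out = length(position))
  if (any(position < 1L | position > ll))
    stop("position out of range for list_length", call. = FALSE)
  ifelse(ll == 1L, 1.0, (ll - position) / (ll - 1))
}

validate_stage1_responses <- function(responses) {
  req <- c("expert_id", "variable", "category", "position", "list_length")
  missing_cols <- setdiff(req, names(responses))
  if (length(missing_cols))
    stop("stage 1 responses missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad_cat <- !(responses$category %in% EB_CATEGORIES)
  if (any(bad_cat))
    stop("unknown category in rows: ",
         paste(which(bad_cat), collapse = ", "), call. = FALSE)
  dup <- duplicated(responses[, c("expert_id", "variable")])
  if (any(dup))
    stop("expert(s) placed a variable more than once: ",
         paste(unique(paste(responses$expert_id[dup], responses$variable[dup],
                            sep = "/")), collapse = ", "), call. = FALSE)
  # within one expert and category: one list length, in-range positions,
  # no duplicated positions (a response file may legitimately cover only a
  # subset of an expert's list, so contiguity is not required)
  grp <- paste(responses$expert_id, responses$category, sep = "\r")
  for (k in unique(grp)) {
    rows <- which(grp == k)
    if (length(unique(responses$list_length[rows])) != 1L)
      stop("inconsistent list_length for expert/category ",
           sub("\r", "/", k), call. = FALSE)
    if (anyDuplicated(responses$position[rows]))
      stop("duplicated positions for expert/category ",
           sub("\r", "/", k), call. = FALSE)
    if (any(responses$position[rows] < 1L |
              responses$position[rows] > responses$list_length[rows]))
      stop("position out of range for expert/category ",
           sub("\r", "/", k), call. = FALSE)
  }
  invisible(responses)
}

#' Rewrite suggested-variable aliases to canonical names
#'
#' Applies a manually curated duplicate map (suggested name -> canonical
#' name). If the rewrite makes one expert mention a canonical variable twice,
#' the better (higher normalized) rank is kept and a warning identifies the
#' merge; positions of the surviving entries are recompacted per expert and
#' category so each list stays 1..m.
#'
#' @param responses Stage 1 response data frame.
#' @param alias_map Named character vector: `names()` are aliases, values the
#'   canonical names. Chains (alias of an alias) are rejected.
#' @return Rewritten response data frame.
#' @export
apply_alias_map <- function(responses, alias_map) {
  if (length(alias_map) == 0L) return(responses)
  if (any(names(alias_map) %in% alias_map))
    stop("alias map contains chains/cycles", call. = FALSE)
  hit <- responses$variable %in% names(alias_map)
  responses$variable[hit] <- unname(alias_map[responses$variable[hit]])
  responses$.nr <- normalized_rank(responses$position, responses$list_length)
  dup_key <- paste(responses$expert_id, responses$variable, sep = "\r")
  if (anyDuplicated(dup_key)) {
    keep <- !logical(nrow(responses))
    for (k in unique(dup_key[duplicated(dup_key)])) {
      rows <- which(dup_key == k)
      best <- rows[which.max(responses$.nr[rows])]
      keep[setdiff(rows, best)] <- FALSE
      warning("merged duplicate placements for ", sub("\r", "/", k),
              "; kept the better rank", call. = FALSE)
    }
    responses <- responses[keep, , drop = FALSE]
  }
  # recompact positions so each expert/category list is 1..m again
  grp <- paste(responses$expert_id, responses$category, sep = "\r")
  for (g in unique(grp)) {
    rows <- which(grp == g)
    ord <- order(responses$position[rows])
    responses$position[rows[ord]] <- seq_along(rows)
    responses$list_length[rows] <- length(rows)
  }
  responses$.nr <- NULL
  rownames(responses) <- NULL
  responses
}

#' Fraction of placing experts allocating a variable to a category
#'
#' The denominator is the set of experts who placed the variable anywhere;
#' experts who omitted it carry no weight.
#'
#' @param responses Stage 1 response data frame.
#' @param variable Variable name.
#' @param category Category to test.
#' @return Fraction in \[0, 1\].
#' @export
allocation_fraction <- function(responses, variable, category) {
  rows <- responses[responses$variable == variable, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("no expert placed variable '", variable, "'", call. = FALSE)
  mean(rows$category == category)
}

#' Aggregate Stage 1 placements into an included, ranked variable set
#'
#' For each variable the winning category is the one most experts chose; the
#' variable is included only when that allocation fraction strictly exceeds
#' `threshold`. Among the allocating experts the preference score is the
#' median normalized rank penalized by disagreement:
#' `adjusted = max(0, median - lambda * IPR80)`. Included variables are
#' ordered by adjusted score (ties broken by higher allocation fraction, then
#' name) and truncated at `cap`.
#'
#' @param responses Stage 1 response data frame (alias map already applied).
#' @param threshold Allocation fraction that must be strictly exceeded
#'   (default 0.8, the "more than 80\%" rule).
#' @param lambda_penalty Weight of the IPR80 penalty (default 0.5).
#' @param cap Maximum number of variables taken forward (default 50).
#' @return List with `results` (data frame: variable, category, fraction,
#'   median, ipr80, adjusted_score, included, n_responses) and `selected`
#'   (character vector in rank order).
#' @export
aggregate_stage1 <- function(responses, threshold = 0.8, lambda_penalty = 0.5,
                             cap = 50L) {
  validate_stage1_responses(responses)
  if (length(unique(responses$expert_id)) < 2L)
    stop("at least 2 experts required", call. = FALSE)
  responses$.nr <- normalized_rank(responses$position, responses$list_length)
  vars <- sort(unique(responses$variable))
  out <- lapply(vars, function(v) {
    rows <- responses[responses$variable == v, , drop = FALSE]
    tab <- table(factor(rows$category, levels = EB_CATEGORIES))
    win <- EB_CATEGORIES[which.max(tab)]   # deterministic: first max in order
    frac <- as.numeric(max(tab)) / nrow(rows)
    ranks <- rows$.nr[rows$category == win]
    med <- stats::median(ranks)
    ipr <- ipr80(ranks)
    adj <- max(0, med - lambda_penalty * ipr)
    data.frame(variable = v, category = win, fraction = frac,
               median = med, ipr80 = ipr, adjusted_score = adj,
               included = frac > threshold, n_responses = nrow(rows),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  inc <- res[res$included, , drop = FALSE]
  ord <- order(-inc$adjusted_score, -inc$fraction, inc$variable)
  selected <- utils::head(inc$variable[ord], cap)
  res$included <- res$included & res$variable %in% selected
  rownames(res) <- NULL
  list(results = res, selected = selected)
}
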