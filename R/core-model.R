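#' @keywords internal
"_PACKAGE"

# Category and kind vocabularies are fixed: the elicitation skeleton layers
# risk factors above judgement factors above signs-and-symptoms.
EB_CATEGORIES <- c("RISK_FACTOR", "JUDGEMENT_FACTOR", "SIGN_SYMPTOM")
EB_KINDS <- c("BINARY", "LABELED", "RANKED")

#' Define an elicitation variable
#'
#' A variable is the unit of elicitation: a named clinical quantity placed in
#' one of three skeleton categories (risk factor, judgement factor, sign and
#' symptom) with a discrete state space. `BINARY` variables have exactly two
#' states; `LABELED` states are nominal; `RANKED` states are ordinal and map
#' onto equal-width sub-intervals of \[0, 1\] in listed order (first state =
#' lowest interval).
#'
#' @param name Short unique identifier.
#' @param category One of `"RISK_FACTOR"`, `"JUDGEMENT_FACTOR"`,
#'   `"SIGN_SYMPTOM"`.
#' @param kind One of `"BINARY"`, `"LABELED"`, `"RANKED"`.
#' @param states Ordered character vector of state labels.
#' @param question_text Free-text question shown to experts.
#' @param measurement_note Free-text note on mode/units of measurement.
#' @return An object of class `eb_variable`.
#' @examples
#' eb_variable("age", "RISK_FACTOR", "RANKED", c("under40", "40to65", "over65"))
#' @export
eb_variable <- function(name, category, kind, states,
                        question_text = "", measurement_note = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  category <- match.arg(category, EB_CATEGORIES)
  kind <- match.arg(kind, EB_KINDS)
  states <- as.character(states)
  if (anyDuplicated(states))
    stop("variable '", name, "': duplicate state labels", call. = FALSE)
  if (kind == "BINARY" && length(states) != 2L)
    stop("variable '", name, "': BINARY requires exactly 2 states", call. = FALSE)
  if (kind != "BINARY" && length(states) < 2L)
    stop("variable '", name, "': at least 2 states required", call. = FALSE)
  structure(
    list(name = name, category = category, kind = kind, states = states,
         question_text = question_text, measurement_note = measurement_note),
    class = "eb_variable")
}

#' @export
print.eb_variable <- function(x, ...) {
  cat(sprintf("<eb_variable> %s [%s, %s]: %s\n", x$name, x$category, x$kind,
              paste(x$states, collapse = " | ")))
  invisible(x)
}

#' Collect variables into a validated pool
#'
#' @param ... `eb_variable` objects, or a single list of them.
#' @return Named list of class `eb_varset`; names are variable names.
#' @export
eb_varset <- function(...) {
  vars <- list(...)
  if (length(vars) == 1L && !inherits(vars[[1L]], "eb_variable"))
    vars <- vars[[1L]]
  ok <- vapply(vars, inherits, logical(1), "eb_variable")
  if (!all(ok)) stop("all elements must be eb_variable objects", call. = FALSE)
  nms <- vapply(vars, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate variable names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  names(vars) <- nms
  structure(vars, class = "eb_varset")
}

#' @export
print.eb_varset <- function(x, ...) {
  cat(sprintf("<eb_varset> %d variables\n", length(x)))
  for (v in x) print(v)
  invisible(x)
}

#' Skeleton causal template
#'
#' The skeleton constrains which directed edges may be elicited: by default
#' risk factors may point at judgement factors and judgement factors at signs
#' and symptoms. Because the default relation is a strict layering, any edge
#' set respecting it is automatically acyclic.
#'
#' @param allowed Two-column character matrix or data.frame of
#'   (parent category, child category) pairs. Default: the two-layer rule.
#' @return Object of class `eb_skeleton`.
#' @export
eb_skeleton <- function(allowed = NULL) {
  if (is.null(allowed)) {
    allowed <- data.frame(
      from = c("RISK_FACTOR", "JUDGEMENT_FACTOR"),
      to = c("JUDGEMENT_FACTOR", "SIGN_SYMPTOM"),
      stringsAsFactors = FALSE)
  } else {
    allowed <- as.data.frame(allowed, stringsAsFactors = FALSE)
    names(allowed) <- c("from", "to")
    bad <- !(allowed$from %in% EB_CATEGORIES) | !(allowed$to %in% EB_CATEGORIES)
    if (any(bad)) stop("unknown category in skeleton", call. = FALSE)
  }
  structure(list(allowed = allowed), class = "eb_skeleton")
}

skeleton_allows <- function(skeleton, from_cat, to_cat) {
  any(skeleton$allowed$from == from_cat & skeleton$allowed$to == to_cat)
}

#' Percentile with linear interpolation between order statistics
#'
#' For sorted values x_1..x_n the q-th percentile sits at rank
#' r = 1 + q(n-1)/100, linearly interpolated between the flanking order
#' statistics (the common "type 7" convention). This is the primitive behind
#' every interpercentile-range consensus statistic in the pipeline.
#'
#' @param values Non-empty numeric vector.
#' @param q Percentile in \[0, 100\].
#' @return The interpolated percentile.
#' @examples
#' eb_percentile(c(0, 10), 90) # 9
#' @export
eb_percentile <- function(values, q) {
  if (length(values) == 0L) stop("no responses: empty value vector", call. = FALSE)
  stopifnot(is.numeric(values), length(q) == 1L, q >= 0, q <= 100)
  unname(stats::quantile(values, probs = q / 100, type = 7, names = FALSE))
}

#' 80\% interpercentile range (P90 - P10)
#'
#' The disagreement measure of the RAND appropriateness procedure: the width
#' of the central 80\% of panel responses. Zero when all responses agree.
#'
#' @param values Non-empty numeric vector of panel responses.
#' @return Non-negative width.
#' @examples
#' ipr80(c(0, 3)) # 2.4
#' @export
ipr80 <- function(values) {
  eb_percentile(values, 90) - eb_percentile(values, 10)
}

#' Check that an edge set respects the skeleton layering
#'
#' Returns `TRUE` iff every edge's (parent category, child category) pair is
#' allowed by the skeleton. Under the default two-layer skeleton this also
#' guarantees acyclicity.
#'
#' @param edges Data frame with columns `from`, `to` (variable names); may
#'   have zero rows.
#' @param variables An `eb_varset` covering every name in `edges`.
#' @param skeleton An `eb_skeleton`.
#' @return Logical scalar.
#' @export
check_dag <- function(edges, variables, skeleton = eb_skeleton()) {
  edges <- as_edge_df(edges)
  if (nrow(edges) == 0L) return(TRUE)
  unknown <- setdiff(c(edges$from, edges$to), names(variables))
  if (length(unknown))
    stop("unknown variable name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  ok <- mapply(function(f, t)
    skeleton_allows(skeleton, variables[[f]]$category, variables[[t]]$category),
    edges$from, edges$to)
  all(ok)
}

as_edge_df <- function(edges) {
  if (is.null(edges)) return(data.frame(from = character(), to = character(),
                                        stringsAsFactors = FALSE))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L)
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  if (!all(c("from", "to") %in% names(edges))) names(edges)[1:2] <- c("from", "to")
  edges[, c("from", "to")]
}

#' Consensus summary for one elicited item
#'
#' Bundles the RAND-style descriptive statistics for a single item: panel
#' median, 80\% interpercentile range, the IPR-penalized score, the fixed
#' (consensus-reached) flag and the inclusion decision.
#'
#' @param item_id Item identifier.
#' @param median Panel median.
#' @param ipr80 80\% interpercentile range (non-negative).
#' @param adjusted_score Median minus the consensus penalty (never above the
#'   median).
#' @param fixed Whether consensus suffices to freeze the item.
#' @param included Inclusion decision.
#' @param n_responses Number of contributing experts.
#' @return Object of class `eb_consensus`.
#' @export
eb_consensus <- function(item_id, median, ipr80, adjusted_score, fixed,
                         included, n_responses) {
  stopifnot(ipr80 >= 0, n_responses >= 1L)
  if (adjusted_score > median + 1e-12)
    stop("adjusted_score must not exceed the median (penalty, not bonus)",
         call. = FALSE)
  structure(list(item_id = item_id, median = median, ipr80 = ipr80,
                 adjusted_score = adjusted_score, fixed = isTRUE(fixed),
                 included = isTRUE(included), n_responses = as.integer(n_responses)),
            class = "eb_consensus")
}

# Midpoints of the equal-width [0,1] partition a RANKED (or any ordered
# discrete) variable's states map onto; used by ranked-node CPT construction.
state_midpoints <- function(n_states) {
  (seq_len(n_states) - 0.5) / n_states
}
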