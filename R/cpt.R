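# Conditional probability tables. Parent configurations are enumerated
# row-major over the parents in listed order (last parent varies fastest),
# states in listed order, so every export is deterministic.

#' Enumerate parent configurations in canonical order
#'
#' @param parent_states Named list: parent name -> character vector of states.
#' @return Data frame, one row per configuration, columns in parent order;
#'   the last parent varies fastest. A single empty-row frame when there are
#'   no parents.
#' @export
cpt_config_grid <- function(parent_states) {
  if (length(parent_states) == 0L)
    return(data.frame(row.names = "1")[, 0, drop = FALSE])
  g <- expand.grid(rev(parent_states), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g <- g[, rev(seq_along(g)), drop = FALSE]
  names(g) <- names(parent_states)
  rownames(g) <- NULL
  g
}

#' Construct a conditional probability table
#'
#' @param child Child variable name.
#' @param states Child state labels (ordered).
#' @param parents Character vector of parent names (possibly empty).
#' @param parent_states Named list of parent state vectors, in `parents` order.
#' @param prob Numeric matrix, `length(states)` rows by one column per parent
#'   configuration in [cpt_config_grid()] order; each column a distribution.
#' @return Object of class `eb_cpt`.
#' @export
eb_cpt <- function(child, states, parents = character(), parent_states = list(),
                   prob) {
  stopifnot(is.character(child), length(states) >= 1L)
  parents <- as.character(parents)
  if (!identical(names(parent_states), parents) && length(parents))
    stop("parent_states must be named by parents, in order", call. = FALSE)
  n_cfg <- if (length(parents)) prod(lengths(parent_states)) else 1L
  prob <- as.matrix(prob)
  if (nrow(prob) != length(states) || ncol(prob) != n_cfg)
    stop(sprintf("CPT for '%s': prob must be %d x %d", child,
                 length(states), n_cfg), call. = FALSE)
  if (any(prob < -1e-12) || any(prob > 1 + 1e-12))
    stop(sprintf("CPT for '%s': probabilities outside [0,1]", child),
         call. = FALSE)
  sums <- colSums(prob)
  if (any(abs(sums - 1) > 1e-9))
    stop(sprintf("CPT for '%s': column(s) %s do not sum to 1", child,
                 paste(which(abs(sums - 1) > 1e-9), collapse = ",")),
         call. = FALSE)
  dimnames(prob) <- list(states, NULL)
  structure(list(child = child, states = states, parents = parents,
                 parent_states = parent_states, prob = prob),
            class = "eb_cpt")
}

#' @export
print.eb_cpt <- function(x, ...) {
  cat(sprintf("<eb_cpt> %s | %s  (%d states x %d configs)\n", x$child,
              if (length(x$parents)) paste(x$parents, collapse = ", ") else "-",
              nrow(x$prob), ncol(x$prob)))
  invisible(x)
}

# Index of a parent configuration (named character vector) in canonical order.
cpt_config_index <- function(cpt, config) {
  if (length(cpt$parents) == 0L) return(1L)
  idx <- 1L
  for (p in cpt$parents) {
    s <- config[[p]]
    if (is.null(s)) stop("configuration missing parent '", p, "'", call. = FALSE)
    k <- match(s, cpt$parent_states[[p]])
    if (is.na(k)) stop("unknown state '", s, "' for parent '", p, "'",
                       call. = FALSE)
    idx <- (idx - 1L) * length(cpt$parent_states[[p]]) + k
  }
  idx
}

# Distribution over child states for one parent configuration.
cpt_column <- function(cpt, config = NULL) {
  cpt$prob[, cpt_config_index(cpt, config)]
}

#' Assemble a Bayesian network
#'
#' Validates that the edge set respects the skeleton (hence is acyclic under
#' the default layering), that each variable carries exactly one CPT whose
#' parent list equals its in-edges, and that CPT state spaces match the
#' variable definitions.
#'
#' @param variables An `eb_varset`.
#' @param edges Data frame with `from`, `to` columns.
#' @param cpts Named list of `eb_cpt`, one per variable.
#' @param skeleton An `eb_skeleton` (default layering).
#' @return Object of class `eb_network`.
#' @export
eb_network <- function(variables, edges, cpts, skeleton = eb_skeleton()) {
  if (!inherits(variables, "eb_varset")) variables <- eb_varset(variables)
  edges <- as_edge_df(edges)
  if (!check_dag(edges, variables, skeleton))
    stop("edge set violates the skeleton layering", call. = FALSE)
  if (!setequal(names(cpts), names(variables)))
    stop("cpts must cover exactly the variables", call. = FALSE)
  for (nm in names(variables)) {
    cpt <- cpts[[nm]]
    v <- variables[[nm]]
    if (!inherits(cpt, "eb_cpt") || cpt$child != nm)
      stop("cpt for '", nm, "' malformed", call. = FALSE)
    if (!identical(cpt$states, v$states))
      stop("cpt states for '", nm, "' disagree with the variable", call. = FALSE)
    pa <- sort(edges$from[edges$to == nm])
    if (!identical(sort(cpt$parents), pa))
      stop("cpt parents for '", nm, "' do not equal its in-edges", call. = FALSE)
  }
  structure(list(variables = variables, edges = edges, cpts = cpts,
                 skeleton = skeleton),
            class = "eb_network")
}

#' @export
print.eb_network <- function(x, ...) {
  cat(sprintf("<eb_network> %d variables, %d edges\n",
              length(x$variables), nrow(x$edges)))
  invisible(x)
}

network_parents <- function(network, child) {
  network$cpts[[child]]$parents
}
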