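# Exact inference by variable elimination over table factors, with a full
# joint-enumeration path kept as an independent oracle. Networks here are
# small layered DAGs (tens of nodes, few states), so factors are plain R
# arrays with state dimnames.

# --- factors ---------------------------------------------------------------

ebf_new <- function(vars, states, val) {
  dims <- lengths(states[vars])
  a <- array(val, dim = dims, dimnames = states[vars])
  list(vars = vars, states = states[vars], val = a)
}

ebf_from_cpt <- function(cpt) {
  vars <- c(cpt$child, cpt$parents)
  states <- c(stats::setNames(list(cpt$states), cpt$child), cpt$parent_states)
  dims <- lengths(states)
  a <- array(0, dim = dims, dimnames = states)
  if (length(cpt$parents) == 0L) {
    a[] <- cpt$prob[, 1L]
  } else {
    grid <- cpt_config_grid(cpt$parent_states)
    for (j in seq_len(nrow(grid))) {
      # assign the column; the child dimension comes first
      a <- do.call(`[<-`, c(list(a), list(TRUE),
                            unname(lapply(cpt$parents, function(p) grid[j, p])),
                            list(value = cpt$prob[, j])))
    }
  }
  list(vars = vars, states = states, val = a)
}

# restrict a factor to evidence (drop observed dimensions)
ebf_reduce <- function(f, evidence) {
  hit <- intersect(f$vars, names(evidence))
  if (length(hit) == 0L) return(f)
  idx <- lapply(f$vars, function(v)
    if (v %in% hit) evidence[[v]] else TRUE)
  val <- do.call(`[`, c(list(f$val), unname(idx), list(drop = FALSE)))
  keep <- setdiff(f$vars, hit)
  if (length(keep) == 0L)
    return(list(vars = character(), states = list(), val = sum(val)))
  val <- array(val, dim = lengths(f$states[keep]), dimnames = f$states[keep])
  list(vars = keep, states = f$states[keep], val = val)
}

ebf_product <- function(f1, f2) {
  if (length(f1$vars) == 0L)
    return(list(vars = f2$vars, states = f2$states, val = f2$val * as.numeric(f1$val)))
  if (length(f2$vars) == 0L)
    return(list(vars = f1$vars, states = f1$states, val = f1$val * as.numeric(f2$val)))
  vars <- union(f1$vars, f2$vars)
  states <- c(f1$states, f2$states[setdiff(f2$vars, f1$vars)])[vars]
  dims <- lengths(states)
  # broadcast each factor to the joint dimension order by aperm + replication
  expand <- function(f) {
    miss <- setdiff(vars, f$vars)
    a <- f$val
    if (length(miss)) {
      a <- array(rep(as.vector(a), prod(lengths(states[miss]))),
                 dim = c(lengths(f$states), lengths(states[miss])),
                 dimnames = c(f$states, states[miss]))
    }
    aperm(a, match(vars, c(f$vars, miss)))
  }
  val <- expand(f1) * expand(f2)
  dimnames(val) <- states
  list(vars = vars, states = states, val = val)
}

ebf_marginalize <- function(f, var) {
  keep <- setdiff(f$vars, var)
  if (length(keep) == 0L)
    return(list(vars = character(), states = list(), val = sum(f$val)))
  val <- apply(f$val, match(keep, f$vars), sum)
  val <- array(val, dim = lengths(f$states[keep]), dimnames = f$states[keep])
  list(vars = keep, states = f$states[keep], val = val)
}

# --- joint and enumeration oracle ------------------------------------------

#' Joint probability of a complete assignment
#'
#' Chain-rule product of CPT entries: `prod_v P(v = a_v | parents(v) = a)`.
#'
#' @param network An `eb_network`.
#' @param assignment Named character vector covering every variable.
#' @return Probability in \[0, 1\].
#' @export
joint_probability <- function(network, assignment) {
  missing_v <- setdiff(names(network$variables), names(assignment))
  if (length(missing_v))
    stop("assignment incomplete; missing: ",
         paste(missing_v, collapse = ", "), call. = FALSE)
  p <- 1
  for (nm in names(network$variables)) {
    cpt <- network$cpts[[nm]]
    col <- cpt_column(cpt, assignment[cpt$parents])
    s <- assignment[[nm]]
    k <- match(s, cpt$states)
    if (is.na(k)) stop("unknown state '", s, "' for '", nm, "'", call. = FALSE)
    p <- p * col[k]
  }
  unname(p)
}

all_assignments <- function(network) {
  states <- lapply(network$variables, `[[`, "states")
  cpt_config_grid(states)
}

# brute-force posterior by summing the joint; the independent oracle
posterior_enumerate <- function(network, query, evidence = character()) {
  grid <- all_assignments(network)
  if (length(evidence)) {
    for (v in names(evidence))
      grid <- grid[grid[[v]] == evidence[[v]], , drop = FALSE]
  }
  states <- network$variables[[query]]$states
  mass <- stats::setNames(numeric(length(states)), states)
  for (i in seq_len(nrow(grid))) {
    a <- stats::setNames(as.character(grid[i, ]), names(grid))
    mass[a[[query]]] <- mass[a[[query]]] + joint_probability(network, a)
  }
  tot <- sum(mass)
  if (tot <= 0) stop("impossible evidence: zero marginal probability",
                     call. = FALSE)
  mass / tot
}

# --- variable elimination --------------------------------------------------

#' Exact posterior distribution by variable elimination
#'
#' Computes `P(query | evidence)` exactly. Hidden variables are eliminated
#' in min-degree order (fewest neighbours in the current factor graph,
#' deterministic tie-break by name). Evidence with zero marginal probability
#' raises an error rather than returning NaN.
#'
#' @param network An `eb_network`.
#' @param query Variable name to query (must not be observed).
#' @param evidence Named character vector of observed states (may be empty).
#' @param method `"ve"` (default) or `"enumeration"` (the brute-force
#'   oracle; exponential, small networks only).
#' @return Named probability vector over the query's states.
#' @export
posterior <- function(network, query, evidence = character(),
                      method = c("ve", "enumeration")) {
  method <- match.arg(method)
  if (!query %in% names(network$variables))
    stop("unknown query variable '", query, "'", call. = FALSE)
  bad_ev <- setdiff(names(evidence), names(network$variables))
  if (length(bad_ev))
    stop("unknown evidence variable(s): ", paste(bad_ev, collapse = ", "),
         call. = FALSE)
  for (v in names(evidence)) {
    if (!(evidence[[v]] %in% network$variables[[v]]$states))
      stop("unknown state '", evidence[[v]], "' for evidence variable '", v,
           "'", call. = FALSE)
  }
  if (query %in% names(evidence))
    stop("query variable is observed", call. = FALSE)
  if (method == "enumeration")
    return(posterior_enumerate(network, query, evidence))
  factors <- lapply(network$cpts, ebf_from_cpt)
  factors <- lapply(factors, ebf_reduce, evidence = evidence)
  hidden <- setdiff(names(network$variables), c(query, names(evidence)))
  while (length(hidden)) {
    # min-degree: neighbours of each hidden var in the current factor set
    degree <- vapply(hidden, function(v) {
      nb <- unique(unlist(lapply(factors, function(f)
        if (v %in% f$vars) f$vars else NULL)))
      length(setdiff(nb, v))
    }, numeric(1))
    v <- hidden[order(degree, hidden)][1L]
    touch <- vapply(factors, function(f) v %in% f$vars, logical(1))
    prod_f <- Reduce(ebf_product, factors[touch])
    factors <- c(factors[!touch], list(ebf_marginalize(prod_f, v)))
    hidden <- setdiff(hidden, v)
  }
  result <- Reduce(ebf_product, factors)
  if (!identical(result$vars, query))
    result$val <- aperm(result$val, match(query, result$vars))
  mass <- as.vector(result$val)
  names(mass) <- network$variables[[query]]$states
  tot <- sum(mass)
  if (tot <= 0) stop("impossible evidence: zero marginal probability",
                     call. = FALSE)
  mass / tot
}
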