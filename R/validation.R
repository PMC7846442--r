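# Stage 4: face validity against clinical scenarios, and the recovery
# metrics used to score pipeline runs against a known ground truth.

#' Define a face-validity scenario
#'
#' A scenario couples an evidence assignment (the presenting case) with the
#' qualitative ordering of judgement factors a clinician expects, most
#' probable first.
#'
#' @param name Scenario label.
#' @param evidence Named character vector of observed states.
#' @param expected_ordering Judgement-factor names, most probable first; no
#'   duplicates.
#' @param states_of_interest Optional named character vector giving, per
#'   judgement factor, the state whose posterior is ranked; defaults to each
#'   variable's last listed state (the "present"/highest state under the
#'   package conventions).
#' @return List of class `eb_scenario`.
#' @export
eb_scenario <- function(name, evidence, expected_ordering,
                        states_of_interest = NULL) {
  if (anyDuplicated(expected_ordering))
    stop("expected_ordering contains duplicates", call. = FALSE)
  structure(list(name = name, evidence = evidence,
                 expected_ordering = expected_ordering,
                 states_of_interest = states_of_interest),
            class = "eb_scenario")
}

#' Face-validity check of a network against a scenario
#'
#' Computes the posterior probability of each listed judgement factor's
#' state of interest given the scenario evidence, ranks the factors by that
#' probability, and reports whether the model's top factor matches the
#' expected one plus the Kendall rank correlation between the model and
#' expected orderings.
#'
#' @param network An `eb_network`.
#' @param scenario An `eb_scenario`.
#' @return List: `name`, `probabilities` (named, model order), `model_ordering`,
#'   `expected_ordering`, `top1_match` (logical), `kendall_tau`.
#' @export
face_validity <- function(network, scenario) {
  vars <- scenario$expected_ordering
  unknown <- setdiff(c(vars, names(scenario$evidence)),
                     names(network$variables))
  if (length(unknown))
    stop("scenario references unknown variable(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  probs <- vapply(vars, function(v) {
    soi <- if (!is.null(scenario$states_of_interest) &&
               v %in% names(scenario$states_of_interest))
      scenario$states_of_interest[[v]]
    else utils::tail(network$variables[[v]]$states, 1L)
    post <- posterior(network, v, scenario$evidence)
    post[[soi]]
  }, numeric(1))
  model_order <- vars[order(-probs, vars)]
  # Kendall tau between expected ranks and model ranks
  exp_rank <- seq_along(vars)
  mod_rank <- match(vars, model_order)
  tau <- if (length(vars) >= 2L)
    stats::cor(exp_rank, mod_rank, method = "kendall") else 1
  list(name = scenario$name,
       probabilities = probs,
       model_ordering = model_order,
       expected_ordering = vars,
       top1_match = model_order[1L] == vars[1L],
       kendall_tau = tau)
}

#' Structure-recovery metrics against a true edge set
#'
#' Standard set-overlap scores. With an empty estimated set and a non-empty
#' truth both precision and recall are reported as 0 (and F1 as 0); two
#' empty sets score 1 throughout.
#'
#' @param estimated,true Edge data frames (`from`, `to`).
#' @return List: `precision`, `recall`, `f1`, `tp`, `fp`, `fn`.
#' @export
structure_recovery <- function(estimated, true) {
  ekey <- paste(estimated$from, estimated$to, sep = "\r")
  tkey <- paste(true$from, true$to, sep = "\r")
  tp <- length(intersect(ekey, tkey))
  fp <- length(setdiff(ekey, tkey))
  fn <- length(setdiff(tkey, ekey))
  if (tp + fp + fn == 0L)
    return(list(precision = 1, recall = 1, f1 = 1, tp = 0L, fp = 0L, fn = 0L))
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall)
        else 0
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn)
}

#' CPT-recovery error between two networks with identical structure
#'
#' @param estimated,true `eb_network`s over the same variables and edges.
#' @return List: `max_abs_error`, `mean_abs_error`, `per_variable` (named
#'   vector of per-variable max absolute errors).
#' @export
cpt_recovery <- function(estimated, true) {
  if (!setequal(names(estimated$variables), names(true$variables)))
    stop("networks cover different variables", call. = FALSE)
  rec <- structure_recovery(estimated$edges, true$edges)
  if (rec$f1 < 1)
    stop("networks have different structures; compare edges first",
         call. = FALSE)
  per_var <- vapply(names(true$variables), function(nm) {
    max(abs(estimated$cpts[[nm]]$prob - true$cpts[[nm]]$prob))
  }, numeric(1))
  all_err <- unlist(lapply(names(true$variables), function(nm)
    abs(estimated$cpts[[nm]]$prob - true$cpts[[nm]]$prob)))
  list(max_abs_error = max(per_var), mean_abs_error = mean(all_err),
       per_variable = per_var)
}
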