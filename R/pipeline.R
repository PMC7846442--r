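# File formats and the end-to-end pipeline. Response files are plain
# tab-separated text with a header, hand-editable by a clinical team; model
# and scenario definitions are JSON. Every pipeline run writes its fully
# resolved configuration next to its outputs for provenance.

#' Read and validate an elicitation response file
#'
#' Parses a tab-separated response file against one of the stage schemas and
#' either returns the fully validated data frame or stops with a
#' line-addressed error list; a file never half-parses silently.
#'
#' Schemas: `"stage1"` (expert_id, variable, category, position,
#' list_length), `"stage2"` (expert_id, source, target, score),
#' `"sliders"` (expert_id, child, config, state, prob), `"spreads"`
#' (expert_id, child, config, mode, halfwidth).
#'
#' @param path File path.
#' @param schema Schema identifier.
#' @return Validated data frame.
#' @export
validate_responses <- function(path,
                               schema = c("stage1", "stage2", "sliders",
                                          "spreads")) {
  schema <- match.arg(schema)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  errs <- character()
  req <- switch(schema,
    stage1 = c("expert_id", "variable", "category", "position", "list_length"),
    stage2 = c("expert_id", "source", "target", "score"),
    sliders = c("expert_id", "child", "config", "state", "prob"),
    spreads = c("expert_id", "child", "config", "mode", "halfwidth"))
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  line <- function(i) i + 1L  # header offset
  if (schema == "stage1") {
    bad <- which(!(df$category %in% EB_CATEGORIES))
    errs <- c(errs, sprintf("line %d: unknown category '%s'", line(bad),
                            df$category[bad]))
    bad <- which(df$position < 1 | df$position > df$list_length)
    errs <- c(errs, sprintf("line %d: position outside 1..list_length",
                            line(bad)))
  } else if (schema == "stage2") {
    bad <- which(!(df$score %in% 0:3))
    errs <- c(errs, sprintf("line %d: score %s outside 0..3 (cell %s -> %s)",
                            line(bad), df$score[bad], df$source[bad],
                            df$target[bad]))
  } else if (schema == "sliders") {
    bad <- which(df$prob < 0 | df$prob > 1)
    errs <- c(errs, sprintf("line %d: probability outside [0,1]", line(bad)))
    sums <- tapply(df$prob, paste(df$expert_id, df$child, df$config,
                                  sep = "\r"), sum)
    bad_sum <- names(sums)[abs(sums - 1) > 1e-6]
    errs <- c(errs, sprintf(
      "answer %s: slider probabilities sum to %.4f, not 1 (percentages must add up to 100)",
      gsub("\r", "/", bad_sum), sums[bad_sum]))
  } else {
    bad <- which(df$mode < 0 | df$mode > 1)
    errs <- c(errs, sprintf("line %d: mode outside [0,1]", line(bad)))
    bad <- which(df$halfwidth <= 0 | df$halfwidth > 1)
    errs <- c(errs, sprintf("line %d: half-width outside (0,1]", line(bad)))
  }
  if (length(errs))
    stop(path, ": invalid ", schema, " file:\n",
         paste(errs, collapse = "\n"), call. = FALSE)
  df
}

#' Write / read a variable-model definition file (JSON)
#'
#' @param variables An `eb_varset`.
#' @param path File path.
#' @return For the reader, an `eb_varset`.
#' @export
write_model_file <- function(variables, path) {
  lst <- lapply(unclass(variables), function(v) unclass(v))
  jsonlite::write_json(unname(lst), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_file
#' @export
read_model_file <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  vars <- lapply(lst, function(v)
    eb_variable(v$name, v$category, v$kind, unlist(v$states),
                question_text = v$question_text %||% "",
                measurement_note = v$measurement_note %||% ""))
  eb_varset(vars)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a scenario file (JSON)
#'
#' Each scenario lists evidence pairs and an expected judgement-factor
#' ordering; see [eb_scenario()].
#'
#' @param path File path.
#' @return List of `eb_scenario`.
#' @export
read_scenarios <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(lst, function(s)
    eb_scenario(s$name,
                evidence = unlist(s$evidence),
                expected_ordering = unlist(s$expected_ordering),
                states_of_interest = if (!is.null(s$states_of_interest))
                  unlist(s$states_of_interest) else NULL))
}

#' Run the full elicitation pipeline on response files
#'
#' Executes the stages in protocol order — variable aggregation, structure
#' aggregation (with optional workshop merge), probability pooling, CPT
#' construction, optional face-validity scenarios — halting at the first
#' stage that fails. Writes the final network (XMLBIF), the per-stage
#' reports, and the fully resolved configuration (with input-file digests)
#' into `out_dir`. Reruns with identical inputs and configuration produce
#' identical outputs.
#'
#' @param model_file JSON variable-model file.
#' @param stage1_file,stage2_file Stage 1 / Stage 2 response files (TSV).
#' @param sliders_file,spreads_file Stage 3 answer files (TSV; either may be
#'   absent if no question of that format exists).
#' @param out_dir Output directory (created if missing).
#' @param stage2_workshop_file Optional workshop-round Stage 2 file.
#' @param scenario_file Optional JSON scenario file.
#' @param threshold,lambda_penalty,cap Stage 1 parameters.
#' @param fix_threshold,keep_threshold Stage 2 parameters.
#' @param k,confidence,mode Stage 3 parameters.
#' @param alias_map Optional named character vector of variable aliases.
#' @return List: `network`, `stage1`, `structure`, `consensus`, `pooled`,
#'   `validation` (or `NULL`), `paths`.
#' @export
run_pipeline <- function(model_file, stage1_file, stage2_file,
                         sliders_file = NULL, spreads_file = NULL,
                         out_dir, stage2_workshop_file = NULL,
                         scenario_file = NULL,
                         threshold = 0.8, lambda_penalty = 0.5, cap = 50L,
                         fix_threshold = 1.0, keep_threshold = 2.0,
                         k = 1.5, confidence = 0.90, mode = "noisy_or",
                         alias_map = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fail <- function(stage, e)
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE)

  variables <- tryCatch(read_model_file(model_file),
                        error = function(e) fail("model", e))

  stage1 <- tryCatch({
    resp <- validate_responses(stage1_file, "stage1")
    if (!is.null(alias_map)) resp <- apply_alias_map(resp, alias_map)
    aggregate_stage1(resp, threshold = threshold,
                     lambda_penalty = lambda_penalty, cap = cap)
  }, error = function(e) fail("stage1", e))
  kept_vars <- eb_varset(unclass(variables)[stage1$selected])

  structure_out <- tryCatch({
    resp2 <- validate_responses(stage2_file, "stage2")
    consensus <- aggregate_grid(resp2, fix_threshold = fix_threshold)
    if (!is.null(stage2_workshop_file)) {
      w <- validate_responses(stage2_workshop_file, "stage2")
      consensus <- merge_rounds(consensus, w, fix_threshold = fix_threshold)
    }
    dag <- build_dag(consensus, kept_vars, keep_threshold = keep_threshold)
    list(consensus = consensus, dag = dag)
  }, error = function(e) fail("stage2", e))
  net_vars <- eb_varset(unclass(kept_vars)[structure_out$dag$kept])

  result <- tryCatch({
    qinfo <- generate_questions(structure_out$dag$edges, net_vars, mode)
    sliders <- if (!is.null(sliders_file))
      validate_responses(sliders_file, "sliders")
    else data.frame(expert_id = character(), child = character(),
                    config = character(), state = character(), prob = numeric())
    spreads <- if (!is.null(spreads_file))
      validate_responses(spreads_file, "spreads")
    else data.frame(expert_id = character(), child = character(),
                    config = character(), mode = numeric(),
                    halfwidth = numeric())
    pooled <- pool_answers(qinfo$questions, sliders, spreads, net_vars, k = k)
    cpts <- build_cpts(structure_out$dag$edges, net_vars, pooled, mode = mode,
                       confidence = confidence)
    net <- eb_network(net_vars, structure_out$dag$edges[, c("from", "to")],
                      cpts)
    list(network = net, pooled = pooled, questions = qinfo)
  }, error = function(e) fail("stage3", e))

  validation <- NULL
  if (!is.null(scenario_file)) {
    validation <- tryCatch({
      lapply(read_scenarios(scenario_file), function(s)
        face_validity(result$network, s))
    }, error = function(e) fail("validate", e))
  }

  net_path <- file.path(out_dir, "network.xmlbif")
  export_network(result$network, net_path, "XMLBIF")
  utils::write.table(stage1$results, file.path(out_dir, "stage1_consensus.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(structure_out$consensus,
                     file.path(out_dir, "stage2_consensus.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  inputs <- c(model_file, stage1_file, stage2_file, sliders_file,
              spreads_file, stage2_workshop_file, scenario_file)
  digests <- vapply(inputs[!vapply(inputs, is.null, logical(1))],
                    function(p) sprintf("%s:%d", basename(p),
                                        file.info(p)$size),
                    character(1))
  config <- list(threshold = threshold, lambda_penalty = lambda_penalty,
                 cap = cap, fix_threshold = fix_threshold,
                 keep_threshold = keep_threshold, k = k,
                 confidence = confidence, mode = mode,
                 inputs = as.list(digests))
  jsonlite::write_json(config, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(network = result$network, stage1 = stage1,
       structure = structure_out$dag, consensus = structure_out$consensus,
       pooled = result$pooled, validation = validation,
       paths = list(network = net_path, out_dir = out_dir))
}

#' Write simulated panel response files to disk
#'
#' Emits the full set of stage response files plus the ground-truth network
#' for an end-to-end pipeline run on synthetic data.
#'
#' @param truth An `eb_ground_truth`.
#' @param config An `eb_panel_config`.
#' @param out_dir Output directory.
#' @param mode Question-generation mode for stage 3.
#' @return Named list of written paths.
#' @export
write_simulated_panel <- function(truth, config, out_dir, mode = "noisy_or") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    p
  }
  qinfo <- generate_questions(truth$network$edges, truth$network$variables,
                              mode)
  s3 <- simulate_stage3(truth, config, qinfo$questions)
  paths <- list(
    model = file.path(out_dir, "model.json"),
    stage1 = wt(simulate_stage1(truth, config), "stage1_responses.tsv"),
    stage2 = wt(simulate_stage2(truth, config), "stage2_responses.tsv"),
    sliders = wt(s3$sliders, "stage3_sliders.tsv"),
    spreads = wt(s3$spreads, "stage3_spreads.tsv"),
    truth_network = file.path(out_dir, "truth_network.xmlbif"))
  write_model_file(truth$network$variables, paths$model)
  export_network(truth$network, paths$truth_network, "XMLBIF")
  paths
}
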