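# Stage 2: relationship-strength grids. Each expert scores every allowed
# (source, target) cell 0-3; the panel median and 80% IPR decide which cells
# are fixed (consensus reached) and which go to workshop discussion; the
# strongest surviving relationships become the network structure.

validate_stage2_responses <- function(responses) {
  req <- c("expert_id", "source", "target", "score")
  missing_cols <- setdiff(req, names(responses))
  if (length(missing_cols))
    stop("stage 2 responses missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- !(responses$score %in% 0:3)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("score %s outside 0..3 (expert %s, cell %s -> %s)",
                 responses$score[i], responses$expert_id[i],
                 responses$source[i], responses$target[i]), call. = FALSE)
  }
  dup <- duplicated(responses[, c("expert_id", "source", "target")])
  if (any(dup)) stop("duplicate grid cells for an expert", call. = FALSE)
  invisible(responses)
}

#' Aggregate relationship-strength grids into per-cell consensus
#'
#' Per cell: panel median, 80\% interpercentile range, and the fixed flag
#' (`ipr80 <= fix_threshold`, default 1 — cells fixed this way cannot be
#' edited in the workshop round). Experts missing a cell are treated as
#' scoring 0 (a blank grid cell means "no relationship") with a warning.
#'
#' @param responses Data frame: `expert_id`, `source`, `target`,
#'   `score` in 0..3.
#' @param fix_threshold IPR80 at or below which a cell is fixed (default 1).
#' @param pairs Optional data frame (`source`, `target`) giving the full cell
#'   set; defaults to the union of cells seen in `responses`.
#' @return Data frame, one row per cell: `source`, `target`, `median`,
#'   `ipr80`, `fixed`, `final_strength`, `n_responses`.
#' @export
aggregate_grid <- function(responses, fix_threshold = 1.0, pairs = NULL) {
  validate_stage2_responses(responses)
  experts <- unique(responses$expert_id)
  if (length(experts) < 2L) stop("at least 2 experts required", call. = FALSE)
  if (is.null(pairs))
    pairs <- unique(responses[, c("source", "target")])
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$source, pairs$target), , drop = FALSE]
  key <- function(s, t) paste(s, t, sep = "\r")
  rkey <- key(responses$source, responses$target)
  out <- vector("list", nrow(pairs))
  n_missing <- 0L
  for (i in seq_len(nrow(pairs))) {
    rows <- responses[rkey == key(pairs$source[i], pairs$target[i]), , drop = FALSE]
    scores <- rows$score
    absent <- setdiff(experts, rows$expert_id)
    if (length(absent)) {
      scores <- c(scores, rep(0, length(absent)))
      n_missing <- n_missing + length(absent)
    }
    med <- stats::median(scores)
    ipr <- ipr80(scores)
    out[[i]] <- data.frame(
      source = pairs$source[i], target = pairs$target[i],
      median = med, ipr80 = ipr, fixed = ipr <= fix_threshold,
      final_strength = med, n_responses = length(scores),
      stringsAsFactors = FALSE)
  }
  if (n_missing > 0L)
    warning(n_missing, " missing grid cell(s) treated as score 0", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cells lacking consensus, ordered for workshop discussion
#'
#' @param consensus Output of [aggregate_grid()].
#' @return The non-fixed rows sorted by descending `ipr80` (most contested
#'   first; ties by source then target name).
#' @export
contested_cells <- function(consensus) {
  con <- consensus[!consensus$fixed, , drop = FALSE]
  con <- con[order(-con$ipr80, con$source, con$target), , drop = FALSE]
  rownames(con) <- NULL
  con
}

#' Merge workshop re-scores into the online consensus
#'
#' Fixed cells keep their online medians (by protocol they cannot be edited);
#' contested cells are re-aggregated from the workshop responses. A workshop
#' response touching a fixed cell is an error naming the cell.
#'
#' @param online Output of [aggregate_grid()] on the online round.
#' @param workshop_responses Stage 2 response data frame covering (a subset
#'   of) the contested cells.
#' @param fix_threshold Passed to the re-aggregation (default 1).
#' @return Consensus data frame in the same shape as [aggregate_grid()].
#' @export
merge_rounds <- function(online, workshop_responses, fix_threshold = 1.0) {
  if (is.null(workshop_responses) || nrow(workshop_responses) == 0L)
    return(online)
  validate_stage2_responses(workshop_responses)
  okey <- paste(online$source, online$target, sep = "\r")
  wkey <- unique(paste(workshop_responses$source, workshop_responses$target,
                       sep = "\r"))
  unknown <- setdiff(wkey, okey)
  if (length(unknown))
    stop("workshop response for unknown cell(s): ",
         paste(gsub("\r", " -> ", unknown), collapse = ", "), call. = FALSE)
  fixed_hit <- intersect(wkey, okey[online$fixed])
  if (length(fixed_hit))
    stop("workshop response edits fixed cell(s): ",
         paste(gsub("\r", " -> ", fixed_hit), collapse = ", "), call. = FALSE)
  redo <- aggregate_grid(workshop_responses, fix_threshold = fix_threshold)
  rkey <- paste(redo$source, redo$target, sep = "\r")
  out <- online
  for (i in seq_len(nrow(redo))) {
    j <- which(okey == rkey[i])
    out[j, c("median", "ipr80", "fixed", "final_strength", "n_responses")] <-
      redo[i, c("median", "ipr80", "fixed", "final_strength", "n_responses")]
  }
  out
}

#' Keep the strongest relationships and prune isolated variables
#'
#' An edge survives iff `final_strength >= keep_threshold` (default 2:
#' medium-or-stronger under the 0-3 scale, where 1 means only "sometimes a
#' small effect"). Alternatively `top_k` keeps the k strongest cells.
#' Variables left with no incident edge are discarded from the network.
#'
#' @param consensus Consensus data frame (post-workshop merge).
#' @param variables An `eb_varset` covering all cell endpoints.
#' @param skeleton An `eb_skeleton`.
#' @param keep_threshold Minimum `final_strength` for retention (default 2).
#' @param top_k If non-`NULL`, keep the `top_k` strongest cells instead
#'   (ties at the boundary broken by source then target name).
#' @return List: `edges` (data frame `from`, `to`, `strength`), `kept`
#'   (variable names in the network) and `discarded` (isolated names).
#' @export
build_dag <- function(consensus, variables, skeleton = eb_skeleton(),
                      keep_threshold = 2.0, top_k = NULL) {
  if (is.null(top_k)) {
    kept_cells <- consensus[consensus$final_strength >= keep_threshold, ,
                            drop = FALSE]
  } else {
    ord <- order(-consensus$final_strength, consensus$source, consensus$target)
    kept_cells <- utils::head(consensus[ord, , drop = FALSE], top_k)
  }
  edges <- data.frame(from = kept_cells$source, to = kept_cells$target,
                      strength = kept_cells$final_strength,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  if (!check_dag(edges, variables, skeleton))
    stop("kept edges violate the skeleton layering", call. = FALSE)
  touched <- unique(c(edges$from, edges$to))
  all_vars <- names(variables)
  list(edges = edges,
       kept = intersect(all_vars, touched),
       discarded = setdiff(all_vars, touched))
}
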