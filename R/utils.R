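# Small shared helpers: parent-configuration serialization for tabular
# question/answer files, and named substream seeding so every simulated
# response file is independently reproducible from one master seed.

#' Serialize / parse a parent configuration
#'
#' Configurations travel in tabular files as `parent=state` pairs joined by
#' `|`, in the parent order given; a prior variable's configuration is the
#' empty string. `=` and `|` are therefore reserved characters in variable
#' and state names.
#'
#' @param config Named character vector (parent -> state); may be empty.
#' @return Single string.
#' @export
config_to_string <- function(config) {
  if (length(config) == 0L) return("")
  if (any(grepl("[=|]", c(names(config), config))))
    stop("'=' and '|' are reserved in names and states", call. = FALSE)
  paste(paste0(names(config), "=", config), collapse = "|")
}

#' @rdname config_to_string
#' @param s String produced by `config_to_string()`.
#' @export
string_to_config <- function(s) {
  if (is.na(s) || !nzchar(s)) return(stats::setNames(character(), character()))
  parts <- strsplit(s, "|", fixed = TRUE)[[1L]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, character(1), 2L),
                  vapply(kv, `[`, character(1), 1L))
}

# Deterministic 32-bit substream seed derived from a master seed and a text
# label (e.g. "stage3/expert04"), so any expert/stage block is reproducible
# in isolation.
stream_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483562
  as.integer((as.numeric(seed) + h) %% 2147483562) + 1L
}

with_stream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, label))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
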