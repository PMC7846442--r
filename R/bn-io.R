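# Network interchange: XMLBIF 0.3 (via xml2) and the textual BIF dialect.
# Category/kind metadata ride along as PROPERTY entries so a round trip
# reconstructs the full eb_network, CPTs bit-for-bit up to decimal printing
# (17 significant digits, i.e. within 1e-9 and far beyond).

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

# BIF tokens containing characters outside [A-Za-z0-9_.-] are double-quoted.
bif_token <- function(x) {
  need <- grepl("[^A-Za-z0-9_.-]", x)
  x[need] <- paste0('"', gsub('"', '\\\\"', x[need]), '"')
  x
}
bif_untoken <- function(x) {
  q <- grepl('^".*"$', x)
  x[q] <- gsub('\\\\"', '"', substr(x[q], 2L, nchar(x[q]) - 1L))
  x
}

#' Export a network to XMLBIF or BIF
#'
#' Writes the structure, state spaces and CPTs in a standard interchange
#' format; category and kind annotations are carried as properties so that
#' [import_network()] reproduces the original `eb_network`. Table entries
#' follow the canonical ordering: parent configurations row-major (last
#' parent fastest), child states fastest within a configuration.
#'
#' @param network An `eb_network`.
#' @param path Output file path.
#' @param format `"XMLBIF"` (default) or `"BIF"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("XMLBIF", "BIF")) {
  format <- match.arg(format)
  if (format == "XMLBIF") export_xmlbif(network, path) else export_bif(network, path)
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("XMLBIF", "BIF")) {
  format <- match.arg(format)
  if (format == "XMLBIF") import_xmlbif(path) else import_bif(path)
}

export_xmlbif <- function(network, path) {
  doc <- xml2::xml_new_root("BIF", VERSION = "0.3")
  net <- xml2::xml_add_child(doc, "NETWORK")
  xml2::xml_add_child(net, "NAME", "elicited")
  for (nm in names(network$variables)) {
    v <- network$variables[[nm]]
    vn <- xml2::xml_add_child(net, "VARIABLE", TYPE = "nature")
    xml2::xml_add_child(vn, "NAME", nm)
    for (s in v$states) xml2::xml_add_child(vn, "OUTCOME", s)
    xml2::xml_add_child(vn, "PROPERTY", paste0("category = ", v$category))
    xml2::xml_add_child(vn, "PROPERTY", paste0("kind = ", v$kind))
  }
  for (nm in names(network$variables)) {
    cpt <- network$cpts[[nm]]
    dn <- xml2::xml_add_child(net, "DEFINITION")
    xml2::xml_add_child(dn, "FOR", nm)
    for (p in cpt$parents) xml2::xml_add_child(dn, "GIVEN", p)
    xml2::xml_add_child(dn, "TABLE",
                        paste(fmt_num(as.vector(cpt$prob)), collapse = " "))
  }
  xml2::write_xml(doc, path)
}

import_xmlbif <- function(path) {
  doc <- xml2::read_xml(path)
  vars <- list()
  for (vn in xml2::xml_find_all(doc, ".//VARIABLE")) {
    nm <- xml2::xml_text(xml2::xml_find_first(vn, "./NAME"))
    states <- xml2::xml_text(xml2::xml_find_all(vn, "./OUTCOME"))
    props <- xml2::xml_text(xml2::xml_find_all(vn, "./PROPERTY"))
    getp <- function(key, default) {
      hit <- grep(paste0("^", key, " = "), props, value = TRUE)
      if (length(hit)) sub(paste0("^", key, " = "), "", hit[1L]) else default
    }
    kind <- getp("kind", if (length(states) == 2L) "BINARY" else "LABELED")
    vars[[nm]] <- eb_variable(nm, getp("category", "RISK_FACTOR"), kind, states)
  }
  varset <- eb_varset(vars)
  cpts <- list()
  edges <- list()
  for (dn in xml2::xml_find_all(doc, ".//DEFINITION")) {
    child <- xml2::xml_text(xml2::xml_find_first(dn, "./FOR"))
    given <- xml2::xml_text(xml2::xml_find_all(dn, "./GIVEN"))
    vals <- as.numeric(strsplit(trimws(xml2::xml_text(
      xml2::xml_find_first(dn, "./TABLE"))), "\\s+")[[1L]])
    pstates <- stats::setNames(lapply(given, function(p) varset[[p]]$states),
                               given)
    n_states <- length(varset[[child]]$states)
    prob <- matrix(vals, nrow = n_states)
    cpts[[child]] <- eb_cpt(child, varset[[child]]$states, given, pstates, prob)
    if (length(given))
      edges[[length(edges) + 1L]] <- data.frame(from = given, to = child,
                                                stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character())
  eb_network(varset, edges, cpts)
}

export_bif <- function(network, path) {
  lines <- c("network elicited {", "}")
  for (nm in names(network$variables)) {
    v <- network$variables[[nm]]
    lines <- c(lines,
      paste0("variable ", bif_token(nm), " {"),
      sprintf("  type discrete [ %d ] { %s };", length(v$states),
              paste(bif_token(v$states), collapse = ", ")),
      sprintf("  property category %s ;", v$category),
      sprintf("  property kind %s ;", v$kind),
      "}")
  }
  for (nm in names(network$variables)) {
    cpt <- network$cpts[[nm]]
    if (length(cpt$parents) == 0L) {
      lines <- c(lines,
        paste0("probability ( ", bif_token(nm), " ) {"),
        sprintf("  table %s;", paste(fmt_num(cpt$prob[, 1L]), collapse = ", ")),
        "}")
    } else {
      head <- paste0("probability ( ", bif_token(nm), " | ",
                     paste(bif_token(cpt$parents), collapse = ", "), " ) {")
      grid <- cpt_config_grid(cpt$parent_states)
      rows <- vapply(seq_len(nrow(grid)), function(j)
        sprintf("  (%s) %s;",
                paste(bif_token(as.character(grid[j, ])), collapse = ", "),
                paste(fmt_num(cpt$prob[, j]), collapse = ", ")),
        character(1))
      lines <- c(lines, head, rows, "}")
    }
  }
  writeLines(lines, path)
}

# split a comma-separated token list honouring double quotes
bif_split <- function(s) {
  toks <- regmatches(s, gregexpr('"(\\\\"|[^"])*"|[^,()[:space:]]+', s))[[1L]]
  bif_untoken(trimws(toks))
}

# Line-oriented BIF reader (the writer above emits one declaration per line,
# so block structure is unambiguous without a full grammar).
import_bif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vars <- list()
  cpt_raw <- list()
  i <- 1L
  grab_token <- function(s) bif_untoken(
    regmatches(s, regexpr('"(\\\\"|[^"])*"|[^[:space:]{]+', s)))
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "variable ")) {
      nm <- grab_token(sub("^variable\\s+", "", ln))
      states <- character(); category <- "RISK_FACTOR"; kind <- NULL
      repeat {
        i <- i + 1L
        bl <- trimws(lines[i])
        if (bl == "}") break
        if (startsWith(bl, "type discrete")) {
          inner <- sub("^.*\\{", "", sub("\\};\\s*$", "", bl))
          states <- bif_split(inner)
        } else if (startsWith(bl, "property category")) {
          category <- sub(";.*$", "", sub("^property category\\s+", "", bl))
          category <- trimws(category)
        } else if (startsWith(bl, "property kind")) {
          kind <- trimws(sub(";.*$", "", sub("^property kind\\s+", "", bl)))
        }
      }
      if (is.null(kind)) kind <- if (length(states) == 2L) "BINARY" else "LABELED"
      vars[[nm]] <- eb_variable(nm, category, kind, states)
    } else if (startsWith(ln, "probability ")) {
      head <- sub("^probability\\s*\\(", "", sub("\\)\\s*\\{\\s*$", "", ln))
      if (grepl("|", head, fixed = TRUE)) {
        hp <- strsplit(head, "|", fixed = TRUE)[[1L]]
        child <- bif_split(hp[1L]); given <- bif_split(hp[2L])
      } else {
        child <- bif_split(head); given <- character()
      }
      rows <- list(); tab <- NULL
      repeat {
        i <- i + 1L
        bl <- trimws(lines[i])
        if (bl == "}") break
        if (startsWith(bl, "table ")) {
          tab <- as.numeric(bif_split(sub(";\\s*$", "",
                                          sub("^table\\s+", "", bl))))
        } else {
          rp <- regmatches(bl, regexec("^\\(([^)]*)\\)\\s*(.*);\\s*$", bl))[[1L]]
          rows[[length(rows) + 1L]] <- list(cfg = bif_split(rp[2L]),
                                            vals = as.numeric(bif_split(rp[3L])))
        }
      }
      cpt_raw[[child]] <- list(given = given, table = tab, rows = rows)
    }
    i <- i + 1L
  }
  varset <- eb_varset(vars)
  cpts <- list()
  edges <- list()
  for (child in names(cpt_raw)) {
    raw <- cpt_raw[[child]]
    given <- raw$given
    pstates <- stats::setNames(lapply(given, function(p) varset[[p]]$states),
                               given)
    n_states <- length(varset[[child]]$states)
    if (length(given) == 0L) {
      prob <- matrix(raw$table, nrow = n_states)
    } else {
      grid <- cpt_config_grid(pstates)
      prob <- matrix(NA_real_, n_states, nrow(grid))
      for (r in raw$rows) {
        j <- which(apply(grid, 1L, function(g) all(as.character(g) == r$cfg)))
        prob[, j] <- r$vals
      }
      if (anyNA(prob))
        stop("BIF table for '", child, "' missing configurations", call. = FALSE)
      edges[[length(edges) + 1L]] <- data.frame(from = given, to = child,
                                                stringsAsFactors = FALSE)
    }
    cpts[[child]] <- eb_cpt(child, varset[[child]]$states, given, pstates, prob)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character())
  eb_network(varset, edges, cpts)
}
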