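#' Parse an OBO 1.x ontology
#'
#' Reads `[Term]` stanzas: `id`, `name`, `is_a` parent links (trailing
#' `! comment` labels are stripped), and the `is_obsolete` flag.  Other
#' tag lines and other stanza kinds (`[Typedef]`, ...) are ignored.
#' Unresolvable `is_a` references are kept and reported via the
#' `unresolved` field rather than failing, so partial ontology extracts
#' remain loadable.
#'
#' @param text OBO source, as a single string or character vector of lines.
#' @return an object of class `wf_ontology`: `terms` is a map
#'   id -> (id, name, parents, obsolete); `unresolved` lists is_a targets
#'   that do not occur as term ids.
#' @export
parse_obo <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  terms <- list()
  cur <- NULL
  cur_line <- 0L
  in_term <- FALSE
  flush <- function() {
    if (is.null(cur)) return()
    if (is.null(cur$id))
      stop(sprintf("OBO parse error: [Term] stanza starting at line %d has no id",
                   cur_line), call. = FALSE)
    if (!is.null(terms[[cur$id]]))
      stop(sprintf("OBO parse error: duplicate term id '%s'", cur$id),
           call. = FALSE)
    terms[[cur$id]] <<- list(id = cur$id,
                             name = if (is.null(cur$name)) cur$id else cur$name,
                             parents = cur$parents %||% character(),
                             obsolete = isTRUE(cur$obsolete))
    cur <<- NULL
  }
  for (k in seq_along(lines)) {
    ln <- trimws(lines[[k]])
    if (startsWith(ln, "[")) {
      flush()
      in_term <- identical(ln, "[Term]")
      if (in_term) { cur <- list(); cur_line <- k }
      next
    }
    if (!in_term || !nzchar(ln) || startsWith(ln, "!")) next
    m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (!length(m)) next
    tag <- m[2]; val <- trimws(m[3])
    if (tag == "id") cur$id <- val
    else if (tag == "name") cur$name <- val
    else if (tag == "is_a") {
      target <- trimws(sub("\\s*!.*$", "", val))
      cur$parents <- c(cur$parents, target)
    } else if (tag == "is_obsolete") cur$obsolete <- tolower(val) == "true"
  }
  flush()
  ids <- names(terms)
  unresolved <- setdiff(unique(unlist(lapply(terms, `[[`, "parents"))), ids)
  structure(list(terms = terms, unresolved = unresolved),
            class = "wf_ontology")
}

#' @rdname parse_obo
#' @param path path to an `.obo` file.
#' @export
parse_obo_file <- function(path) parse_obo(readLines(path, warn = FALSE))

#' @export
print.wf_ontology <- function(x, ...) {
  nobs <- sum(vapply(x$terms, `[[`, logical(1), "obsolete"))
  cat(sprintf("<ontology> %d term(s) (%d obsolete)%s\n",
              length(x$terms), nobs,
              if (length(x$unresolved))
                sprintf("; %d unresolved is_a target(s)", length(x$unresolved))
              else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# term lookup by id, exact name, or sanitized name; NULL when absent
ontology_find_term <- function(ontology, ref) {
  if (is.null(ref) || is.na(ref)) return(NULL)
  t <- ontology$terms[[ref]]
  if (!is.null(t)) return(t)
  want <- sanitize_term_name(ref)
  for (t in ontology$terms)
    if (identical(sanitize_term_name(t$name), want)) return(t)
  NULL
}
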