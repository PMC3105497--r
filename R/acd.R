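#' Parse an EMBOSS ACD (Ajax Command Definition) tool descriptor
#'
#' Supports the block-structured core of the ACD language: a leading
#' `application: name [ attributes ]` block followed by
#' `section: kind [ ... ] ... endsection: kind` groups whose members are
#' parameter definitions `datatype: name [ attributes ]` (e.g.
#' `seqset: sequences [...]`, `outfile: outfile [...]`).  Attribute
#' values are quoted strings (which may span lines) or bare tokens and
#' are preserved verbatim; repeated keys (notably `relations:`) are
#' collected.  `relations` attribute values are additionally parsed
#' leniently as ontology term references of the form
#' `"EDAM: <id> ! <label>"` (id and label both optional).
#'
#' @param text ACD source, as a single string or character vector of lines.
#' @return an object of class `wf_acd` with fields `application`
#'   (`name`, `attributes`, `relations`) and `sections` (each with `kind`
#'   and `parameters`; every parameter has `name`, `datatype`,
#'   `attributes`, `relations`).
#' @export
parse_acd <- function(text) {
  toks <- acd_tokenize(paste(text, collapse = "\n"))
  i <- 1L
  peek <- function() if (i <= length(toks)) toks[[i]] else NULL
  advance <- function() { t <- toks[[i]]; i <<- i + 1L; t }
  fail <- function(msg, tok = peek()) {
    where <- if (is.null(tok)) "end of file" else sprintf("line %d", tok$line)
    stop(sprintf("ACD parse error at %s: %s", where, msg), call. = FALSE)
  }
  expect <- function(kind, what) {
    t <- peek()
    if (is.null(t) || t$kind != kind) fail(paste("expected", what))
    advance()
  }

  # one `key: value` attribute; value is a string or bare token
  p_attr <- function() {
    key <- expect("word", "attribute name")
    expect("colon", "':'")
    t <- peek()
    if (is.null(t) || !t$kind %in% c("string", "word"))
      fail(sprintf("expected a value for attribute '%s'", key$text))
    list(key = key$text, value = advance()$text)
  }

  p_block <- function() {
    kind <- expect("word", "block kind")
    expect("colon", "':'")
    name <- expect("word", "block name")
    if (tolower(kind$text) == "endsection")     # endsection: name has no body
      return(list(kind = kind$text, name = name$text, attributes = list(),
                  relations = list()))
    expect("lbracket", "'['")
    attrs <- list()
    relations <- list()
    while (!is.null(peek()) && peek()$kind != "rbracket") {
      a <- p_attr()
      if (tolower(a$key) %in% c("relations", "relation")) {
        relations[[length(relations) + 1L]] <- parse_acd_relation(a$value)
      }
      attrs[[a$key]] <- c(attrs[[a$key]], a$value)
    }
    if (is.null(peek())) fail("unbalanced block: missing ']'", toks[[i - 1L]])
    advance()
    list(kind = kind$text, name = name$text, attributes = attrs,
         relations = relations)
  }

  blocks <- list()
  while (!is.null(peek())) blocks[[length(blocks) + 1L]] <- p_block()
  if (!length(blocks) || tolower(blocks[[1L]]$kind) != "application")
    stop("ACD parse error: file must start with an application block",
         call. = FALSE)
  if (sum(vapply(blocks, function(b) tolower(b$kind) == "application",
                 logical(1))) > 1L)
    stop("ACD parse error: multiple application blocks", call. = FALSE)

  app <- blocks[[1L]]
  sections <- list()
  current <- NULL
  param_names <- character()
  for (b in blocks[-1L]) {
    k <- tolower(b$kind)
    if (k == "section") {
      if (!is.null(current))
        sections[[length(sections) + 1L]] <- current
      current <- list(kind = b$name, attributes = b$attributes,
                      parameters = list())
    } else if (k == "endsection") {
      if (is.null(current) || current$kind != b$name)
        stop(sprintf("ACD parse error: endsection '%s' does not match an open section",
                     b$name), call. = FALSE)
      sections[[length(sections) + 1L]] <- current
      current <- NULL
    } else {
      if (b$name %in% param_names)
        stop(sprintf("ACD parse error: duplicate parameter '%s'", b$name),
             call. = FALSE)
      param_names <- c(param_names, b$name)
      param <- list(name = b$name, datatype = b$kind,
                    attributes = b$attributes, relations = b$relations)
      if (is.null(current))
        current <- list(kind = "(none)", attributes = list(),
                        parameters = list())
      current$parameters[[length(current$parameters) + 1L]] <- param
    }
  }
  if (!is.null(current)) sections[[length(sections) + 1L]] <- current

  structure(
    list(application = list(name = app$name, attributes = app$attributes,
                            relations = app$relations),
         sections = sections),
    class = "wf_acd")
}

#' @rdname parse_acd
#' @param path path to a `.acd` file.
#' @export
parse_acd_file <- function(path) {
  doc <- parse_acd(readLines(path, warn = FALSE))
  doc$path <- path
  doc
}

#' @export
print.wf_acd <- function(x, ...) {
  np <- sum(vapply(x$sections, function(s) length(s$parameters), integer(1)))
  cat(sprintf("<acd> application '%s': %d section(s), %d parameter(s)\n",
              x$application$name, length(x$sections), np))
  invisible(x)
}

acd_tokenize <- function(text) {
  toks <- list()
  pos <- 1L
  line <- 1L
  n <- nchar(text)
  push <- function(kind, txt) toks[[length(toks) + 1L]] <<-
    list(kind = kind, text = txt, line = line)
  while (pos <= n) {
    ch <- substr(text, pos, pos)
    if (ch == "\n") { line <- line + 1L; pos <- pos + 1L; next }
    if (grepl("^\\s$", ch)) { pos <- pos + 1L; next }
    if (ch == "#") {                       # comment to end of line
      while (pos <= n && substr(text, pos, pos) != "\n") pos <- pos + 1L
      next
    }
    if (ch == "\"") {
      start_line <- line
      end <- pos + 1L
      while (end <= n && substr(text, end, end) != "\"") {
        if (substr(text, end, end) == "\n") line <- line + 1L
        end <- end + 1L
      }
      if (end > n)
        stop(sprintf("ACD parse error at line %d: unterminated string",
                     start_line), call. = FALSE)
      push("string", substr(text, pos + 1L, end - 1L))
      pos <- end + 1L
      next
    }
    if (ch == "[") { push("lbracket", "["); pos <- pos + 1L; next }
    if (ch == "]") { push("rbracket", "]"); pos <- pos + 1L; next }
    if (ch == ":" || ch == "=") { push("colon", ch); pos <- pos + 1L; next }
    m <- regexpr("^[^\\]\\[:=\"#\\s]+", substr(text, pos, n), perl = TRUE)
    if (m == 1L) {
      len <- attr(m, "match.length")
      push("word", substr(text, pos, pos + len - 1L))
      pos <- pos + len
      next
    }
    stop(sprintf("ACD parse error at line %d: unexpected character '%s'",
                 line, ch), call. = FALSE)
  }
  toks
}

# lenient "EDAM: 0001187 ! Sequence record" -> list(id, label); either part
# may be missing, and ids keep any namespace prefix they came with
parse_acd_relation <- function(value) {
  v <- trimws(value)
  v <- sub("^EDAM:?\\s*", "", v, ignore.case = TRUE)
  id <- NA_character_
  m <- regmatches(v, regexec("^([0-9]{4,})\\s*", v))[[1]]
  if (length(m)) {
    id <- paste0("EDAM:", m[2])
    v <- substr(v, nchar(m[1]) + 1L, nchar(v))
  }
  label <- trimws(sub("^!\\s*", "", v))
  list(id = id, label = if (nzchar(label)) label else NA_character_)
}

# "Sequence record (full)" -> "sequence_record_full"
sanitize_term_name <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}
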