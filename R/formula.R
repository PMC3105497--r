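#' Temporal-logic formulas over service executions
#'
#' Formulas are linear-time temporal logic with finite-trace semantics,
#' extended with taxonomy-aware atomic propositions: `f_exec(name)` holds
#' at a trace position when the service executed there is subsumed by
#' `name` in the service taxonomy (so an abstract service class matches
#' all of its instances), and `f_avail(name)` holds when the state at the
#' position satisfies the type requirement `name`.  `f_end()` holds
#' exactly at the final trace position.  `f_next()` is the strong next
#' (false at the final position); `f_wuntil()` is weak until
#' (`G(p) | p U q`).
#'
#' @param name atom name (service/class name for `f_exec`, type/class name
#'   for `f_avail`).
#' @param x,y subformulas.
#' @return an object of class `wf_formula`.
#' @name formula-constructors
NULL

fnode <- function(op, ...) structure(list(op = op, ...), class = "wf_formula")

#' @rdname formula-constructors
#' @export
f_true <- function() fnode("true")
#' @rdname formula-constructors
#' @export
f_false <- function() fnode("false")
#' @rdname formula-constructors
#' @export
f_end <- function() fnode("end")
#' @rdname formula-constructors
#' @export
f_exec <- function(name) { stopifnot(is.character(name), nzchar(name)); fnode("exec", name = name) }
#' @rdname formula-constructors
#' @export
f_avail <- function(name) { stopifnot(is.character(name), nzchar(name)); fnode("avail", name = name) }
#' @rdname formula-constructors
#' @export
f_not <- function(x) fnode("not", x = as_formula(x))
#' @rdname formula-constructors
#' @export
f_and <- function(x, y) fnode("and", x = as_formula(x), y = as_formula(y))
#' @rdname formula-constructors
#' @export
f_or <- function(x, y) fnode("or", x = as_formula(x), y = as_formula(y))
#' @rdname formula-constructors
#' @export
f_implies <- function(x, y) fnode("implies", x = as_formula(x), y = as_formula(y))
#' @rdname formula-constructors
#' @export
f_next <- function(x) fnode("next", x = as_formula(x))
#' @rdname formula-constructors
#' @export
f_eventually <- function(x) fnode("eventually", x = as_formula(x))
#' @rdname formula-constructors
#' @export
f_globally <- function(x) fnode("globally", x = as_formula(x))
#' @rdname formula-constructors
#' @export
f_until <- function(x, y) fnode("until", x = as_formula(x), y = as_formula(y))
#' @rdname formula-constructors
#' @export
f_wuntil <- function(x, y) fnode("wuntil", x = as_formula(x), y = as_formula(y))

as_formula <- function(x) {
  if (inherits(x, "wf_formula")) return(x)
  stop("expected a wf_formula", call. = FALSE)
}

#' Conjoin an ordered collection of formulas
#'
#' Right-folded conjunction; the empty collection yields `f_true()`.
#' Used to combine the global domain constraints with the per-branch
#' constraints into the single specification formula handed to the
#' synthesis search.
#'
#' @param formulas list of `wf_formula` objects.
#' @return a `wf_formula`.
#' @export
conjoin <- function(formulas) {
  if (!length(formulas)) return(f_true())
  formulas <- lapply(formulas, as_formula)
  Reduce(f_and, formulas, right = TRUE)
}

#' Render a formula as parseable text
#'
#' Produces the ASCII infix syntax accepted by [parse_pltl()]:
#' `! & | =>` for the boolean connectives, `X F G U WU` for the
#' modalities, `true`/`false`/`end` for the constants, bare identifiers
#' for service-execution atoms and `avail(name)` for type-availability
#' atoms.  `parse_pltl(render_formula(f))` is structurally identical to
#' `f`.
#'
#' @param f a `wf_formula`.
#' @return character scalar.
#' @export
render_formula <- function(f) {
  stopifnot(inherits(f, "wf_formula"))
  wrap <- function(g) {
    r <- render_formula(g)
    if (g$op %in% c("true", "false", "end", "exec", "avail")) r
    else paste0("(", r, ")")
  }
  switch(f$op,
    "true" = "true", "false" = "false", "end" = "end",
    exec = f$name,
    avail = paste0("avail(", f$name, ")"),
    not = paste0("! ", wrap(f$x)),
    "next" = paste0("X ", wrap(f$x)),
    eventually = paste0("F ", wrap(f$x)),
    globally = paste0("G ", wrap(f$x)),
    and = paste0("(", render_formula(f$x), " & ", render_formula(f$y), ")"),
    or = paste0("(", render_formula(f$x), " | ", render_formula(f$y), ")"),
    implies = paste0("(", render_formula(f$x), " => ", render_formula(f$y), ")"),
    until = paste0("(", render_formula(f$x), " U ", render_formula(f$y), ")"),
    wuntil = paste0("(", render_formula(f$x), " WU ", render_formula(f$y), ")"),
    stop("unknown formula op: ", f$op))
}

#' @export
print.wf_formula <- function(x, ...) {
  cat("<formula>", render_formula(x), "\n")
  invisible(x)
}

#' @export
format.wf_formula <- function(x, ...) render_formula(x)

# ---- parser -----------------------------------------------------------------

pltl_tokenize <- function(text) {
  pats <- c(ws = "\\s+", lpar = "\\(", rpar = "\\)",
            implies = "=>", and = "&&?", or = "\\|\\|?", not = "[!~]",
            ident = "[A-Za-z_][A-Za-z0-9_.:-]*")
  toks <- list()
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    hit <- FALSE
    for (k in names(pats)) {
      m <- regexpr(paste0("^(", pats[[k]], ")"), substr(text, pos, n))
      if (m == 1L) {
        len <- attr(m, "match.length")
        if (k != "ws")
          toks[[length(toks) + 1L]] <- list(kind = k,
                                            text = substr(text, pos, pos + len - 1L),
                                            pos = pos)
        pos <- pos + len
        hit <- TRUE
        break
      }
    }
    if (!hit)
      stop(sprintf("formula syntax error at position %d: unexpected '%s'",
                   pos, substr(text, pos, pos)), call. = FALSE)
  }
  # reclassify reserved identifiers
  for (i in seq_along(toks)) {
    if (toks[[i]]$kind == "ident") {
      kw <- switch(toks[[i]]$text,
                   U = "until", WU = "wuntil", X = "next", F = "nextF",
                   G = "globally", true = "true", false = "false",
                   end = "end", avail = "avail", NULL)
      if (!is.null(kw)) toks[[i]]$kind <- if (kw == "nextF") "eventually" else kw
    }
  }
  toks
}

#' Parse a temporal-logic formula from text
#'
#' Grammar (loosest binding first): `=>` (right-associative), `|`, `&`,
#' `U`/`WU` (right-associative), then the unary operators `!  X F G`, then
#' atoms: `true`, `false`, `end`, `avail(name)`, parentheses, and bare
#' identifiers, which denote service-execution atoms (a name may be a
#' concrete service or an abstract service class; matching is by taxonomy
#' subsumption at evaluation time).
#'
#' @param text formula text, e.g.
#'   `"ehmmbuild => (!ehmmemit WU ehmmcalibrate)"`.
#' @return a `wf_formula`.
#' @export
parse_pltl <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- pltl_tokenize(text)
  i <- 1L
  peek <- function() if (i <= length(toks)) toks[[i]] else NULL
  advance <- function() { t <- toks[[i]]; i <<- i + 1L; t }
  fail <- function(msg) {
    t <- peek()
    where <- if (is.null(t)) "end of input" else sprintf("position %d ('%s')", t$pos, t$text)
    stop(sprintf("formula syntax error at %s: %s", where, msg), call. = FALSE)
  }
  expect <- function(kind, what) {
    t <- peek()
    if (is.null(t) || t$kind != kind) fail(paste("expected", what))
    advance()
  }

  p_implies <- function() {
    l <- p_or()
    if (!is.null(peek()) && peek()$kind == "implies") {
      advance()
      l <- f_implies(l, p_implies())
    }
    l
  }
  p_or <- function() {
    l <- p_and()
    while (!is.null(peek()) && peek()$kind == "or") {
      advance()
      l <- f_or(l, p_and())
    }
    l
  }
  p_and <- function() {
    l <- p_until()
    while (!is.null(peek()) && peek()$kind == "and") {
      advance()
      l <- f_and(l, p_until())
    }
    l
  }
  p_until <- function() {
    l <- p_unary()
    t <- peek()
    if (!is.null(t) && t$kind %in% c("until", "wuntil")) {
      advance()
      r <- p_until()
      l <- if (t$kind == "until") f_until(l, r) else f_wuntil(l, r)
    }
    l
  }
  p_unary <- function() {
    t <- peek()
    if (is.null(t)) fail("expected a formula")
    switch(t$kind,
      not = { advance(); f_not(p_unary()) },
      "next" = { advance(); f_next(p_unary()) },
      eventually = { advance(); f_eventually(p_unary()) },
      globally = { advance(); f_globally(p_unary()) },
      p_primary())
  }
  p_primary <- function() {
    t <- peek()
    if (is.null(t)) fail("expected a formula")
    switch(t$kind,
      lpar = { advance(); r <- p_implies(); expect("rpar", "')'"); r },
      "true" = { advance(); f_true() },
      "false" = { advance(); f_false() },
      end = { advance(); f_end() },
      avail = {
        advance(); expect("lpar", "'(' after avail")
        nm <- expect("ident", "type name")
        expect("rpar", "')'")
        f_avail(nm$text)
      },
      ident = { f_exec(advance()$text) },
      fail("unexpected token"))
  }

  out <- p_implies()
  if (!is.null(peek())) fail("trailing input")
  out
}

# ---- simplification ---------------------------------------------------------

is_true <- function(f) f$op == "true"
is_false <- function(f) f$op == "false"

# constant folding + idempotence; keeps formulas canonical enough that
# progression residues can be keyed by their rendered text
simplify_formula <- function(f) {
  s <- function(g) simplify_formula(g)
  switch(f$op,
    not = {
      x <- s(f$x)
      if (is_true(x)) f_false()
      else if (is_false(x)) f_true()
      else if (x$op == "not") x$x
      else f_not(x)
    },
    and = {
      x <- s(f$x); y <- s(f$y)
      if (is_false(x) || is_false(y)) f_false()
      else if (is_true(x)) y
      else if (is_true(y)) x
      else if (identical(x, y)) x
      else f_and(x, y)
    },
    or = {
      x <- s(f$x); y <- s(f$y)
      if (is_true(x) || is_true(y)) f_true()
      else if (is_false(x)) y
      else if (is_false(y)) x
      else if (identical(x, y)) x
      else f_or(x, y)
    },
    implies = {
      x <- s(f$x); y <- s(f$y)
      if (is_false(x) || is_true(y)) f_true()
      else if (is_true(x)) y
      else if (is_false(y)) f_not(x)
      else f_implies(x, y)
    },
    "next" = f_next(s(f$x)),   # X true is satisfiable only off the last position
    eventually = {
      x <- s(f$x)
      if (is_true(x) || is_false(x)) x else f_eventually(x)
    },
    globally = {
      x <- s(f$x)
      if (is_true(x) || is_false(x)) x else f_globally(x)
    },
    until = {
      x <- s(f$x); y <- s(f$y)
      if (is_true(y) || is_false(y)) y
      else if (is_false(x)) y
      else f_until(x, y)
    },
    wuntil = {
      x <- s(f$x); y <- s(f$y)
      if (is_true(y)) f_true()
      else if (is_true(x)) f_true()
      else if (is_false(y) && is_false(x)) f_false()
      else if (is_false(y)) f_globally(x)
      else if (is_false(x)) y
      else f_wuntil(x, y)
    },
    f)
}

# every atom name used in a formula, split by atom kind
formula_atoms <- function(f) {
  out <- list(exec = character(), avail = character())
  walk <- function(g) {
    if (g$op == "exec") out$exec <<- c(out$exec, g$name)
    if (g$op == "avail") out$avail <<- c(out$avail, g$name)
    if (!is.null(g$x)) walk(g$x)
    if (!is.null(g$y)) walk(g$y)
  }
  walk(f)
  lapply(out, unique)
}
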