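#' Natural-language constraint templates
#'
#' Constraints on synthesized service sequences are written as short
#' natural-language sentences rather than raw temporal logic.  Supported
#' templates (names may be concrete services or abstract service-taxonomy
#' classes; class names match all their instances by subsumption):
#'
#' * `"Enforce the use of module <X>"` -- `F exec(X)`
#' * `"Use <X> as last service in solution"` -- `F (exec(X) & X end)`
#' * `"Do not use <X>"` -- `G ! exec(X)`
#' * `"Use <A> before <B>"` -- `! exec(B) WU exec(A)`
#'
#' The named service or class must exist in the domain's service taxonomy;
#' otherwise the error lists the nearest known names.
#'
#' @param text a template sentence.
#' @param domain the `wf_domain` whose service taxonomy resolves the names.
#' @return a `wf_formula`.
#' @export
template_to_formula <- function(text, domain) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  known <- taxonomy_names(domain$service_taxonomy)
  resolve <- function(nm) {
    nm <- trimws(nm)
    if (!nm %in% known) {
      d <- utils::adist(nm, known, ignore.case = TRUE)
      near <- known[order(d)][seq_len(min(3L, length(known)))]
      stop(sprintf(
        "constraint names unknown service or class '%s'; nearest known names: %s",
        nm, paste(near, collapse = ", ")), call. = FALSE)
    }
    nm
  }
  m <- regmatches(txt, regexec(
    "^Enforce the use of (?:module|service)\\s+(\\S+)$", txt, ignore.case = TRUE))[[1]]
  if (length(m)) return(f_eventually(f_exec(resolve(m[2]))))
  m <- regmatches(txt, regexec(
    "^Use\\s+(\\S+)\\s+as last service in solution$", txt, ignore.case = TRUE))[[1]]
  if (length(m)) return(f_eventually(f_and(f_exec(resolve(m[2])), f_next(f_end()))))
  m <- regmatches(txt, regexec(
    "^Do not use\\s+(\\S+)$", txt, ignore.case = TRUE))[[1]]
  if (length(m)) return(f_globally(f_not(f_exec(resolve(m[2])))))
  m <- regmatches(txt, regexec(
    "^Use\\s+(\\S+)\\s+before\\s+(\\S+)$", txt, ignore.case = TRUE))[[1]]
  if (length(m)) return(f_wuntil(f_not(f_exec(resolve(m[3]))), f_exec(resolve(m[2]))))
  stop(sprintf("unrecognized constraint template: '%s'", text), call. = FALSE)
}

#' Render a template formula back to its sentence
#'
#' Inverse of [template_to_formula()] for formulas having exactly one of
#' the four supported template shapes; re-parsing the returned sentence
#' yields a structurally identical formula.
#'
#' @param f a `wf_formula` in template shape.
#' @return character scalar.
#' @export
formula_to_template <- function(f) {
  stopifnot(inherits(f, "wf_formula"))
  if (f$op == "eventually" && f$x$op == "exec")
    return(sprintf("Enforce the use of module %s", f$x$name))
  if (f$op == "eventually" && f$x$op == "and" &&
      f$x$x$op == "exec" && f$x$y$op == "next" && f$x$y$x$op == "end")
    return(sprintf("Use %s as last service in solution", f$x$x$name))
  if (f$op == "globally" && f$x$op == "not" && f$x$x$op == "exec")
    return(sprintf("Do not use %s", f$x$x$name))
  if (f$op == "wuntil" && f$x$op == "not" && f$x$x$op == "exec" &&
      f$y$op == "exec")
    return(sprintf("Use %s before %s", f$y$name, f$x$x$name))
  stop("formula does not match any supported template shape", call. = FALSE)
}
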