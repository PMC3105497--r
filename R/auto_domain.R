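#' Build a taxonomy skeleton from an ontology
#'
#' Extracts the non-obsolete terms reachable downward from the given root
#' terms, names the classes by their sanitized term names (lowercase,
#' non-alphanumerics collapsed to underscores), copies the `is_a` edges,
#' and roots the result at a fresh most-general class above the given
#' roots.  Obsolete terms (and anything only reachable through them) are
#' excluded.  With an empty root set the result contains only the root
#' class.
#'
#' @param ontology a `wf_ontology` ([parse_obo()]).
#' @param roots character vector of term ids to grow the skeleton from.
#' @param root_class name of the most-general class of the new taxonomy.
#' @return a `wf_taxonomy`.
#' @export
taxonomy_from_ontology <- function(ontology, roots, root_class = "Thing") {
  stopifnot(inherits(ontology, "wf_ontology"))
  unknown <- setdiff(roots, names(ontology$terms))
  if (length(unknown))
    stop("unknown root term id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  live <- Filter(function(t) !t$obsolete, ontology$terms)
  children <- list()
  for (t in live)
    for (p in t$parents)
      children[[p]] <- c(children[[p]], t$id)
  keep <- character()
  queue <- roots
  while (length(queue)) {
    id <- queue[[1L]]; queue <- queue[-1L]
    if (id %in% keep || is.null(live[[id]])) next
    keep <- c(keep, id)
    queue <- c(queue, children[[id]])
  }
  class_name <- vapply(keep, function(id) sanitize_term_name(live[[id]]$name),
                       character(1))
  classes <- list()
  for (id in keep) {
    nm <- class_name[[id]]
    up <- intersect(live[[id]]$parents, keep)
    parents <- if (id %in% roots || !length(up)) root_class
               else unique(class_name[up])
    classes[[nm]] <- sort(unique(c(classes[[nm]], parents)))
  }
  taxonomy(root_class, classes = classes)
}

default_root_terms <- function(ontology, name) {
  hit <- Filter(function(t) !t$obsolete &&
                  identical(sanitize_term_name(t$name), name),
                ontology$terms)
  vapply(hit, `[[`, character(1), "id")
}

acd_sections_of <- function(acd, kind) {
  Filter(function(s) identical(tolower(s$kind), kind), acd$sections)
}

acd_parameters_of <- function(acd, kind) {
  unlist(lapply(acd_sections_of(acd, kind), `[[`, "parameters"),
         recursive = FALSE)
}

first_attr <- function(attributes, key) {
  v <- attributes[[key]]
  if (is.null(v)) NA_character_ else v[[1L]]
}

# resolve a parsed relation (id + label) against the ontology
resolve_relation <- function(rel, ontology) {
  t <- ontology_find_term(ontology, rel$id)
  if (is.null(t)) t <- ontology_find_term(ontology, rel$label)
  t
}

#' Derive a domain model from ACD descriptors and an ontology
#'
#' Reproduces the automatic domain setup: (1) taxonomy skeletons are
#' grown from the ontology's data and operation branches
#' ([taxonomy_from_ontology()]); (2) one service per ACD application,
#' with input types from input-section parameters and output types from
#' output-section parameters (sections `required`, `additional` and
#' `advanced` contribute no types); (3) derived types and services are
#' linked to their annotated ontology terms, and entities without usable
#' annotations become direct instances of the root class.
#'
#' Input parameters are typed by their annotated term's class name (an
#' unresolvable annotation contributes a class directly under the root;
#' an unannotated input parameter is named `<app>_<param>_input`).
#' Output parameters are named, in order of precedence, by their
#' sanitized `knowntype` attribute, by their annotated term when that
#' term is a leaf class of the data skeleton, or by the pattern
#' `<app>_<param>_output`; pattern- and knowntype-named outputs become
#' instances of their annotated term's class when one resolves, else of
#' the root.  Services are placed under the class of their first
#' application relation when it resolves, else directly under the root.
#'
#' @param acds list of `wf_acd` documents ([parse_acd()]).
#' @param ontology a `wf_ontology`.
#' @param type_roots,service_roots term ids for the data and operation
#'   branches; by default the terms named `data` and `operation`.
#' @return a `wf_domain` that passes [validate_domain()] cleanly.
#' @export
build_auto_domain <- function(acds, ontology,
                              type_roots = NULL, service_roots = NULL) {
  stopifnot(inherits(ontology, "wf_ontology"))
  if (inherits(acds, "wf_acd")) acds <- list(acds)
  if (is.null(type_roots)) type_roots <- default_root_terms(ontology, "data")
  if (is.null(service_roots)) service_roots <- default_root_terms(ontology, "operation")
  ttx <- taxonomy_from_ontology(ontology, type_roots)
  stx <- taxonomy_from_ontology(ontology, service_roots)

  type_classes <- taxonomy_classes(ttx)
  has_child <- unique(unlist(ttx$classes, use.names = FALSE))
  extra_type_classes <- list()
  type_instances <- list()
  service_instances <- list()
  services <- list()

  type_for_input <- function(app, param) {
    if (length(param$relations)) {
      rel <- param$relations[[1L]]
      term <- resolve_relation(rel, ontology)
      nm <- if (!is.null(term)) sanitize_term_name(term$name)
            else sanitize_term_name(if (is.na(rel$label)) rel$id else rel$label)
      if (!nm %in% c(type_classes, names(extra_type_classes)))
        extra_type_classes[[nm]] <<- ttx$root
      return(nm)
    }
    nm <- sprintf("%s_%s_input", app, param$name)
    if (is.null(type_instances[[nm]])) type_instances[[nm]] <<- character()
    nm
  }

  type_for_output <- function(app, param) {
    term <- if (length(param$relations))
      resolve_relation(param$relations[[1L]], ontology) else NULL
    term_class <- if (!is.null(term)) sanitize_term_name(term$name) else NULL
    knowntype <- first_attr(param$attributes, "knowntype")
    nm <- if (!is.na(knowntype)) {
      sanitize_term_name(knowntype)
    } else if (!is.null(term_class) && term_class %in% type_classes &&
               !term_class %in% has_child) {
      return(term_class)                   # leaf data term used directly
    } else {
      sprintf("%s_%s_output", app, param$name)
    }
    parents <- if (!is.null(term_class) && term_class %in% type_classes)
      term_class else character()
    type_instances[[nm]] <<- sort(unique(c(type_instances[[nm]], parents)))
    nm
  }

  for (acd in acds) {
    app <- acd$application$name
    inputs <- vapply(acd_parameters_of(acd, "input") %||% list(),
                     function(p) type_for_input(app, p), character(1))
    outputs <- vapply(acd_parameters_of(acd, "output") %||% list(),
                      function(p) type_for_output(app, p), character(1))
    services[[length(services) + 1L]] <-
      service_spec(app, inputs = inputs, outputs = outputs,
                   description = first_attr(acd$application$attributes,
                                            "documentation"))
    placement <- character()
    if (length(acd$application$relations)) {
      term <- resolve_relation(acd$application$relations[[1L]], ontology)
      if (!is.null(term)) {
        cl <- sanitize_term_name(term$name)
        if (cl %in% taxonomy_classes(stx)) placement <- cl
      }
    }
    service_instances[[app]] <- placement
  }

  ttx_full <- taxonomy(ttx$root,
                       classes = c(ttx$classes, extra_type_classes),
                       instances = type_instances)
  stx_full <- taxonomy(stx$root, classes = stx$classes,
                       instances = service_instances)
  domain_model(services, type_taxonomy = ttx_full,
               service_taxonomy = stx_full)
}

#' Annotation-coverage statistics over a collection of ACD files
#'
#' Summarizes how thoroughly a set of tool descriptors is annotated with
#' ontology-term relations: the share of files carrying any relation,
#' application-level relations, or parameter-level relations; the share
#' of parameters (over all sections) carrying a relation; and the
#' per-file counts of application and parameter relations (minimum,
#' maximum, mean over the files that have any).
#'
#' @param acds list of `wf_acd` documents.
#' @return an object of class `wf_annotation_stats`.
#' @export
annotation_stats <- function(acds) {
  if (inherits(acds, "wf_acd")) acds <- list(acds)
  n <- length(acds)
  pct <- function(k, total) if (total > 0) 100 * k / total else 0
  app_counts <- integer(n)
  par_counts <- integer(n)
  n_params <- 0L
  n_params_rel <- 0L
  for (i in seq_along(acds)) {
    acd <- acds[[i]]
    app_counts[[i]] <- length(acd$application$relations)
    pars <- unlist(lapply(acd$sections, `[[`, "parameters"), recursive = FALSE)
    n_params <- n_params + length(pars)
    with_rel <- vapply(pars %||% list(),
                       function(p) length(p$relations) > 0L, logical(1))
    n_params_rel <- n_params_rel + sum(with_rel)
    par_counts[[i]] <- sum(vapply(pars %||% list(),
                                  function(p) length(p$relations), integer(1)))
  }
  summ <- function(x) {
    x <- x[x > 0L]
    if (!length(x)) list(min = 0L, max = 0L, mean = 0)
    else list(min = min(x), max = max(x), mean = mean(x))
  }
  structure(
    list(n_files = n,
         pct_files_with_any_relation = pct(sum(app_counts + par_counts > 0L), n),
         pct_files_with_application_relation = pct(sum(app_counts > 0L), n),
         pct_files_with_parameter_relation = pct(sum(par_counts > 0L), n),
         pct_parameters_with_relation = pct(n_params_rel, n_params),
         application_relations_per_file = summ(app_counts),
         parameter_relations_per_file = summ(par_counts)),
    class = "wf_annotation_stats")
}

#' @export
print.wf_annotation_stats <- function(x, ...) {
  cat(sprintf("<annotation stats> %d file(s)\n", x$n_files))
  cat(sprintf("  files with any relation:          %5.1f%%\n",
              x$pct_files_with_any_relation))
  cat(sprintf("  files with application relation:  %5.1f%%\n",
              x$pct_files_with_application_relation))
  cat(sprintf("  files with parameter relation:    %5.1f%%\n",
              x$pct_files_with_parameter_relation))
  cat(sprintf("  parameters with relation:         %5.1f%%\n",
              x$pct_parameters_with_relation))
  a <- x$application_relations_per_file
  p <- x$parameter_relations_per_file
  cat(sprintf("  application relations per file:   min %d / max %d / mean %.1f\n",
              a$min, a$max, a$mean))
  cat(sprintf("  parameter relations per file:     min %d / max %d / mean %.1f\n",
              p$min, p$max, p$mean))
  invisible(x)
}
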