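#' Describe a service by its symbolic input and output types
#'
#' Services are characterized purely symbolically: a set of mandatory input
#' type names that must all be available before the service can run, and a
#' set of output type names it adds to the pool of available data.  Sources
#' (e.g. a random-sequence generator) have empty inputs; sinks (e.g. a
#' pretty-printer) have empty outputs.
#'
#' @param name service name (non-empty, no whitespace).
#' @param inputs,outputs character vectors of type names; duplicates are
#'   dropped and the sets stored sorted.
#' @param description free-text description.
#' @return an object of class `wf_service`.
#' @export
service_spec <- function(name, inputs = character(), outputs = character(),
                         description = "") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!nzchar(name) || grepl("\\s", name))
    stop("service name must be a non-empty token without whitespace",
         call. = FALSE)
  structure(
    list(name = name,
         inputs = sort(unique(as.character(inputs))),
         outputs = sort(unique(as.character(outputs))),
         description = as.character(description)[1L]),
    class = "wf_service")
}

#' @export
print.wf_service <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(v, collapse = ", ") else "-"
  cat(sprintf("<service> %s: %s -> %s\n", x$name, fmt(x$inputs), fmt(x$outputs)))
  invisible(x)
}

#' Assemble a domain model
#'
#' A domain model bundles everything the synthesis and verification
#' machinery needs to know about a service collection: the service
#' input/output descriptions, a type taxonomy classifying the data types,
#' a service taxonomy classifying the services into abstract groups, and
#' an ordered list of global constraint strings (template sentences applied
#' to every synthesis run in the domain).
#'
#' Every service must appear in the service taxonomy and every referenced
#' type name in the type taxonomy; [domain_model()] attaches missing names
#' as direct instances of the respective root rather than failing, mirroring
#' how automatically derived domains place unannotated entities directly
#' under the generic root class.
#'
#' @param services list of [service_spec()] objects (or a named list).
#' @param type_taxonomy,service_taxonomy `wf_taxonomy` objects.
#' @param constraints character vector of global constraint template strings.
#' @return an object of class `wf_domain`.
#' @export
domain_model <- function(services,
                         type_taxonomy = taxonomy("Thing"),
                         service_taxonomy = taxonomy("Thing"),
                         constraints = character()) {
  stopifnot(inherits(type_taxonomy, "wf_taxonomy"),
            inherits(service_taxonomy, "wf_taxonomy"))
  if (inherits(services, "wf_service")) services <- list(services)
  ok <- vapply(services, inherits, logical(1), "wf_service")
  if (!all(ok)) stop("all services must be service_spec() objects", call. = FALSE)
  nms <- vapply(services, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate service name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  services <- stats::setNames(services, nms)[order(nms)]

  # attach unlisted services / types directly under the root
  add_missing <- function(tx, missing) {
    if (!length(missing)) return(tx)
    inst <- tx$instances
    for (m in missing) inst[[m]] <- character()
    taxonomy(tx$root, tx$classes, inst)
  }
  service_taxonomy <- add_missing(
    service_taxonomy, setdiff(nms, taxonomy_names(service_taxonomy)))
  used_types <- sort(unique(unlist(lapply(services, function(s)
    c(s$inputs, s$outputs)), use.names = FALSE)))
  type_taxonomy <- add_missing(
    type_taxonomy, setdiff(used_types, taxonomy_names(type_taxonomy)))

  structure(
    list(services = services,
         type_taxonomy = type_taxonomy,
         service_taxonomy = service_taxonomy,
         constraints = as.character(constraints)),
    class = "wf_domain")
}

#' @export
print.wf_domain <- function(x, ...) {
  cat(sprintf("<domain> %d services, %d type names, %d service-taxonomy names, %d global constraints\n",
              length(x$services), length(taxonomy_names(x$type_taxonomy)),
              length(taxonomy_names(x$service_taxonomy)), length(x$constraints)))
  invisible(x)
}

domain_service <- function(domain, name) {
  svc <- domain$services[[name]]
  if (is.null(svc))
    stop(sprintf("unknown service '%s' in domain", name), call. = FALSE)
  svc
}

#' Execution states: sets of available type names
#'
#' A state of the configuration universe is simply the set of type names
#' currently available.  States are stored as sorted unique character
#' vectors; executing a service adds its outputs, so states only ever grow
#' along an execution.
#'
#' @param types character vector of type names.
#' @return sorted unique character vector (a state).
#' @export
state <- function(types = character()) sort(unique(as.character(types)))

#' Does an available-type state satisfy a required type?
#'
#' A requirement may be a concrete type name (satisfied only by itself) or
#' an abstract class (satisfied by any member it subsumes).  A member `t`
#' of the state satisfies requirement `required` when
#' `subsumes(taxonomy, required, t)` holds.
#'
#' @param st a [state()] (character vector of type names).
#' @param required the required type or class name.
#' @param tx the type taxonomy.
#' @return logical scalar.
#' @export
satisfies_requirement <- function(st, required, tx) {
  taxonomy_lookup(tx, required, "type taxonomy")
  for (t in st) if (subsumes(tx, required, t)) return(TRUE)
  FALSE
}

#' Is a service applicable in a state?
#'
#' True iff every declared input requirement of the service is satisfied by
#' some available type in the state (subset check lifted through taxonomy
#' subsumption).  A service with no inputs is applicable everywhere.
#'
#' @param service a [service_spec()] or a service name (resolved in `domain`).
#' @param st a [state()].
#' @param domain the `wf_domain` supplying taxonomies (and name resolution).
#' @return logical scalar.
#' @export
applicable <- function(service, st, domain) {
  if (is.character(service)) service <- domain_service(domain, service)
  for (req in service$inputs)
    if (!satisfies_requirement(st, req, domain$type_taxonomy)) return(FALSE)
  TRUE
}

#' Execute a service: the successor state
#'
#' The successor state is the union of the current state and the service's
#' output types.  It is a contract violation to apply a service that is not
#' applicable in `st`.
#'
#' @inheritParams applicable
#' @return the successor [state()].
#' @export
successor <- function(st, service, domain) {
  if (is.character(service)) service <- domain_service(domain, service)
  if (!applicable(service, st, domain))
    stop(sprintf("service '%s' is not applicable in state {%s}",
                 service$name, paste(st, collapse = ", ")), call. = FALSE)
  state(c(st, service$outputs))
}

#' Diagnose structural problems in a domain model
#'
#' Collects diagnostics rather than raising errors: taxonomy `is-a` cycles,
#' unresolved taxonomy parent references, type names used by services but
#' unknown to the type taxonomy, services missing from the service
#' taxonomy, and (only when explicit start states are supplied) services
#' that can never become applicable from any of those starts.
#'
#' @param domain a `wf_domain`.
#' @param starts optional list of start [state()]s; enables the
#'   reachability check.
#' @return data.frame with columns `code` and `message`; zero rows iff the
#'   domain is well-formed.
#' @export
validate_domain <- function(domain, starts = NULL) {
  stopifnot(inherits(domain, "wf_domain"))
  diags <- list()
  note <- function(code, message)
    diags[[length(diags) + 1L]] <<- data.frame(code = code, message = message)

  for (side in c("type_taxonomy", "service_taxonomy")) {
    tx <- domain[[side]]
    for (cy in taxonomy_cycles(tx))
      note("cycle", sprintf("%s: is-a cycle %s", side, paste(cy, collapse = " -> ")))
    for (u in tx$unknown_parents)
      note("unknown_parent", sprintf("%s: parent class '%s' is not declared", side, u))
  }

  ttx_names <- taxonomy_names(domain$type_taxonomy)
  stx_names <- taxonomy_names(domain$service_taxonomy)
  for (svc in domain$services) {
    for (t in setdiff(c(svc$inputs, svc$outputs), ttx_names))
      note("unknown_type", sprintf("service '%s' references unknown type '%s'",
                                   svc$name, t))
    if (!svc$name %in% stx_names)
      note("unlisted_service",
           sprintf("service '%s' missing from the service taxonomy", svc$name))
  }

  if (!is.null(starts) && !length(diags)) {
    if (is.character(starts)) starts <- list(starts)
    reach <- function(st) {
      repeat {
        grown <- st
        for (svc in domain$services)
          if (applicable(svc, grown, domain))
            grown <- state(c(grown, svc$outputs))
        if (identical(grown, st)) return(st)
        st <- grown
      }
    }
    closures <- lapply(starts, function(s) reach(state(s)))
    for (svc in domain$services) {
      ok <- any(vapply(closures, function(cl) applicable(svc, cl, domain),
                       logical(1)))
      if (!ok)
        note("unreachable_service",
             sprintf("service '%s' is never applicable from any declared start",
                     svc$name))
    }
  }

  if (!length(diags))
    return(data.frame(code = character(), message = character()))
  out <- do.call(rbind, diags)
  rownames(out) <- NULL
  out
}
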