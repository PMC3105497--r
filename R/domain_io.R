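#' Read and write domain models in the canonical YAML format
#'
#' The canonical on-disk representation of a domain model is a single YAML
#' document with sections `types` (all type names, informational),
#' `services` (name -> inputs/outputs/description), `type_taxonomy` and
#' `service_taxonomy` (root, classes with their is-a parents, instances
#' with their instance-of parents), and `constraints` (ordered global
#' constraint strings).  `read_domain(write_domain(d))` reproduces `d`
#' structurally.
#'
#' @param path file path.
#' @return `read_domain()`: a `wf_domain`.  `write_domain()`: `path`,
#'   invisibly.
#' @export
read_domain <- function(path) {
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop(sprintf(
                    "failed to parse domain file '%s': %s",
                    path, conditionMessage(e)), call. = FALSE))
  domain_from_list(doc, where = path)
}

domain_from_list <- function(doc, where = "domain document") {
  need <- c("services", "type_taxonomy", "service_taxonomy")
  missing <- setdiff(need, names(doc))
  if (length(missing))
    stop(sprintf("%s: missing section(s): %s", where,
                 paste(missing, collapse = ", ")), call. = FALSE)
  tax_from <- function(sec, label) {
    if (is.null(sec$root))
      stop(sprintf("%s: %s has no root", where, label), call. = FALSE)
    taxonomy(sec$root,
             classes = lapply(as_yaml_map(sec$classes), as.character),
             instances = lapply(as_yaml_map(sec$instances), as.character))
  }
  services <- lapply(names(as_yaml_map(doc$services)), function(nm) {
    s <- doc$services[[nm]]
    service_spec(nm,
                 inputs = as.character(unlist(s$inputs)),
                 outputs = as.character(unlist(s$outputs)),
                 description = if (is.null(s$description)) "" else s$description)
  })
  domain_model(services,
               type_taxonomy = tax_from(doc$type_taxonomy, "type_taxonomy"),
               service_taxonomy = tax_from(doc$service_taxonomy, "service_taxonomy"),
               constraints = as.character(unlist(doc$constraints)))
}

as_yaml_map <- function(x) if (is.null(x)) list() else x

#' @param domain a `wf_domain`.
#' @rdname read_domain
#' @export
write_domain <- function(domain, path) {
  stopifnot(inherits(domain, "wf_domain"))
  tax_to <- function(tx) list(
    root = tx$root,
    classes = lapply(tx$classes, as.list),
    instances = lapply(tx$instances, as.list))
  doc <- list(
    types = as.list(sort(taxonomy_names(domain$type_taxonomy))),
    services = lapply(domain$services, function(s) list(
      inputs = as.list(s$inputs),
      outputs = as.list(s$outputs),
      description = s$description)),
    type_taxonomy = tax_to(domain$type_taxonomy),
    service_taxonomy = tax_to(domain$service_taxonomy),
    constraints = as.list(domain$constraints))
  yaml::write_yaml(doc, path)
  invisible(path)
}
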