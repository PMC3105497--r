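#' Build a taxonomy of classes and concrete instances
#'
#' A taxonomy is a simple ontology: an acyclic `is-a` hierarchy of abstract
#' classes rooted at a single most-general class (conventionally `Thing`),
#' plus concrete names attached to one or more classes by an `instance-of`
#' relation.  Both domain types and services are classified this way, and
#' subsumption queries against the taxonomy drive all semantic matching:
#' a concrete type satisfies an abstract requirement when the requirement's
#' class is reachable from the type via `instance-of` followed by `is-a`
#' links.
#'
#' Class names and concrete names share one namespace per taxonomy.  A
#' concrete name given no explicit parent is implicitly an instance of the
#' root.  Multiple parents are permitted for classes and instances alike
#' (e.g. a type that is both a `MultipleSequence` and a
#' `NucleotideSequence`).
#'
#' Cycles in the `is-a` relation are detected but do not abort
#' construction: the offending taxonomy is marked and reported by
#' [validate_domain()]; subsumption queries on a cyclic taxonomy raise an
#' error.
#'
#' @param root single class name of the most-general class.
#' @param classes named list: class name -> character vector of parent class
#'   names (the `is-a` relation).  The root must not appear as a key; every
#'   other class must ultimately reach the root.
#' @param instances named list: concrete name -> character vector of parent
#'   class names (the `instance-of` relation).  An empty vector attaches the
#'   instance directly below the root.
#' @return an object of class `wf_taxonomy`.
#' @examples
#' tx <- taxonomy("Thing",
#'   classes   = list(Sequence = "Thing", MultipleSequence = "Sequence"),
#'   instances = list(MultipleNucleotideSequence = "MultipleSequence"))
#' subsumes(tx, "Sequence", "MultipleNucleotideSequence")
#' @export
taxonomy <- function(root, classes = list(), instances = list()) {
  stopifnot(is.character(root), length(root) == 1L, nzchar(root))
  classes <- lapply(classes, as.character)
  instances <- lapply(instances, as.character)
  check_names <- function(x, what) {
    nm <- names(x) %||% character()
    if (length(x) && (!length(nm) || any(!nzchar(nm))))
      stop("all ", what, " must be named", call. = FALSE)
    if (anyDuplicated(nm))
      stop("duplicate ", what, " name(s): ",
           paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
    nm
  }
  cls_names <- check_names(classes, "classes")
  ins_names <- check_names(instances, "instances")
  if (root %in% cls_names)
    stop("the root class must not declare a parent", call. = FALSE)
  both <- intersect(c(root, cls_names), ins_names)
  if (length(both))
    stop("name(s) used both as class and instance: ",
         paste(both, collapse = ", "), call. = FALSE)
  all_classes <- c(root, cls_names)
  bad_ws <- grepl("\\s", c(all_classes, ins_names))
  if (any(bad_ws))
    stop("taxonomy names must not contain whitespace", call. = FALSE)
  # unresolved parent references
  parent_refs <- unique(unlist(c(classes, instances), use.names = FALSE))
  unknown <- setdiff(parent_refs, all_classes)

  tx <- structure(
    list(root = root,
         classes = classes[order(cls_names)],
         instances = instances[order(ins_names)],
         unknown_parents = sort(unknown)),
    class = "wf_taxonomy")
  tx$cyclic <- length(taxonomy_cycles(tx)) > 0L
  if (!tx$cyclic && !length(unknown)) {
    tx$ancestors <- compute_ancestors(tx)
  }
  tx
}

# class names including the root
taxonomy_classes <- function(tx) c(tx$root, names(tx$classes))

#' All names known to a taxonomy (classes, root, and instances)
#' @param tx a `wf_taxonomy`.
#' @return character vector.
#' @export
taxonomy_names <- function(tx) c(taxonomy_classes(tx), names(tx$instances))

# is_a edges among classes that form a cycle, as a list of class vectors
taxonomy_cycles <- function(tx) {
  nodes <- taxonomy_classes(tx)
  colour <- stats::setNames(rep(0L, length(nodes)), nodes) # 0 new 1 open 2 done
  cycles <- list()
  visit <- function(n, path) {
    if (!n %in% nodes) return()
    if (colour[[n]] == 1L) {
      cycles[[length(cycles) + 1L]] <<- c(path[which(path == n)[1L]:length(path)], n)
      return()
    }
    if (colour[[n]] == 2L) return()
    colour[[n]] <<- 1L
    for (p in tx$classes[[n]]) visit(p, c(path, n))
    colour[[n]] <<- 2L
  }
  for (n in nodes) if (colour[[n]] == 0L) visit(n, character())
  cycles
}

# named list: every known name -> character vector of all names subsuming it
# (reflexive; instances climb instance_of then is_a; root subsumes all)
compute_ancestors <- function(tx) {
  anc <- list()
  cls <- taxonomy_classes(tx)
  class_anc <- function(n) {
    if (!is.null(anc[[n]])) return(anc[[n]])
    up <- unique(unlist(lapply(tx$classes[[n]], class_anc), use.names = FALSE))
    anc[[n]] <<- unique(c(n, up, tx$root))
    anc[[n]]
  }
  for (n in cls) class_anc(n)
  for (i in names(tx$instances)) {
    up <- unique(unlist(lapply(tx$instances[[i]], function(p) anc[[p]]),
                        use.names = FALSE))
    anc[[i]] <- unique(c(i, up, tx$root))
  }
  anc
}

taxonomy_lookup <- function(tx, name, context = "taxonomy") {
  if (!name %in% taxonomy_names(tx))
    stop(sprintf("unknown name '%s' in %s", name, context), call. = FALSE)
  invisible(name)
}

ancestors_of <- function(tx, name) {
  if (is.null(tx$ancestors))
    stop("taxonomy is cyclic or has unresolved parents; run validate_domain()",
         call. = FALSE)
  taxonomy_lookup(tx, name)
  tx$ancestors[[name]]
}

#' Subsumption query against a taxonomy
#'
#' Tests whether `general` subsumes `specific`: true when the two names are
#' equal, or when `specific` reaches `general` through its `instance-of`
#' link followed by zero or more `is-a` steps (the reflexive-transitive
#' closure).  The root class subsumes every known name.
#'
#' @param tx a `wf_taxonomy`.
#' @param general class (or concrete) name taken as the general side.
#' @param specific class or concrete name taken as the specific side.
#' @return logical scalar.
#' @export
subsumes <- function(tx, general, specific) {
  stopifnot(inherits(tx, "wf_taxonomy"))
  taxonomy_lookup(tx, general)
  general %in% ancestors_of(tx, specific)
}

#' @export
print.wf_taxonomy <- function(x, ...) {
  cat(sprintf("<taxonomy> root '%s': %d classes, %d instances%s\n",
              x$root, length(x$classes) + 1L, length(x$instances),
              if (isTRUE(x$cyclic)) " [cyclic!]" else ""))
  invisible(x)
}

#' @export
format.wf_taxonomy <- function(x, ...) {
  sprintf("<taxonomy root=%s classes=%d instances=%d>",
          x$root, length(x$classes) + 1L, length(x$instances))
}
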