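#' Specification for a seeded random domain
#'
#' Random domains drive property-based testing of the synthesis machinery
#' against the brute-force oracle: small universes of concrete types, a
#' shallow random class hierarchy, and services with random input
#' requirements and outputs.  Generation is a pure function of the spec
#' (same spec, same domain).
#'
#' @param seed integer RNG seed.
#' @param n_types number of concrete type names.
#' @param n_services number of services.
#' @param max_inputs,max_outputs per-service bounds on the sizes of the
#'   input and output sets.
#' @param taxonomy_depth maximum depth of the random class hierarchy
#'   below the root.
#' @param p_abstract_grouping probability that a type instance is placed
#'   under an abstract class (rather than directly under the root), that a
#'   service input names a class rather than a concrete type, and that a
#'   service is placed in an abstract service group.
#' @return an object of class `wf_random_spec`.
#' @export
random_domain_spec <- function(seed, n_types = 6L, n_services = 8L,
                               max_inputs = 2L, max_outputs = 2L,
                               taxonomy_depth = 2L,
                               p_abstract_grouping = 0.5) {
  stopifnot(n_types >= 1L, n_services >= 1L, max_inputs >= 0L,
            max_outputs >= 0L, taxonomy_depth >= 1L,
            p_abstract_grouping >= 0, p_abstract_grouping <= 1)
  structure(list(seed = as.integer(seed), n_types = as.integer(n_types),
                 n_services = as.integer(n_services),
                 max_inputs = as.integer(max_inputs),
                 max_outputs = as.integer(max_outputs),
                 taxonomy_depth = as.integer(taxonomy_depth),
                 p_abstract_grouping = p_abstract_grouping),
            class = "wf_random_spec")
}

with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(expr)
}

#' Generate a random domain from a spec
#'
#' Deterministic for a given spec; the first service is always a source
#' (no inputs) so that non-trivial synthesis problems exist, and the
#' result always passes [validate_domain()] cleanly.
#'
#' @param spec a [random_domain_spec()].
#' @return a `wf_domain`.
#' @export
generate_random_domain <- function(spec) {
  stopifnot(inherits(spec, "wf_random_spec"))
  with_preserved_rng(spec$seed, {
    # class hierarchy: a few classes, parents at strictly smaller depth
    n_classes <- sample.int(2L * spec$taxonomy_depth, 1L)
    class_names <- sprintf("Group%d", seq_len(n_classes))
    class_depth <- integer(n_classes)
    classes <- list()
    for (i in seq_len(n_classes)) {
      shallower <- which(class_depth[seq_len(i - 1L)] < spec$taxonomy_depth)
      if (length(shallower) && stats::runif(1) < 0.6) {
        p <- shallower[[sample.int(length(shallower), 1L)]]
        classes[[class_names[i]]] <- class_names[p]
        class_depth[i] <- class_depth[p] + 1L
      } else {
        classes[[class_names[i]]] <- "Thing"
        class_depth[i] <- 1L
      }
    }

    type_names <- sprintf("t%d", seq_len(spec$n_types))
    instances <- list()
    for (t in type_names) {
      instances[[t]] <- if (n_classes && stats::runif(1) < spec$p_abstract_grouping) {
        k <- min(n_classes, 1L + (stats::runif(1) < 0.25))
        sort(sample(class_names, k))
      } else character()
    }
    type_tx <- taxonomy("Thing", classes, instances)

    requirement_pool <- c(type_names, class_names)
    services <- vector("list", spec$n_services)
    svc_names <- sprintf("svc%02d", seq_len(spec$n_services))
    for (i in seq_len(spec$n_services)) {
      n_in <- if (i == 1L) 0L else sample.int(spec$max_inputs + 1L, 1L) - 1L
      n_out <- sample.int(spec$max_outputs + 1L, 1L) - 1L
      if (i == 1L) n_out <- max(n_out, 1L)    # the source must produce something
      ins <- if (n_in) {
        pick <- sample(requirement_pool, n_in)
        # bias requirements towards classes per p_abstract_grouping
        vapply(pick, function(x) {
          if (x %in% type_names && n_classes &&
              stats::runif(1) < spec$p_abstract_grouping / 2)
            sample(class_names, 1L) else x
        }, character(1))
      } else character()
      outs <- if (n_out) sample(type_names, n_out) else character()
      services[[i]] <- service_spec(svc_names[i], ins, outs,
                                    sprintf("random service %d", i))
    }

    svc_groups <- c("GroupA", "GroupB")
    svc_instances <- lapply(stats::setNames(nm = svc_names), function(s) {
      if (stats::runif(1) < spec$p_abstract_grouping)
        sample(svc_groups, 1L) else character()
    })
    service_tx <- taxonomy("Thing",
                           classes = list(GroupA = "Thing", GroupB = "Thing"),
                           instances = svc_instances)
    domain_model(services, type_taxonomy = type_tx,
                 service_taxonomy = service_tx)
  })
}
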