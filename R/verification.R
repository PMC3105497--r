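#' Model-check a process graph against a temporal-logic formula
#'
#' For every node `v` of a fully concretized process graph, decides
#' whether the formula holds on *all* maximal control-flow paths starting
#' at `v`.  Paths ending at a sink node are evaluated with finite-trace
#' semantics (the `end` atom holding after the sink's service has
#' executed); paths through loops are treated as lasso-shaped infinite
#' traces and evaluated with standard infinite-trace fixpoint semantics.
#' A service-execution atom holds at a node whose service is subsumed by
#' the atom's name in the service taxonomy; the initial position's atom is
#' the node's own service.
#'
#' Lassos are enumerated by depth-first exploration in which each node
#' may occur at most twice on the current path: revisiting a node closes
#' a lasso there (and exploration continues one level deeper, so loops
#' combining two simple cycles are also covered).
#'
#' Processes with loose edges must be concretized first (see
#' [synthesize()] / [insert_solution()]); type-availability atoms are not
#' meaningful on process graphs and are rejected.
#'
#' @param process a `wf_process` without loose edges.
#' @param formula a `wf_formula` or [parse_pltl()] text.
#' @param domain a `wf_domain` (service taxonomy for atom matching).
#' @return an object of class `wf_verdict`: a data.frame-like mapping of
#'   node ids to `"holds"`/`"violated"`, with one witness path per
#'   violated node.
#' @export
check_process <- function(process, formula, domain) {
  stopifnot(inherits(process, "wf_process"), inherits(domain, "wf_domain"))
  if (is.character(formula)) formula <- parse_pltl(formula)
  stopifnot(inherits(formula, "wf_formula"))
  if (any(process$edges$loose))
    stop("process has loosely specified edges; synthesize them first",
         call. = FALSE)
  if (length(formula_atoms(formula)$avail))
    stop("type-availability atoms are not supported in process checking",
         call. = FALSE)
  for (nm in formula_atoms(formula)$exec)
    taxonomy_lookup(domain$service_taxonomy, nm, "service taxonomy")

  succs <- split(process$edges$to, factor(process$edges$from,
                                          levels = process$nodes$id))
  node_service <- stats::setNames(process$nodes$service, process$nodes$id)

  verdicts <- character(nrow(process$nodes))
  names(verdicts) <- process$nodes$id
  witnesses <- stats::setNames(vector("list", nrow(process$nodes)),
                               process$nodes$id)

  for (v in process$nodes$id) {
    witness <- NULL
    explore <- function(path) {
      if (!is.null(witness)) return()
      head_node <- path[length(path)]
      nexts <- succs[[head_node]]
      if (!length(nexts)) {
        if (!eval_finite_node_path(formula, node_service[path], domain))
          witness <<- list(nodes = path, loop_start = NA_integer_)
        return()
      }
      for (s in nexts) {
        if (!is.null(witness)) return()
        occ <- which(path == s)
        if (length(occ) >= 2L) {
          if (!eval_lasso(formula, node_service[c(path, s)], occ[2L], domain))
            witness <<- list(nodes = c(path, s), loop_start = occ[2L])
        } else {
          if (length(occ) == 1L) {
            if (!eval_lasso(formula, node_service[c(path, s)], occ[1L], domain))
              witness <<- list(nodes = c(path, s), loop_start = occ[1L])
          }
          explore(c(path, s))
        }
      }
    }
    explore(v)
    verdicts[[v]] <- if (is.null(witness)) "holds" else "violated"
    witnesses[[v]] <- witness
  }

  structure(list(verdicts = verdicts, witnesses = witnesses,
                 formula = formula),
            class = "wf_verdict")
}

#' @export
print.wf_verdict <- function(x, ...) {
  cat("<verdict>", render_formula(x$formula), "\n")
  for (n in names(x$verdicts)) {
    mark <- if (x$verdicts[[n]] == "holds") "ok" else "X "
    cat(sprintf("  [%s] %s\n", mark, n))
    w <- x$witnesses[[n]]
    if (!is.null(w)) {
      loop <- if (!is.na(w$loop_start))
        sprintf(" (loop back to position %d)", w$loop_start) else ""
      cat(sprintf("       witness: %s%s\n", paste(w$nodes, collapse = " -> "),
                  loop))
    }
  }
  invisible(x)
}

#' Nodes reported as violated by a verdict
#' @param verdict a `wf_verdict`.
#' @return character vector of node ids.
#' @export
violated_nodes <- function(verdict) {
  names(verdict$verdicts)[verdict$verdicts == "violated"]
}

# finite maximal node path -> action trace svc[1..k] with the end position
# after the sink; reuses the finite-trace evaluator (no avail atoms here,
# so the per-position states are never consulted)
eval_finite_node_path <- function(formula, services, domain) {
  tr <- structure(list(states = rep(list(character()), length(services) + 1L),
                       services = unname(services)),
                  class = "wf_trace")
  evaluate(formula, tr, domain)
}

# infinite-trace evaluation on a lasso: positions 1..L with the successor
# of L wrapping to loop_start.  Temporal operators are solved as fixpoints
# of their one-step unfoldings over the lasso (least for U/F, greatest for
# WU/G); `end` never holds and next is total.
eval_lasso <- function(formula, services, loop_start, domain) {
  L <- length(services)
  succ <- c(seq_len(L)[-1L], loop_start)
  stx <- domain$service_taxonomy
  fixpoint <- function(x, y, least) {
    val <- rep(!least, L)
    repeat {
      new <- y | (x & val[succ])
      if (identical(new, val)) return(val)
      val <- new
    }
  }
  ev <- function(g) {
    switch(g$op,
      "true" = rep(TRUE, L),
      "false" = rep(FALSE, L),
      end = rep(FALSE, L),
      exec = vapply(services, function(a) subsumes(stx, g$name, a), logical(1),
                    USE.NAMES = FALSE),
      not = !ev(g$x),
      and = ev(g$x) & ev(g$y),
      or = ev(g$x) | ev(g$y),
      implies = !ev(g$x) | ev(g$y),
      "next" = ev(g$x)[succ],
      eventually = fixpoint(rep(TRUE, L), ev(g$x), least = TRUE),
      globally = fixpoint(ev(g$x), rep(FALSE, L), least = FALSE),
      until = fixpoint(ev(g$x), ev(g$y), least = TRUE),
      wuntil = fixpoint(ev(g$x), ev(g$y), least = FALSE),
      stop("unsupported formula op on lasso traces: ", g$op))
  }
  ev(formula)[1L]
}
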