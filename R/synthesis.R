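#' Define a synthesis problem
#'
#' A synthesis problem asks for service sequences that, starting from the
#' types in `start`, make every `goal` type available (goal matching uses
#' the same taxonomy subsumption as service inputs: the goal is literally
#' the input requirement of the downstream service) while the conjunction
#' of all constraints holds on the execution trace.  Constraints may be
#' given as `wf_formula` objects, [parse_pltl()] text prefixed with
#' `"pltl:"`, or natural-language template sentences
#' ([template_to_formula()]); the domain's global constraints are appended
#' unless `include_global = FALSE`.
#'
#' @param domain a `wf_domain`.
#' @param start character vector of start type names.
#' @param goal character vector of required type (or class) names.
#' @param constraints list of constraints (formulas or strings).
#' @param depth_bound maximum solution length searched.
#' @param solution_cap maximum number of solutions returned; service
#'   collections in which many tools consume and produce near-identical
#'   types can yield thousands of valid sequences even at modest bounds,
#'   so a cap is always applied.
#' @param include_global append the domain's global constraints?
#' @return an object of class `wf_problem`.
#' @export
synthesis_problem <- function(domain, start, goal, constraints = list(),
                              depth_bound = 6L, solution_cap = 1000L,
                              include_global = TRUE) {
  stopifnot(inherits(domain, "wf_domain"),
            depth_bound >= 0L, solution_cap >= 1L)
  if (inherits(constraints, "wf_formula")) constraints <- list(constraints)
  if (is.character(constraints)) constraints <- as.list(constraints)
  all_cons <- c(as.list(constraints),
                if (include_global) as.list(domain$constraints))
  formulas <- lapply(all_cons, function(con) {
    if (inherits(con, "wf_formula")) return(con)
    if (is.character(con) && length(con) == 1L) {
      if (startsWith(con, "pltl:"))
        return(parse_pltl(sub("^pltl:\\s*", "", con)))
      return(template_to_formula(con, domain))
    }
    stop("constraints must be formulas or constraint strings", call. = FALSE)
  })
  goal <- state(goal)
  for (g in goal) taxonomy_lookup(domain$type_taxonomy, g, "type taxonomy")
  structure(
    list(domain = domain, start = state(start), goal = goal,
         constraints = formulas,
         depth_bound = as.integer(depth_bound),
         solution_cap = as.integer(solution_cap)),
    class = "wf_problem")
}

#' @export
print.wf_problem <- function(x, ...) {
  cat(sprintf("<synthesis problem> start {%s} -> goal {%s}; %d constraint(s); bound %d\n",
              paste(x$start, collapse = ", "), paste(x$goal, collapse = ", "),
              length(x$constraints), x$depth_bound))
  invisible(x)
}

new_solution <- function(services, final_state) {
  structure(list(services = as.character(services), final_state = final_state),
            class = "wf_solution")
}

#' @export
print.wf_solution <- function(x, ...) {
  cat(sprintf("<solution> [%s]\n",
              if (length(x$services)) paste(x$services, collapse = " -> ")
              else "empty"))
  invisible(x)
}

goal_satisfied <- function(st, goal, domain) {
  for (g in goal)
    if (!satisfies_requirement(st, g, domain$type_taxonomy)) return(FALSE)
  TRUE
}

#' Check a solution against its problem's invariants
#'
#' Replays the service sequence from the problem start (every step must be
#' applicable), then checks goal satisfaction in the final state and the
#' conjoined constraints on the full trace.
#'
#' @param problem a `wf_problem`.
#' @param solution a `wf_solution` (or character vector of service names).
#' @return logical scalar.
#' @export
solution_valid <- function(problem, solution) {
  services <- if (inherits(solution, "wf_solution")) solution$services
              else as.character(solution)
  tr <- tryCatch(trace_replay(problem$domain, problem$start, services),
                 error = function(e) NULL)
  if (is.null(tr)) return(FALSE)
  goal_satisfied(tr$states[[length(tr$states)]], problem$goal, problem$domain) &&
    evaluate(conjoin(problem$constraints), tr, problem$domain)
}

state_key <- function(st) paste0("s:", paste(st, collapse = "\x01"))

# lexicographic order of equal-length service sequences
order_sequences <- function(seqs) {
  if (!length(seqs)) return(integer())
  keys <- vapply(seqs, function(s) paste(s, collapse = "\x01"), character(1))
  order(keys, method = "radix")
}

#' Synthesize service sequences for a loose branch
#'
#' Breadth-first search of the configuration universe (states are sets of
#' available types; transitions are applicable services adding their
#' outputs) evaluated in parallel with the specification formula by
#' formula progression: the search front holds (state, residual formula)
#' pairs, expanded on the fly rather than from an explicitly built
#' transition system.  A sequence is emitted as a solution when the goal
#' types are satisfied in its final state and its residue is accepted at
#' the end of the trace; the empty sequence is considered at length 0.
#' Solutions are returned ordered by length, ties broken lexicographically
#' by the service-name sequence, truncated at the problem's
#' `solution_cap`.
#'
#' Search-front entries with identical (state, residue) pairs are merged
#' (their future behavior is identical); the distinct prefixes reaching a
#' pair are all retained, so the result is exactly the set a brute-force
#' enumeration to the same depth produces (see [brute_force_oracle()]).
#'
#' @param problem a `wf_problem`.
#' @param shortest_only stop after the first length that yields solutions.
#' @return list of `wf_solution`, possibly empty.
#' @export
synthesize <- function(problem, shortest_only = FALSE) {
  stopifnot(inherits(problem, "wf_problem"))
  domain <- problem$domain
  cap <- problem$solution_cap
  phi0 <- simplify_formula(conjoin(problem$constraints))

  # per-state expansion cache: applicable services and successor states
  moves_cache <- new.env(parent = emptyenv())
  state_pool <- new.env(parent = emptyenv())
  pool_state <- function(st) {
    k <- state_key(st)
    if (is.null(state_pool[[k]])) state_pool[[k]] <- st
    k
  }
  moves_for <- function(skey) {
    if (!is.null(moves_cache[[skey]])) return(moves_cache[[skey]])
    st <- state_pool[[skey]]
    mv <- list()
    for (svc in domain$services) {          # services are stored name-sorted
      if (applicable(svc, st, domain)) {
        nxt <- state(c(st, svc$outputs))
        mv[[length(mv) + 1L]] <- list(action = svc$name, skey = pool_state(nxt))
      }
    }
    moves_cache[[skey]] <- mv
    mv
  }

  solutions <- list()
  emit <- function(front, len) {
    hits <- list()
    for (cl in front) {
      st <- state_pool[[cl$skey]]
      if (goal_satisfied(st, problem$goal, domain) &&
          accept_at_end(cl$residue, st, domain)) {
        for (p in cl$prefixes)
          hits[[length(hits) + 1L]] <- list(services = p, st = st)
      }
    }
    if (!length(hits)) return(FALSE)
    ord <- order_sequences(lapply(hits, `[[`, "services"))
    for (i in ord) {
      if (length(solutions) >= cap) break
      solutions[[length(solutions) + 1L]] <<-
        new_solution(hits[[i]]$services, hits[[i]]$st)
    }
    TRUE
  }

  start_key <- pool_state(problem$start)
  front <- list()
  if (phi0$op != "false")
    front[[paste(start_key, render_formula(phi0), sep = "\x02")]] <-
      list(skey = start_key, residue = phi0, prefixes = list(character()))

  depth <- 0L
  repeat {
    found <- emit(front, depth)
    if ((found && shortest_only) || length(solutions) >= cap ||
        depth >= problem$depth_bound || !length(front)) break
    nxt <- list()
    for (cl in front) {
      for (mv in moves_for(cl$skey)) {
        st <- state_pool[[cl$skey]]
        res <- progress_formula(cl$residue, st, mv$action, domain)
        if (res$op == "false") next
        key <- paste(mv$skey, render_formula(res), sep = "\x02")
        prefixes <- lapply(cl$prefixes, function(p) c(p, mv$action))
        if (is.null(nxt[[key]])) {
          nxt[[key]] <- list(skey = mv$skey, residue = res, prefixes = prefixes)
        } else {
          nxt[[key]]$prefixes <- c(nxt[[key]]$prefixes, prefixes)
        }
      }
    }
    # keep per-class prefix lists ordered and bounded by the cap
    for (k in names(nxt)) {
      pf <- nxt[[k]]$prefixes
      pf <- pf[order_sequences(pf)]
      if (length(pf) > cap) pf <- pf[seq_len(cap)]
      nxt[[k]]$prefixes <- pf
    }
    front <- nxt
    depth <- depth + 1L
  }
  solutions
}

#' Brute-force enumeration oracle
#'
#' Independent reference for [synthesize()]: enumerates every service
#' sequence up to `depth_bound` by depth-first expansion in service-name
#' order, filters by replay validity, goal satisfaction, and direct
#' [evaluate()] of the conjoined constraints on the full trace, and
#' returns the survivors in the same order (length, then lexicographic)
#' truncated at the cap.  Exponential in the bound; intended for small
#' problems.
#'
#' @param problem a `wf_problem` (bounds of 5 or less recommended).
#' @return list of `wf_solution`.
#' @export
brute_force_oracle <- function(problem) {
  stopifnot(inherits(problem, "wf_problem"))
  domain <- problem$domain
  phi0 <- conjoin(problem$constraints)
  by_len <- rep(list(list()), problem$depth_bound + 1L)

  recurse <- function(st, services, states) {
    len <- length(services)
    tr <- structure(list(states = states, services = services),
                    class = "wf_trace")
    if (goal_satisfied(st, problem$goal, domain) &&
        evaluate(phi0, tr, domain)) {
      by_len[[len + 1L]][[length(by_len[[len + 1L]]) + 1L]] <<-
        new_solution(services, st)
    }
    if (len >= problem$depth_bound) return()
    for (svc in domain$services) {
      if (applicable(svc, st, domain)) {
        nxt <- state(c(st, svc$outputs))
        recurse(nxt, c(services, svc$name), c(states, list(nxt)))
      }
    }
  }
  recurse(problem$start, character(), list(problem$start))

  out <- list()
  for (bucket in by_len) {
    if (!length(bucket)) next
    ord <- order_sequences(lapply(bucket, `[[`, "services"))
    for (i in ord) {
      if (length(out) >= problem$solution_cap) return(out)
      out[[length(out) + 1L]] <- bucket[[i]]
    }
  }
  out
}

# ---- loose-branch plumbing --------------------------------------------------

resolve_loose_edge <- function(process, loose_edge) {
  ed <- process$edges
  if (is.numeric(loose_edge)) {
    i <- as.integer(loose_edge)
    if (i < 1L || i > nrow(ed)) stop("loose edge index out of range", call. = FALSE)
    return(i)
  }
  if (is.character(loose_edge) && length(loose_edge) == 2L) {
    i <- which(ed$from == loose_edge[1L] & ed$to == loose_edge[2L])
    if (!length(i))
      stop(sprintf("no edge %s -> %s in process", loose_edge[1L], loose_edge[2L]),
           call. = FALSE)
    return(i[1L])
  }
  stop("loose_edge must be an edge index or c(from, to)", call. = FALSE)
}

#' Infer the start types available at a loose branch
#'
#' Data-flow analysis of the process graph: the types guaranteed to be
#' available when control reaches the loose branch are the intersection,
#' over all simple control-flow paths from the initial node to the loose
#' edge's source node (inclusive), of the union of the output types of the
#' services executed along each path.
#'
#' @param process a `wf_process`.
#' @param loose_edge edge index or `c(from, to)` pair.
#' @param domain a `wf_domain` resolving node services.
#' @return a [state()].
#' @export
infer_start_types <- function(process, loose_edge, domain) {
  i <- resolve_loose_edge(process, loose_edge)
  src <- process$edges$from[i]
  g <- process_igraph(process)
  paths <- if (src == process$initial) {
    list(src)
  } else {
    sp <- igraph::all_simple_paths(g, from = process$initial, to = src,
                                   mode = "out")
    lapply(sp, function(p) names(p))
  }
  if (!length(paths))
    stop(sprintf("loose edge source '%s' is unreachable from initial node '%s'",
                 src, process$initial), call. = FALSE)
  per_path <- lapply(paths, function(ids) {
    outs <- lapply(ids, function(id)
      domain_service(domain, process_service_of(process, id))$outputs)
    state(unlist(outs))
  })
  state(Reduce(intersect, per_path))
}

#' Build the synthesis problem defined by a loose edge
#'
#' The start state is inferred from the control flow upstream of the edge
#' ([infer_start_types()]); the goal is the input-type set of the service
#' at the edge's target node.
#'
#' @inheritParams infer_start_types
#' @param ... passed on to [synthesis_problem()] (constraints, bounds, ...).
#' @return a `wf_problem`.
#' @export
problem_from_loose_edge <- function(process, loose_edge, domain, ...) {
  i <- resolve_loose_edge(process, loose_edge)
  tgt_service <- process_service_of(process, process$edges$to[i])
  synthesis_problem(
    domain,
    start = infer_start_types(process, i, domain),
    goal = domain_service(domain, tgt_service)$inputs,
    ...)
}

#' Replace a loose edge by a synthesized service chain
#'
#' The loose edge is removed and the solution's services inserted as a
#' linear chain of fresh nodes between its endpoints (an empty solution
#' yields a direct concrete edge).  All other nodes and edges are
#' untouched.  The solution is re-validated against the edge's inferred
#' problem; an invalid solution is a contract violation.
#'
#' @inheritParams infer_start_types
#' @param solution a `wf_solution` (or character vector of service names).
#' @param validate re-check the solution against the inferred problem?
#' @return a new `wf_process` with no loose flag on that path.
#' @export
insert_solution <- function(process, loose_edge, solution, domain,
                            validate = TRUE) {
  i <- resolve_loose_edge(process, loose_edge)
  services <- if (inherits(solution, "wf_solution")) solution$services
              else as.character(solution)
  if (validate) {
    prob <- problem_from_loose_edge(process, i, domain)
    if (!solution_valid(prob, services))
      stop("contract violation: solution is not valid for this loose edge",
           call. = FALSE)
  }
  nodes <- process$nodes
  edges <- process$edges
  from <- edges$from[i]; to <- edges$to[i]; label <- edges$label[i]
  edges <- edges[-i, , drop = FALSE]
  fresh_id <- function(base) {
    id <- base; k <- 1L
    while (id %in% nodes$id) { k <- k + 1L; id <- sprintf("%s_%d", base, k) }
    id
  }
  prev <- from
  for (svc in services) {
    id <- fresh_id(paste0("synth_", svc))
    nodes <- rbind(nodes, data.frame(id = id, service = svc))
    edges <- rbind(edges, data.frame(from = prev, to = id, label = "",
                                     loose = FALSE))
    prev <- id
  }
  edges <- rbind(edges, data.frame(from = prev, to = to, label = label,
                                   loose = FALSE))
  process_model(nodes, edges, process$initial)
}
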