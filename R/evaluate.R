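#' Finite execution traces
#'
#' A trace is an alternating sequence `s0, a1, s1, ..., an, sn` of states
#' and executed services (possibly empty, `n = 0`): each `s[i+1]` is the
#' [successor()] of `s[i]` under the applicable service `a[i+1]`.
#' `trace_replay()` builds (and validates) the trace obtained by replaying
#' a service sequence from a start state.
#'
#' @param domain a `wf_domain`.
#' @param start the start [state()].
#' @param services character vector of service names (possibly empty).
#' @return an object of class `wf_trace` with fields `states` (list of
#'   `n + 1` states) and `services` (character vector of length `n`).
#' @export
trace_replay <- function(domain, start, services = character()) {
  st <- state(start)
  states <- list(st)
  for (a in services) {
    st <- successor(st, a, domain)
    states[[length(states) + 1L]] <- st
  }
  structure(list(states = states, services = as.character(services)),
            class = "wf_trace")
}

#' @export
print.wf_trace <- function(x, ...) {
  cat(sprintf("<trace> %d step(s): %s\n", length(x$services),
              if (length(x$services)) paste(x$services, collapse = " -> ")
              else "(empty)"))
  invisible(x)
}

trace_length <- function(trace) length(trace$services)

#' Evaluate a formula on a finite trace
#'
#' Finite-trace semantics over positions `0..n` (where `n` is the number
#' of executed services): `f_exec(C)` holds at position `i < n` iff the
#' service executed next (`a[i+1]`) is subsumed by `C` in the service
#' taxonomy, and is false at the final position; `f_avail(T)` holds at
#' `i` iff the state `s[i]` satisfies the type requirement `T`;
#' `f_end()` holds only at the final position; `f_next()` is strong (false
#' at the final position); `f_wuntil(p, q)` is `G(p) | (p U q)`.  The
#' result is satisfaction at position 0.
#'
#' @param f a `wf_formula`.
#' @param trace a `wf_trace` (see [trace_replay()]).
#' @param domain the `wf_domain` supplying the service and type taxonomies.
#' @return logical scalar.
#' @export
evaluate <- function(f, trace, domain) {
  stopifnot(inherits(f, "wf_formula"), inherits(trace, "wf_trace"))
  n <- trace_length(trace)
  stx <- domain$service_taxonomy
  ttx <- domain$type_taxonomy
  ev <- function(g, i) {
    switch(g$op,
      "true" = TRUE,
      "false" = FALSE,
      end = i == n,
      exec = i < n && subsumes(stx, g$name, trace$services[[i + 1L]]),
      avail = satisfies_requirement(trace$states[[i + 1L]], g$name, ttx),
      not = !ev(g$x, i),
      and = ev(g$x, i) && ev(g$y, i),
      or = ev(g$x, i) || ev(g$y, i),
      implies = !ev(g$x, i) || ev(g$y, i),
      "next" = i < n && ev(g$x, i + 1L),
      eventually = {
        ok <- FALSE
        for (j in i:n) if (ev(g$x, j)) { ok <- TRUE; break }
        ok
      },
      globally = {
        ok <- TRUE
        for (j in i:n) if (!ev(g$x, j)) { ok <- FALSE; break }
        ok
      },
      until = {
        ok <- FALSE
        for (j in i:n) {
          if (ev(g$y, j)) { ok <- TRUE; break }
          if (!ev(g$x, j)) break
        }
        ok
      },
      wuntil = {
        ok <- TRUE
        for (j in i:n) {
          if (ev(g$y, j)) break
          if (!ev(g$x, j)) { ok <- FALSE; break }
        }
        ok
      },
      stop("unknown formula op: ", g$op))
  }
  ev(f, 0L)
}

# ---- formula progression ----------------------------------------------------
#
# The synthesis search evaluates the specification formula in parallel with
# the configuration universe by *progression*: consuming one trace position
# (state `st`, executed service `action`) rewrites the formula into the
# residue that the remaining suffix must satisfy.  Atoms are decided
# immediately against (st, action); modalities unfold one step:
#   X p        ->  p
#   F p        ->  p' | F p
#   G p        ->  p' & G p
#   p U q      ->  q' | (p' & p U q)
#   p WU q     ->  q' | (p' & p WU q)
# (primes denoting progressed subformulas).  `end` progresses to false,
# because a position that is stepped over is not the final one.

progress_formula <- function(f, st, action, domain) {
  stx <- domain$service_taxonomy
  ttx <- domain$type_taxonomy
  pr <- function(g) {
    switch(g$op,
      "true" = f_true(),
      "false" = f_false(),
      end = f_false(),
      exec = if (subsumes(stx, g$name, action)) f_true() else f_false(),
      avail = if (satisfies_requirement(st, g$name, ttx)) f_true() else f_false(),
      not = f_not(pr(g$x)),
      and = f_and(pr(g$x), pr(g$y)),
      or = f_or(pr(g$x), pr(g$y)),
      implies = f_implies(pr(g$x), pr(g$y)),
      "next" = g$x,
      eventually = f_or(pr(g$x), g),
      globally = f_and(pr(g$x), g),
      until = f_or(pr(g$y), f_and(pr(g$x), g)),
      wuntil = f_or(pr(g$y), f_and(pr(g$x), g)),
      stop("unknown formula op: ", g$op))
  }
  simplify_formula(pr(f))
}

# Satisfaction of a residue at the final trace position (state `st`, no
# further action): exec atoms are false, `end` is true, strong next is
# false, and the modalities collapse to their final-position readings.
accept_at_end <- function(f, st, domain) {
  ttx <- domain$type_taxonomy
  acc <- function(g) {
    switch(g$op,
      "true" = TRUE,
      "false" = FALSE,
      end = TRUE,
      exec = FALSE,
      avail = satisfies_requirement(st, g$name, ttx),
      not = !acc(g$x),
      and = acc(g$x) && acc(g$y),
      or = acc(g$x) || acc(g$y),
      implies = !acc(g$x) || acc(g$y),
      "next" = FALSE,
      eventually = acc(g$x),
      globally = acc(g$x),
      until = acc(g$y),
      wuntil = acc(g$y) || acc(g$x),
      stop("unknown formula op: ", g$op))
  }
  acc(f)
}
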