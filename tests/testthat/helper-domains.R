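# Shared helpers: small in-code domains, exhaustive trace enumeration, and
# a random-formula generator for parser/semantics property tests.

# Tiny pipeline domain: src makes a raw record, two alternative analyzers
# promote it, a renderer consumes either analyzer's output via the class.
tiny_domain <- function() {
  domain_model(
    list(
      service_spec("src", character(), "raw", "produce a raw record"),
      service_spec("alpha", "raw", "resA", "analysis A"),
      service_spec("beta", "raw", "resB", "analysis B"),
      service_spec("render", "Result", character(), "render any result")),
    type_taxonomy = taxonomy(
      "Thing",
      classes = list(Result = "Thing"),
      instances = list(raw = character(), resA = "Result", resB = "Result")),
    service_taxonomy = taxonomy(
      "Thing",
      classes = list(Analysis = "Thing"),
      instances = list(src = character(), alpha = "Analysis",
                       beta = "Analysis", render = character())))
}

# all valid traces (tree-expanded) from `start` up to `depth` steps
enumerate_traces <- function(domain, start, depth) {
  out <- list()
  recurse <- function(states, services) {
    out[[length(out) + 1L]] <<- structure(
      list(states = states, services = services), class = "wf_trace")
    if (length(services) >= depth) return()
    st <- states[[length(states)]]
    for (svc in domain$services)
      if (applicable(svc, st, domain))
        recurse(c(states, list(state(c(st, svc$outputs)))),
                c(services, svc$name))
  }
  recurse(list(state(start)), character())
  out
}

random_formula <- function(depth, exec_names = c("a", "bb", "c_d"),
                           avail_names = "t1") {
  if (depth == 0L)
    return(switch(sample.int(5L, 1L),
                  f_true(), f_false(), f_end(),
                  f_exec(sample(exec_names, 1L)),
                  f_avail(sample(avail_names, 1L))))
  sub <- function() random_formula(depth - 1L, exec_names, avail_names)
  switch(sample.int(9L, 1L),
         f_not(sub()), f_and(sub(), sub()), f_or(sub(), sub()),
         f_implies(sub(), sub()), f_next(sub()), f_eventually(sub()),
         f_globally(sub()), f_until(sub(), sub()), f_wuntil(sub(), sub()))
}

# fold a formula along a trace by progression, accepting at the end;
# independent re-implementation of what the synthesis search does
progression_verdict <- function(f, trace, domain) {
  res <- flowsynth:::simplify_formula(f)
  n <- length(trace$services)
  for (i in seq_len(n)) {
    res <- flowsynth:::progress_formula(res, trace$states[[i]],
                                        trace$services[[i]], domain)
  }
  flowsynth:::accept_at_end(res, trace$states[[n + 1L]], domain)
}

solution_services <- function(solutions) lapply(solutions, `[[`, "services")
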