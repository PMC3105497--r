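test_that("the alignment branch is completed by a single alignment service", {
  d <- load_fixture("manual_hmmer")
  problem <- synthesis_problem(d, "MultipleNucleotideSequence", "Alignment",
                               depth_bound = 4)
  shortest <- synthesize(problem, shortest_only = TRUE)
  expect_identical(solution_services(shortest),
                   list("edialign", "emma"))
  expect_true(all(vapply(shortest, function(s) solution_valid(problem, s),
                         logical(1))))
})

test_that("a goal already satisfied yields the empty sequence first", {
  d <- load_fixture("manual_hmmer")
  problem <- synthesis_problem(d, "MultipleProteinSequence", "Sequence",
                               depth_bound = 3)
  sols <- synthesize(problem)
  expect_identical(sols[[1]]$services, character())
  # trivially: goal contained in start, no constraints
  p0 <- synthesis_problem(tiny_domain(), "raw", "raw", depth_bound = 2)
  expect_identical(synthesize(p0)[[1]]$services, character())
  expect_identical(brute_force_oracle(p0)[[1]]$services, character())
})

test_that("enforcing a service lengthens the shortest solution to three steps", {
  d <- load_fixture("manual_hmmer")
  problem <- synthesis_problem(
    d, "MultipleProteinSequence", "Sequence",
    constraints = "Enforce the use of module ehmmemit",
    depth_bound = 4)
  shortest <- synthesize(problem, shortest_only = TRUE)
  expect_identical(solution_services(shortest),
                   list(c("edialign", "ehmmbuild", "ehmmemit"),
                        c("emma", "ehmmbuild", "ehmmemit")))
})

test_that("start types are inferred by path-intersection data flow", {
  d <- load_fixture("manual_hmmer")
  p1 <- load_fixture("align_view_process")
  expect_identical(infer_start_types(p1, 1, d),
                   state("MultipleNucleotideSequence"))

  # two branches produce {A,B} and {A,C}; only A is guaranteed at the merge
  dom <- domain_model(list(
    service_spec("src", character(), character()),
    service_spec("p1", character(), c("A", "B")),
    service_spec("p2", character(), c("A", "C")),
    service_spec("merge", character(), character()),
    service_spec("sink", "A", character())))
  proc <- process_model(
    c(n0 = "src", n1 = "p1", n2 = "p2", n3 = "merge", n4 = "sink"),
    data.frame(from = c("n0", "n0", "n1", "n2", "n3"),
               to = c("n1", "n2", "n3", "n3", "n4"),
               loose = c(FALSE, FALSE, FALSE, FALSE, TRUE)),
    initial = "n0")
  expect_identical(infer_start_types(proc, c("n3", "n4"), dom), state("A"))

  # single node, loose self-referential edge source with no outputs
  solo <- process_model(c(n = "src"),
                        data.frame(from = "n", to = "n", loose = TRUE),
                        initial = "n")
  expect_identical(infer_start_types(solo, 1, dom), state(character()))

  # unreachable loose edge source
  disc <- process_model(c(a = "src", b = "p1", c = "sink"),
                        data.frame(from = c("a", "b"), to = c("a", "c"),
                                   loose = c(FALSE, TRUE)),
                        initial = "a")
  expect_error(infer_start_types(disc, c("b", "c"), dom), "unreachable")
})

test_that("problems built from loose edges use the downstream input types", {
  d <- load_fixture("manual_hmmer")
  pr <- problem_from_loose_edge(load_fixture("align_view_process"), 1, d)
  expect_identical(pr$start, state("MultipleNucleotideSequence"))
  expect_identical(pr$goal, state("Alignment"))
})

test_that("solutions are spliced into the process as a concrete chain", {
  d <- load_fixture("manual_hmmer")
  p1 <- load_fixture("align_view_process")
  done <- insert_solution(p1, 1, "emma", d)
  expect_identical(nrow(loose_edges(done)), 0L)
  expect_identical(done$nodes$service[match(c("makenucseq", "synth_emma",
                                              "showalign"), done$nodes$id)],
                   c("makenucseq", "emma", "showalign"))
  expect_setequal(paste(done$edges$from, done$edges$to),
                  c("makenucseq synth_emma", "synth_emma showalign"))

  # empty solution becomes a direct concrete edge
  p2 <- load_fixture("feature_view_process")
  direct <- insert_solution(p2, 1, character(), d)
  expect_identical(nrow(loose_edges(direct)), 0L)
  expect_identical(nrow(direct$edges), 1L)

  # an invalid solution is a contract violation
  expect_error(insert_solution(p1, 1, "ehmmfetch", d), "contract violation")

  # the three-step solution yields the five-node display chain
  five <- insert_solution(p2, 1, c("emma", "ehmmbuild", "ehmmemit"), d)
  expect_identical(nrow(five$nodes), 5L)
  tail_node <- five$edges$from[five$edges$to == "showfeat"]
  expect_identical(five$nodes$service[five$nodes$id == tail_node], "ehmmemit")
})

test_that("search agrees with the brute-force oracle under constraints", {
  d <- load_fixture("manual_hmmer")
  problems <- list(
    synthesis_problem(d, "MultipleNucleotideSequence", "Alignment",
                      depth_bound = 3),
    synthesis_problem(d, "MultipleProteinSequence", "Sequence",
                      constraints = "Enforce the use of module ehmmemit",
                      depth_bound = 3),
    synthesis_problem(d, "MultipleProteinSequence", "Sequence",
                      constraints = list("Do not use emma",
                                         "Use Display as last service in solution"),
                      depth_bound = 3))
  for (pr in problems) {
    expect_identical(solution_services(synthesize(pr)),
                     solution_services(brute_force_oracle(pr)))
  }
})

test_that("solution ordering is by length then lexicographic, capped", {
  d <- load_fixture("manual_hmmer")
  pr <- synthesis_problem(d, "MultipleNucleotideSequence", "Alignment",
                          depth_bound = 2)
  sols <- solution_services(synthesize(pr))
  lens <- lengths(sols)
  expect_true(all(diff(lens) >= 0))
  within <- split(vapply(sols, paste, character(1), collapse = "\x01"), lens)
  for (grp in within) expect_false(is.unsorted(grp))

  capped <- synthesis_problem(d, "MultipleNucleotideSequence", "Alignment",
                              depth_bound = 2, solution_cap = 3)
  expect_length(synthesize(capped), 3L)
  expect_identical(solution_services(synthesize(capped)), sols[1:3])
})

test_that("adding constraints never shortens the shortest solution", {
  d <- load_fixture("manual_hmmer")
  base <- synthesis_problem(d, "MultipleProteinSequence", "Sequence",
                            depth_bound = 3)
  len0 <- length(synthesize(base, shortest_only = TRUE)[[1]]$services)
  for (con in c("Enforce the use of module ehmmemit",
                "Do not use emma",
                "Use showfeat as last service in solution")) {
    pr <- synthesis_problem(d, "MultipleProteinSequence", "Sequence",
                            constraints = con, depth_bound = 3)
    sols <- synthesize(pr, shortest_only = TRUE)
    if (length(sols))
      expect_gte(length(sols[[1]]$services), len0)
  }
})

test_that("unsatisfiable specifications return an empty collection", {
  d <- load_fixture("auto_hmmer")
  pr <- synthesis_problem(d, "makenucseq_seqoutall_output",
                          "sequence_alignment_data", depth_bound = 4)
  expect_length(synthesize(pr), 0L)
  pr2 <- synthesis_problem(tiny_domain(), "raw", "raw",
                           constraints = list(f_false()), depth_bound = 2)
  expect_length(synthesize(pr2), 0L)
})
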