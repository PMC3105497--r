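test_that("states satisfy requirements through subsumption", {
  d <- load_fixture("manual_hmmer")
  tx <- d$type_taxonomy
  expect_true(satisfies_requirement(state("MultipleNucleotideSequence"),
                                    "MultipleSequence", tx))
  expect_true(satisfies_requirement(state("Alignment"), "Alignment", tx))
  expect_false(satisfies_requirement(state(), "Alignment", tx))
  expect_false(satisfies_requirement(state("MultipleNucleotideSequence"),
                                     "HMM", tx))
})

test_that("applicability is the subsumption-lifted subset check", {
  d <- load_fixture("manual_hmmer")
  mns <- state("MultipleNucleotideSequence")
  expect_true(applicable("emma", mns, d))
  expect_true(applicable("makenucseq", state(), d))
  expect_false(applicable("ehmmalign", mns, d))
  expect_true(applicable("showseq", mns, d))
  expect_false(applicable("showpep", mns, d))
})

test_that("successor unions the outputs and rejects inapplicable services", {
  d <- load_fixture("manual_hmmer")
  mns <- state("MultipleNucleotideSequence")
  expect_identical(successor(mns, "emma", d),
                   state(c("MultipleNucleotideSequence", "Alignment", "Tree")))
  s <- state(c("Alignment", "MultipleNucleotideSequence"))
  expect_identical(successor(s, "showalign", d), s)  # sink adds nothing
  expect_identical(successor(successor(mns, "emma", d), "emma", d),
                   successor(mns, "emma", d))        # idempotent union
  expect_error(successor(mns, "ehmmalign", d), "not applicable")
})

test_that("states grow monotonically and applicability is monotone", {
  d <- tiny_domain()
  for (tr in enumerate_traces(d, "raw", 3)) {
    sts <- tr$states
    for (i in seq_len(length(sts) - 1L))
      expect_true(all(sts[[i]] %in% sts[[i + 1L]]))
  }
  # applicable(svc, S) and S subset S2 implies applicable(svc, S2)
  md <- load_fixture("manual_hmmer")
  univ <- names(md$type_taxonomy$instances)
  set.seed(42)
  for (rep in 1:50) {
    s1 <- state(sample(univ, sample.int(4L, 1L)))
    s2 <- state(c(s1, sample(univ, sample.int(3L, 1L))))
    for (svc in sample(names(md$services), 4L)) {
      if (applicable(svc, s1, md)) expect_true(applicable(svc, s2, md))
      # successor commutes with state enlargement
      if (applicable(svc, s1, md)) {
        extra <- setdiff(s2, s1)
        expect_identical(state(c(successor(s1, svc, md), extra)),
                         successor(s2, svc, md))
      }
    }
  }
})

test_that("validate_domain reports structural defects as diagnostics", {
  expect_identical(nrow(validate_domain(load_fixture("manual_hmmer"))), 0L)
  expect_identical(nrow(validate_domain(load_fixture("auto_hmmer"))), 0L)

  # service referencing an undeclared type: constructor attaches it under
  # the root, so build the broken taxonomy state by hand
  d <- load_fixture("manual_hmmer")
  broken <- d
  broken$services$emma$inputs <- c(broken$services$emma$inputs, "NoSuchType")
  diags <- validate_domain(broken)
  expect_identical(diags$code, "unknown_type")
  expect_match(diags$message, "NoSuchType")

  cyc <- d
  cyc$type_taxonomy <- taxonomy("Thing", classes = list(A = "B", B = "A"))
  diags <- validate_domain(cyc)
  expect_true("cycle" %in% diags$code)
})

test_that("reachability diagnostics only run against declared starts", {
  d <- load_fixture("manual_hmmer")
  expect_identical(nrow(validate_domain(d)), 0L)
  diags <- validate_domain(d, starts = list(character()))
  # nothing produces the HMM/sequence databases from scratch
  expect_setequal(
    sub("service '(.*)' is never.*", "\\1",
        diags$message[diags$code == "unreachable_service"]),
    c("ehmmfetch", "ehmmindex", "ehmmpfam", "ehmmsearch"))
})

test_that("domain files round-trip structurally", {
  for (fx in c("manual_hmmer", "auto_hmmer", "dbloop_domain")) {
    d <- load_fixture(fx)
    path <- withr::local_tempfile(fileext = ".yaml")
    write_domain(d, path)
    expect_identical(read_domain(path), d)
  }
})

test_that("malformed domain files produce parse errors", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("services:\n  s1:\n    inputs: [a]", path)
  expect_error(read_domain(path), "missing section")
  writeLines("not yaml: [unbalanced", path)
  expect_error(read_domain(path), "parse")
})
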