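calibrate_formula <- "ehmmbuild => (!ehmmemit WU ehmmcalibrate)"

test_that("an uncalibrated HMM chain is flagged exactly at the build step", {
  d <- load_fixture("manual_hmmer")
  v <- check_process(load_fixture("hmm_emit_chain"), calibrate_formula, d)
  expect_identical(violated_nodes(v), "ehmmbuild")
  expect_identical(unname(v$verdicts[c("ehmmemit", "showseq")]),
                   c("holds", "holds"))
  w <- v$witnesses[["ehmmbuild"]]
  expect_identical(w$nodes[1], "ehmmbuild")
  expect_true(is.na(w$loop_start))
})

test_that("inserting the calibration step satisfies the property everywhere", {
  d <- load_fixture("manual_hmmer")
  v <- check_process(load_fixture("hmm_emit_chain_calibrated"), calibrate_formula, d)
  expect_length(violated_nodes(v), 0L)
})

test_that("fetching the HMM instead of building it holds vacuously", {
  d <- load_fixture("manual_hmmer")
  v <- check_process(load_fixture("hmm_fetch_chain"), calibrate_formula, d)
  expect_length(violated_nodes(v), 0L)
})

test_that("chain verdicts at the initial node match trace evaluation", {
  d <- load_fixture("manual_hmmer")
  chains <- list(c("emma", "ehmmbuild", "ehmmemit", "showseq"),
                 c("emma", "ehmmbuild", "ehmmcalibrate", "ehmmemit", "showseq"),
                 c("makenucseq", "showseq"),
                 c("emma"))
  formulas <- list(parse_pltl(calibrate_formula),
                   f_eventually(f_exec("Display")),
                   f_globally(f_implies(f_exec("ehmmbuild"),
                                        f_eventually(f_exec("ehmmcalibrate")))),
                   f_until(f_not(f_exec("showseq")), f_exec("ehmmemit")))
  for (services in chains) {
    proc <- process_model(stats::setNames(services,
                                          paste0("n", seq_along(services))),
                          if (length(services) > 1L)
                            data.frame(from = paste0("n", seq_len(length(services) - 1L)),
                                       to = paste0("n", seq_len(length(services) - 1L) + 1L))
                          else NULL,
                          initial = "n1")
    tr <- structure(list(states = rep(list(character()),
                                      length(services) + 1L),
                         services = services),
                    class = "wf_trace")
    for (f in formulas) {
      v <- check_process(proc, f, d)
      expect_identical(unname(v$verdicts[["n1"]] == "holds"),
                       evaluate(f, tr, d))
    }
  }
})

test_that("loops are checked with lasso semantics", {
  d <- load_fixture("dbloop_domain")
  # fetch -> iterate -> fetch ... forever: the loop never reaches a display
  proc <- process_model(c(f = "uniprot_fetch", i = "next_uniprot_id"),
                        data.frame(from = c("f", "i"), to = c("i", "f")),
                        initial = "f")
  v <- check_process(proc, f_eventually(f_exec("Display")), d)
  expect_identical(sort(violated_nodes(v)), c("f", "i"))
  expect_false(is.na(v$witnesses[["f"]]$loop_start))
  # safety properties hold on the same loop
  v2 <- check_process(proc, f_globally(f_not(f_exec("Display"))), d)
  expect_length(violated_nodes(v2), 0L)
  # a liveness property satisfied inside the loop holds
  v3 <- check_process(proc, f_globally(f_eventually(f_exec("uniprot_fetch"))), d)
  expect_length(violated_nodes(v3), 0L)
})

test_that("weakening the formula never adds violations", {
  d <- load_fixture("manual_hmmer")
  procs <- list(load_fixture("hmm_emit_chain"), load_fixture("hmm_emit_chain_calibrated"))
  pairs <- list(
    list(strong = f_globally(f_not(f_exec("ehmmemit"))),
         weak = f_eventually(f_not(f_exec("ehmmemit")))),
    list(strong = f_and(f_eventually(f_exec("ehmmbuild")),
                        f_eventually(f_exec("showseq"))),
         weak = f_eventually(f_exec("ehmmbuild"))))
  for (proc in procs) {
    for (p in pairs) {
      strong <- check_process(proc, p$strong, d)
      weak <- check_process(proc, p$weak, d)
      expect_true(all(violated_nodes(weak) %in% violated_nodes(strong)))
    }
  }
})

test_that("preconditions are enforced", {
  d <- load_fixture("manual_hmmer")
  expect_error(check_process(load_fixture("align_view_process"),
                             "G true", d), "loosely specified")
  expect_error(check_process(load_fixture("hmm_emit_chain"),
                             f_globally(f_avail("HMM")), d),
               "not supported")
  expect_error(check_process(load_fixture("hmm_emit_chain"),
                             "G nonexistent_service", d), "unknown name")
})
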