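# Expected input/output behavior of the automatically derived HMMER-subset
# domain, one entry per service (input and output cells compared as sets).
auto_expected <- list(
  edialign = list(inputs = "sequence_record",
                  outputs = c("edialign_seqoutall_output", "edialign_output")),
  ehmmalign = list(inputs = c("protein_sequence_record",
                              "hmmer_hidden_markov_model"),
                   outputs = "ehmmalign_align_output"),
  ehmmbuild = list(inputs = "protein_sequence_alignment_data",
                   outputs = "hmm"),
  ehmmcalibrate = list(inputs = "hmmer_hidden_markov_model",
                       outputs = c("hmmer_histogram", "hmmcalibrate_output")),
  ehmmconvert = list(inputs = "hmmer_hidden_markov_model", outputs = "hmm"),
  ehmmemit = list(inputs = "hmmer_hidden_markov_model",
                  outputs = "hmmemit_output"),
  ehmmfetch = list(inputs = c("hmmer_hidden_markov_model_identifier",
                              "hmmer_hidden_markov_model_database"),
                   outputs = "hmm"),
  ehmmindex = list(inputs = "hmmer_hidden_markov_model_database",
                   outputs = character()),
  ehmmpfam = list(inputs = c("protein_sequence_record",
                             "hmmer_hidden_markov_model"),
                  outputs = "hmmpfam_output"),
  ehmmsearch = list(inputs = c("protein_sequence_record",
                               "hmmer_hidden_markov_model"),
                    outputs = "hmmsearch_output"),
  emma = list(inputs = "sequence_record",
              outputs = c("emma_seqoutset_output", "dendrogram")),
  makenucseq = list(inputs = character(),
                    outputs = "makenucseq_seqoutall_output"),
  makeprotseq = list(inputs = character(),
                     outputs = "makeprotseq_seqoutall_output"),
  showalign = list(inputs = "sequence_alignment_data",
                   outputs = "showalign_output"),
  showfeat = list(inputs = "sequence_record", outputs = "showfeat_output"),
  showpep = list(inputs = "protein_sequence_record",
                 outputs = "showpep_output"),
  showseq = list(inputs = "dna_sequence_record", outputs = "showseq_output"))

test_that("the derived domain reproduces the expected table cell for cell", {
  d <- load_fixture("auto_hmmer")
  expect_setequal(names(d$services), names(auto_expected))
  for (nm in names(auto_expected)) {
    expect_setequal(d$services[[nm]]$inputs, auto_expected[[nm]]$inputs)
    expect_setequal(d$services[[nm]]$outputs, auto_expected[[nm]]$outputs)
  }
})

test_that("derived domains validate cleanly and link types to the ontology", {
  d <- load_fixture("auto_hmmer")
  diags <- validate_domain(d)
  expect_identical(nrow(diags), 0L)
  tx <- d$type_taxonomy
  # annotated outputs are classified; unannotated ones sit under the root
  expect_true(subsumes(tx, "sequence_record", "makenucseq_seqoutall_output"))
  expect_true(subsumes(tx, "sequence_record", "emma_seqoutset_output"))
  expect_true(subsumes(tx, "hmmer_hidden_markov_model", "hmm"))
  expect_identical(tx$instances[["dendrogram"]], character())
  expect_identical(tx$instances[["showfeat_output"]], character())
  # terms outside the ontology become classes directly under the root
  expect_true("sequence_alignment_data" %in% taxonomy_names(tx))
  expect_true("protein_sequence_alignment_data" %in% taxonomy_names(tx))
})

test_that("only the annotated services are classified below the root", {
  d <- load_fixture("auto_hmmer")
  stx <- d$service_taxonomy
  classified <- names(Filter(length, stx$instances))
  expect_setequal(classified, c("edialign", "emma", "showalign"))
  expect_true(subsumes(stx, "multiple_sequence_alignment", "emma"))
  expect_true(subsumes(stx, "sequence_alignment", "edialign"))
  expect_true(subsumes(stx, "sequence_visualisation", "showalign"))
})

test_that("an ACD without parameters yields an I/O-free service", {
  onto <- load_fixture("mini_edam")
  acd <- parse_acd('application: bare [ documentation: "no parameters" ]')
  d <- build_auto_domain(list(acd), onto)
  expect_identical(d$services$bare$inputs, character())
  expect_identical(d$services$bare$outputs, character())
  expect_identical(nrow(validate_domain(d)), 0L)
})

test_that("non-I/O sections contribute no types", {
  onto <- load_fixture("mini_edam")
  acd <- parse_acd(c(
    'application: toy [ documentation: "toy" ]',
    'section: advanced [ type: "page" ]',
    '  infile: extra [ relations: "EDAM: 1000003 ! Sequence record" ]',
    'endsection: advanced',
    'section: input [ type: "page" ]',
    '  seqset: seqs [ relations: "EDAM: 1000003 ! Sequence record" ]',
    'endsection: input'))
  d <- build_auto_domain(list(acd), onto)
  expect_identical(d$services$toy$inputs, "sequence_record")
  expect_identical(d$services$toy$outputs, character())
})

test_that("annotation statistics count files and parameters as defined", {
  # 3 files: two annotated (one of them only at parameter level), one bare;
  # 10 parameters of which 9 carry relations
  rel <- function(n) sprintf('  infile: p%d [ relations: "EDAM: 1000003 ! Sequence record" ]', n)
  norel <- function(n) sprintf('  infile: p%d [ information: "plain" ]', n)
  f1 <- parse_acd(c('application: one [ relations: "EDAM: 2000003 ! Multiple sequence alignment" ]',
                    'section: input [ ]', vapply(1:4, rel, character(1)),
                    'endsection: input'))
  f2 <- parse_acd(c('application: two [ documentation: "x" ]',
                    'section: input [ ]', vapply(1:5, rel, character(1)),
                    norel(6), 'endsection: input'))
  f3 <- parse_acd('application: three [ documentation: "x" ]')
  st <- annotation_stats(list(f1, f2, f3))
  expect_identical(st$n_files, 3L)
  expect_equal(st$pct_files_with_any_relation, 200 / 3)
  expect_equal(st$pct_files_with_application_relation, 100 / 3)
  expect_equal(st$pct_files_with_parameter_relation, 200 / 3)
  expect_equal(st$pct_parameters_with_relation, 90)
  expect_identical(st$application_relations_per_file$min, 1L)
  expect_identical(st$application_relations_per_file$max, 1L)
  expect_equal(st$parameter_relations_per_file$mean, 4.5)
  expect_identical(st$parameter_relations_per_file$max, 5L)

  none <- annotation_stats(list(f3))
  expect_equal(none$pct_files_with_any_relation, 0)
  expect_equal(none$pct_parameters_with_relation, 0)
  empty <- annotation_stats(list())
  expect_identical(empty$n_files, 0L)
  expect_equal(empty$pct_files_with_any_relation, 0)
})
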