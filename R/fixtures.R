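#' Bundled example domains and processes
#'
#' The package ships a worked example domain: the HMMER subset of the
#' EMBOSS suite (the nine `e`-prefixed HMMER profile-HMM tools plus the
#' multiple-alignment tools `emma` and `edialign`, the random-sequence
#' generators `makenucseq`/`makeprotseq`, and the `show*` display tools).
#' Two disparate setups of the same subset are available: a manually
#' curated domain with high-level type nomenclature, and an automatically
#' derived domain built by [build_auto_domain()] from the ACD descriptors
#' and the miniature EDAM-style ontology under `inst/extdata/` (both
#' synthetic reconstructions of the corresponding upstream files).
#'
#' Known names:
#' \describe{
#'   \item{`manual_hmmer`}{manually curated HMMER-subset domain (17 services).}
#'   \item{`auto_hmmer`}{the same subset derived from the ACD + ontology fixtures.}
#'   \item{`mini_edam`}{the miniature ontology, parsed (`wf_ontology`).}
#'   \item{`edialign_acd`}{text of the edialign ACD descriptor.}
#'   \item{`acd_dir`}{path of the directory holding all ACD fixtures.}
#'   \item{`align_view_process`}{makenucseq -(loose)-> showalign.}
#'   \item{`feature_view_process`}{makeprotseq -(loose)-> showfeat.}
#'   \item{`hmm_emit_chain`}{emma -> ehmmbuild -> ehmmemit -> showseq.}
#'   \item{`hmm_emit_chain_calibrated`}{the same chain with ehmmcalibrate inserted.}
#'   \item{`hmm_fetch_chain`}{ehmmfetch -> ehmmemit -> showseq.}
#'   \item{`dbloop_domain`}{manual domain extended with remote-service
#'     stubs and protein-analysis tools for the loop example.}
#'   \item{`dbloop_process`}{the loop workflow with a loose branch.}
#' }
#'
#' @param name fixture name (see above).
#' @return the fixture object (`wf_domain`, `wf_process`, `wf_ontology`,
#'   or character).
#' @export
load_fixture <- function(name) {
  known <- c("manual_hmmer", "auto_hmmer", "mini_edam", "edialign_acd",
             "acd_dir", "align_view_process", "feature_view_process",
             "hmm_emit_chain", "hmm_emit_chain_calibrated", "hmm_fetch_chain",
             "dbloop_domain", "dbloop_process")
  if (!name %in% known)
    stop(sprintf("unknown fixture '%s'; known fixtures: %s",
                 name, paste(known, collapse = ", ")), call. = FALSE)
  switch(name,
    manual_hmmer = fixture_manual_hmmer(),
    auto_hmmer = fixture_auto_hmmer(),
    mini_edam = parse_obo_file(fixture_path("mini_edam.obo")),
    edialign_acd = paste(readLines(fixture_path("acd/edialign.acd")),
                         collapse = "\n"),
    acd_dir = fixture_path("acd"),
    align_view_process = process_model(
      c(makenucseq = "makenucseq", showalign = "showalign"),
      data.frame(from = "makenucseq", to = "showalign", loose = TRUE),
      initial = "makenucseq"),
    feature_view_process = process_model(
      c(makeprotseq = "makeprotseq", showfeat = "showfeat"),
      data.frame(from = "makeprotseq", to = "showfeat", loose = TRUE),
      initial = "makeprotseq"),
    hmm_emit_chain = chain_process(c("emma", "ehmmbuild", "ehmmemit", "showseq")),
    hmm_emit_chain_calibrated = chain_process(c("emma", "ehmmbuild", "ehmmcalibrate",
                                       "ehmmemit", "showseq")),
    hmm_fetch_chain = chain_process(c("ehmmfetch", "ehmmemit", "showseq")),
    dbloop_domain = fixture_dbloop_domain(),
    dbloop_process = fixture_dbloop_process())
}

fixture_path <- function(...) {
  p <- system.file("extdata", ..., package = "flowsynth")
  if (!nzchar(p))
    stop("fixture file not found: ", file.path(...), call. = FALSE)
  p
}

# linear chain whose node ids equal the service names
chain_process <- function(services) {
  n <- length(services)
  process_model(stats::setNames(services, services),
                if (n > 1L) data.frame(from = services[-n], to = services[-1L])
                else NULL,
                initial = services[[1L]])
}

# Manually curated HMMER-subset domain: service descriptions, symbolic
# input/output types, and the hand-drawn service and type taxonomies.
fixture_manual_hmmer <- function() {
  svc <- function(name, ins, outs, desc)
    service_spec(name, ins, outs, desc)
  services <- list(
    svc("edialign", "MultipleSequence", "Alignment",
        "Local multiple alignment of sequences."),
    svc("ehmmalign", c("HMM", "Sequence"), "Alignment",
        "Align sequences to an HMM profile."),
    svc("ehmmbuild", "Alignment", "HMM",
        "Build a profile HMM from an alignment."),
    svc("ehmmcalibrate", "HMM", "HMM",
        "Calibrate HMM search statistics."),
    svc("ehmmconvert", "HMM", "HMM",
        "Convert between profile HMM file formats."),
    svc("ehmmemit", "HMM", "EhmmemitOutput",
        "Generate sequences from a profile HMM."),
    svc("ehmmfetch", "HMMDatabase", "HMM",
        "Retrieve an HMM from an HMM database."),
    svc("ehmmindex", "HMMDatabase", "HMMDatabase",
        "Create a binary SSI index for an HMM database."),
    svc("ehmmpfam", c("HMMDatabase", "Sequence"), "EhmmpfamOutput",
        "Search one or more sequences against an HMM database."),
    svc("ehmmsearch", c("HMM", "SequenceDatabase"), "EhmmsearchOutput",
        "Search sequence database with a profile HMM."),
    svc("emma", "MultipleSequence", c("Alignment", "Tree"),
        "Global multiple alignment of sequences."),
    svc("makenucseq", character(), "MultipleNucleotideSequence",
        "Create random nucleotide sequences."),
    svc("makeprotseq", character(), "MultipleProteinSequence",
        "Create random protein sequences."),
    svc("showalign", "Alignment", character(),
        "Display a multiple sequence alignment in pretty format."),
    svc("showfeat", "Sequence", character(),
        "Display features of a sequence in pretty format."),
    svc("showpep", "ProteinSequence", character(),
        "Displays protein sequences with features in pretty format."),
    svc("showseq", "NucleotideSequence", character(),
        "Display sequences with features in pretty format."))

  type_tx <- taxonomy(
    "Thing",
    classes = list(
      Text = "Thing",
      Sequence = "Text",
      ProteinSequence = "Sequence",
      NucleotideSequence = "Sequence",
      MultipleSequence = "Sequence"),
    instances = list(
      MultipleNucleotideSequence = c("MultipleSequence", "NucleotideSequence"),
      MultipleProteinSequence = c("MultipleSequence", "ProteinSequence"),
      Alignment = "Text",
      HMM = "Text",
      HMMDatabase = "Text",
      SequenceDatabase = "Text",
      Tree = "Text",
      EhmmemitOutput = "Text",
      EhmmpfamOutput = "Text",
      EhmmsearchOutput = "Text"))

  service_tx <- taxonomy(
    "Thing",
    classes = list(
      Edit = "Thing",
      Display = "Thing",
      AlignmentMultiple = "Thing",
      HMM = "Thing"),
    instances = list(
      makenucseq = "Edit",
      makeprotseq = "Edit",
      showalign = "Display",
      showfeat = "Display",
      showpep = "Display",
      showseq = "Display",
      edialign = "AlignmentMultiple",
      emma = "AlignmentMultiple",
      ehmmalign = "HMM",
      ehmmbuild = "HMM",
      ehmmcalibrate = "HMM",
      ehmmconvert = "HMM",
      ehmmemit = "HMM",
      ehmmfetch = "HMM",
      ehmmindex = "HMM",
      ehmmpfam = "HMM",
      ehmmsearch = "HMM"))

  domain_model(services, type_taxonomy = type_tx,
               service_taxonomy = service_tx)
}

fixture_auto_hmmer <- function() {
  dir <- fixture_path("acd")
  acds <- lapply(sort(list.files(dir, pattern = "\\.acd$", full.names = TRUE)),
                 parse_acd_file)
  build_auto_domain(acds, parse_obo_file(fixture_path("mini_edam.obo")))
}

# Manual domain extended for the database-loop example: opaque stubs for
# the remote DDBJ/BLAST/Uniprot steps plus a handful of protein-analysis
# and display tools with reconstructed symbolic types.
fixture_dbloop_domain <- function() {
  base <- fixture_manual_hmmer()
  extra <- list(
    service_spec("ddbj_getentry", character(), "DDBJEntry",
                 "Fetch a nucleotide sequence entry from DDBJ (stub)."),
    service_spec("ddbj_blast", "NucleotideSequence", "BlastReport",
                 "BLAST search against a protein database (stub)."),
    service_spec("extract_uniprot_ids", "BlastReport", "UniprotID",
                 "Extract Uniprot identifiers from a BLAST report (stub)."),
    service_spec("uniprot_fetch", "UniprotID", "UniprotEntry",
                 "Fetch the Uniprot entry for an identifier (stub)."),
    service_spec("next_uniprot_id", "UniprotID", character(),
                 "Advance the identifier loop (stub)."),
    service_spec("pepwheel", "ProteinSequence", "PepwheelPlot",
                 "Draw a helical wheel diagram for a protein sequence."),
    service_spec("garnier", "ProteinSequence", "GarnierReport",
                 "Predict protein secondary structure (GOR method)."),
    service_spec("pepcoil", "ProteinSequence", "PepcoilReport",
                 "Predict coiled-coil regions in protein sequences."),
    service_spec("helixturnhelix", "ProteinSequence", "HthReport",
                 "Identify nucleic-acid-binding motifs in proteins."),
    service_spec("pepstats", "ProteinSequence", "PepstatsReport",
                 "Calculate statistics of protein properties."),
    service_spec("shuffleseq", "Sequence", "ShuffledSequence",
                 "Shuffle a set of sequences maintaining composition."),
    service_spec("showreport", "Report", character(),
                 "Display the textual content of an analysis report."))

  ttx <- base$type_taxonomy
  ttx_classes <- c(ttx$classes, list(Report = "Text"))
  ttx_instances <- c(ttx$instances, list(
    DDBJEntry = "NucleotideSequence",
    BlastReport = "Report",
    UniprotID = "Text",
    UniprotEntry = "ProteinSequence",
    PepwheelPlot = "Text",
    GarnierReport = "Report",
    PepcoilReport = "Report",
    HthReport = "Report",
    PepstatsReport = "Report",
    ShuffledSequence = "Sequence"))

  stx <- base$service_taxonomy
  stx_classes <- c(stx$classes, list(Protein2dStructure = "Thing",
                                     Remote = "Thing"))
  stx_instances <- c(stx$instances, list(
    ddbj_getentry = "Remote",
    ddbj_blast = "Remote",
    extract_uniprot_ids = "Remote",
    uniprot_fetch = "Remote",
    next_uniprot_id = "Remote",
    pepwheel = c("Protein2dStructure", "Display"),
    garnier = "Protein2dStructure",
    pepcoil = "Protein2dStructure",
    helixturnhelix = "Protein2dStructure",
    pepstats = "Edit",
    shuffleseq = "Edit",
    showreport = "Display"))

  domain_model(
    c(unname(base$services), extra),
    type_taxonomy = taxonomy("Thing", ttx_classes, ttx_instances),
    service_taxonomy = taxonomy("Thing", stx_classes, stx_instances))
}

fixture_dbloop_process <- function() {
  process_model(
    c(getentry = "ddbj_getentry",
      blast = "ddbj_blast",
      extract = "extract_uniprot_ids",
      fetch = "uniprot_fetch",
      iterate = "next_uniprot_id"),
    data.frame(
      from = c("getentry", "blast", "extract", "fetch", "iterate"),
      to = c("blast", "extract", "fetch", "iterate", "fetch"),
      label = c("", "", "", "loop body", "next id"),
      loose = c(FALSE, FALSE, FALSE, TRUE, FALSE)),
    initial = "getentry")
}
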