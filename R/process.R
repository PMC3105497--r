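#' Workflow process graphs with loosely specified branches
#'
#' A process model is a directed graph of service instances: nodes carry a
#' unique id and the name of the service they execute, edges carry an
#' optional branch label and a `loose` flag.  A loose edge marks an
#' underspecified branch whose concretization is delegated to the
#' synthesis machinery ([synthesize()] / [insert_solution()]).
#'
#' @param nodes data.frame with columns `id` and `service`, or a named
#'   character vector `id = service`.
#' @param edges data.frame with columns `from`, `to` and optionally
#'   `label` (character) and `loose` (logical).
#' @param initial id of the initial node.
#' @return an object of class `wf_process`.
#' @export
process_model <- function(nodes, edges, initial) {
  if (is.character(nodes) && !is.null(names(nodes)))
    nodes <- data.frame(id = names(nodes), service = unname(nodes))
  stopifnot(is.data.frame(nodes), all(c("id", "service") %in% names(nodes)))
  nodes <- data.frame(id = as.character(nodes$id),
                      service = as.character(nodes$service))
  if (anyDuplicated(nodes$id))
    stop("duplicate node id(s): ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "),
         call. = FALSE)
  if (is.null(edges) || !nrow(as.data.frame(edges))) {
    edges <- data.frame(from = character(), to = character(),
                        label = character(), loose = logical())
  } else {
    edges <- as.data.frame(edges)
    stopifnot(all(c("from", "to") %in% names(edges)))
    if (is.null(edges$label)) edges$label <- ""
    if (is.null(edges$loose)) edges$loose <- FALSE
    edges <- data.frame(from = as.character(edges$from),
                        to = as.character(edges$to),
                        label = as.character(edges$label),
                        loose = as.logical(edges$loose))
    bad <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(bad))
      stop("edge endpoint(s) not in node set: ", paste(unique(bad), collapse = ", "),
           call. = FALSE)
  }
  stopifnot(is.character(initial), length(initial) == 1L)
  if (!initial %in% nodes$id)
    stop(sprintf("initial node '%s' is not in the node set", initial),
         call. = FALSE)
  structure(list(nodes = nodes, edges = edges, initial = initial),
            class = "wf_process")
}

#' @export
print.wf_process <- function(x, ...) {
  cat(sprintf("<process> %d nodes, %d edges (%d loose), initial '%s'\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$loose), x$initial))
  invisible(x)
}

process_service_of <- function(process, id) {
  i <- match(id, process$nodes$id)
  if (is.na(i)) stop(sprintf("unknown node id '%s'", id), call. = FALSE)
  process$nodes$service[i]
}

#' Loose edges of a process
#' @param process a `wf_process`.
#' @return data.frame of loose edges (subset of `process$edges`).
#' @export
loose_edges <- function(process) process$edges[process$edges$loose, , drop = FALSE]

process_igraph <- function(process) {
  igraph::graph_from_data_frame(
    process$edges[, c("from", "to"), drop = FALSE],
    directed = TRUE, vertices = process$nodes$id)
}

#' Read and write process files
#'
#' Processes are stored as YAML: a `nodes` map (id -> service name), an
#' `edges` list (`from`, `to`, optional `label`, optional `loose`), and
#' the `initial` node id.
#'
#' @param path file path.
#' @return `read_process()`: a `wf_process`; `write_process()`: `path`,
#'   invisibly.
#' @export
read_process <- function(path) {
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop(sprintf(
                    "failed to parse process file '%s': %s",
                    path, conditionMessage(e)), call. = FALSE))
  need <- c("nodes", "initial")
  missing <- setdiff(need, names(doc))
  if (length(missing))
    stop(sprintf("%s: missing section(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  nodes <- data.frame(id = names(doc$nodes),
                      service = as.character(unlist(doc$nodes)))
  edges <- if (length(doc$edges)) {
    do.call(rbind, lapply(doc$edges, function(e) data.frame(
      from = e$from, to = e$to,
      label = if (is.null(e$label)) "" else e$label,
      loose = isTRUE(e$loose))))
  } else NULL
  process_model(nodes, edges, doc$initial)
}

#' @param process a `wf_process`.
#' @rdname read_process
#' @export
write_process <- function(process, path) {
  stopifnot(inherits(process, "wf_process"))
  doc <- list(
    nodes = stats::setNames(as.list(process$nodes$service), process$nodes$id),
    edges = lapply(seq_len(nrow(process$edges)), function(i) {
      e <- process$edges[i, ]
      out <- list(from = e$from, to = e$to)
      if (nzchar(e$label)) out$label <- e$label
      if (e$loose) out$loose <- TRUE
      out
    }),
    initial = process$initial)
  yaml::write_yaml(doc, path)
  invisible(path)
}
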