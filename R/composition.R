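## Compatibility search and automatic pipeline discovery.
##
## Graph model: nodes are datatypes; every (operation, input parameter,
## output parameter) triple is a directed edge usable from the current
## datatype C whenever C is a subtype of the input parameter's declared
## datatype (services accept subtypes of their declared inputs).  Search is
## breadth-first over datatype states with a configurable depth bound;
## "optimum" means fewest operations, ties broken lexicographically on the
## (tool name, operation name, parameter name) sequence.  Secondary
## parameters never participate in linking.

## edge table, cached per registry version
.compatEdges <- function(registry) {
  .cached(registry, "edges", function() {
    ops <- .allRecords(registry, "operation")
    tools <- .allRecords(registry, "tool")
    rows <- list()
    for (op in ops) {
      tname <- if (op@toolRef %in% names(tools)) tools[[op@toolRef]]@name else ""
      ins <- Filter(function(p) p@kind == "input", op@parameters)
      outs <- Filter(function(p) p@kind == "output", op@parameters)
      for (pin in ins) for (pout in outs)
        rows[[length(rows) + 1L]] <- data.frame(
          opId = op@id, opName = op@name, toolId = op@toolRef, toolName = tname,
          inParam = pin@name, inType = pin@datatypeRef,
          outParam = pout@name, outType = pout@datatypeRef,
          stringsAsFactors = FALSE)
    }
    if (!length(rows))
      return(data.frame(opId = character(), opName = character(),
                        toolId = character(), toolName = character(),
                        inParam = character(), inType = character(),
                        outParam = character(), outType = character(),
                        stringsAsFactors = FALSE))
    df <- do.call(rbind, rows)
    df[order(df$toolName, df$opName, df$inParam, df$outParam, df$opId), ,
       drop = FALSE]
  })
}

#' Find operations that can consume a datatype
#'
#' Operations with at least one input parameter whose declared datatype is a
#' supertype (or the type itself) of `datatype` -- i.e. services that accept
#' an instance of it.
#'
#' @inheritParams newTool
#' @param datatype datatype name.
#' @return list of [OperationRecord-class], id-sorted.
#' @export
findConsumers <- function(registry, datatype) {
  .mustGet(registry, "datatype", datatype)
  keep <- character()
  for (op in .allRecords(registry, "operation"))
    for (p in op@parameters)
      if (p@kind == "input" && isSubtypeOf(registry, datatype, p@datatypeRef))
        keep <- union(keep, op@id)
  lapply(sort(keep), function(i) .mustGet(registry, "operation", i))
}

#' Find operations that can produce a datatype
#'
#' Operations with at least one output parameter whose declared datatype is
#' a subtype (or the type itself) of `datatype`.
#'
#' @inheritParams findConsumers
#' @return list of [OperationRecord-class], id-sorted.
#' @export
findProducers <- function(registry, datatype) {
  .mustGet(registry, "datatype", datatype)
  keep <- character()
  for (op in .allRecords(registry, "operation"))
    for (p in op@parameters)
      if (p@kind == "output" && isSubtypeOf(registry, p@datatypeRef, datatype))
        keep <- union(keep, op@id)
  lapply(sort(keep), function(i) .mustGet(registry, "operation", i))
}

.edgeStage <- function(edges, i) {
  list(operationId = edges$opId[i], operationName = edges$opName[i],
       toolId = edges$toolId[i], toolName = edges$toolName[i],
       inputParam = edges$inParam[i], inputDatatype = edges$inType[i],
       outputParam = edges$outParam[i], outputDatatype = edges$outType[i])
}

.mkPipeline <- function(registry, stageIdx, edges, source, target) {
  stages <- lapply(stageIdx, function(i) .edgeStage(edges, i))
  unresolved <- list()
  for (k in seq_along(stageIdx)) {
    i <- stageIdx[[k]]
    op <- .mustGet(registry, "operation", edges$opId[i])
    for (p in op@parameters)
      if (p@kind == "input" && p@name != edges$inParam[i])
        unresolved[[length(unresolved) + 1L]] <- list(
          stage = k, operation = op@id, parameter = p@name,
          datatype = p@datatypeRef)
  }
  new("Pipeline", stages = stages, source = source, target = target,
      unresolvedInputs = unresolved)
}

.pipelineSortKey <- function(p) {
  paste(c(sprintf("%04d", length(p@stages)),
          vapply(p@stages, function(s)
            paste(s$toolName, s$operationName, s$inputParam, s$outputParam,
                  sep = "\r"), character(1))),
        collapse = "\n")
}

#' Enumerate all valid pipelines between two datatypes
#'
#' Depth-first enumeration of every distinct operation chain of length
#' `1..maxLen` satisfying the type-link invariants, sorted by length and
#' then lexicographically by the (tool name, operation name) sequence so
#' that clients can present alternatives deterministically.
#'
#' @inheritParams newTool
#' @param source,target datatype names.
#' @param maxLen maximum number of operations per pipeline (>= 1).
#' @return list of [Pipeline-class] objects.
#' @export
enumeratePaths <- function(registry, source, target, maxLen = 4) {
  .mustGet(registry, "datatype", source)
  .mustGet(registry, "datatype", target)
  if (maxLen < 1) twStop("tw_bad_spec", "maxLen must be >= 1")
  edges <- .compatEdges(registry)
  found <- list()
  recurse <- function(current, path) {
    if (length(path) > 0 && isSubtypeOf(registry, current, target))
      found[[length(found) + 1L]] <<- path
    if (length(path) >= maxLen) return(invisible(NULL))
    for (i in seq_len(nrow(edges)))
      if (isSubtypeOf(registry, current, edges$inType[i]))
        recurse(edges$outType[i], c(path, i))
  }
  recurse(source, integer())
  pipes <- lapply(found, .mkPipeline, registry = registry, edges = edges,
                  source = source, target = target)
  pipes[order(vapply(pipes, .pipelineSortKey, character(1)))]
}

#' Find a shortest type-compatible pipeline
#'
#' Breadth-first search from the source datatype: an operation extends the
#' chain when the datatype produced so far is a subtype of one of its input
#' parameters; the chain is complete when the produced datatype satisfies
#' the target.  Returns a pipeline with the fewest operations; among equally
#' short pipelines the lexicographically smallest (tool name, operation
#' name) sequence is returned.  When the source already satisfies the target
#' the empty pipeline is returned.
#'
#' @inheritParams enumeratePaths
#' @param maxDepth depth bound for the search (default 6 operations).
#' @return a [Pipeline-class].
#' @export
findPath <- function(registry, source, target, maxDepth = 6) {
  .mustGet(registry, "datatype", source)
  .mustGet(registry, "datatype", target)
  if (isSubtypeOf(registry, source, target))
    return(new("Pipeline", stages = list(), source = source, target = target))
  edges <- .compatEdges(registry)
  ## BFS over datatype states for the minimal length
  frontier <- source
  visited <- source
  depth <- 0L
  minLen <- NA_integer_
  while (length(frontier) && depth < maxDepth && is.na(minLen)) {
    depth <- depth + 1L
    nxt <- character()
    for (cur in frontier) {
      for (i in seq_len(nrow(edges))) {
        if (!isSubtypeOf(registry, cur, edges$inType[i])) next
        out <- edges$outType[i]
        if (isSubtypeOf(registry, out, target)) minLen <- depth
        if (!(out %in% visited)) { visited <- c(visited, out); nxt <- c(nxt, out) }
      }
    }
    frontier <- unique(nxt)
  }
  if (is.na(minLen))
    twStop("tw_no_path", "no pipeline from '%s' to '%s' within depth %d",
           source, target, maxDepth)
  ## deterministic tie-break: smallest pipeline of that minimal length
  pipes <- enumeratePaths(registry, source, target, maxLen = minLen)
  pipes[[1L]]
}

#' Re-validate a pipeline's type-link invariants
#'
#' Independent re-check (not reusing any search state): the first stage must
#' accept the source, each stage's output must be a subtype of the next
#' stage's chosen input, and the last output must satisfy the target.
#'
#' @inheritParams newTool
#' @param pipeline a [Pipeline-class].
#' @return character vector of violations; empty when the pipeline is valid.
#' @export
checkPipeline <- function(registry, pipeline) {
  bad <- character()
  st <- pipeline@stages
  if (!length(st)) {
    if (!isSubtypeOf(registry, pipeline@source, pipeline@target))
      bad <- c(bad, "empty pipeline but source does not satisfy target")
    return(bad)
  }
  if (!isSubtypeOf(registry, pipeline@source, st[[1]]$inputDatatype))
    bad <- c(bad, "stage 1 does not accept the source datatype")
  if (length(st) > 1)
    for (k in seq_len(length(st) - 1))
      if (!isSubtypeOf(registry, st[[k]]$outputDatatype, st[[k + 1]]$inputDatatype))
        bad <- c(bad, sprintf("link %d -> %d violates the subtype relation", k, k + 1))
  if (!isSubtypeOf(registry, st[[length(st)]]$outputDatatype, pipeline@target))
    bad <- c(bad, "final output does not satisfy the target datatype")
  bad
}
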