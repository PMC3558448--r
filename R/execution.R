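## Execution module: protocol workers, the task lifecycle, pipeline
## enactment with automatic data adaptation, endpoint selection and usage
## statistics.

#' Construct a protocol worker
#'
#' Workers are the plug-ins that actually invoke tools; each handles exactly
#' the protocol it registers for.  The invoke function receives the resolved
#' [ToolLocationRecord-class], the [OperationRecord-class] and the named
#' input list, and returns a named list of outputs keyed by output parameter
#' name (or throws on failure).  A worker that declares a `wireFormat` asks
#' enactment to serialize structured data into that format before invocation
#' and to parse results back -- mirroring service protocols with a fixed
#' wire representation.  Workers run synchronously in-process; the
#' submit/poll/retrieve lifecycle is still observable through the task
#' status machine, and `passByReference` workers accept opaque string
#' references instead of inline data, which they resolve themselves.
#'
#' @param protocol protocol tag the worker serves.
#' @param invoke function(location, operation, inputs) -> named output list.
#' @param wireFormat optional format id for on-the-wire serialization.
#' @param passByReference whether inputs may be opaque references.
#' @return a worker object.
#' @export
newWorker <- function(protocol, invoke, wireFormat = NULL, passByReference = FALSE) {
  if (!is.character(protocol) || !nzchar(protocol))
    twStop("tw_bad_kind", "worker protocol tag must be non-empty")
  structure(list(protocol = protocol, invoke = invoke, wireFormat = wireFormat,
                 passByReference = passByReference), class = "tw_worker")
}

#' @rdname newWorker
#' @details `echoWorker` returns its inputs unchanged (keyed additionally by
#'   the operation's output parameter names), useful for tests and dry runs.
#' @export
echoWorker <- function(protocol = "local") {
  newWorker(protocol, function(location, operation, inputs) {
    outs <- Filter(function(p) p@kind == "output", operation@parameters)
    res <- inputs
    if (length(outs) && length(inputs))
      for (o in outs) res[[o@name]] <- inputs[[1]]
    res
  })
}

#' @rdname newWorker
#' @param results named output list (or function(location, operation,
#'   inputs) computing one) returned by `mockWorker` for every invocation.
#' @export
mockWorker <- function(protocol, results, wireFormat = NULL) {
  fn <- if (is.function(results)) results else function(location, operation, inputs) results
  newWorker(protocol, fn, wireFormat = wireFormat)
}

#' Register a worker for its protocol
#'
#' After registration, [addTask()] routes every location speaking the
#' worker's protocol to it.
#'
#' @inheritParams newTool
#' @param worker a worker from [newWorker()].
#' @return the protocol tag, invisibly.
#' @export
registerWorker <- function(registry, worker) {
  stopifnot(inherits(worker, "tw_worker"))
  st <- regState(registry)
  if (worker$protocol %in% names(st$workers))
    twStop("tw_duplicate_protocol", "a worker for protocol '%s' is already registered",
           worker$protocol)
  st$workers[[worker$protocol]] <- worker
  invisible(worker$protocol)
}

## legal transitions of the task state machine
.taskTransition <- function(task, to) {
  ok <- (task@status == "SUBMITTED" && to == "RUNNING") ||
        (task@status == "RUNNING" && to %in% c("SUCCEEDED", "FAILED"))
  if (!ok)
    twStop("tw_bad_kind", "illegal task transition %s -> %s", task@status, to)
  task@status <- to
  task@log <- c(task@log, to)
  task
}

.statBump <- function(registry, locationId, ok, elapsed) {
  be <- regState(registry)$backend
  rec <- bkGet(be, "stat", locationId)
  if (is.null(rec)) {
    rec <- new("StatRecord", locationRef = locationId)
    .storeAdd(registry, "stat", locationId, rec)
  }
  rec@count <- rec@count + 1
  rec@success <- rec@success + as.numeric(ok)
  rec@latency <- rec@latency + elapsed
  .storeUpdate(registry, "stat", locationId, rec)
}

#' Submit a task: invoke an operation at a concrete endpoint
#'
#' Creates the task (`SUBMITTED`), transitions it to `RUNNING`, routes it to
#' the worker registered for the location's protocol and finishes it as
#' `SUCCEEDED` or `FAILED`.  Every mandatory input parameter must be
#' present; structured inputs must be of the declared parameter datatype or
#' a subtype of it.  Usage statistics for the endpoint are recorded either
#' way.
#'
#' @inheritParams newTool
#' @param location id of the endpoint to invoke.
#' @param operation id of the operation.
#' @param inputs named list: parameter name -> [StructuredData-class],
#'   serialized string, or opaque data reference.
#' @return the finished [Task-class].
#' @export
addTask <- function(registry, location, operation, inputs = list()) {
  st <- regState(registry)
  loc <- .mustGet(registry, "location", location)
  op <- .mustGet(registry, "operation", operation)
  worker <- st$workers[[loc@protocol]]
  if (is.null(worker))
    twStop("tw_no_worker", "no worker registered for protocol '%s'", loc@protocol)
  for (p in op@parameters) {
    if (p@kind != "input") next
    if (!p@name %in% names(inputs))
      twStop("tw_missing_input", "mandatory input '%s' missing", p@name)
    v <- inputs[[p@name]]
    if (is(v, "StructuredData") && !isSubtypeOf(registry, v@datatype, p@datatypeRef))
      twStop("tw_type_mismatch", "input '%s' is a %s, not a subtype of %s",
             p@name, v@datatype, p@datatypeRef)
  }
  id <- .nextId(registry, "task")
  task <- new("Task", id = id, locationRef = loc@id, operationRef = op@id,
              inputs = inputs, status = "SUBMITTED", log = "SUBMITTED",
              timestamps = c(submitted = as.numeric(Sys.time())))
  task <- .taskTransition(task, "RUNNING")
  task@timestamps[["started"]] <- as.numeric(Sys.time())
  st$tasks[[id]] <- task
  t0 <- proc.time()[["elapsed"]]
  outcome <- tryCatch(list(ok = TRUE, value = worker$invoke(loc, op, inputs)),
                      error = function(e) list(ok = FALSE, error = e))
  elapsed <- proc.time()[["elapsed"]] - t0
  if (outcome$ok) {
    task <- .taskTransition(task, "SUCCEEDED")
    task@results <- outcome$value %||% list()
  } else {
    task <- .taskTransition(task, "FAILED")
    task@error <- list(message = conditionMessage(outcome$error),
                       class = class(outcome$error)[1])
  }
  task@timestamps[["finished"]] <- as.numeric(Sys.time())
  st$tasks[[id]] <- task
  .statBump(registry, loc@id, outcome$ok, elapsed)
  task
}

#' Query the task store
#'
#' `getTask` returns the stored [Task-class]; `getStatus` its status;
#' `getResults` the results map, erroring with `tw_not_finished` (carrying
#' the error payload for failed tasks) unless the task `SUCCEEDED`.
#'
#' @inheritParams newTool
#' @param task task id.
#' @return see details.
#' @export
getTask <- function(registry, task) {
  t <- regState(registry)$tasks[[task]]
  if (is.null(t)) twStop("tw_not_found", "task '%s' not found", task)
  t
}

#' @rdname getTask
#' @export
getStatus <- function(registry, task) getTask(registry, task)@status

#' @rdname getTask
#' @export
getResults <- function(registry, task) taskResults(getTask(registry, task))

#' Pick an endpoint for a tool (round-robin over mirrors)
#'
#' Eligible locations are the tool's mirrors whose protocol has a registered
#' worker, id-sorted; successive calls rotate through them so load spreads
#' and a dead mirror does not pin the client.
#'
#' @inheritParams getLocations
#' @return a [ToolLocationRecord-class].
#' @export
selectLocation <- function(registry, tool) {
  st <- regState(registry)
  locs <- getLocations(registry, tool)
  locs <- Filter(function(l) l@protocol %in% names(st$workers), locs)
  if (!length(locs))
    twStop("tw_no_location", "tool '%s' has no location with a registered worker", tool)
  cur <- st$rr[[tool]] %||% 0L
  pick <- locs[[(cur %% length(locs)) + 1L]]
  st$rr[[tool]] <- cur + 1L
  pick
}

#' Invoke a tool through mirror selection with optional retry
#'
#' Selects a location with [selectLocation()] and submits the task; when the
#' invocation fails, the registry option `retryOnFailure` (or the `retry`
#' argument) allows one retry on the next eligible mirror.
#'
#' @inheritParams addTask
#' @param tool tool id.
#' @param retry retry once on the next mirror after a failure; defaults to
#'   the registry option.
#' @return the finished [Task-class] (of the retry, when one happened).
#' @export
invokeTool <- function(registry, tool, operation, inputs = list(), retry = NULL) {
  st <- regState(registry)
  if (is.null(retry)) retry <- isTRUE(st$options$retryOnFailure)
  loc <- selectLocation(registry, tool)
  task <- addTask(registry, loc@id, operation, inputs)
  if (task@status == "FAILED" && retry) {
    nxt <- selectLocation(registry, tool)
    if (nxt@id != loc@id)
      task <- addTask(registry, nxt@id, operation, inputs)
  }
  task
}

#' Enact a discovered pipeline end to end
#'
#' Runs each stage in order: the datatype of the data produced so far is
#' re-checked against the stage's declared input parameter (subtype
#' acceptance), in-scope loaders run, the data is serialized into the wire
#' format the stage's worker declares (when it declares one), and the task
#' is submitted at a mirror chosen by [selectLocation()].  Mandatory inputs
#' the chain does not feed must be supplied in `extraInputs`, keyed by
#' parameter name.  Enactment aborts at the first failed stage; later
#' stages are never invoked.
#'
#' @inheritParams newTool
#' @param pipeline a [Pipeline-class] from [findPath()]/[enumeratePaths()].
#' @param initial [StructuredData-class] fed to the first stage (returned
#'   unchanged for an empty pipeline).
#' @param extraInputs named list covering the pipeline's unresolved inputs.
#' @return list with `data` (final stage output, parsed back to structured
#'   data when the wire format allows), `results` (the final task's raw
#'   result map) and `taskIds`.
#' @export
enactPipeline <- function(registry, pipeline, initial, extraInputs = list()) {
  if (!length(pipeline@stages))
    return(list(data = initial, results = list(), taskIds = character()))
  for (u in pipeline@unresolvedInputs)
    if (!u$parameter %in% names(extraInputs))
      twStop("tw_missing_input",
             "unresolved input '%s' of stage %d not covered by extraInputs",
             u$parameter, u$stage)
  st <- regState(registry)
  current <- initial
  taskIds <- character()
  lastResults <- list()
  for (k in seq_along(pipeline@stages)) {
    s <- pipeline@stages[[k]]
    if (is(current, "StructuredData") &&
        !isSubtypeOf(registry, current@datatype, s$inputDatatype))
      twStop("tw_stage_failed",
             "stage %d: data of type %s is not a subtype of declared input %s",
             k, current@datatype, s$inputDatatype, data = list(stage = k))
    loc <- selectLocation(registry, s$toolId)
    worker <- st$workers[[loc@protocol]]
    wire <- worker$wireFormat
    prep <- function(v) {
      if (!is(v, "StructuredData")) return(v)
      v <- applyLoaders(registry, v)$data
      if (is.null(wire)) v else serializeData(registry, v, wire)
    }
    inputs <- stats::setNames(list(prep(current)), s$inputParam)
    op <- .mustGet(registry, "operation", s$operationId)
    for (p in op@parameters)
      if (p@kind == "input" && p@name != s$inputParam &&
          p@name %in% names(extraInputs))
        inputs[[p@name]] <- prep(extraInputs[[p@name]])
    task <- addTask(registry, loc@id, s$operationId, inputs)
    if (task@status == "FAILED" && isTRUE(st$options$retryOnFailure)) {
      nxt <- selectLocation(registry, s$toolId)
      if (nxt@id != loc@id) {
        taskIds <- c(taskIds, task@id)
        task <- addTask(registry, nxt@id, s$operationId, inputs)
      }
    }
    taskIds <- c(taskIds, task@id)
    if (task@status != "SUCCEEDED")
      twStop("tw_stage_failed", "stage %d (%s) failed: %s", k, s$operationName,
             task@error$message %||% "worker failure",
             data = list(stage = k, task = task@id))
    lastResults <- task@results
    out <- task@results[[s$outputParam]] %||%
      (if (length(task@results)) task@results[[1]] else NULL)
    if (is.character(out) && !is.null(wire))
      out <- tryCatch(parseData(registry, out, wire, s$outputDatatype),
                      tw_error = function(e) out)
    current <- out
  }
  list(data = current, results = lastResults, taskIds = taskIds)
}

#' Usage statistics per endpoint
#'
#' Invocation, success and cumulative latency counters recorded by
#' [addTask()]; persisted with the registry store.  A known location that
#' was never invoked reports a zero record.
#'
#' @inheritParams addTask
#' @param location endpoint id; `NULL` returns records for all locations.
#' @return list of [StatRecord-class], location-id-sorted.
#' @export
getStatistics <- function(registry, location = NULL) {
  be <- regState(registry)$backend
  if (!is.null(location)) {
    .mustGet(registry, "location", location)
    rec <- bkGet(be, "stat", location)
    if (is.null(rec)) rec <- new("StatRecord", locationRef = location)
    return(list(rec))
  }
  out <- list()
  for (id in bkList(be, "location")) {
    rec <- bkGet(be, "stat", id)
    if (is.null(rec)) rec <- new("StatRecord", locationRef = id)
    out[[length(out) + 1L]] <- rec
  }
  out
}
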