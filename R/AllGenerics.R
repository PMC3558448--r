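## Backend contract (internal generics; backends and layers implement these).

setGeneric("bkList", function(backend, kind) standardGeneric("bkList"))
setGeneric("bkGet", function(backend, kind, id) standardGeneric("bkGet"))
setGeneric("bkAdd", function(backend, kind, id, record) standardGeneric("bkAdd"))
setGeneric("bkDelete", function(backend, kind, id) standardGeneric("bkDelete"))
setGeneric("bkUpdate", function(backend, kind, id, record) standardGeneric("bkUpdate"))
setGeneric("bkNativeEdit", function(backend) standardGeneric("bkNativeEdit"))

#' @name accessors
#' @title Record accessors
#' @description Small accessor generics for the metadata record classes;
#'   user code should use these rather than reaching into slots.
#' @param x a record object.
#' @return the corresponding field.
#' @aliases recordId recordName taskStatus taskResults
#' @examples
#' reg <- buildUsecaseRegistry()
#' tools <- getToolList(reg)
#' recordName(tools[[1]])
NULL

#' @rdname accessors
#' @export
setGeneric("recordId", function(x) standardGeneric("recordId"))

#' @rdname accessors
#' @export
setGeneric("recordName", function(x) standardGeneric("recordName"))

#' @rdname accessors
#' @export
setGeneric("taskStatus", function(x) standardGeneric("taskStatus"))

#' @rdname accessors
#' @export
setGeneric("taskResults", function(x) standardGeneric("taskResults"))

setMethod("recordId", "ToolRecord", function(x) x@id)
setMethod("recordId", "OperationRecord", function(x) x@id)
setMethod("recordId", "ParameterRecord", function(x) x@id)
setMethod("recordId", "ToolLocationRecord", function(x) x@id)
setMethod("recordId", "Task", function(x) x@id)
setMethod("recordId", "DatatypeNode", function(x) x@name)
setMethod("recordId", "FunctionalCategoryNode", function(x) x@name)
setMethod("recordId", "NamespaceRecord", function(x) x@name)
setMethod("recordId", "StatRecord", function(x) x@locationRef)

setMethod("recordName", "ToolRecord", function(x) x@name)
setMethod("recordName", "OperationRecord", function(x) x@name)
setMethod("recordName", "ParameterRecord", function(x) x@name)
setMethod("recordName", "DatatypeNode", function(x) x@name)
setMethod("recordName", "FunctionalCategoryNode", function(x) x@name)
setMethod("recordName", "NamespaceRecord", function(x) x@name)

setMethod("taskStatus", "Task", function(x) x@status)
setMethod("taskResults", "Task", function(x) {
  if (x@status != "SUCCEEDED")
    twStop("tw_not_finished", "task %s is %s; results unavailable",
           x@id, x@status, data = list(error = x@error))
  x@results
})

## show methods --------------------------------------------------------------

setMethod("show", "ToolRecord", function(object) {
  cat(sprintf("ToolRecord '%s' (%s)\n", object@name, object@id))
  if (nzchar(object@description)) cat(" ", object@description, "\n")
  cat(sprintf("  operations: %d, categories: %s\n",
              length(object@operationIds),
              if (length(object@categoryRefs)) paste(object@categoryRefs, collapse = ", ") else "none"))
})

setMethod("show", "OperationRecord", function(object) {
  cat(sprintf("OperationRecord '%s' (%s)%s on tool %s\n", object@name, object@id,
              if (object@virtual) " [virtual]" else "", object@toolRef))
  for (p in object@parameters)
    cat(sprintf("  %-9s %s : %s\n", p@kind, p@name, p@datatypeRef))
})

setMethod("show", "DatatypeNode", function(object) {
  parent <- if (length(object@isParent)) object@isParent else "<root>"
  cat(sprintf("DatatypeNode '%s' IS %s\n", object@name, parent))
  attrs <- if (length(object@effectiveAttributes)) object@effectiveAttributes else object@attributes
  if (length(attrs))
    cat("  attributes:", paste(sprintf("%s:%s", names(attrs), attrs), collapse = ", "), "\n")
  if (length(object@hasParts))
    cat("  HAS:", paste(sprintf("%s[%s]", names(object@hasParts), object@hasParts), collapse = ", "), "\n")
  if (length(object@hasaParts))
    cat("  HASA:", paste(sprintf("%s[%s]", names(object@hasaParts), object@hasaParts), collapse = ", "), "\n")
})

setMethod("show", "StructuredData", function(object) {
  cat(sprintf("StructuredData <%s>%s\n", object@datatype,
              if (nzchar(object@provenance)) sprintf(" (from %s)", object@provenance) else ""))
  for (a in names(object@attributes))
    cat(sprintf("  %s = %s\n", a, format(object@attributes[[a]])))
  for (p in names(object@parts)) {
    v <- object@parts[[p]]
    n <- if (is.list(v) && !is(v, "StructuredData")) length(v) else 1L
    cat(sprintf("  part %s (%d)\n", p, n))
  }
})

setMethod("show", "Pipeline", function(object) {
  cat(sprintf("Pipeline %s -> %s (%d stage%s)\n", object@source, object@target,
              length(object@stages), if (length(object@stages) == 1) "" else "s"))
  for (i in seq_along(object@stages)) {
    s <- object@stages[[i]]
    cat(sprintf("  %d. %s:%s  [%s -> %s]\n", i, s$toolName, s$operationName,
                s$inputDatatype, s$outputDatatype))
  }
  if (length(object@unresolvedInputs))
    cat(sprintf("  unresolved inputs: %d\n", length(object@unresolvedInputs)))
})

setMethod("show", "Task", function(object) {
  cat(sprintf("Task %s [%s] op=%s at %s\n", object@id, object@status,
              object@operationRef, object@locationRef))
})

setMethod("show", "StatRecord", function(object) {
  cat(sprintf("StatRecord %s: %d invocation(s), %d ok, %.3fs total\n",
              object@locationRef, as.integer(object@count),
              as.integer(object@success), object@latency))
})

setMethod("show", "ServiceRegistry", function(object) {
  st <- object@env
  counts <- vapply(c("datatype", "category", "namespace", "tool", "operation", "location"),
                   function(k) length(bkList(st$backend, k)), integer(1))
  cat("ServiceRegistry\n")
  cat(sprintf("  datatypes: %d, categories: %d, namespaces: %d\n",
              counts["datatype"], counts["category"], counts["namespace"]))
  cat(sprintf("  tools: %d, operations: %d, locations: %d\n",
              counts["tool"], counts["operation"], counts["location"]))
  cat(sprintf("  loaders: %d, formatters: %d, workers: %d, tasks: %d\n",
              length(st$loaders), length(st$formatters),
              length(st$workers), length(st$tasks)))
})
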