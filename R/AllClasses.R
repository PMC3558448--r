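#' @import methods
NULL

## ---------------------------------------------------------------------------
## Metadata records
## ---------------------------------------------------------------------------

#' Abstract service metadata records
#'
#' The registry represents every web service as an abstract `ToolRecord`
#' (a grouping of software components solving one type of problem) owning an
#' ordered list of operations; each `OperationRecord` owns an ordered list of
#' typed `ParameterRecord`s, and each tool may have any number of
#' `ToolLocationRecord` endpoints (mirrors) speaking possibly different
#' protocols.  Records are value objects: all mutation goes through the
#' registry operations, never through slots.
#'
#' @slot id opaque unique identifier, assigned by the registry.
#' @slot name human-readable name (non-empty for tools).
#' @slot description free-text description.
#' @slot categoryRefs character vector of functional-category names the tool
#'   is annotated with.
#' @slot operationIds ordered character vector of operation ids.
#' @aliases ToolRecord-class OperationRecord-class ParameterRecord-class
#'   ToolLocationRecord-class
#' @name ToolRecord-class
#' @rdname ToolRecord-class
#' @exportClass ToolRecord
setClass("ToolRecord", representation(
  id = "character", name = "character", description = "character",
  categoryRefs = "character", operationIds = "character"
), prototype(description = "", categoryRefs = character(), operationIds = character()))

setValidity("ToolRecord", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("tool name must be a single non-empty string")
  TRUE
})

#' @slot kind one of `"input"`, `"output"`, `"secondary"`.
#' @slot datatypeRef name of the parameter's datatype in the taxonomy.
#' @slot namespaceRef optional namespace name (`""` when unset).
#' @slot cardinality `"one"` or `"many"`.
#' @rdname ToolRecord-class
#' @exportClass ParameterRecord
setClass("ParameterRecord", representation(
  id = "character", name = "character", kind = "character",
  datatypeRef = "character", namespaceRef = "character", cardinality = "character"
), prototype(namespaceRef = "", cardinality = "one"))

.PARAM_KINDS <- c("input", "output", "secondary")

setValidity("ParameterRecord", function(object) {
  if (!object@kind %in% .PARAM_KINDS)
    return(sprintf("parameter kind must be one of %s", paste(.PARAM_KINDS, collapse = "/")))
  if (!object@cardinality %in% c("one", "many"))
    return("cardinality must be 'one' or 'many'")
  TRUE
})

#' @slot toolRef id of the owning tool.
#' @slot parameters ordered list of [ParameterRecord-class] objects.
#' @slot virtual `TRUE` when the operation was synthesized for a protocol
#'   that has no operation concept.
#' @rdname ToolRecord-class
#' @exportClass OperationRecord
setClass("OperationRecord", representation(
  id = "character", name = "character", toolRef = "character",
  parameters = "list", virtual = "logical"
), prototype(parameters = list(), virtual = FALSE))

#' @slot protocol free protocol tag, e.g. `"biomoby"`, `"soap"`, `"local"`.
#' @slot endpoint endpoint URI.
#' @slot hostInfo named list of opaque host properties (memory, bandwidth...).
#' @rdname ToolRecord-class
#' @exportClass ToolLocationRecord
setClass("ToolLocationRecord", representation(
  id = "character", toolRef = "character", protocol = "character",
  endpoint = "character", hostInfo = "list"
), prototype(hostInfo = list()))

## ---------------------------------------------------------------------------
## Taxonomy nodes
## ---------------------------------------------------------------------------

#' Datatype taxonomy node
#'
#' A node of the shared datatype taxonomy.  Nodes are related by single
#' inheritance (the IS relation), by HAS parts (arrays of another datatype)
#' and by HASA parts (containment of exactly one instance).  Primitive
#' attributes are typed `String`/`Integer`/`Float`/`Boolean`.  The node name
#' is its identity.  `effectiveAttributes` (and the effective part slots) are
#' only populated on nodes returned by [getDatatype()], where inherited
#' members have been materialized ancestor-first.
#'
#' @slot name node name (the identifier).
#' @slot description free text.
#' @slot isParent name of the IS parent, or `character(0)` for a root.
#' @slot attributes named character vector mapping attribute name to
#'   primitive type, own attributes only.
#' @slot hasParts named character vector part name -> datatype name,
#'   cardinality many.
#' @slot hasaParts named character vector part name -> datatype name,
#'   cardinality one.
#' @slot effectiveAttributes own plus inherited attributes (filled by
#'   [getDatatype()]).
#' @slot effectiveHasParts,effectiveHasaParts own plus inherited parts.
#' @exportClass DatatypeNode
setClass("DatatypeNode", representation(
  name = "character", description = "character", isParent = "character",
  attributes = "character", hasParts = "character", hasaParts = "character",
  effectiveAttributes = "character", effectiveHasParts = "character",
  effectiveHasaParts = "character"
), prototype(description = "", isParent = character(),
             attributes = character(), hasParts = character(), hasaParts = character(),
             effectiveAttributes = character(), effectiveHasParts = character(),
             effectiveHasaParts = character()))

.PRIMITIVES <- c("String", "Integer", "Float", "Boolean")

setValidity("DatatypeNode", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("datatype name must be a single non-empty string")
  if (length(object@isParent) > 1L)
    return("a datatype has at most one IS parent")
  if (length(object@attributes) && is.null(names(object@attributes)))
    return("attributes must be a named vector")
  bad <- setdiff(object@attributes, .PRIMITIVES)
  if (length(bad))
    return(sprintf("unknown primitive type(s): %s", paste(bad, collapse = ", ")))
  TRUE
})

#' Functional category node
#'
#' Hierarchical keyword used to annotate tools for browsing and discovery.
#' `toolRefs` is materialized on retrieval from the current tool annotations.
#'
#' @slot name category name (identity).
#' @slot description free text.
#' @slot parent parent category name, or `character(0)` for a root.
#' @slot toolRefs ids of tools annotated with this category (filled on get).
#' @exportClass FunctionalCategoryNode
setClass("FunctionalCategoryNode", representation(
  name = "character", description = "character", parent = "character",
  toolRefs = "character"
), prototype(description = "", parent = character(), toolRefs = character()))

#' Namespace record
#'
#' Data-provenance label qualifying identifiers by their source database.
#'
#' @slot name unique namespace name.
#' @slot description free text.
#' @slot source free-text note about the originating data source.
#' @exportClass NamespaceRecord
setClass("NamespaceRecord", representation(
  name = "character", description = "character", source = "character"
), prototype(description = "", source = ""))

## ---------------------------------------------------------------------------
## Structured data, pipelines, tasks
## ---------------------------------------------------------------------------

#' Structured data instance
#'
#' DOM-like tree instance of a taxonomy datatype: primitive attribute values
#' plus named parts which are themselves `StructuredData` (HASA, single) or
#' lists of `StructuredData` (HAS, many).  This is the unit all loaders and
#' formatters work on.
#'
#' @slot datatype name of the instantiated datatype.
#' @slot attributes named list of primitive attribute values.
#' @slot parts named list; each element a `StructuredData` or a list of them.
#' @slot provenance source format tag (`"fasta"`, `"genbank"`, ...) or `""`.
#' @exportClass StructuredData
setClass("StructuredData", representation(
  datatype = "character", attributes = "list", parts = "list",
  provenance = "character"
), prototype(attributes = list(), parts = list(), provenance = ""))

#' Discovered service pipeline
#'
#' Ordered chain of operations connecting a source datatype to a target
#' datatype.  For consecutive stages the datatype produced by stage *k* is a
#' subtype of the datatype consumed by stage *k+1*; the first stage accepts
#' the source and the last stage's output satisfies the target.  Mandatory
#' inputs that the chain itself does not feed are listed in
#' `unresolvedInputs` and must be supplied at enactment.
#'
#' @slot stages list of per-stage descriptors (operation/tool ids and names,
#'   chosen input and output parameter with their datatypes).
#' @slot source,target the requested endpoint datatypes.
#' @slot unresolvedInputs list of mandatory inputs not fed by the chain.
#' @exportClass Pipeline
setClass("Pipeline", representation(
  stages = "list", source = "character", target = "character",
  unresolvedInputs = "list"
), prototype(stages = list(), unresolvedInputs = list()))

#' Task record
#'
#' One invocation of an operation at a concrete endpoint.  The status machine
#' admits only `SUBMITTED -> RUNNING -> {SUCCEEDED, FAILED}`; results are
#' only available once `SUCCEEDED`.  `log` records every transition with a
#' timestamp for auditing.
#'
#' @slot id task id.
#' @slot locationRef,operationRef the invoked endpoint and operation.
#' @slot inputs named list of inputs as handed to the worker.
#' @slot status one of `SUBMITTED`, `RUNNING`, `SUCCEEDED`, `FAILED`.
#' @slot results named list of outputs (only when `SUCCEEDED`).
#' @slot error error payload (only when `FAILED`).
#' @slot timestamps named numeric vector (`submitted`, `started`, `finished`).
#' @slot log character vector of status transitions in order.
#' @exportClass Task
setClass("Task", representation(
  id = "character", locationRef = "character", operationRef = "character",
  inputs = "list", status = "character", results = "list", error = "list",
  timestamps = "numeric", log = "character"
), prototype(inputs = list(), status = "SUBMITTED", results = list(),
             error = list(), timestamps = numeric(), log = character()))

.TASK_STATES <- c("SUBMITTED", "RUNNING", "SUCCEEDED", "FAILED")

setValidity("Task", function(object) {
  if (!object@status %in% .TASK_STATES) return("unknown task status")
  TRUE
})

#' Per-endpoint usage statistics
#'
#' @slot locationRef endpoint id.
#' @slot count total invocations.
#' @slot success successful invocations (`success <= count`).
#' @slot latency cumulative wall-clock seconds across invocations.
#' @exportClass StatRecord
setClass("StatRecord", representation(
  locationRef = "character", count = "numeric", success = "numeric",
  latency = "numeric"
), prototype(count = 0, success = 0, latency = 0))

setValidity("StatRecord", function(object) {
  if (object@success > object@count) return("success count exceeds invocation count")
  TRUE
})

## ---------------------------------------------------------------------------
## Filters, plug-in specs
## ---------------------------------------------------------------------------

#' Resource filter
#'
#' Pure predicate over a metadata record.  Filters compose by conjunction:
#' a list of filters passed to [getToolList()] keeps the records satisfying
#' every one of them, so order is irrelevant.
#'
#' @slot name filter label.
#' @slot predicate function(record) -> logical(1); must not mutate.
#' @exportClass Filter
setClass("Filter", representation(name = "character", predicate = "function"))

#' Loader specification
#'
#' A loader transforms structured data, e.g. injecting attributes required by
#' a data standard or computing derived attributes.  It applies to its scope
#' datatype and every IS-descendant, without the caller asking for it.
#'
#' @slot name unique loader name.
#' @slot scopeDatatype datatype whose subtree the loader applies to.
#' @slot transform function(registry, data) -> data; deterministic.
#' @slot priority smaller runs earlier among loaders at the same scope depth.
#' @exportClass LoaderSpec
setClass("LoaderSpec", representation(
  name = "character", scopeDatatype = "character", transform = "function",
  priority = "numeric"
), prototype(priority = 100))

#' Formatter specification
#'
#' A formatter parses a concrete wire format into structured data and
#' serializes structured data back.  It covers its scope datatype and all
#' IS-descendants; `lossy` marks formats whose parse discards information
#' (e.g. the GenBank flat file), making the conversion irreversible.
#'
#' @slot format format id (`"fasta"`, `"raw"`, `"genbank"`, `"moby-xml"`).
#' @slot scopeDatatype datatype subtree the formatter covers.
#' @slot parse function(registry, content, targetDatatype) -> StructuredData,
#'   or `NULL` for write-only formats.
#' @slot serialize function(registry, data) -> character, or `NULL` for
#'   read-only formats.
#' @slot lossy `TRUE` when parsing discards source information.
#' @exportClass FormatterSpec
setClass("FormatterSpec", representation(
  format = "character", scopeDatatype = "character",
  parse = "ANY", serialize = "ANY", lossy = "logical"
), prototype(parse = NULL, serialize = NULL, lossy = FALSE))

## ---------------------------------------------------------------------------
## Backends and the registry
## ---------------------------------------------------------------------------

#' Registry backends and layers
#'
#' The Access layer of the framework: a backend maps the uniform record model
#' onto a concrete store.  `MemoryBackend` keeps records in an environment;
#' with `nativeEdit = FALSE` it refuses in-place updates, emulating registry
#' protocols that only support deregister-and-register editing (the module
#' layer then performs delete+add preserving the id, transparently).  Extra
#' layers wrap a backend behind the same generic contract: `CacheLayer`
#' serves repeated reads from memory and invalidates on any write;
#' `CountingBackend` tallies calls per verb, which tests use to observe cache
#' behaviour.  Adding layers never changes results, only behaviour.
#'
#' @aliases MemoryBackend-class CacheLayer-class CountingBackend-class
#' @name RegistryBackend-class
#' @rdname RegistryBackend-class
#' @exportClass RegistryBackend
setClass("RegistryBackend", representation("VIRTUAL"))

#' @rdname RegistryBackend-class
#' @exportClass MemoryBackend
setClass("MemoryBackend", contains = "RegistryBackend",
         representation(env = "environment", nativeEdit = "logical"))

#' @rdname RegistryBackend-class
#' @exportClass CacheLayer
setClass("CacheLayer", contains = "RegistryBackend",
         representation(inner = "RegistryBackend", cache = "environment"))

#' @rdname RegistryBackend-class
#' @exportClass CountingBackend
setClass("CountingBackend", contains = "RegistryBackend",
         representation(inner = "RegistryBackend", counts = "environment"))

#' Service metadata registry
#'
#' The central handle tying all modules together: record storage via a
#' swappable [RegistryBackend-class], the datatype/category taxonomies,
#' registered loaders, formatters, format-recognition rules, protocol
#' workers, tasks and statistics.  The object has reference semantics (all
#' state lives in the `env` slot) so registry operations mutate in place,
#' like a connection object.
#'
#' @slot env environment holding the backend and all session state.
#' @seealso [newRegistry()], [buildUsecaseRegistry()]
#' @exportClass ServiceRegistry
setClass("ServiceRegistry", representation(env = "environment"))
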