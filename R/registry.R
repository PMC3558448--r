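## Tool/ToolLocation module: registration, listing, filtering, editing with
## cascade semantics, and interface generation.

#' Register an abstract tool
#'
#' A tool is an abstract grouping of software components solving one type of
#' problem; concrete deployments are added separately as locations
#' ([newToolLocation()]) and callable operations as [addOperation()].
#'
#' @param registry a [ServiceRegistry-class].
#' @param name tool name (non-empty).  By default names need not be unique
#'   registry-wide; set the registry option `uniqueToolNames = TRUE` to
#'   reject duplicates.
#' @param description free-text description.
#' @param categories character vector of functional-category names to
#'   annotate the tool with; every one must already exist.
#' @return the persisted [ToolRecord-class].
#' @examples
#' reg <- newRegistry()
#' tool <- newTool(reg, "runRPSBlast", "domain search against CDD")
#' @export
newTool <- function(registry, name, description = "", categories = character()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    twStop("tw_empty_name", "tool name must be a non-empty string")
  for (cat in categories) .mustResolve(registry, "category", cat)
  if (isTRUE(regState(registry)$options$uniqueToolNames)) {
    nm <- vapply(.allRecords(registry, "tool"), recordName, character(1))
    if (name %in% nm)
      twStop("tw_duplicate_name", "a tool named '%s' already exists", name)
  }
  id <- .nextId(registry, "tool")
  rec <- new("ToolRecord", id = id, name = name, description = description,
             categoryRefs = as.character(categories))
  .storeAdd(registry, "tool", id, rec)
  rec
}

#' Add an operation to a tool
#'
#' Operations are appended to the tool's ordered list.  Names need not be
#' unique -- ids are the identity.
#'
#' @inheritParams newTool
#' @param tool id of an existing tool.
#' @param virtual mark the operation as synthesized for a protocol without an
#'   operation concept (see [newToolLocation()], which auto-creates one for
#'   operation-less protocols).
#' @return the persisted [OperationRecord-class].
#' @export
addOperation <- function(registry, tool, name, virtual = FALSE) {
  trec <- .mustResolve(registry, "tool", tool)
  id <- .nextId(registry, "operation")
  rec <- new("OperationRecord", id = id, name = name, toolRef = trec@id,
             virtual = isTRUE(virtual))
  .storeAdd(registry, "operation", id, rec)
  trec@operationIds <- c(trec@operationIds, id)
  .storeUpdate(registry, "tool", trec@id, trec)
  rec
}

#' Add a typed parameter to an operation
#'
#' Appends a parameter in declaration order and invalidates the composition
#' indexes.  The datatype (and namespace, when given) must resolve in the
#' taxonomy.
#'
#' @inheritParams newTool
#' @param operation id of an existing operation.
#' @param kind `"input"`, `"output"` or `"secondary"` (fine-tune settings;
#'   secondary parameters never participate in pipeline linking).
#' @param datatype name of the parameter's datatype.
#' @param namespace optional namespace name.
#' @param cardinality `"one"` or `"many"`.
#' @return the persisted [ParameterRecord-class].
#' @export
addParameter <- function(registry, operation, name, kind, datatype,
                         namespace = NULL, cardinality = "one") {
  op <- .mustResolve(registry, "operation", operation)
  if (!kind %in% .PARAM_KINDS)
    twStop("tw_bad_kind", "parameter kind '%s' is not one of %s",
           kind, paste(.PARAM_KINDS, collapse = "/"))
  .mustResolve(registry, "datatype", datatype)
  if (!is.null(namespace) && nzchar(namespace))
    .mustResolve(registry, "namespace", namespace)
  id <- .nextId(registry, "parameter")
  prec <- new("ParameterRecord", id = id, name = name, kind = kind,
              datatypeRef = datatype,
              namespaceRef = if (is.null(namespace)) "" else namespace,
              cardinality = cardinality)
  op@parameters <- c(op@parameters, prec)
  .storeUpdate(registry, "operation", op@id, op)
  prec
}

#' Register a concrete endpoint (mirror) for a tool
#'
#' A tool may accumulate several locations; multiple endpoints make clients
#' robust because another mirror can be called when one is unavailable.  For
#' protocols without an operation concept (`"biomoby"`), registering the
#' first location of an operation-less tool synthesizes a virtual operation
#' so the uniform model always has one.
#'
#' @inheritParams newTool
#' @param tool id of an existing tool.
#' @param protocol free protocol tag (e.g. `"biomoby"`, `"soap"`, `"local"`).
#' @param endpoint endpoint URI.
#' @param hostInfo named list of opaque host properties (memory, bandwidth
#'   etc.; units unspecified, stored as given).
#' @return the persisted [ToolLocationRecord-class].
#' @export
newToolLocation <- function(registry, tool, protocol, endpoint, hostInfo = list()) {
  trec <- .mustResolve(registry, "tool", tool)
  id <- .nextId(registry, "location")
  rec <- new("ToolLocationRecord", id = id, toolRef = trec@id,
             protocol = protocol, endpoint = endpoint, hostInfo = hostInfo)
  .storeAdd(registry, "location", id, rec)
  if (identical(protocol, "biomoby") && length(trec@operationIds) == 0L)
    addOperation(registry, trec@id, trec@name, virtual = TRUE)
  rec
}

## ---- filters --------------------------------------------------------------

#' Construct resource filters
#'
#' Filters are pure predicates over records; lists of filters compose by
#' conjunction (set intersection), so their order never matters.
#' `nameFilter` keeps records whose name contains a substring;
#' `categoryFilter` keeps tools annotated with a category.
#'
#' @param name filter label (`newFilter`) / substring to match (`nameFilter`).
#' @param predicate function taking a record and returning `TRUE`/`FALSE`.
#' @return a [Filter-class].
#' @export
newFilter <- function(name, predicate) new("Filter", name = name, predicate = predicate)

#' @rdname newFilter
#' @param substring substring matched against record names (fixed, not regex).
#' @export
nameFilter <- function(substring) {
  newFilter(paste0("name~", substring),
            function(rec) grepl(substring, recordName(rec), fixed = TRUE))
}

#' @rdname newFilter
#' @param category functional-category name.
#' @export
categoryFilter <- function(category) {
  newFilter(paste0("category=", category),
            function(rec) is(rec, "ToolRecord") && category %in% rec@categoryRefs)
}

.applyFilters <- function(records, filters) {
  for (f in filters) {
    if (!is(f, "Filter")) twStop("tw_bad_kind", "filters must be Filter objects")
    records <- Filter(function(r) isTRUE(f@predicate(r)), records)
  }
  records
}

#' List tools, optionally filtered
#'
#' Returns all tools passing every filter, in deterministic id-sorted order.
#'
#' @inheritParams newTool
#' @param filters list of [Filter-class] objects, combined by conjunction.
#' @return list of [ToolRecord-class] objects.
#' @export
getToolList <- function(registry, filters = list()) {
  unname(.applyFilters(.allRecords(registry, "tool"), filters))
}

#' List the ids of all records of a kind
#'
#' @inheritParams newTool
#' @param module record kind (see [getResource()]).
#' @return character vector of ids, sorted.
#' @export
listResources <- function(registry, module) {
  bkList(regState(registry)$backend, module)
}

#' Fetch one metadata record
#'
#' @inheritParams newTool
#' @param module record kind: `"tool"`, `"operation"`, `"location"`,
#'   `"datatype"`, `"category"` or `"namespace"`.
#' @param id record id (the name, for taxonomy kinds).
#' @return the record.
#' @export
getResource <- function(registry, module, id) {
  .mustGet(registry, module, id)
}

#' List the locations (mirrors) of a tool
#'
#' @inheritParams newTool
#' @param tool tool id.
#' @return list of [ToolLocationRecord-class], id-sorted.
#' @export
getLocations <- function(registry, tool) {
  .mustGet(registry, "tool", tool)
  locs <- .allRecords(registry, "location")
  unname(Filter(function(l) l@toolRef == tool, locs))
}

#' List the operations of a tool in declaration order
#'
#' @inheritParams getLocations
#' @return list of [OperationRecord-class].
#' @export
getOperations <- function(registry, tool) {
  trec <- .mustGet(registry, "tool", tool)
  lapply(trec@operationIds, function(i) .mustGet(registry, "operation", i))
}

## ---- editing --------------------------------------------------------------

## field -> slot map per kind; everything else is rejected, ids are immutable
.EDITABLE <- list(
  tool      = c(name = "name", description = "description", categoryRefs = "categoryRefs"),
  operation = c(name = "name", virtual = "virtual"),
  location  = c(protocol = "protocol", endpoint = "endpoint", hostInfo = "hostInfo"),
  datatype  = c(description = "description"),
  category  = c(description = "description"),
  namespace = c(description = "description", source = "source")
)

#' Update fields of a record
#'
#' On a native-edit backend the update happens in place; on a backend without
#' native editing it is emulated as deregister + register preserving the id,
#' transparently -- both routes leave byte-identical stores.  All references
#' to the record stay valid because the id never changes.
#'
#' @inheritParams getResource
#' @param changes named list of new field values; an empty list is the
#'   identity update and performs no backend write.  Ids (and the name of
#'   name-keyed taxonomy records) are immutable.
#' @return the updated record.
#' @export
updateResource <- function(registry, module, id, changes = list()) {
  rec <- .mustGet(registry, module, id)
  if (length(changes) == 0L) return(rec)
  if (any(c("id", if (module %in% c("datatype", "category", "namespace")) "name")
          %in% names(changes)))
    twStop("tw_immutable_field", "the identity of a %s cannot be changed", module)
  allowed <- .EDITABLE[[module]]
  if (is.null(allowed)) twStop("tw_bad_kind", "kind '%s' is not editable", module)
  unknown <- setdiff(names(changes), names(allowed))
  if (length(unknown))
    twStop("tw_bad_kind", "field(s) not editable on %s: %s",
           module, paste(unknown, collapse = ", "))
  if (module == "tool" && "categoryRefs" %in% names(changes))
    for (cat in changes$categoryRefs) .mustResolve(registry, "category", cat)
  for (f in names(changes)) slot(rec, allowed[[f]]) <- changes[[f]]
  validObject(rec)
  .storeUpdate(registry, module, id, rec)
  rec
}

## ---- deletion with cascade ------------------------------------------------

## Dependency model: parameters depend on datatypes and namespaces;
## datatypes depend on their IS parent and on part datatypes; categories on
## their parent category.  Operations, parameters and locations are owned
## components of their tool/operation and are removed together with the
## owner regardless of `cascade`; category annotations on tools are removed
## without deleting the tool.

.directDependents <- function(registry, kind, id) {
  out <- list()
  push <- function(kind, id, owner = NA_character_, owned = FALSE)
    out[[length(out) + 1L]] <<- list(kind = kind, id = id, owner = owner, owned = owned)
  if (kind == "tool") {
    trec <- .mustGet(registry, "tool", id)
    for (o in trec@operationIds) push("operation", o, owned = TRUE)
    for (l in .allRecords(registry, "location"))
      if (l@toolRef == id) push("location", l@id, owned = TRUE)
  } else if (kind == "operation") {
    op <- .mustGet(registry, "operation", id)
    for (p in op@parameters) push("parameter", p@id, owner = id, owned = TRUE)
  } else if (kind == "datatype") {
    for (d in .allRecords(registry, "datatype")) {
      if (length(d@isParent) && d@isParent == id) push("datatype", d@name)
      else if (id %in% c(d@hasParts, d@hasaParts)) push("datatype", d@name)
    }
    for (op in .allRecords(registry, "operation"))
      for (p in op@parameters)
        if (p@datatypeRef == id) push("parameter", p@id, owner = op@id)
  } else if (kind == "namespace") {
    for (op in .allRecords(registry, "operation"))
      for (p in op@parameters)
        if (p@namespaceRef == id) push("parameter", p@id, owner = op@id)
  } else if (kind == "category") {
    for (c in .allRecords(registry, "category"))
      if (length(c@parent) && c@parent == id) push("category", c@name)
  }
  out
}

#' Delete a record, cascading or rejecting
#'
#' With `cascade = TRUE` the resource and all transitive dependents are
#' removed and the report lists every removed id (parameters included; tools
#' whose parameters referenced a cascaded datatype survive, dangling-free,
#' because only the parameters are removed).  With `cascade = FALSE` the
#' deletion is rejected while any dependency exists and nothing is removed.
#'
#' @inheritParams getResource
#' @param cascade remove dependents transitively instead of rejecting.
#' @return a deletion report: list with element `removed`, the sorted ids of
#'   every removed record.
#' @export
deleteResource <- function(registry, module, id, cascade = FALSE) {
  .mustGet(registry, module, id)
  seen <- character()
  items <- list()
  queue <- list(list(kind = module, id = id, owner = NA_character_, owned = TRUE))
  crossRefs <- character()
  while (length(queue)) {
    it <- queue[[1L]]; queue <- queue[-1L]
    key <- paste(it$kind, it$id)
    if (key %in% seen) next
    seen <- c(seen, key)
    items[[length(items) + 1L]] <- it
    if (!it$owned) crossRefs <- c(crossRefs, it$id)
    if (it$kind != "parameter")
      queue <- c(queue, .directDependents(registry, it$kind, it$id))
  }
  if (!cascade && length(crossRefs))
    twStop("tw_dependency_exists",
           "cannot delete %s '%s': dependencies exist (%s); nothing removed",
           module, id, paste(sort(unique(crossRefs)), collapse = ", "))

  kinds <- vapply(items, `[[`, character(1), "kind")
  ids <- vapply(items, `[[`, character(1), "id")
  removedOps <- ids[kinds == "operation"]
  removedTools <- ids[kinds == "tool"]

  ## strip parameters from surviving operations
  paramItems <- items[kinds == "parameter"]
  byOp <- split(vapply(paramItems, `[[`, character(1), "id"),
                vapply(paramItems, `[[`, character(1), "owner"))
  for (opId in names(byOp)) {
    if (opId %in% removedOps) next
    op <- .mustGet(registry, "operation", opId)
    op@parameters <- Filter(function(p) !(p@id %in% byOp[[opId]]), op@parameters)
    .storeUpdate(registry, "operation", opId, op)
  }
  ## strip deleted-category annotations from surviving tools
  for (catId in ids[kinds == "category"]) {
    for (t in .allRecords(registry, "tool")) {
      if (t@id %in% removedTools || !(catId %in% t@categoryRefs)) next
      t@categoryRefs <- setdiff(t@categoryRefs, catId)
      .storeUpdate(registry, "tool", t@id, t)
    }
  }
  ## detach deleted operations from surviving tools
  for (opId in removedOps) {
    op <- .mustGet(registry, "operation", opId)
    if (!(op@toolRef %in% removedTools)) {
      t <- .mustGet(registry, "tool", op@toolRef)
      t@operationIds <- setdiff(t@operationIds, opId)
      .storeUpdate(registry, "tool", t@id, t)
    }
  }
  ## delete backend records (stats go with their location)
  be <- regState(registry)$backend
  for (i in seq_along(items)) {
    k <- kinds[[i]]
    if (k == "parameter") next
    bkDelete(be, k, ids[[i]])
    if (k == "location" && !is.null(bkGet(be, "stat", ids[[i]])))
      bkDelete(be, "stat", ids[[i]])
  }
  .touch(registry)
  list(removed = sort(ids))
}

## ---- interface generation -------------------------------------------------

#' Describe an operation's parameters for interface generation
#'
#' Returns parameter descriptors in declaration order, sufficient for a
#' client to render an input form.
#'
#' @inheritParams newTool
#' @param operation operation id.
#' @return list of descriptors, each a list with `name`, `kind`, `datatype`,
#'   `namespace`, `cardinality`.
#' @export
generateInterface <- function(registry, operation) {
  op <- .mustGet(registry, "operation", operation)
  lapply(op@parameters, function(p) list(
    name = p@name, kind = p@kind, datatype = p@datatypeRef,
    namespace = p@namespaceRef, cardinality = p@cardinality))
}

## ---- integrity scan -------------------------------------------------------

#' Scan the whole registry for referential-integrity violations
#'
#' Full scan verifying that every reference held by any record resolves:
#' tool category annotations and operation lists, operation tool backrefs,
#' parameter datatypes and namespaces, location tool refs, taxonomy parents
#' and part datatypes.
#'
#' @inheritParams newTool
#' @return character vector of human-readable findings; empty when clean.
#' @export
validateRegistry <- function(registry) {
  f <- character()
  dts <- .allRecords(registry, "datatype")
  cats <- .allRecords(registry, "category")
  tools <- .allRecords(registry, "tool")
  ops <- .allRecords(registry, "operation")
  nss <- .allRecords(registry, "namespace")
  for (t in tools) {
    for (cat in t@categoryRefs)
      if (!cat %in% names(cats))
        f <- c(f, sprintf("tool %s references missing category %s", t@id, cat))
    for (o in t@operationIds)
      if (!o %in% names(ops))
        f <- c(f, sprintf("tool %s references missing operation %s", t@id, o))
  }
  for (op in ops) {
    if (!op@toolRef %in% names(tools))
      f <- c(f, sprintf("operation %s references missing tool %s", op@id, op@toolRef))
    for (p in op@parameters) {
      if (!p@datatypeRef %in% names(dts))
        f <- c(f, sprintf("parameter %s references missing datatype %s", p@id, p@datatypeRef))
      if (nzchar(p@namespaceRef) && !p@namespaceRef %in% names(nss))
        f <- c(f, sprintf("parameter %s references missing namespace %s", p@id, p@namespaceRef))
    }
  }
  for (l in .allRecords(registry, "location"))
    if (!l@toolRef %in% names(tools))
      f <- c(f, sprintf("location %s references missing tool %s", l@id, l@toolRef))
  c(f, .taxonomyRefFindings(dts, cats))
}
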