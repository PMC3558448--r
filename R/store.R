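## Single-file JSON registry store: versioned schema, round-trip identity,
## validation on load.

.SCHEMA_VERSION <- 1L

.paramToList <- function(p) list(
  id = p@id, name = p@name, kind = p@kind, datatype = p@datatypeRef,
  namespace = p@namespaceRef, cardinality = p@cardinality)

.namedOrEmpty <- function(x) {
  if (!length(x)) return(stats::setNames(list(), character()))
  as.list(x)
}

#' Canonical serializable form of a registry
#'
#' The deterministic document [saveRegistry()] writes: every record kind
#' id-sorted, operations and parameters nested under their tools, loader
#' enable/disable configuration and statistics included.  Two registries
#' with identical metadata produce identical documents, which the editing
#' tests rely on.
#'
#' @inheritParams newTool
#' @return a nested list (JSON-ready).
#' @export
registryToList <- function(registry) {
  dts <- .allRecords(registry, "datatype")
  cats <- .allRecords(registry, "category")
  nss <- .allRecords(registry, "namespace")
  tools <- .allRecords(registry, "tool")
  ops <- .allRecords(registry, "operation")
  locs <- .allRecords(registry, "location")
  st <- regState(registry)
  list(
    schema_version = .SCHEMA_VERSION,
    counters = as.list(if (length(st$counters))
      st$counters[order(names(st$counters))] else st$counters),
    datatypes = unname(lapply(dts, function(d) list(
      name = d@name, description = d@description,
      parent = if (length(d@isParent)) d@isParent else NULL,
      attributes = .namedOrEmpty(d@attributes),
      has = .namedOrEmpty(d@hasParts), hasa = .namedOrEmpty(d@hasaParts)))),
    categories = unname(lapply(cats, function(c) list(
      name = c@name, description = c@description,
      parent = if (length(c@parent)) c@parent else NULL))),
    namespaces = unname(lapply(nss, function(n) list(
      name = n@name, description = n@description, source = n@source))),
    tools = unname(lapply(tools, function(t) list(
      id = t@id, name = t@name, description = t@description,
      categories = as.list(t@categoryRefs),
      operations = unname(lapply(t@operationIds, function(oid) {
        op <- ops[[oid]]
        list(id = op@id, name = op@name, virtual = op@virtual,
             parameters = unname(lapply(op@parameters, .paramToList)))
      }))))),
    locations = unname(lapply(locs, function(l) list(
      id = l@id, tool = l@toolRef, protocol = l@protocol,
      endpoint = l@endpoint, host_info = .namedOrEmpty(l@hostInfo)))),
    loader_config = .namedOrEmpty(
      if (length(st$loaderConfig)) st$loaderConfig[order(names(st$loaderConfig))]
      else st$loaderConfig),
    statistics = unname(lapply(bkList(regState(registry)$backend, "stat"), function(id) {
      s <- bkGet(regState(registry)$backend, "stat", id)
      list(location = s@locationRef, count = s@count, success = s@success,
           latency = s@latency)
    }))
  )
}

#' Canonical JSON snapshot of a registry store
#'
#' @inheritParams newTool
#' @return character scalar with the canonical JSON document.
#' @export
registrySnapshot <- function(registry) {
  jsonlite::toJSON(registryToList(registry), auto_unbox = TRUE, digits = NA,
                   null = "null", pretty = TRUE)
}

#' Save / load a registry store
#'
#' `saveRegistry` writes the canonical JSON document; `loadRegistry` reads
#' one back, rejecting unknown schema versions and malformed JSON with a
#' `tw_schema_error`, re-registers the shipped data handlers when their
#' scope datatypes exist, and validates the loaded taxonomy and referential
#' integrity.  Custom loaders, formatters and workers are code and must be
#' re-registered by the caller; the persisted loader configuration
#' (enable/disable) is re-applied to the shipped loaders.  Load then save
#' reproduces the input byte for byte.
#'
#' @inheritParams newTool
#' @param path file path.
#' @return `saveRegistry`: the path, invisibly; `loadRegistry`: a
#'   [ServiceRegistry-class].
#' @export
saveRegistry <- function(registry, path) {
  writeLines(registrySnapshot(registry), path, useBytes = TRUE)
  invisible(path)
}

.chr0 <- function(x) if (is.null(x)) "" else x

#' @rdname saveRegistry
#' @param backend backend for the loaded registry.
#' @export
loadRegistry <- function(path, backend = memoryBackend()) {
  if (!file.exists(path)) twStop("tw_schema_error", "no such registry store: %s", path)
  doc <- tryCatch(
    jsonlite::fromJSON(paste(readLines(path, warn = FALSE), collapse = "\n"),
                       simplifyVector = FALSE),
    error = function(e) twStop("tw_schema_error", "malformed registry store: %s",
                               conditionMessage(e)))
  ver <- doc$schema_version
  if (is.null(ver) || !identical(as.integer(ver), .SCHEMA_VERSION))
    twStop("tw_schema_error", "unsupported schema version '%s' (supported: %d)",
           ver %||% "<missing>", .SCHEMA_VERSION)

  reg <- newRegistry(backend = backend)
  be <- regState(reg)$backend
  for (d in doc$datatypes) {
    node <- new("DatatypeNode", name = d$name, description = .chr0(d$description),
                isParent = if (is.null(d$parent)) character() else d$parent,
                attributes = .asNamedChr(unlist(d$attributes) %||% character()),
                hasParts = .asNamedChr(unlist(d$has) %||% character()),
                hasaParts = .asNamedChr(unlist(d$hasa) %||% character()))
    bkAdd(be, "datatype", node@name, node)
  }
  for (c in doc$categories)
    bkAdd(be, "category", c$name,
          new("FunctionalCategoryNode", name = c$name,
              description = .chr0(c$description),
              parent = if (is.null(c$parent)) character() else c$parent))
  for (n in doc$namespaces)
    bkAdd(be, "namespace", n$name,
          new("NamespaceRecord", name = n$name,
              description = .chr0(n$description), source = .chr0(n$source)))
  for (t in doc$tools) {
    opIds <- vapply(t$operations, function(o) o$id, character(1))
    bkAdd(be, "tool", t$id,
          new("ToolRecord", id = t$id, name = t$name,
              description = .chr0(t$description),
              categoryRefs = as.character(unlist(t$categories) %||% character()),
              operationIds = opIds))
    for (o in t$operations) {
      params <- lapply(o$parameters, function(p)
        new("ParameterRecord", id = p$id, name = p$name, kind = p$kind,
            datatypeRef = p$datatype, namespaceRef = .chr0(p$namespace),
            cardinality = p$cardinality %||% "one"))
      bkAdd(be, "operation", o$id,
            new("OperationRecord", id = o$id, name = o$name, toolRef = t$id,
                parameters = params, virtual = isTRUE(o$virtual)))
    }
  }
  for (l in doc$locations)
    bkAdd(be, "location", l$id,
          new("ToolLocationRecord", id = l$id, toolRef = l$tool,
              protocol = l$protocol, endpoint = l$endpoint,
              hostInfo = l$host_info %||% list()))
  for (s in doc$statistics)
    bkAdd(be, "stat", s$location,
          new("StatRecord", locationRef = s$location, count = as.numeric(s$count),
              success = as.numeric(s$success), latency = as.numeric(s$latency)))
  st <- regState(reg)
  st$counters <- stats::setNames(as.integer(unlist(doc$counters) %||% integer()),
                                 names(doc$counters))
  .touch(reg)

  ## validate before handing the registry out
  tax <- validateTaxonomy(reg)
  if (length(tax))
    twStop("tw_schema_error", "loaded taxonomy is invalid: %s", tax[[1]]$detail)
  refs <- validateRegistry(reg)
  if (length(refs))
    twStop("tw_schema_error", "loaded store fails integrity scan: %s", refs[[1]])

  ## shipped handlers are code, not data: re-register when applicable
  if (!is.null(.getOrNull(reg, "datatype", "Object")) &&
      !is.null(.getOrNull(reg, "datatype", "GenericSequence")))
    registerDefaultDataHandlers(reg)
  cfg <- doc$loader_config
  for (nm in names(cfg))
    if (nm %in% names(st$loaders)) st$loaderConfig[[nm]] <- isTRUE(cfg[[nm]])
  reg
}
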