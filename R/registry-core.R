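## Registry construction and the internal plumbing shared by all modules.

#' Create an empty service registry
#'
#' Builds the central [ServiceRegistry-class] handle over a storage backend.
#' The registry starts with no taxonomy, tools, loaders or formatters; see
#' [buildUsecaseRegistry()] for a populated example and
#' [registerDefaultDataHandlers()] for the shipped sequence loaders,
#' formatters and format-recognition rules.
#'
#' @param backend a [RegistryBackend-class]; defaults to a native-edit
#'   in-memory backend.
#' @param layers character vector of extra layer names to attach on top of
#'   the backend (currently `"cache"`).
#' @param options named list of registry options.  Supported:
#'   `uniqueToolNames` (reject duplicate tool names, default `FALSE`),
#'   `retryOnFailure` (retry a failed invocation once on the next eligible
#'   mirror, default `TRUE`).
#' @return a [ServiceRegistry-class].
#' @examples
#' reg <- newRegistry()
#' addDatatype(reg, "Object")
#' @export
newRegistry <- function(backend = memoryBackend(), layers = character(),
                        options = list()) {
  env <- new.env(parent = emptyenv())
  env$backend <- backend
  env$counters <- integer()
  env$loaders <- list()          # name -> LoaderSpec
  env$loaderConfig <- logical()  # name -> enabled
  env$formatters <- list()       # list of FormatterSpec
  env$rules <- list()            # format recognition rules
  env$workers <- list()          # protocol -> worker
  env$tasks <- list()            # id -> Task
  env$rr <- list()               # tool id -> round-robin cursor
  env$version <- 0L              # bumped on every write; caches key on it
  env$caches <- list()           # derived indexes (taxonomy closure, edges)
  env$fixtureInfo <- NULL
  env$options <- utils::modifyList(
    list(uniqueToolNames = FALSE, retryOnFailure = TRUE), options)
  reg <- new("ServiceRegistry", env = env)
  for (l in layers) attachLayer(reg, l)
  reg
}

#' Attach an extra layer to the registry's backend stack
#'
#' Layers follow the same internal contract as the backend itself, so adding
#' one never changes what the public operations return -- only how reads and
#' writes are served.  The only layer shipped is `"cache"`.
#'
#' @param registry a [ServiceRegistry-class].
#' @param layer layer name.
#' @return the registry, invisibly (modified in place).
#' @export
attachLayer <- function(registry, layer = "cache") {
  st <- registry@env
  if (identical(layer, "cache")) {
    st$backend <- cacheLayer(st$backend)
  } else {
    twStop("tw_unknown_layer", "unknown layer '%s'", layer)
  }
  invisible(registry)
}

## ---- internal helpers -----------------------------------------------------

regState <- function(registry) registry@env

.touch <- function(registry) {
  st <- regState(registry)
  st$version <- st$version + 1L
  st$caches <- list()
  invisible(NULL)
}

.nextId <- function(registry, kind) {
  st <- regState(registry)
  n <- if (kind %in% names(st$counters)) st$counters[[kind]] else 0L
  n <- n + 1L
  st$counters[[kind]] <- n
  sprintf("%s-%06d", kind, n)
}

.getOrNull <- function(registry, kind, id) {
  if (length(id) != 1L || is.na(id)) return(NULL)
  bkGet(regState(registry)$backend, kind, id)
}

.mustGet <- function(registry, kind, id, class = "tw_not_found") {
  rec <- .getOrNull(registry, kind, id)
  if (is.null(rec)) twStop(class, "%s '%s' not found", kind, id)
  rec
}

.mustResolve <- function(registry, kind, id) {
  .mustGet(registry, kind, id, class = "tw_unresolved_reference")
}

.allRecords <- function(registry, kind) {
  be <- regState(registry)$backend
  ids <- bkList(be, kind)
  stats::setNames(lapply(ids, function(i) bkGet(be, kind, i)), ids)
}

## Write a full record back.  On a native-edit backend this is an in-place
## update; otherwise it is emulated as deregister+register preserving the id
## (one uninterrupted transaction for in-process backends).
.storeUpdate <- function(registry, kind, id, record) {
  be <- regState(registry)$backend
  if (bkNativeEdit(be)) {
    bkUpdate(be, kind, id, record)
  } else {
    if (is.null(bkGet(be, kind, id)))
      twStop("tw_not_found", "%s '%s' not found", kind, id)
    bkDelete(be, kind, id)
    bkAdd(be, kind, id, record)
  }
  .touch(registry)
  invisible(record)
}

.storeAdd <- function(registry, kind, id, record) {
  bkAdd(regState(registry)$backend, kind, id, record)
  .touch(registry)
  invisible(record)
}

.storeDelete <- function(registry, kind, id) {
  bkDelete(regState(registry)$backend, kind, id)
  .touch(registry)
  invisible(id)
}

## Versioned derived-index cache: recompute when any write happened since.
.cached <- function(registry, key, compute) {
  st <- regState(registry)
  hit <- st$caches[[key]]
  if (!is.null(hit)) return(hit)
  val <- compute()
  st$caches[[key]] <- val
  val
}
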