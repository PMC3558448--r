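## Access-layer backends.  All record kinds share one generic verb contract;
## the module (Interface) layer never touches storage except through these.

.KINDS <- c("datatype", "category", "namespace", "tool", "operation",
            "location", "stat")

.checkKind <- function(kind) {
  if (!kind %in% .KINDS)
    twStop("tw_bad_kind", "unknown record kind '%s'", kind)
  kind
}

#' Create an in-memory backend
#'
#' @param nativeEdit whether the backend supports in-place updates.  With
#'   `FALSE` the registry emulates editing by deregistering and registering
#'   again under the same id, as clients of edit-less registry protocols
#'   must; for the in-memory store the two steps are a single uninterrupted
#'   transaction, so no inconsistency window is observable.  Remote backends
#'   implementing this contract may not be atomic.
#' @return a [MemoryBackend-class].
#' @export
memoryBackend <- function(nativeEdit = TRUE) {
  env <- new.env(parent = emptyenv())
  env$records <- stats::setNames(rep(list(list()), length(.KINDS)), .KINDS)
  new("MemoryBackend", env = env, nativeEdit = nativeEdit)
}

setMethod("bkNativeEdit", "MemoryBackend", function(backend) backend@nativeEdit)

setMethod("bkList", "MemoryBackend", function(backend, kind) {
  sort(names(backend@env$records[[.checkKind(kind)]]))
})

setMethod("bkGet", "MemoryBackend", function(backend, kind, id) {
  backend@env$records[[.checkKind(kind)]][[id]]   # NULL when absent
})

setMethod("bkAdd", "MemoryBackend", function(backend, kind, id, record) {
  recs <- backend@env$records
  if (!is.null(recs[[.checkKind(kind)]][[id]]))
    twStop("tw_duplicate_name", "%s id '%s' already present", kind, id)
  recs[[kind]][[id]] <- record
  backend@env$records <- recs
  invisible(id)
})

setMethod("bkDelete", "MemoryBackend", function(backend, kind, id) {
  recs <- backend@env$records
  if (is.null(recs[[.checkKind(kind)]][[id]]))
    twStop("tw_not_found", "%s '%s' not found", kind, id)
  recs[[kind]][[id]] <- NULL
  backend@env$records <- recs
  invisible(id)
})

setMethod("bkUpdate", "MemoryBackend", function(backend, kind, id, record) {
  if (!backend@nativeEdit)
    twStop("tw_bad_kind", "backend does not support native editing")
  recs <- backend@env$records
  if (is.null(recs[[.checkKind(kind)]][[id]]))
    twStop("tw_not_found", "%s '%s' not found", kind, id)
  recs[[kind]][[id]] <- record
  backend@env$records <- recs
  invisible(id)
})

## ---- cache layer ----------------------------------------------------------

#' Wrap a backend with a read cache
#'
#' Reads (`get`, `list`) are served from memory after the first call; every
#' write passes through to the inner backend and flushes the cache, so a read
#' after a write always sees the new value.  The module surface above is
#' unaffected.
#'
#' @param inner the backend to wrap.
#' @return a [CacheLayer-class].
#' @export
cacheLayer <- function(inner) {
  cache <- new.env(parent = emptyenv())
  cache$get <- list(); cache$list <- list()
  new("CacheLayer", inner = inner, cache = cache)
}

.cacheFlush <- function(backend) {
  backend@cache$get <- list(); backend@cache$list <- list()
}

setMethod("bkNativeEdit", "CacheLayer", function(backend) bkNativeEdit(backend@inner))

setMethod("bkList", "CacheLayer", function(backend, kind) {
  hit <- backend@cache$list[[kind]]
  if (!is.null(hit)) return(hit)
  val <- bkList(backend@inner, kind)
  backend@cache$list[[kind]] <- val
  val
})

setMethod("bkGet", "CacheLayer", function(backend, kind, id) {
  key <- paste0(kind, "\r", id)
  hit <- backend@cache$get[[key]]
  if (!is.null(hit)) return(hit)
  val <- bkGet(backend@inner, kind, id)
  if (!is.null(val)) backend@cache$get[[key]] <- val
  val
})

setMethod("bkAdd", "CacheLayer", function(backend, kind, id, record) {
  on.exit(.cacheFlush(backend))
  bkAdd(backend@inner, kind, id, record)
})

setMethod("bkDelete", "CacheLayer", function(backend, kind, id) {
  on.exit(.cacheFlush(backend))
  bkDelete(backend@inner, kind, id)
})

setMethod("bkUpdate", "CacheLayer", function(backend, kind, id, record) {
  on.exit(.cacheFlush(backend))
  bkUpdate(backend@inner, kind, id, record)
})

## ---- counting layer (test instrumentation) --------------------------------

#' Wrap a backend counting calls per verb
#'
#' Instrumentation layer used in tests to observe how many calls reach the
#' wrapped backend (e.g. to show a cache absorbs repeated reads).
#'
#' @param inner the backend to wrap.
#' @return a [CountingBackend-class]; read counts with [backendCounts()].
#' @export
countingBackend <- function(inner) {
  counts <- new.env(parent = emptyenv())
  counts$n <- c(list = 0, get = 0, add = 0, delete = 0, update = 0)
  new("CountingBackend", inner = inner, counts = counts)
}

#' @rdname countingBackend
#' @param backend a [CountingBackend-class].
#' @export
backendCounts <- function(backend) backend@counts$n

.bump <- function(backend, verb) {
  backend@counts$n[verb] <- backend@counts$n[verb] + 1
}

setMethod("bkNativeEdit", "CountingBackend", function(backend) bkNativeEdit(backend@inner))
setMethod("bkList", "CountingBackend", function(backend, kind) {
  .bump(backend, "list"); bkList(backend@inner, kind)
})
setMethod("bkGet", "CountingBackend", function(backend, kind, id) {
  .bump(backend, "get"); bkGet(backend@inner, kind, id)
})
setMethod("bkAdd", "CountingBackend", function(backend, kind, id, record) {
  .bump(backend, "add"); bkAdd(backend@inner, kind, id, record)
})
setMethod("bkDelete", "CountingBackend", function(backend, kind, id) {
  .bump(backend, "delete"); bkDelete(backend@inner, kind, id)
})
setMethod("bkUpdate", "CountingBackend", function(backend, kind, id, record) {
  .bump(backend, "update"); bkUpdate(backend@inner, kind, id, record)
})
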