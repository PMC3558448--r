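## Per-client configuration file: selects the backend, extra layers and
## loader switches, so two clients can share module code but talk to
## different stores with different features enabled.

#' Build a registry from a client configuration file
#'
#' The YAML document maps the registry to a backend and layer stack,
#' mirroring the two-layer (Access/Interface) module contract: changing the
#' configuration swaps stores or enables the cache without touching client
#' code.  Recognized keys:
#'
#' ```yaml
#' registry:
#'   backend: memory        # "memory" (empty) or "json" (load `store`)
#'   native_edit: true      # false emulates edit-less backends
#'   store: registry.json   # required for backend "json"
#'   layers: [cache]        # optional extra layers
#' options:
#'   uniqueToolNames: false
#'   retryOnFailure: true
#' loaders:                 # enable/disable loaders by name
#'   sequence-length: true
#' ```
#'
#' @param path path to the YAML configuration file.
#' @return a configured [ServiceRegistry-class].
#' @export
registryFromConfig <- function(path) {
  if (!file.exists(path))
    twStop("tw_schema_error", "no such configuration file: %s", path)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) twStop("tw_schema_error",
                                             "malformed configuration: %s",
                                             conditionMessage(e)))
  rcfg <- cfg$registry %||% list()
  nativeEdit <- !isFALSE(rcfg$native_edit)
  backendName <- rcfg$backend %||% "memory"
  reg <- switch(backendName,
    memory = newRegistry(backend = memoryBackend(nativeEdit = nativeEdit),
                         options = cfg$options %||% list()),
    json = {
      if (is.null(rcfg$store))
        twStop("tw_schema_error", "backend 'json' requires a 'store' path")
      storePath <- rcfg$store
      if (!grepl("^/", storePath))
        storePath <- file.path(dirname(path), storePath)
      r <- loadRegistry(storePath, backend = memoryBackend(nativeEdit = nativeEdit))
      rst <- regState(r)
      rst$options <- utils::modifyList(rst$options, cfg$options %||% list())
      r
    },
    twStop("tw_schema_error", "unknown backend '%s'", backendName))
  for (l in rcfg$layers %||% character()) attachLayer(reg, l)
  for (nm in names(cfg$loaders %||% list()))
    if (nm %in% names(regState(reg)$loaders))
      setLoaderEnabled(reg, nm, isTRUE(cfg$loaders[[nm]]))
  reg
}
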