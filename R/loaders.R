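## Loaders: inheritance-scoped structure transformers applied seamlessly.

#' Register a loader
#'
#' The loader applies to its scope datatype and every IS-descendant, without
#' callers asking for it: [applyLoaders()] runs each in-scope loader exactly
#' once, ancestor scopes first (so base-standard loaders precede derived
#' ones), then by priority, then by registration order.
#'
#' @inheritParams newTool
#' @param name unique loader name.
#' @param scopeDatatype datatype whose subtree the loader covers.
#' @param transform function(registry, data) returning the transformed
#'   [StructuredData-class]; must be deterministic.
#' @param priority smaller runs earlier within the same scope depth.
#' @return the loader name, invisibly.
#' @export
registerLoader <- function(registry, name, scopeDatatype, transform,
                           priority = 100) {
  .mustResolve(registry, "datatype", scopeDatatype)
  st <- regState(registry)
  if (name %in% names(st$loaders))
    twStop("tw_duplicate_name", "loader '%s' already registered", name)
  st$loaders[[name]] <- new("LoaderSpec", name = name,
                            scopeDatatype = scopeDatatype,
                            transform = transform, priority = priority)
  st$loaderConfig[[name]] <- TRUE
  invisible(name)
}

#' Enable or disable a loader by name
#'
#' Mirrors the configuration-file switch: disabled loaders are skipped by
#' [applyLoaders()] without being unregistered.
#'
#' @inheritParams registerLoader
#' @param enabled logical.
#' @export
setLoaderEnabled <- function(registry, name, enabled = TRUE) {
  st <- regState(registry)
  if (!name %in% names(st$loaders))
    twStop("tw_not_found", "loader '%s' not registered", name)
  st$loaderConfig[[name]] <- isTRUE(enabled)
  invisible(name)
}

.datatypeDepth <- function(registry, name) {
  length(.ancestorsOrSelf(.parentMap(registry), name)) - 1L
}

#' Apply every in-scope loader to a data instance
#'
#' Selects the enabled loaders whose scope datatype is an ancestor-or-self
#' of the data's datatype and runs each exactly once, in deterministic
#' order: ancestor scope first, then priority, then registration order.
#' A loader configured on a parent datatype therefore also runs for data of
#' any child datatype.
#'
#' @inheritParams getPart
#' @return list with `data` (the transformed [StructuredData-class]) and
#'   `applied` (loader names in execution order).
#' @export
applyLoaders <- function(registry, data) {
  st <- regState(registry)
  lineage <- .ancestorsOrSelf(.parentMap(registry), data@datatype)
  specs <- Filter(function(l) isTRUE(st$loaderConfig[[l@name]]) &&
                    l@scopeDatatype %in% lineage,
                  st$loaders)
  if (length(specs)) {
    depth <- vapply(specs, function(l) .datatypeDepth(registry, l@scopeDatatype),
                    numeric(1))
    prio <- vapply(specs, slot, numeric(1), "priority")
    specs <- specs[order(depth, prio, seq_along(specs))]
  }
  applied <- character()
  for (l in specs) {
    data <- tryCatch(l@transform(registry, data), error = function(e) {
      if (inherits(e, "tw_loader_failure")) stop(e)
      twStop("tw_loader_failure", "loader '%s' failed: %s",
             l@name, conditionMessage(e), data = list(loader = l@name, cause = e))
    })
    if (!is(data, "StructuredData"))
      twStop("tw_loader_failure", "loader '%s' did not return StructuredData", l@name)
    applied <- c(applied, l@name)
  }
  list(data = data, applied = applied)
}

## ---- shipped loaders ------------------------------------------------------

## Every data object in the BioMOBY-style model must carry an identifier and
## a namespace; inject them (empty-string default) when the datatype
## declares them and the instance lacks them.
.mobyBaseLoader <- function(registry, data) {
  eff <- getDatatype(registry, data@datatype)@effectiveAttributes
  for (a in c("id", "namespace"))
    if (a %in% names(eff) && is.null(data@attributes[[a]]))
      data@attributes[[a]] <- ""
  data
}

## Sequences must state their length explicitly; compute it from the
## sequence characters.
.sequenceLengthLoader <- function(registry, data) {
  eff <- getDatatype(registry, data@datatype)@effectiveAttributes
  if ("length" %in% names(eff) && "SequenceString" %in% names(eff)) {
    seq <- data@attributes[["SequenceString"]] %||% ""
    data@attributes[["length"]] <- nchar(seq)
  }
  data
}
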