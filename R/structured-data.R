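## StructuredData construction, validation and navigation.

.checkPrimitive <- function(value, primitive, what) {
  ok <- switch(primitive,
    String = is.character(value) && length(value) == 1L,
    Integer = (is.numeric(value) && length(value) == 1L &&
                 !is.na(value) && value == trunc(value)),
    Float = is.numeric(value) && length(value) == 1L,
    Boolean = is.logical(value) && length(value) == 1L,
    FALSE)
  if (!ok)
    twStop("tw_type_mismatch", "%s must be a scalar %s", what, primitive)
  if (primitive == "Integer") value <- as.integer(value)
  value
}

#' Create a structured-data instance of a datatype
#'
#' Builds the DOM-like tree the loaders and formatters work on.  Attribute
#' names must be declared (directly or by inheritance) on the datatype and
#' values must match the declared primitive types; HASA parts are single
#' instances, HAS parts lists of instances.
#'
#' @inheritParams newTool
#' @param datatype name of the datatype to instantiate.
#' @param attributes named list of primitive attribute values.
#' @param parts named list of parts (`StructuredData` for HASA, list of
#'   `StructuredData` for HAS).
#' @param provenance source format tag, e.g. `"fasta"`; `""` when built
#'   programmatically.
#' @return a [StructuredData-class].
#' @examples
#' reg <- buildUsecaseRegistry()
#' seq <- newData(reg, "GenericSequence",
#'                attributes = list(id = "s1", SequenceString = "MKT"))
#' @export
newData <- function(registry, datatype, attributes = list(), parts = list(),
                    provenance = "") {
  node <- getDatatype(registry, datatype)
  eff <- node@effectiveAttributes
  for (a in names(attributes)) {
    if (!a %in% names(eff))
      twStop("tw_bad_path", "datatype '%s' declares no attribute '%s'", datatype, a)
    attributes[[a]] <- .checkPrimitive(attributes[[a]], eff[[a]],
                                       sprintf("attribute '%s'", a))
  }
  declaredParts <- c(node@effectiveHasParts, node@effectiveHasaParts)
  for (p in names(parts)) {
    if (!p %in% names(declaredParts))
      twStop("tw_bad_path", "datatype '%s' declares no part '%s'", datatype, p)
    single <- p %in% names(node@effectiveHasaParts)
    if (single && !is(parts[[p]], "StructuredData"))
      twStop("tw_type_mismatch", "HASA part '%s' must be a single StructuredData", p)
    if (!single) {
      if (is(parts[[p]], "StructuredData")) parts[[p]] <- list(parts[[p]])
      if (!all(vapply(parts[[p]], is, logical(1), "StructuredData")))
        twStop("tw_type_mismatch", "HAS part '%s' must be a list of StructuredData", p)
    }
  }
  new("StructuredData", datatype = datatype, attributes = attributes,
      parts = parts, provenance = provenance)
}

.splitPath <- function(path) {
  segs <- strsplit(path, "/", fixed = TRUE)[[1]]
  segs <- segs[nzchar(segs)]
  if (!length(segs)) twStop("tw_bad_path", "empty part path")
  segs
}

#' Read a value from a structured-data tree
#'
#' `path` names attributes or parts, nested segments separated by `/`
#' (e.g. `"SequenceString"` or `"annotations/0/note"`; numeric segments
#' index HAS lists, 1-based).  Returns `NULL` when the addressed attribute
#' or part is declared but absent.
#'
#' @inheritParams newTool
#' @param data a [StructuredData-class].
#' @param path slash-separated path of attribute/part names.
#' @return the primitive value, part, or `NULL` when absent.
#' @export
getPart <- function(registry, data, path) {
  segs <- .splitPath(path)
  cur <- data
  for (k in seq_along(segs)) {
    s <- segs[[k]]
    if (grepl("^[0-9]+$", s)) {
      if (!is.list(cur)) twStop("tw_bad_path", "index '%s' into a non-list", s)
      idx <- as.integer(s)
      if (idx < 1L || idx > length(cur)) return(NULL)
      cur <- cur[[idx]]
      next
    }
    if (!is(cur, "StructuredData"))
      twStop("tw_bad_path", "path segment '%s' applied to a primitive", s)
    node <- getDatatype(registry, cur@datatype)
    if (s %in% names(node@effectiveAttributes)) {
      if (k != length(segs))
        twStop("tw_bad_path", "attribute '%s' is a leaf", s)
      return(cur@attributes[[s]])
    }
    if (s %in% c(names(node@effectiveHasParts), names(node@effectiveHasaParts))) {
      val <- cur@parts[[s]]
      if (is.null(val)) return(NULL)
      cur <- val
      next
    }
    twStop("tw_bad_path", "datatype '%s' declares no attribute or part '%s'",
           cur@datatype, s)
  }
  cur
}

#' Set a value in a structured-data tree
#'
#' Validates the new value against the declared primitive type (for
#' attributes) or against the part's datatype.  `StructuredData` has value
#' semantics: the modified tree is returned, the input is untouched.
#'
#' @inheritParams getPart
#' @param value new attribute value or part.
#' @return the modified [StructuredData-class].
#' @export
setPart <- function(registry, data, path, value) {
  segs <- .splitPath(path)
  node <- getDatatype(registry, data@datatype)
  s <- segs[[1]]
  if (length(segs) == 1L) {
    if (s %in% names(node@effectiveAttributes)) {
      data@attributes[[s]] <- .checkPrimitive(value, node@effectiveAttributes[[s]],
                                              sprintf("attribute '%s'", s))
      return(data)
    }
    if (s %in% names(node@effectiveHasaParts)) {
      if (!is(value, "StructuredData"))
        twStop("tw_type_mismatch", "HASA part '%s' must be a StructuredData", s)
      if (!isSubtypeOf(registry, value@datatype, node@effectiveHasaParts[[s]]))
        twStop("tw_type_mismatch", "part '%s' must be a subtype of %s",
               s, node@effectiveHasaParts[[s]])
      data@parts[[s]] <- value
      return(data)
    }
    if (s %in% names(node@effectiveHasParts)) {
      if (is(value, "StructuredData")) value <- list(value)
      for (v in value)
        if (!isSubtypeOf(registry, v@datatype, node@effectiveHasParts[[s]]))
          twStop("tw_type_mismatch", "part '%s' items must be subtypes of %s",
                 s, node@effectiveHasParts[[s]])
      data@parts[[s]] <- value
      return(data)
    }
    twStop("tw_bad_path", "datatype '%s' declares no attribute or part '%s'",
           data@datatype, s)
  }
  ## nested: recurse into a part
  child <- getPart(registry, data, s)
  if (is.null(child))
    twStop("tw_bad_path", "part '%s' is absent; set it first", s)
  if (!is(child, "StructuredData"))
    twStop("tw_bad_path", "cannot descend through '%s'", s)
  data@parts[[s]] <- setPart(registry, child,
                             paste(segs[-1], collapse = "/"), value)
  data
}

#' Validate a structured-data tree against the taxonomy
#'
#' @inheritParams getPart
#' @return character vector of violations; empty when valid.
#' @export
validateData <- function(registry, data) {
  bad <- character()
  node <- tryCatch(getDatatype(registry, data@datatype), tw_error = function(e) NULL)
  if (is.null(node))
    return(sprintf("unknown datatype '%s'", data@datatype))
  extra <- setdiff(names(data@attributes), names(node@effectiveAttributes))
  if (length(extra))
    bad <- c(bad, sprintf("undeclared attribute(s): %s", paste(extra, collapse = ", ")))
  for (p in names(data@parts)) {
    v <- data@parts[[p]]
    items <- if (is(v, "StructuredData")) list(v) else v
    for (item in items) bad <- c(bad, validateData(registry, item))
  }
  bad
}
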