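## Datatype taxonomy (IS/HAS/HASA), functional categories, namespaces.

## parent map cached per registry version: named character, NA for roots
.parentMap <- function(registry, kind = "datatype") {
  .cached(registry, paste0("parents.", kind), function() {
    recs <- .allRecords(registry, kind)
    vapply(recs, function(n) {
      p <- if (kind == "datatype") n@isParent else n@parent
      if (length(p)) p else NA_character_
    }, character(1))
  })
}

.ancestorsOrSelf <- function(parents, name) {
  out <- character()
  cur <- name
  while (!is.na(cur) && cur %in% names(parents) && !(cur %in% out)) {
    out <- c(out, cur)
    cur <- parents[[cur]]
  }
  out
}

#' Add a datatype to the shared taxonomy
#'
#' Datatypes follow the object-oriented pattern of the BioMOBY taxonomy:
#' single inheritance via the IS relation, arrays of parts via HAS, single
#' contained parts via HASA, and typed primitive attributes.  The node name
#' is the identity.  Declaring a service parameter with a datatype promises
#' the service can process that type and, by inheritance, all its subtypes.
#'
#' @inheritParams newTool
#' @param name new node name (unique).
#' @param description free text.
#' @param parent name of the IS parent, or `NULL` for a root.
#' @param attributes named character vector mapping attribute names to
#'   primitive types (`String`, `Integer`, `Float`, `Boolean`).
#' @param hasParts named character vector part name -> datatype name
#'   (cardinality many).
#' @param hasaParts named character vector part name -> datatype name
#'   (cardinality one).
#' @return the stored [DatatypeNode-class].
#' @examples
#' reg <- newRegistry()
#' addDatatype(reg, "Object")
#' addDatatype(reg, "VirtualSequence", parent = "Object",
#'             attributes = c(id = "String", namespace = "String", length = "Integer"))
#' @export
addDatatype <- function(registry, name, description = "", parent = NULL,
                        attributes = character(), hasParts = character(),
                        hasaParts = character()) {
  if (!is.null(.getOrNull(registry, "datatype", name)))
    twStop("tw_duplicate_name", "datatype '%s' already exists", name)
  if (!is.null(parent)) {
    if (identical(parent, name))
      twStop("tw_cycle", "datatype '%s' cannot be its own parent", name)
    .mustResolve(registry, "datatype", parent)
  }
  for (ref in c(hasParts, hasaParts))
    if (!identical(ref, name) && is.null(.getOrNull(registry, "datatype", ref)))
      twStop("tw_unresolved_reference", "part datatype '%s' not found", ref)
  node <- new("DatatypeNode", name = name, description = description,
              isParent = if (is.null(parent)) character() else parent,
              attributes = .asNamedChr(attributes),
              hasParts = .asNamedChr(hasParts), hasaParts = .asNamedChr(hasaParts))
  validObject(node)
  .storeAdd(registry, "datatype", name, node)
  node
}

.asNamedChr <- function(x) {
  if (!length(x)) return(stats::setNames(character(), character()))
  stats::setNames(as.character(x), names(x))
}

#' Retrieve a datatype with inherited members materialized
#'
#' Returns the node with its effective attributes and parts: its own plus
#' everything inherited along the IS chain, ancestor-first.  For example a
#' sequence type inheriting `id`, `namespace` and `length` and adding
#' `SequenceString` reports all four.
#'
#' @inheritParams newTool
#' @param name datatype name.
#' @return a [DatatypeNode-class] with the `effective*` slots filled.
#' @export
getDatatype <- function(registry, name) {
  node <- .mustGet(registry, "datatype", name)
  parents <- .parentMap(registry)
  chain <- rev(.ancestorsOrSelf(parents, name))   # root first
  eff <- character(); has <- character(); hasa <- character()
  for (nm in chain) {
    n <- .mustGet(registry, "datatype", nm)
    eff <- c(eff, n@attributes[setdiff(names(n@attributes), names(eff))])
    has <- c(has, n@hasParts[setdiff(names(n@hasParts), names(has))])
    hasa <- c(hasa, n@hasaParts[setdiff(names(n@hasaParts), names(hasa))])
  }
  node@effectiveAttributes <- .asNamedChr(eff)
  node@effectiveHasParts <- .asNamedChr(has)
  node@effectiveHasaParts <- .asNamedChr(hasa)
  node
}

#' Test the subtype relation between two datatypes
#'
#' `TRUE` iff `ancestor` is reachable from `child` following IS edges; the
#' relation is reflexive, so every type is a subtype of itself.  This is the
#' compatibility test used everywhere: a service declaring an input datatype
#' accepts instances of any subtype.
#'
#' @inheritParams newTool
#' @param child,ancestor datatype names (both must resolve).
#' @return logical(1).
#' @export
isSubtypeOf <- function(registry, child, ancestor) {
  parents <- .parentMap(registry)
  if (!child %in% names(parents)) twStop("tw_not_found", "datatype '%s' not found", child)
  if (!ancestor %in% names(parents)) twStop("tw_not_found", "datatype '%s' not found", ancestor)
  ancestor %in% .ancestorsOrSelf(parents, child)
}

## ---- categories and namespaces -------------------------------------------

#' Add a functional category
#'
#' Functional categories are hierarchical keywords annotating tools, from
#' generic to very specific; browsing starts at the roots and descends.
#'
#' @inheritParams newTool
#' @param name category name (unique).
#' @param description free text.
#' @param parent parent category name or `NULL` for a root.
#' @return the stored [FunctionalCategoryNode-class].
#' @export
addCategory <- function(registry, name, description = "", parent = NULL) {
  if (!is.null(.getOrNull(registry, "category", name)))
    twStop("tw_duplicate_name", "category '%s' already exists", name)
  if (!is.null(parent)) {
    if (identical(parent, name))
      twStop("tw_cycle", "category '%s' cannot be its own parent", name)
    .mustResolve(registry, "category", parent)
  }
  node <- new("FunctionalCategoryNode", name = name, description = description,
              parent = if (is.null(parent)) character() else parent)
  .storeAdd(registry, "category", name, node)
  node
}

#' Add a namespace (data-provenance label)
#'
#' @inheritParams newTool
#' @param name unique namespace name.
#' @param description free text.
#' @param source note about the originating data source.
#' @return the stored [NamespaceRecord-class].
#' @export
addNamespace <- function(registry, name, description = "", source = "") {
  if (!is.null(.getOrNull(registry, "namespace", name)))
    twStop("tw_duplicate_name", "namespace '%s' already exists", name)
  rec <- new("NamespaceRecord", name = name, description = description, source = source)
  .storeAdd(registry, "namespace", name, rec)
  rec
}

#' Roots of the functional-category taxonomy
#'
#' @inheritParams newTool
#' @return list of parentless [FunctionalCategoryNode-class], name-sorted.
#' @export
getCategoryRoots <- function(registry) {
  cats <- .allRecords(registry, "category")
  unname(Filter(function(c) length(c@parent) == 0L, cats))
}

#' Direct children of a taxonomy node
#'
#' Works for both datatypes and functional categories; returns direct
#' children only (`c` is returned iff its parent is `name`).
#'
#' @inheritParams newTool
#' @param name node name.
#' @return list of nodes, name-sorted.
#' @export
getChildren <- function(registry, name) {
  for (kind in c("datatype", "category")) {
    if (!is.null(.getOrNull(registry, kind, name))) {
      parents <- .parentMap(registry, kind)
      kids <- names(parents)[!is.na(parents) & parents == name]
      return(lapply(sort(kids), function(k) .mustGet(registry, kind, k)))
    }
  }
  twStop("tw_not_found", "no datatype or category named '%s'", name)
}

#' Tools annotated with a functional category
#'
#' @inheritParams newTool
#' @param category category name.
#' @param recursive also include tools annotated with any descendant
#'   category.
#' @return list of [ToolRecord-class], id-sorted.
#' @export
getToolsForCategory <- function(registry, category, recursive = FALSE) {
  .mustGet(registry, "category", category)
  wanted <- category
  if (recursive) {
    parents <- .parentMap(registry, "category")
    wanted <- names(parents)[vapply(names(parents), function(n)
      category %in% .ancestorsOrSelf(parents, n), logical(1))]
  }
  tools <- .allRecords(registry, "tool")
  unname(Filter(function(t) any(t@categoryRefs %in% wanted), tools))
}

#' Retrieve a category with its tool annotations materialized
#'
#' @inheritParams getToolsForCategory
#' @return a [FunctionalCategoryNode-class] with `toolRefs` filled.
#' @export
getCategory <- function(registry, category) {
  node <- .mustGet(registry, "category", category)
  node@toolRefs <- vapply(getToolsForCategory(registry, category), recordId, character(1))
  node
}

## ---- structural editing ---------------------------------------------------

#' Move a taxonomy node under a new parent
#'
#' Changes the parent/child relations of the datatype or category taxonomy;
#' the subtype index is rebuilt.  Moving a node under itself or one of its
#' own descendants is rejected.
#'
#' @inheritParams newTool
#' @param name node to move.
#' @param newParent new parent name, or `NULL` to make the node a root.
#' @return the updated node.
#' @export
reparentNode <- function(registry, name, newParent = NULL) {
  kind <- if (!is.null(.getOrNull(registry, "datatype", name))) "datatype"
          else if (!is.null(.getOrNull(registry, "category", name))) "category"
          else twStop("tw_not_found", "no datatype or category named '%s'", name)
  node <- .mustGet(registry, kind, name)
  if (!is.null(newParent)) {
    .mustGet(registry, kind, newParent)
    parents <- .parentMap(registry, kind)
    if (name %in% .ancestorsOrSelf(parents, newParent))
      twStop("tw_cycle", "moving '%s' under '%s' would create a cycle",
             name, newParent)
  }
  np <- if (is.null(newParent)) character() else newParent
  if (kind == "datatype") node@isParent <- np else node@parent <- np
  .storeUpdate(registry, kind, name, node)
  node
}

## ---- validation -----------------------------------------------------------

.taxonomyRefFindings <- function(dts, cats) {
  f <- character()
  for (d in dts) {
    if (length(d@isParent) && !d@isParent %in% names(dts))
      f <- c(f, sprintf("datatype %s has missing parent %s", d@name, d@isParent))
    for (ref in c(d@hasParts, d@hasaParts))
      if (!ref %in% names(dts))
        f <- c(f, sprintf("datatype %s has dangling part datatype %s", d@name, ref))
  }
  for (c in cats)
    if (length(c@parent) && !c@parent %in% names(cats))
      f <- c(f, sprintf("category %s has missing parent %s", c@name, c@parent))
  f
}

#' Validate the datatype taxonomy
#'
#' Reports IS cycles (naming their members), dangling parents and part
#' references, and attribute shadowing (a node redeclaring an attribute name
#' already inherited from an ancestor).  An empty report means every
#' taxonomy invariant holds.
#'
#' @inheritParams newTool
#' @return list of findings, each a list with `type`, `subject`, `detail`;
#'   empty when the taxonomy is well-formed.
#' @export
validateTaxonomy <- function(registry) {
  dts <- .allRecords(registry, "datatype")
  findings <- list()
  note <- function(type, subject, detail)
    findings[[length(findings) + 1L]] <<- list(type = type, subject = subject, detail = detail)

  ## cycles: follow parent chain with a visited set
  parents <- vapply(dts, function(d) if (length(d@isParent)) d@isParent else NA_character_,
                    character(1))
  inCycle <- character()
  for (start in names(parents)) {
    seen <- character(); cur <- start
    while (!is.na(cur) && cur %in% names(parents)) {
      if (cur %in% seen) {
        members <- seen[which(seen == cur):length(seen)]
        inCycle <- union(inCycle, members)
        break
      }
      seen <- c(seen, cur)
      cur <- parents[[cur]]
    }
  }
  if (length(inCycle))
    note("cycle", sort(inCycle)[1],
         sprintf("IS cycle involving: %s", paste(sort(inCycle), collapse = ", ")))

  for (msg in .taxonomyRefFindings(dts, list())) {
    subject <- sub("^datatype (\\S+) .*$", "\\1", msg)
    note(if (grepl("dangling part", msg)) "dangling_part" else "dangling_parent",
         subject, msg)
  }

  ## attribute shadowing along lineages (only meaningful off-cycle)
  for (d in dts) {
    if (d@name %in% inCycle) next
    cur <- if (length(d@isParent)) d@isParent else NA_character_
    while (!is.na(cur) && cur %in% names(dts)) {
      anc <- dts[[cur]]
      shadowed <- intersect(names(d@attributes), names(anc@attributes))
      for (a in shadowed)
        note("shadowed_attribute", d@name,
             sprintf("datatype %s redeclares attribute '%s' inherited from %s",
                     d@name, a, cur))
      cur <- if (length(anc@isParent)) anc@isParent else NA_character_
    }
  }
  findings
}
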