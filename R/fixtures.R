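## Fixture registries: the worked-example registry and a seeded synthetic
## generator for property testing at scale.

#' Build the worked-example registry
#'
#' A complete small registry modelling a provider who deploys two
#' BioMOBY-style services: `getAminoAcidSequence` (input `id` of type
#' `Object`, output `sequence` of type `AminoAcidSequence`) retrieving a
#' protein sequence by identifier, and `runRPSBlast` (input `sequence` of
#' type `GenericSequence`, output `blast_report` of type `BLAST-Text`)
#' comparing a sequence against known domains.  The taxonomy is the
#' BioMOBY-style chain `Object` -> `VirtualSequence` (adds `id`,
#' `namespace`, `length`) -> `GenericSequence` (adds `SequenceString`) ->
#' `AminoAcidSequence`, plus `BLAST-Text` under the root.  Because
#' `AminoAcidSequence` is a subtype of `GenericSequence`, the two services
#' chain into a two-stage pipeline from `Object` to `BLAST-Text`.  Each tool
#' gets one `biomoby` endpoint, and the shipped formatters/loaders are
#' registered.
#'
#' @return a populated [ServiceRegistry-class].
#' @examples
#' reg <- buildUsecaseRegistry()
#' findPath(reg, "Object", "BLAST-Text")
#' @export
buildUsecaseRegistry <- function() {
  reg <- newRegistry()
  addDatatype(reg, "Object", "root of the datatype taxonomy")
  addDatatype(reg, "VirtualSequence", "sequence without the characters",
              parent = "Object",
              attributes = c(id = "String", namespace = "String", length = "Integer"))
  addDatatype(reg, "GenericSequence", "sequence with its characters",
              parent = "VirtualSequence",
              attributes = c(SequenceString = "String"))
  addDatatype(reg, "AminoAcidSequence", "protein sequence",
              parent = "GenericSequence")
  addDatatype(reg, "BLAST-Text", "plain-text BLAST report", parent = "Object")

  addCategory(reg, "Retrieval", "database retrieval services")
  addCategory(reg, "Alignment", "sequence comparison services")
  addNamespace(reg, "UniProt", "protein knowledgebase accessions")

  t1 <- newTool(reg, "getAminoAcidSequence",
                "retrieve an amino-acid sequence by identifier",
                categories = "Retrieval")
  o1 <- addOperation(reg, t1@id, "getAminoAcidSequence")
  addParameter(reg, o1@id, "id", "input", "Object", namespace = "UniProt")
  addParameter(reg, o1@id, "sequence", "output", "AminoAcidSequence")
  newToolLocation(reg, t1@id, "biomoby", "http://host1/moby")

  t2 <- newTool(reg, "runRPSBlast",
                "search a sequence against conserved domains",
                categories = "Alignment")
  o2 <- addOperation(reg, t2@id, "runRPSBlast")
  addParameter(reg, o2@id, "sequence", "input", "GenericSequence")
  addParameter(reg, o2@id, "blast_report", "output", "BLAST-Text")
  newToolLocation(reg, t2@id, "biomoby", "http://host2/moby")

  registerDefaultDataHandlers(reg)
  reg
}

#' Describe a synthetic registry
#'
#' Bundles the knobs of [generateSyntheticRegistry()]: taxonomy size and
#' depth, number of tools and operations, parameter fan-in/out and whether a
#' type-connectable operation chain is planted.  The same spec (same seed)
#' always produces a byte-identical registry store.
#'
#' @param seed integer seed controlling all randomness.
#' @param nDatatypes number of taxonomy nodes (>= 1; a root is always
#'   present).
#' @param depth maximum taxonomy depth.
#' @param nTools number of tools (0 allowed).
#' @param opsPerTool operations per tool.
#' @param paramRange length-2 integer range for inputs and outputs per
#'   operation.
#' @param chainFraction fraction of tools participating in a planted
#'   type-connectable chain (0 disables planting).
#' @param chainLength number of operations in the planted chain.
#' @return a fixture spec (classed list).
#' @export
fixtureSpec <- function(seed = 1L, nDatatypes = 15L, depth = 4L, nTools = 6L,
                        opsPerTool = 2L, paramRange = c(1L, 2L),
                        chainFraction = 0.5, chainLength = 3L) {
  spec <- list(seed = as.integer(seed), nDatatypes = as.integer(nDatatypes),
               depth = as.integer(depth), nTools = as.integer(nTools),
               opsPerTool = as.integer(opsPerTool),
               paramRange = as.integer(paramRange),
               chainFraction = chainFraction, chainLength = as.integer(chainLength))
  if (spec$nDatatypes < 1 || spec$depth < 1 || spec$nTools < 0 ||
      spec$opsPerTool < 1 || length(spec$paramRange) != 2 ||
      any(spec$paramRange < 1) || spec$paramRange[1] > spec$paramRange[2] ||
      spec$chainFraction < 0 || spec$chainFraction > 1 || spec$chainLength < 1)
    twStop("tw_bad_spec", "fixture spec bounds are not sane")
  structure(spec, class = "tw_fixture_spec")
}

#' Generate a seeded synthetic registry
#'
#' Deterministic per seed: a random single-parent (acyclic by construction)
#' datatype taxonomy, random functional categories and namespaces, and
#' tools whose operations consume and produce random datatypes.  When
#' `chainFraction > 0` a type-connectable chain of operations is planted
#' through fresh datatypes, so [findPath()] is guaranteed to succeed for the
#' planted source/target pair (recorded in [fixtureInfo()]).  The caller's
#' RNG state is left untouched.
#'
#' @param spec a [fixtureSpec()].
#' @return a populated [ServiceRegistry-class].
#' @export
generateSyntheticRegistry <- function(spec = fixtureSpec()) {
  if (!inherits(spec, "tw_fixture_spec")) spec <- do.call(fixtureSpec, spec)
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  reg <- newRegistry()
  addDatatype(reg, "Root", "synthetic taxonomy root")
  nodes <- "Root"
  depths <- c(Root = 0L)
  primPool <- c("String", "Integer", "Float", "Boolean")
  for (i in seq_len(spec$nDatatypes - 1L)) {
    name <- sprintf("DT%03d", i)
    eligible <- nodes[depths[nodes] < spec$depth]
    parent <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
    nAttr <- sample(0:2, 1L)
    attrs <- character()
    if (nAttr > 0)
      attrs <- stats::setNames(sample(primPool, nAttr, replace = TRUE),
                               sprintf("%s_a%d", tolower(name), seq_len(nAttr)))
    addDatatype(reg, name, parent = parent, attributes = attrs)
    nodes <- c(nodes, name)
    depths[name] <- depths[[parent]] + 1L
  }

  for (i in seq_len(3L))
    addCategory(reg, sprintf("Cat%02d", i),
                parent = if (i > 1 && stats::runif(1) < 0.5)
                  sprintf("Cat%02d", sample(i - 1L, 1L)) else NULL)
  addNamespace(reg, "SyntheticDB", "generated provenance label")

  randType <- function() if (length(nodes) == 1L) nodes else sample(nodes, 1L)
  for (i in seq_len(spec$nTools)) {
    t <- newTool(reg, sprintf("tool%02d", i),
                 categories = sprintf("Cat%02d", sample(3L, 1L)))
    for (j in seq_len(spec$opsPerTool)) {
      op <- addOperation(reg, t@id, sprintf("op%02d_%d", i, j))
      nIn <- sample(spec$paramRange[1]:spec$paramRange[2], 1L)
      nOut <- sample(spec$paramRange[1]:spec$paramRange[2], 1L)
      for (k in seq_len(nIn))
        addParameter(reg, op@id, sprintf("in%d", k), "input", randType())
      for (k in seq_len(nOut))
        addParameter(reg, op@id, sprintf("out%d", k), "output", randType())
    }
    newToolLocation(reg, t@id, "local", sprintf("local://tool%02d", i))
  }

  info <- list(seed = spec$seed)
  if (spec$chainFraction > 0 && spec$nTools > 0) {
    len <- max(1L, min(spec$chainLength, spec$nTools))
    chainTypes <- sprintf("Chain%02d", seq_len(len + 1L))
    for (ct in chainTypes) addDatatype(reg, ct, parent = "Root")
    t <- newTool(reg, "chainTool")
    for (k in seq_len(len)) {
      op <- addOperation(reg, t@id, sprintf("chain_op%d", k))
      addParameter(reg, op@id, "in1", "input", chainTypes[k])
      addParameter(reg, op@id, "out1", "output", chainTypes[k + 1L])
    }
    newToolLocation(reg, t@id, "local", "local://chainTool")
    info$plantedSource <- chainTypes[1L]
    info$plantedTarget <- chainTypes[len + 1L]
    info$plantedLength <- len
  }
  st <- regState(reg)
  st$fixtureInfo <- info
  reg
}

#' Provenance of a synthetic registry
#'
#' @inheritParams newTool
#' @return the generator info (seed, planted source/target datatypes), or
#'   `NULL` for hand-built registries.
#' @export
fixtureInfo <- function(registry) regState(registry)$fixtureInfo
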