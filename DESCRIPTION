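Package: ToolWeaver
Title: Uniform Metadata Registry, Type-Driven Pipeline Composition and
    Enactment for Heterogeneous Bioinformatics Web Services
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A modular, offline-testable framework that gives client code a
    uniform model of heterogeneous web-service metadata: tools, endpoints
    (mirrors), operations and typed parameters, functional categories,
    namespaces and a shared datatype taxonomy with IS/HAS/HASA relations.
    On top of the registry it discovers type-compatible service pipelines by
    subtype-aware path search, converts user data between biological sequence
    formats (FASTA, GenBank flat file, raw sequence text, a BioMOBY-style XML
    dialect) through inheritance-scoped loaders and formatters with rule-based
    format recognition, and enacts pipelines through pluggable protocol
    workers with a submit/poll/retrieve task lifecycle and per-endpoint usage
    statistics.  Backends are layered (Access/Interface with an optional
    cache layer) and a single-file JSON store plus a synthetic fixture
    generator make the whole stack reproducible without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    jsonlite,
    xml2,
    yaml,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'conditions.R'
    'AllClasses.R'
    'AllGenerics.R'
    'backend.R'
    'registry-core.R'
    'registry.R'
    'taxonomy.R'
    'composition.R'
    'structured-data.R'
    'formats.R'
    'loaders.R'
    'execution.R'
    'store.R'
    'fixtures.R'
    'config.R'
    'cli.R'
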