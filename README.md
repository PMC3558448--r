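# ToolWeaver

Bioinformatics analyses increasingly chain web services — a database
retrieval feeding a BLAST search feeding a report parser — but the services
speak different protocols (SOAP, REST, BioMOBY-style messaging) and
different data formats (FASTA, GenBank flat files, raw sequence text, XML
dialects). ToolWeaver is an R framework for *client* developers who need to
discover, connect and invoke such heterogeneous services through one
uniform model, entirely offline-testable: it ships no network bindings, but
a worker plug-in contract through which real protocol bindings (or the mock
workers used throughout the tests) are attached.

The framework is organised in the modules such systems conventionally use:

* **Registry** — abstract *tools* with *operations* and typed *parameters*,
  plus concrete *tool locations* (endpoint mirrors). Storage goes through a
  two-layer contract (a swappable Access backend beneath a stable Interface
  surface); extra layers such as a read cache stack on top without changing
  any result. Editing works even over backends without native update
  support, emulated transparently as deregister + register under the same
  id. Deletion either cascades through the dependency closure or is
  rejected while dependencies exist.
* **Taxonomy** — the shared datatype taxonomy with single inheritance (IS)
  and HAS/HASA part relations, functional-category hierarchies for
  browsing, and namespaces for data provenance. A service declaring an
  input datatype *D* promises to accept every subtype of *D*:
  `isSubtypeOf(reg, x, d)` is the reflexive–transitive closure of the IS
  relation and drives everything else.
* **Composition** — automatic pipeline discovery. Each (operation, input
  parameter, output parameter) triple is a directed edge between datatypes,
  traversable from the current type `c` whenever `isSubtypeOf(c, input)`;
  `findPath()` returns a shortest chain (breadth-first, deterministic
  lexicographic tie-break), `enumeratePaths()` all alternatives.
* **Data engine** — a DOM-like `StructuredData` tree per datatype,
  rule-based format recognition (GenBank, FASTQ, XML, FASTA, raw text, with
  a 90% ACGTUN letter-fraction rule separating nucleotide from protein),
  parsers/serializers (*formatters*) and inheritance-scoped *loaders* that
  patch data up to a standard's requirements — e.g. injecting the mandatory
  `id`/`namespace` attributes and computing the explicit sequence `length`
  that FASTA does not carry.
* **Execution** — protocol *workers*, a submit/poll/retrieve task lifecycle
  (`SUBMITTED → RUNNING → {SUCCEEDED, FAILED}`), round-robin mirror
  selection with one-shot retry, pipeline enactment with automatic
  per-stage data adaptation, and per-endpoint usage statistics.
* **Store / CLI** — a versioned single-file JSON registry store with
  round-trip identity, a seeded synthetic registry generator for
  property-style testing, and a thin `toolweaver` command-line interface
  (`register`, `list`, `taxonomy`, `compose`, `detect`, `convert`, `run`,
  `stats`).

## Worked example

A provider registers two services: `getAminoAcidSequence` (input `id` of
type `Object`, output `sequence` of type `AminoAcidSequence`) and
`runRPSBlast` (input `sequence` of type `GenericSequence`, output
`blast_report` of type `BLAST-Text`). A client then asks for a route from
a bare identifier to a BLAST report:

```r
library(ToolWeaver)
reg <- buildUsecaseRegistry()
reg
#> ServiceRegistry
#>   datatypes: 5, categories: 2, namespaces: 1
#>   tools: 2, operations: 2, locations: 2
#>   loaders: 2, formatters: 4, workers: 0, tasks: 0

findPath(reg, "Object", "BLAST-Text")
#> Pipeline Object -> BLAST-Text (2 stages)
#>   1. getAminoAcidSequence:getAminoAcidSequence  [Object -> AminoAcidSequence]
#>   2. runRPSBlast:runRPSBlast  [GenericSequence -> BLAST-Text]
```

The two services connect even though their parameter datatypes differ:
`AminoAcidSequence` IS-A `GenericSequence`, so the output of the first is
acceptable to the second. Converting a raw protein sequence into the
XML wire dialect applies the two standard loaders seamlessly — the base
loader injecting `id`/`namespace` and the length loader computing
`length = 8`:

```r
cat(convertData(reg, "MKTAYIAK", "moby-xml", "GenericSequence"))
#> <GenericSequence id="" namespace=""><Integer articleName="Length">8</Integer><String articleName="SequenceString">MKTAYIAK</String></GenericSequence>
```

With a worker registered for the `biomoby` protocol (a mock in the tests),
`enactPipeline(reg, pipe, input)` runs the chain end to end, re-checking
subtype compatibility at every stage and recording per-endpoint statistics.

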