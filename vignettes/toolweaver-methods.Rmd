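---
title: "ToolWeaver: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ToolWeaver: model, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ToolWeaver)
```

ToolWeaver gives client code one uniform model of heterogeneous web-service
metadata and the machinery to compose, adapt and invoke services through
it. This vignette is the package's own account of that model: what it
assumes, which knobs matter, what the synthetic fixtures do and do not
emulate, and where a genuinely open design question was settled one way.

## The metadata model and its layering

A *tool* is an abstract grouping of software components solving one type of
problem; it owns an ordered list of *operations*, each with ordered, typed
*parameters* (`input`, `output`, or `secondary` — fine-tune settings that
never participate in pipeline linking). Concrete deployments are *tool
locations* (mirrors), each tagged with a free protocol label. Functional
categories annotate tools hierarchically; namespaces label data provenance.

Every module presents a stable Interface over a swappable Access backend.
The backend contract is five verbs (`list`, `get`, `add`, `delete`,
`update`) plus a `nativeEdit` capability flag. Registry protocols that
cannot edit in place are modelled by `memoryBackend(nativeEdit = FALSE)`:
the module layer then emulates `updateResource()` as deregister + register
under the same id. For in-process backends the two steps are one
uninterrupted transaction, so the inconsistency window such protocols have
in the wild is not observable here; the contract notes that remote
implementations may not be atomic. Extra layers (the read cache) implement
the same five verbs around an inner backend; because reads are pure and
every write flushes the cache, a layered and an unlayered registry are
observationally identical — a property the test suite checks by comparing
canonical store snapshots after random call sequences.

Record identity is a deterministic per-kind counter (`tool-000001`, ...).
Opaque ids would serve equally; determinism makes fixture stores
byte-reproducible, which the round-trip and equivalence tests rely on.

Deletion distinguishes *ownership* from *dependency*. Operations belong to
their tool, parameters to their operation, locations (and their statistics)
to their tool: they are removed with the owner regardless of the `cascade`
flag. Cross-references — a parameter referencing a datatype or namespace, a
child datatype or category referencing its parent, a part referencing a
datatype — are dependencies: with `cascade = FALSE` the delete is rejected
while any exists, with `cascade = TRUE` the transitive closure is removed
and reported. Category annotations are the one soft edge: deleting a
category strips the annotation and keeps the tool.

## Subtypes and the taxonomy

The datatype taxonomy uses single inheritance (IS), plus HAS (arrays of
parts) and HASA (single contained part). `isSubtypeOf()` is the
reflexive–transitive closure of IS and is the only source of
substitutability: HAS/HASA never confer it, and multiple inheritance is
rejected outright (a second parent could only be expressed by reparenting,
which refuses cycles). Effective attributes and parts are materialized
ancestor-first; a child redeclaring an inherited attribute name is a
validation error rather than a shadowing rule, because silent shadowing
would make the XML dialect's attribute matching ambiguous.

One consequence of subtype acceptance deserves a note: an operation whose
input is declared as the taxonomy *root* accepts every datatype. In the
worked-example registry the retrieval service takes an `Object` identifier,
so it is — correctly — a consumer of everything, and every datatype pair is
connected through it. The tests embrace this rather than special-casing
root-typed inputs, since real registries use exactly this pattern for
identifier-driven services.

## Pipeline discovery

Nodes are datatypes; each (operation, input parameter, output parameter)
triple is a directed edge usable from the current type `c` when
`isSubtypeOf(c, input)`. `findPath()` finds the minimal number of
operations by breadth-first search over datatype states, bounded by
`maxDepth` (default 6 — deeper chains exist in principle but are rarely
wanted interactively, and the bound keeps worst-case cost predictable).
"Optimum" is hop count: the framework records no cost model, and any
scoring beyond length belongs to the client. Ties are broken by
enumerating the pipelines of minimal length and taking the
lexicographically smallest (tool name, operation name, parameter name)
sequence, so results are reproducible across sessions. Multi-input
operations do not block a chain: the chain feeds exactly one input and the
remaining mandatory inputs are reported as `unresolvedInputs`, to be
supplied at enactment — interactive clients prompt for them.

## Structured data, loaders, formatters

`StructuredData` is a value-semantics tree: primitive attributes
(`String`, `Integer`, `Float`, `Boolean`) plus named parts. Loaders are
transformers scoped to a datatype and applied — without the caller asking —
to that type and all IS-descendants, each exactly once, ordered by scope
depth (ancestor first), then priority (smaller first), then registration
order. Ancestor-first ordering is what makes the shipped pair compose: the
base loader injects the `id`/`namespace` attributes every data object must
carry (defaulting to empty strings — failing on absent identifiers would
make anonymous raw input unusable, so the empty default is deliberate and
documented), and the length loader then computes `length` from
`SequenceString`. Both are idempotent, a property the suite checks on
random sequences.

The XML wire dialect is this package's own documented simplification of
BioMOBY-style messaging (the standard's wire format is not reproduced
here): the element is named after the datatype, `id`/`namespace` travel as
XML attributes, every other attribute as a
`<Primitive articleName="Name">value</Primitive>` child in
effective-declaration order, parts as child elements named by their
datatype. Article names capitalize the first letter of the attribute name
(`length` → `Length`, matching the convention of the standard), and
parsing matches article names back case-insensitively. The dialect is
locked by golden-file tests and round-trip properties.

Canonical FASTA output is one header line and an unwrapped sequence; no
60-column wrapping, again locked by golden files. GenBank support is
read-only and lossy: the sequence and accession are extracted, everything
else is discarded, and conversions out of GenBank raise a `tw_lossy`
warning because the dropped fields cannot be recovered. Format detection
applies ordered rules — GenBank before FASTQ before XML before FASTA before
raw, so the more specific signature always wins — and classifies the
alphabet by the fraction of letters in `A/C/G/T/U/N`, nucleotide at ≥ 0.9.
The threshold and priority order are package choices; further formats
(PDB, BLAST reports, alignment outputs) are out of scope but new rules can
be prepended.

Data is loaded fully into memory. On-demand partial loading remains a
contract note on the loader interface, not an implementation: at the data
sizes this framework targets (service messages, not assemblies) the
simplicity is worth more than the memory ceiling.

## Execution

Workers run synchronously in-process. The three-step reference-passing
lifecycle of cloud deployments is modelled locally: task state still walks
`SUBMITTED → RUNNING → {SUCCEEDED, FAILED}` with an audited transition log,
and workers may declare `passByReference` to accept opaque references they
resolve themselves. A worker may declare a wire format; enactment then
serializes each stage's input into it and parses results back — which is
what triggers the formatter/loader machinery between incompatible stages.
Mirror selection is round-robin over the locations whose protocol has a
worker, with one retry on the next mirror after a failure (registry option
`retryOnFailure`, default on). Scheduling beyond round-robin is explicitly
out of scope. Statistics (invocations, successes, cumulative latency per
endpoint) persist in the registry store; tasks are session objects.

## The synthetic generator and what passing means

`generateSyntheticRegistry()` draws, deterministically per seed, a random
single-parent taxonomy (acyclic by construction, up to the configured
depth), random attribute sets, categories, and tools whose operations
consume and produce random datatypes; with `chainFraction > 0` it plants a
guaranteed type-connectable chain through fresh datatypes and records the
planted endpoints. Defaults (15 datatypes, depth 4, 6 tools × 2 operations,
1–2 parameters each) mirror the scale of a small service catalogue.

The generator emulates *structure* — inheritance shapes, fan-in/out,
connectivity — not content: names are synthetic, attribute sets carry no
biological meaning, and no generated endpoint speaks a real protocol.
Passing the property suites therefore shows the algebra and the algorithms
are correct on arbitrary well-formed metadata; it says nothing about
coverage of any live registry's quirks, which is exactly the part the
worker/access plug-in contracts leave to integrations.

The property suites run at fixed sizes chosen to exercise the space while
keeping the default test run quick: 200 random taxonomies (≤ 50 nodes) for
the subtype algebra against a matrix transitive-closure oracle, 100 random
registries (≤ 7 tools + planted chain) for path minimality against
exhaustive enumeration up to length 4, 1000 random sequences for format
round trips and loader laws, and 500 failure-injected task runs for the
lifecycle and statistics-conservation audits. `scripts/acceptance.R`
recomputes the same quantities at moderately reduced counts and reports
them as JSON.

## Known limitations

* No live protocol bindings ship with the package; everything beyond the
  worker contract is mock or local.
* Editing via the emulating backend is atomic only in-process.
* The registry store persists metadata, loader switches and statistics —
  not code (custom loaders, formatters, workers must be re-registered).
* GenBank parsing is deliberately partial (sequence + accession).
* User/permission handling and reasoner-backed taxonomies are out of
  scope; the layering leaves room for both as additional layers/modules.
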