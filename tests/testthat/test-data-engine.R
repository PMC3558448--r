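# Structured data, format recognition, loaders, formatters, conversion.

test_that("format recognition applies the rules in priority order", {
  expect_identical(detectFormat(">p1\nMKTAYIAK"),
                   list(format = "fasta", alphabet = "protein"))
  gb <- "LOCUS       X  8 bp\nORIGIN\n  1 acgtacgt\n//"
  expect_identical(detectFormat(gb),
                   list(format = "genbank", alphabet = "nucleotide"))
  expect_identical(detectFormat("ACGTACGTAC"),
                   list(format = "raw", alphabet = "nucleotide"))
  expect_identical(detectFormat("@r1\nACGT\n+\nIIII")$format, "fastq")
  expect_identical(detectFormat("<GenericSequence id=\"s\"/>")$format, "moby-xml")
  expect_identical(detectFormat("12345!!")$format, "unknown")
  expect_error(detectFormat(""), class = "tw_empty_input")
})

test_that("the 90% ACGTUN letter fraction separates the alphabets", {
  # 9 of 10 letters in the nucleotide alphabet
  expect_identical(detectFormat("ACGTACGTAF")$alphabet, "nucleotide")
  # 8 of 10 pushes below the threshold
  expect_identical(detectFormat("ACGTACGTFF")$alphabet, "protein")
})

test_that("FASTA parses to structured data without derived attributes", {
  reg <- buildUsecaseRegistry()
  d <- parseData(reg, ">s1 some description\nMKT", "fasta", "GenericSequence")
  expect_identical(d@attributes$id, "s1")
  expect_identical(d@attributes$SequenceString, "MKT")
  expect_null(d@attributes$length)          # absent until loaders run
  expect_identical(d@provenance, "fasta")
  expect_error(parseData(reg, "no header", "fasta", "GenericSequence"),
               class = "tw_parse_error")
})

test_that("GenBank parses sequence and accession and is read-only", {
  reg <- buildUsecaseRegistry()
  gb <- paste("LOCUS       TEST8  8 bp  DNA",
              "DEFINITION  synthetic fixture record.",
              "ACCESSION   AB000001",
              "ORIGIN",
              "        1 acgtacgt",
              "//", sep = "\n")
  d <- parseData(reg, gb, "genbank", "GenericSequence")
  expect_identical(d@attributes$id, "AB000001")
  expect_identical(d@attributes$SequenceString, "ACGTACGT")
  expect_error(serializeData(reg, d, "genbank"), class = "tw_no_formatter")
  # converting out of GenBank warns that the discarded fields are gone
  expect_warning(convertData(reg, gb, "fasta", "GenericSequence"),
                 class = "tw_lossy")
})

test_that("malformed XML raises a parse error", {
  reg <- buildUsecaseRegistry()
  expect_error(parseData(reg, "<GenericSequence", "moby-xml", "GenericSequence"),
               class = "tw_parse_error")
  expect_error(parseData(reg, "<Unknown/>", "moby-xml", "GenericSequence"),
               class = "tw_parse_error")
})

test_that("the XML dialect serializes to the locked golden form", {
  reg <- buildUsecaseRegistry()
  d <- newData(reg, "GenericSequence",
               attributes = list(id = "s1", namespace = "",
                                 SequenceString = "MKT", length = 3L))
  golden <- paste0('<GenericSequence id="s1" namespace="">',
                   '<Integer articleName="Length">3</Integer>',
                   '<String articleName="SequenceString">MKT</String>',
                   '</GenericSequence>')
  expect_identical(serializeData(reg, d, "moby-xml"), golden)
  # round trip inverts the dialect
  back <- parseData(reg, golden, "moby-xml", "GenericSequence")
  expect_identical(back@attributes[order(names(back@attributes))],
                   d@attributes[order(names(d@attributes))])
  # FASTA canonical output: one header line, unwrapped sequence
  expect_identical(serializeData(reg, d, "fasta"), ">s1\nMKT\n")
  expect_error(serializeData(reg, newData(reg, "BLAST-Text"), "fasta"),
               class = "tw_no_formatter")
})

test_that("loaders apply by inheritance scope, ancestor-first", {
  reg <- buildUsecaseRegistry()
  d <- parseData(reg, "MKT", "raw", "GenericSequence")
  out <- applyLoaders(reg, d)
  expect_identical(out$applied, c("moby-base", "sequence-length"))
  expect_identical(out$data@attributes$id, "")
  expect_identical(out$data@attributes$namespace, "")
  expect_identical(out$data@attributes$length, 3L)

  # child datatypes inherit the loader set
  d2 <- parseData(reg, "MKT", "raw", "AminoAcidSequence")
  expect_identical(applyLoaders(reg, d2)$applied,
                   c("moby-base", "sequence-length"))

  # the root-scoped loader reaches every descendant, but does nothing when
  # the datatype declares no id/namespace attributes
  blast <- newData(reg, "BLAST-Text")
  out3 <- applyLoaders(reg, blast)
  expect_identical(out3$applied, "moby-base")
  expect_identical(out3$data@attributes, blast@attributes)
  # data outside every loader scope is untouched entirely
  addDatatype(reg, "Standalone")
  out4 <- applyLoaders(reg, newData(reg, "Standalone"))
  expect_identical(out4$applied, character(0))
})

test_that("loader registration, disabling and failure wrapping", {
  reg <- buildUsecaseRegistry()
  registerLoader(reg, "uppercase", "GenericSequence", function(registry, data) {
    data@attributes$SequenceString <- toupper(data@attributes$SequenceString)
    data
  }, priority = 50)
  expect_error(registerLoader(reg, "uppercase", "Object", identity),
               class = "tw_duplicate_name")
  d <- parseData(reg, "mkt", "raw", "GenericSequence")
  out <- applyLoaders(reg, d)
  expect_length(out$applied, 3L)
  expect_identical(out$data@attributes$SequenceString, "MKT")

  setLoaderEnabled(reg, "sequence-length", FALSE)
  out2 <- applyLoaders(reg, d)
  expect_false("sequence-length" %in% out2$applied)
  setLoaderEnabled(reg, "sequence-length", TRUE)

  registerLoader(reg, "broken", "Object", function(registry, data) stop("boom"))
  err <- tryCatch(applyLoaders(reg, d), tw_loader_failure = function(e) e)
  expect_s3_class(err, "tw_loader_failure")
  expect_match(conditionMessage(err), "broken")
})

test_that("part navigation validates paths and primitive types", {
  reg <- buildUsecaseRegistry()
  d <- newData(reg, "GenericSequence",
               attributes = list(id = "s1", SequenceString = "MKT"))
  expect_identical(getPart(reg, d, "SequenceString"), "MKT")
  expect_null(getPart(reg, d, "length"))
  expect_error(setPart(reg, d, "length", "abc"), class = "tw_type_mismatch")
  d2 <- setPart(reg, d, "length", 3L)
  expect_identical(getPart(reg, d2, "length"), 3L)
  expect_identical(getPart(reg, d, "length"), NULL)  # value semantics
  expect_error(getPart(reg, d, "noSuchAttr"), class = "tw_bad_path")
  expect_error(newData(reg, "GenericSequence", attributes = list(bogus = 1)),
               class = "tw_bad_path")
})

test_that("HAS/HASA parts nest, serialize and navigate", {
  reg <- newRegistry()
  addDatatype(reg, "Object", attributes = c(id = "String", namespace = "String"))
  addDatatype(reg, "Annotation", parent = "Object",
              attributes = c(note = "String"))
  addDatatype(reg, "AnnotatedSeq", parent = "Object",
              attributes = c(SequenceString = "String"),
              hasParts = c(annotations = "Annotation"))
  registerFormatter(reg, new("FormatterSpec", format = "moby-xml",
    scopeDatatype = "Object", parse = ToolWeaver:::.mobyParse,
    serialize = ToolWeaver:::.mobySerialize, lossy = FALSE))
  a1 <- newData(reg, "Annotation", attributes = list(note = "first"))
  a2 <- newData(reg, "Annotation", attributes = list(note = "second"))
  d <- newData(reg, "AnnotatedSeq",
               attributes = list(id = "x", SequenceString = "MKT"),
               parts = list(annotations = list(a1, a2)))
  xml <- serializeData(reg, d, "moby-xml")
  back <- parseData(reg, xml, "moby-xml", "AnnotatedSeq")
  expect_length(back@parts$annotations, 2L)
  expect_identical(getPart(reg, back, "annotations/2/note"), "second")
  # cardinality: a HASA part must be single
  addDatatype(reg, "Wrapper", parent = "Object",
              hasaParts = c(payload = "Annotation"))
  expect_error(newData(reg, "Wrapper", parts = list(payload = list(a1, a2))),
               class = "tw_type_mismatch")
})

test_that("conversion runs detect-parse-load-serialize and tags failures", {
  reg <- buildUsecaseRegistry()
  xml <- convertData(reg, "MKTAYIAK", "moby-xml", "GenericSequence")
  expect_match(xml, '<Integer articleName="Length">8</Integer>', fixed = TRUE)
  # fasta -> fasta round trip preserves id and sequence
  out <- convertData(reg, ">s1 desc\nMK\nTAYIAK", "fasta", "GenericSequence")
  expect_identical(out, ">s1\nMKTAYIAK\n")
  err <- tryCatch(convertData(reg, "<broken", "fasta", "GenericSequence"),
                  tw_error = function(e) e)
  expect_match(conditionMessage(err), "\\[parse stage\\]")
  err2 <- tryCatch(convertData(reg, "ACGT", "pdf", "GenericSequence"),
                   tw_error = function(e) e)
  expect_s3_class(err2, "tw_no_formatter")
})

test_that("round trips are the identity for non-lossy formats", {
  reg <- buildUsecaseRegistry()
  set.seed(41)
  for (i in 1:25) {
    seq <- randomSequence()
    id <- paste0("id", i)
    d <- newData(reg, "GenericSequence",
                 attributes = list(id = id, SequenceString = seq))
    d <- applyLoaders(reg, d)$data
    for (fmt in c("fasta", "moby-xml")) {
      back <- parseData(reg, serializeData(reg, d, fmt), fmt, "GenericSequence")
      if (fmt == "moby-xml") {
        expect_identical(back@attributes[order(names(back@attributes))],
                         d@attributes[order(names(d@attributes))])
      } else {
        expect_identical(back@attributes$id, id)
        expect_identical(back@attributes$SequenceString, seq)
      }
    }
    # loaders are idempotent: a second application changes nothing
    once <- applyLoaders(reg, d)
    twice <- applyLoaders(reg, once$data)
    expect_identical(once$data@attributes, twice$data@attributes)
    expect_identical(once$applied, twice$applied)
  }
})

test_that("loader scoping matches an independent ancestry closure", {
  set.seed(43)
  for (rep in 1:3) {
    reg <- generateSyntheticRegistry(fixtureSpec(seed = 1300 + rep,
                                                 nDatatypes = 15, nTools = 0,
                                                 chainFraction = 0))
    nodes <- listResources(reg, "datatype")
    scopes <- sample(nodes, min(4, length(nodes)))
    for (i in seq_along(scopes))
      registerLoader(reg, paste0("probe", i), scopes[i],
                     function(registry, data) data)
    M <- oracleClosure(reg)
    for (dt in nodes) {
      applied <- applyLoaders(reg, newData(reg, dt))$applied
      hits <- which(M[dt, scopes] > 0)
      wanted <- if (length(hits)) paste0("probe", hits) else character(0)
      expect_setequal(applied, wanted)
    }
  }
})
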