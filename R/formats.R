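## Format recognition heuristics and the shipped formatters
## (FASTA, raw sequence text, GenBank flat file, BioMOBY-style XML).

## ---- detection ------------------------------------------------------------

.sequenceAlphabet <- function(seq) {
  letters <- gsub("[^A-Za-z]", "", seq)
  if (!nchar(letters)) return("n/a")
  chars <- strsplit(toupper(letters), "")[[1]]
  frac <- mean(chars %in% c("A", "C", "G", "T", "U", "N"))
  if (frac >= 0.9) "nucleotide" else "protein"
}

.stripWs <- function(x) gsub("[[:space:]]", "", x)

#' Default format-recognition rules
#'
#' Ordered rule set (first match wins): GenBank flat file, FASTQ
#' (detection only), BioMOBY-style XML, FASTA, raw sequence text.  Each rule
#' is a pure predicate plus a sequence extractor used for alphabet
#' classification.  Clients can prepend their own rules for further formats.
#'
#' @return ordered list of rules (lists with `format`, `test`, `extract`).
#' @export
defaultFormatRules <- function() {
  list(
    list(format = "genbank",
         test = function(x) grepl("^[[:space:]]*LOCUS[[:space:]]", x),
         extract = function(x) {
           m <- regmatches(x, regexpr("ORIGIN.*?(//|$)", x))
           if (length(m)) gsub("[^A-Za-z]", "", sub("^ORIGIN", "", m)) else ""
         }),
    list(format = "fastq",
         test = function(x) {
           lines <- strsplit(x, "\n", fixed = TRUE)[[1]]
           length(lines) >= 4 && startsWith(lines[1], "@") && startsWith(lines[3], "+")
         },
         extract = function(x) strsplit(x, "\n", fixed = TRUE)[[1]][2]),
    list(format = "moby-xml",
         test = function(x) startsWith(trimws(x), "<"),
         extract = function(x) ""),
    list(format = "fasta",
         test = function(x) startsWith(trimws(x), ">"),
         extract = function(x) {
           lines <- strsplit(x, "\n", fixed = TRUE)[[1]]
           paste(lines[!startsWith(lines, ">")], collapse = "")
         }),
    list(format = "raw",
         test = function(x) {
           s <- .stripWs(x)
           nchar(s) > 0 && grepl("^[A-Za-z*.-]+$", s)
         },
         extract = function(x) .stripWs(x))
  )
}

#' Recognize the format (and alphabet) of user data
#'
#' Applies the ordered heuristic rules; the first matching rule wins.  The
#' alphabet is classified from the extracted sequence letters: at least 90%
#' of letters in `A/C/G/T/U/N` means nucleotide, otherwise protein; formats
#' without extractable sequence report `"n/a"`.
#'
#' @param content character scalar (file content).
#' @param rules ordered rule list, by default [defaultFormatRules()].
#' @return list with `format` (`"unknown"` when no rule matches) and
#'   `alphabet` (`"nucleotide"`, `"protein"` or `"n/a"`).
#' @examples
#' detectFormat(">p1\nMKTAYIAK")
#' @export
detectFormat <- function(content, rules = defaultFormatRules()) {
  if (!is.character(content) || length(content) != 1L || !nchar(content))
    twStop("tw_empty_input", "cannot detect the format of empty input")
  for (r in rules) {
    if (isTRUE(r$test(content))) {
      seq <- tryCatch(r$extract(content), error = function(e) "")
      return(list(format = r$format, alphabet = .sequenceAlphabet(seq)))
    }
  }
  list(format = "unknown", alphabet = "n/a")
}

## ---- formatter registry ---------------------------------------------------

#' Register a formatter
#'
#' The formatter covers its scope datatype and every IS-descendant; see
#' [FormatterSpec-class].  Format ids are unique.
#'
#' @inheritParams newTool
#' @param spec a [FormatterSpec-class].
#' @return the format id, invisibly.
#' @export
registerFormatter <- function(registry, spec) {
  stopifnot(is(spec, "FormatterSpec"))
  .mustResolve(registry, "datatype", spec@scopeDatatype)
  st <- regState(registry)
  if (spec@format %in% vapply(st$formatters, slot, character(1), "format"))
    twStop("tw_duplicate_name", "formatter '%s' already registered", spec@format)
  st$formatters[[length(st$formatters) + 1L]] <- spec
  invisible(spec@format)
}

.findFormatter <- function(registry, format, datatype, need) {
  for (spec in regState(registry)$formatters) {
    if (spec@format != format) next
    if (!isSubtypeOf(registry, datatype, spec@scopeDatatype)) next
    if (is.null(slot(spec, need))) next
    return(spec)
  }
  twStop("tw_no_formatter", "no formatter can %s '%s' as datatype '%s'",
         need, format, datatype)
}

#' Parse user data into structured data
#'
#' Transforms content in a concrete format into the common structured
#' representation for `targetDatatype`.  Loaders are *not* applied here;
#' see [applyLoaders()] and [convertData()].
#'
#' @inheritParams newTool
#' @param content character scalar with the raw content.
#' @param format format id (see [detectFormat()]).
#' @param targetDatatype datatype to instantiate.
#' @return a [StructuredData-class] with `provenance` set to the format.
#' @export
parseData <- function(registry, content, format, targetDatatype) {
  spec <- .findFormatter(registry, format, targetDatatype, "parse")
  data <- withCallingHandlers(
    tryCatch(spec@parse(registry, content, targetDatatype),
             error = function(e) {
               if (inherits(e, "tw_error")) stop(e)
               twStop("tw_parse_error", "failed to parse %s content: %s",
                      format, conditionMessage(e))
             }),
    warning = function(w) w)
  data@provenance <- format
  data
}

#' Serialize structured data to a concrete format
#'
#' @inheritParams parseData
#' @param data a [StructuredData-class].
#' @return character scalar with the serialized bytes (deterministic).
#' @export
serializeData <- function(registry, data, format) {
  spec <- .findFormatter(registry, format, data@datatype, "serialize")
  spec@serialize(registry, data)
}

## ---- built-in formatters --------------------------------------------------

.needsSeqAttrs <- function(registry, targetDatatype) {
  eff <- getDatatype(registry, targetDatatype)@effectiveAttributes
  if (!"SequenceString" %in% names(eff))
    twStop("tw_parse_error",
           "datatype '%s' carries no SequenceString attribute", targetDatatype)
  eff
}

.fastaParse <- function(registry, content, targetDatatype) {
  eff <- .needsSeqAttrs(registry, targetDatatype)
  lines <- strsplit(content, "\n", fixed = TRUE)[[1]]
  hdr <- which(startsWith(lines, ">"))
  if (!length(hdr)) twStop("tw_parse_error", "no FASTA header line ('>') found")
  first <- hdr[1]
  end <- if (length(hdr) > 1) hdr[2] - 1L else length(lines)
  id <- strsplit(sub("^>", "", lines[first]), "[[:space:]]+")[[1]][1]
  if (is.na(id)) id <- ""
  seq <- .stripWs(paste(lines[seq.int(first + 1L, length.out = max(0L, end - first))],
                        collapse = ""))
  attrs <- list(SequenceString = seq)
  if ("id" %in% names(eff)) attrs$id <- id
  newData(registry, targetDatatype, attributes = attrs)
}

.fastaSerialize <- function(registry, data) {
  seq <- data@attributes[["SequenceString"]]
  if (is.null(seq))
    twStop("tw_missing_attribute", "FASTA output requires the SequenceString attribute")
  id <- data@attributes[["id"]] %||% ""
  ## canonical form: one header line, sequence unwrapped
  sprintf(">%s\n%s\n", id, seq)
}

.rawParse <- function(registry, content, targetDatatype) {
  .needsSeqAttrs(registry, targetDatatype)
  seq <- .stripWs(content)
  if (!nchar(seq)) twStop("tw_parse_error", "no sequence characters in raw input")
  if (!grepl("^[A-Za-z*.-]+$", seq))
    twStop("tw_parse_error", "raw input contains non-sequence characters")
  newData(registry, targetDatatype, attributes = list(SequenceString = seq))
}

.rawSerialize <- function(registry, data) {
  seq <- data@attributes[["SequenceString"]]
  if (is.null(seq))
    twStop("tw_missing_attribute", "raw output requires the SequenceString attribute")
  paste0(seq, "\n")
}

.genbankParse <- function(registry, content, targetDatatype) {
  eff <- .needsSeqAttrs(registry, targetDatatype)
  lines <- strsplit(content, "\n", fixed = TRUE)[[1]]
  locus <- grep("^[[:space:]]*LOCUS[[:space:]]", lines, value = TRUE)
  if (!length(locus)) twStop("tw_parse_error", "no LOCUS line; not a GenBank record")
  id <- strsplit(trimws(sub("^[[:space:]]*LOCUS", "", locus[1])), "[[:space:]]+")[[1]][1]
  acc <- grep("^ACCESSION[[:space:]]", lines, value = TRUE)
  if (length(acc)) {
    accId <- strsplit(trimws(sub("^ACCESSION", "", acc[1])), "[[:space:]]+")[[1]][1]
    if (!is.na(accId) && nzchar(accId)) id <- accId
  }
  o <- grep("^ORIGIN", lines)
  if (!length(o)) twStop("tw_parse_error", "no ORIGIN block in GenBank record")
  term <- grep("^//", lines)
  end <- if (length(term)) term[1] - 1L else length(lines)
  seq <- toupper(gsub("[^A-Za-z]", "", paste(lines[seq.int(o[1] + 1L,
                                                           length.out = max(0L, end - o[1]))],
                                             collapse = "")))
  if (!nchar(seq)) twStop("tw_parse_error", "empty ORIGIN block")
  attrs <- list(SequenceString = seq)
  if ("id" %in% names(eff)) attrs$id <- if (is.na(id)) "" else id
  ## everything else in the record (DEFINITION, FEATURES...) is discarded:
  ## the conversion is irreversible, hence the lossy flag on the spec
  newData(registry, targetDatatype, attributes = attrs)
}

## BioMOBY-style XML dialect (documented simplification, locked by golden
## tests): element named after the datatype, id/namespace as XML attributes,
## remaining attributes as <Primitive articleName="Name">value</Primitive>
## children in effective-declaration order (articleName is the attribute
## name with its first letter uppercased, matching BioMOBY article names),
## parts as child elements named after their datatype with an articleName.

.upFirst <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

.mobyValue <- function(value, primitive) {
  switch(primitive,
    Integer = sprintf("%d", as.integer(value)),
    Float = format(value, scientific = FALSE, trim = TRUE),
    Boolean = if (isTRUE(value)) "true" else "false",
    .xmlEscape(value))
}

.mobySerialize <- function(registry, data) {
  node <- getDatatype(registry, data@datatype)
  eff <- node@effectiveAttributes
  xmlAttrs <- ""
  if ("id" %in% names(eff))
    xmlAttrs <- sprintf(' id="%s"', .xmlEscape(data@attributes[["id"]] %||% ""))
  if ("namespace" %in% names(eff))
    xmlAttrs <- paste0(xmlAttrs, sprintf(' namespace="%s"',
                                         .xmlEscape(data@attributes[["namespace"]] %||% "")))
  children <- character()
  for (a in setdiff(names(eff), c("id", "namespace"))) {
    v <- data@attributes[[a]]
    if (is.null(v)) next
    children <- c(children, sprintf('<%s articleName="%s">%s</%s>',
                                    eff[[a]], .upFirst(a), .mobyValue(v, eff[[a]]), eff[[a]]))
  }
  for (p in c(names(node@effectiveHasaParts), names(node@effectiveHasParts))) {
    v <- data@parts[[p]]
    if (is.null(v)) next
    items <- if (is(v, "StructuredData")) list(v) else v
    for (item in items) {
      inner <- .mobySerialize(registry, item)
      children <- c(children, sub("^<([A-Za-z0-9_.-]+)",
                                  sprintf('<\\1 articleName="%s"', .upFirst(p)),
                                  inner))
    }
  }
  sprintf("<%s%s>%s</%s>", data@datatype, xmlAttrs,
          paste(children, collapse = ""), data@datatype)
}

.mobyParseNode <- function(registry, xnode, datatype) {
  node <- getDatatype(registry, datatype)
  eff <- node@effectiveAttributes
  attrs <- list()
  for (key in c("id", "namespace")) {
    v <- xml2::xml_attr(xnode, key)
    if (!is.na(v) && key %in% names(eff)) attrs[[key]] <- v
  }
  parts <- list()
  declaredParts <- c(node@effectiveHasaParts, node@effectiveHasParts)
  for (child in xml2::xml_children(xnode)) {
    tag <- xml2::xml_name(child)
    article <- xml2::xml_attr(child, "articleName")
    if (tag %in% .PRIMITIVES) {
      if (is.na(article)) twStop("tw_parse_error", "primitive element without articleName")
      hit <- names(eff)[tolower(names(eff)) == tolower(article)]
      if (!length(hit))
        twStop("tw_parse_error", "datatype '%s' declares no attribute matching '%s'",
               datatype, article)
      txt <- xml2::xml_text(child)
      attrs[[hit[1]]] <- switch(tag,
        Integer = as.integer(txt), Float = as.numeric(txt),
        Boolean = identical(txt, "true"), txt)
    } else {
      if (is.na(article)) twStop("tw_parse_error", "part element without articleName")
      hit <- names(declaredParts)[tolower(names(declaredParts)) == tolower(article)]
      if (!length(hit))
        twStop("tw_parse_error", "datatype '%s' declares no part matching '%s'",
               datatype, article)
      pname <- hit[1]
      sub <- .mobyParseNode(registry, child, tag)
      if (pname %in% names(node@effectiveHasaParts)) {
        parts[[pname]] <- sub
      } else {
        parts[[pname]] <- c(parts[[pname]] %||% list(), list(sub))
      }
    }
  }
  newData(registry, datatype, attributes = attrs, parts = parts)
}

.mobyParse <- function(registry, content, targetDatatype) {
  doc <- tryCatch(xml2::read_xml(content),
                  error = function(e) twStop("tw_parse_error",
                                             "malformed XML: %s", conditionMessage(e)))
  root <- xml2::xml_name(doc)
  if (is.null(.getOrNull(registry, "datatype", root)))
    twStop("tw_parse_error", "root element '%s' is not a known datatype", root)
  if (!is.null(targetDatatype) && !isSubtypeOf(registry, root, targetDatatype))
    twStop("tw_type_mismatch", "document is a '%s', not a subtype of '%s'",
           root, targetDatatype)
  .mobyParseNode(registry, doc, root)
}

#' Register the shipped sequence formatters, loaders and detection rules
#'
#' Installs the built-in FASTA (read/write), raw sequence text (read/write),
#' GenBank flat file (read-only, lossy) and BioMOBY-style XML (read/write)
#' formatters, plus the two standard loaders: `moby-base` (scoped to the
#' taxonomy root; injects the `id`/`namespace` attributes every data object
#' must carry, defaulting to empty strings) and `sequence-length` (scoped to
#' the generic sequence type; computes the `length` attribute from
#' `SequenceString`).  The registry taxonomy must already contain the scope
#' datatypes (`Object` and `GenericSequence` by default).
#'
#' @inheritParams newTool
#' @param root name of the taxonomy root datatype.
#' @param sequenceType name of the generic sequence datatype.
#' @return the registry, invisibly.
#' @export
registerDefaultDataHandlers <- function(registry, root = "Object",
                                        sequenceType = "GenericSequence") {
  registerFormatter(registry, new("FormatterSpec", format = "fasta",
    scopeDatatype = sequenceType, parse = .fastaParse,
    serialize = .fastaSerialize, lossy = FALSE))
  registerFormatter(registry, new("FormatterSpec", format = "raw",
    scopeDatatype = sequenceType, parse = .rawParse,
    serialize = .rawSerialize, lossy = FALSE))
  registerFormatter(registry, new("FormatterSpec", format = "genbank",
    scopeDatatype = sequenceType, parse = .genbankParse,
    serialize = NULL, lossy = TRUE))
  registerFormatter(registry, new("FormatterSpec", format = "moby-xml",
    scopeDatatype = root, parse = .mobyParse,
    serialize = .mobySerialize, lossy = FALSE))
  registerLoader(registry, "moby-base", root, .mobyBaseLoader, priority = 10)
  registerLoader(registry, "sequence-length", sequenceType,
                 .sequenceLengthLoader, priority = 10)
  invisible(registry)
}

## ---- conversion -----------------------------------------------------------

#' Convert user data between formats
#'
#' Runs the full chain detect -> parse -> apply loaders -> serialize.  Any
#' stage error is annotated with the failing stage.  Parsing a lossy source
#' format (GenBank) raises a `tw_lossy` warning: the discarded fields cannot
#' be recovered by converting back.
#'
#' @inheritParams newTool
#' @param content character scalar with the raw content.
#' @param targetFormat format to produce.
#' @param targetDatatype datatype to go through.
#' @param sourceFormat source format id; auto-detected when `NULL`.
#' @return character scalar with the converted content.
#' @examples
#' reg <- buildUsecaseRegistry()
#' convertData(reg, "MKTAYIAK", "moby-xml", "GenericSequence")
#' @export
convertData <- function(registry, content, targetFormat, targetDatatype,
                        sourceFormat = NULL) {
  stage <- function(name, expr) {
    withCallingHandlers(expr, condition = function(c) {
      if (inherits(c, "tw_error")) {
        c$message <- sprintf("[%s stage] %s", name, c$message)
        stop(c)
      }
    })
  }
  if (is.null(sourceFormat)) {
    det <- stage("detect", detectFormat(content))
    sourceFormat <- det$format
    if (sourceFormat == "unknown")
      twStop("tw_parse_error", "[detect stage] unrecognized input format")
  }
  srcSpec <- tryCatch(.findFormatter(registry, sourceFormat, targetDatatype, "parse"),
                      tw_error = function(e) { e$message <- paste("[parse stage]", e$message); stop(e) })
  if (srcSpec@lossy && !identical(sourceFormat, targetFormat))
    twWarn("tw_lossy", "parsing %s discards information; the conversion cannot be reversed",
           sourceFormat)
  data <- stage("parse", parseData(registry, content, sourceFormat, targetDatatype))
  loaded <- stage("load", applyLoaders(registry, data))
  stage("serialize", serializeData(registry, loaded$data, targetFormat))
}
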