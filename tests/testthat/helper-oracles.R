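# Independent oracles used to cross-check the implementation.  These go
# through the exported record surface only and reimplement the logic from
# first principles (matrix transitive closure, exhaustive sequence
# enumeration) so they share no code path with what they verify.

# reflexive-transitive closure of the IS relation by boolean matrix powers
oracleClosure <- function(registry) {
  nodes <- listResources(registry, "datatype")
  k <- length(nodes)
  M <- diag(1, k)
  rownames(M) <- colnames(M) <- nodes
  for (n in nodes) {
    p <- getResource(registry, "datatype", n)@isParent
    if (length(p)) M[n, p] <- 1
  }
  repeat {
    M2 <- ((M %*% M) > 0) * 1
    if (all(M2 == M)) break
    M <- M2
  }
  M
}

# every (operation, input parameter, output parameter) pair as an edge
oracleEdges <- function(registry) {
  out <- list()
  for (o in listResources(registry, "operation")) {
    desc <- generateInterface(registry, o)
    ins <- Filter(function(d) d$kind == "input", desc)
    outs <- Filter(function(d) d$kind == "output", desc)
    for (i in ins) for (j in outs)
      out[[length(out) + 1L]] <- list(op = o, inType = i$datatype,
                                      outType = j$datatype)
  }
  out
}

# minimal number of operations connecting source to target, by exhaustive
# depth-first enumeration of operation sequences up to maxLen; NA when none
oracleMinPathLength <- function(registry, source, target, maxLen = 4L) {
  M <- oracleClosure(registry)
  sub <- function(c, a) M[c, a] > 0
  if (sub(source, target)) return(0L)
  edges <- oracleEdges(registry)
  best <- NA_integer_
  rec <- function(cur, len) {
    if (!is.na(best) && len >= best) return(invisible(NULL))
    for (e in edges) {
      if (!sub(cur, e$inType)) next
      if (sub(e$outType, target) && (is.na(best) || len + 1L < best))
        best <<- len + 1L
      if (len + 1L < maxLen) rec(e$outType, len + 1L)
    }
  }
  rec(source, 0L)
  best
}

# validate a pipeline purely against the oracle closure
oracleCheckPipeline <- function(registry, pipeline) {
  M <- oracleClosure(registry)
  sub <- function(c, a) M[c, a] > 0
  st <- pipeline@stages
  if (!length(st)) return(sub(pipeline@source, pipeline@target))
  ok <- sub(pipeline@source, st[[1]]$inputDatatype) &&
    sub(st[[length(st)]]$outputDatatype, pipeline@target)
  if (length(st) > 1)
    for (k in seq_len(length(st) - 1))
      ok <- ok && sub(st[[k]]$outputDatatype, st[[k + 1]]$inputDatatype)
  ok
}

randomSequence <- function(alphabet = c(LETTERS), len = sample(1:80, 1)) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# a registry with one tool, one operation and two local mirrors, for
# execution-lifecycle tests
twoMirrorRegistry <- function() {
  reg <- newRegistry()
  addDatatype(reg, "Object")
  t <- newTool(reg, "echoTool")
  op <- addOperation(reg, t@id, "echo")
  addParameter(reg, op@id, "x", "input", "Object")
  addParameter(reg, op@id, "y", "output", "Object")
  locA <- newToolLocation(reg, t@id, "local", "local://a")
  locB <- newToolLocation(reg, t@id, "local", "local://b")
  list(reg = reg, tool = t, op = op, locA = locA, locB = locB)
}
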