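# Tool/ToolLocation module: registration, filtering, editing, cascade.

test_that("tool registration builds the worked-example metadata", {
  reg <- buildUsecaseRegistry()
  tools <- getToolList(reg)
  expect_length(tools, 2L)
  expect_setequal(vapply(tools, recordName, character(1)),
                  c("getAminoAcidSequence", "runRPSBlast"))
  rps <- getToolList(reg, list(nameFilter("RPS")))
  expect_length(rps, 1L)
  desc <- generateInterface(reg, getOperations(reg, rps[[1]]@id)[[1]]@id)
  expect_equal(vapply(desc, `[[`, character(1), "name"),
               c("sequence", "blast_report"))
  expect_equal(desc[[1]]$datatype, "GenericSequence")
  expect_equal(desc[[2]]$kind, "output")
})

test_that("registration preconditions are enforced", {
  reg <- buildUsecaseRegistry()
  expect_error(newTool(reg, ""), class = "tw_empty_name")
  expect_error(newTool(reg, "x", categories = "NoSuchCategory"),
               class = "tw_unresolved_reference")
  expect_error(addOperation(reg, "tool-999999", "op"),
               class = "tw_unresolved_reference")
  op <- getOperations(reg, getToolList(reg)[[1]]@id)[[1]]
  expect_error(addParameter(reg, op@id, "p", "inout", "Object"),
               class = "tw_bad_kind")
  expect_error(addParameter(reg, op@id, "p", "input", "NoSuchType"),
               class = "tw_unresolved_reference")
  expect_error(newToolLocation(reg, "tool-999999", "soap", "http://x"),
               class = "tw_unresolved_reference")
  # names need not be unique by default; ids are the identity
  t <- newTool(reg, "dup")
  o1 <- addOperation(reg, t@id, "same")
  o2 <- addOperation(reg, t@id, "same")
  expect_false(identical(o1@id, o2@id))
  regU <- newRegistry(options = list(uniqueToolNames = TRUE))
  newTool(regU, "once")
  expect_error(newTool(regU, "once"), class = "tw_duplicate_name")
})

test_that("tool count equals the number of successful registrations", {
  reg <- newRegistry()
  set.seed(1)
  n <- 100L
  for (i in seq_len(n)) newTool(reg, sprintf("tool-%03d-%d", i, sample(1e6, 1)))
  expect_length(getToolList(reg), n)
  # id-sorted deterministic order
  ids <- vapply(getToolList(reg), recordId, character(1))
  expect_identical(ids, sort(ids))
})

test_that("filters compose by conjunction and commute", {
  set.seed(7)
  for (rep in 1:5) {
    reg <- newRegistry()
    addCategory(reg, "C1"); addCategory(reg, "C2")
    for (i in 1:30)
      newTool(reg, paste0(sample(c("alpha", "beta", "gamma"), 1), i),
              categories = sample(c("C1", "C2"), 1))
    fA <- nameFilter("a")   # matches alpha/gamma/beta? ('a' in all three) vary:
    fA <- nameFilter("alpha")
    fB <- categoryFilter("C1")
    idsOf <- function(tools) sort(vapply(tools, recordId, character(1)))
    ab <- idsOf(getToolList(reg, list(fA, fB)))
    ba <- idsOf(getToolList(reg, list(fB, fA)))
    inter <- intersect(idsOf(getToolList(reg, list(fA))),
                       idsOf(getToolList(reg, list(fB))))
    expect_identical(ab, ba)
    expect_identical(ab, sort(inter))
  }
})

test_that("mirrors accumulate and biomoby tools get a virtual operation", {
  reg <- newRegistry()
  addDatatype(reg, "Object")
  t <- newTool(reg, "mirrored")
  newToolLocation(reg, t@id, "soap", "http://a")
  newToolLocation(reg, t@id, "soap", "http://b")
  expect_length(getLocations(reg, t@id), 2L)

  tb <- newTool(reg, "mobyService")
  newToolLocation(reg, tb@id, "biomoby", "http://host/moby")
  ops <- getOperations(reg, tb@id)
  expect_length(ops, 1L)
  expect_true(ops[[1]]@virtual)
  expect_identical(ops[[1]]@name, "mobyService")
})

test_that("get_resource reads its own writes and reports missing ids", {
  reg <- buildUsecaseRegistry()
  id <- getToolList(reg)[[1]]@id
  expect_s4_class(getResource(reg, "tool", id), "ToolRecord")
  expect_error(getResource(reg, "tool", "tool-424242"), class = "tw_not_found")
  updateResource(reg, "tool", id, list(description = "new text"))
  expect_identical(getResource(reg, "tool", id)@description, "new text")
})

test_that("update keeps ids immutable and empty changes write nothing", {
  counting <- countingBackend(memoryBackend())
  reg <- newRegistry(backend = counting)
  t <- newTool(reg, "t1")
  expect_error(updateResource(reg, "tool", t@id, list(id = "other")),
               class = "tw_immutable_field")
  before <- backendCounts(counting)
  out <- updateResource(reg, "tool", t@id, list())
  after <- backendCounts(counting)
  expect_identical(out@name, "t1")
  expect_identical(before[c("add", "update", "delete")],
                   after[c("add", "update", "delete")])
  expect_error(updateResource(reg, "tool", "tool-999999", list(name = "x")),
               class = "tw_not_found")
})

test_that("editing on a no-native-edit backend is emulated transparently", {
  f <- tempfile(fileext = ".json")
  saveRegistry(buildUsecaseRegistry(), f)
  native <- loadRegistry(f, backend = memoryBackend(nativeEdit = TRUE))
  emulated <- loadRegistry(f, backend = memoryBackend(nativeEdit = FALSE))
  id <- getToolList(native)[[1]]@id
  changes <- list(name = "renamedTool", description = "edited")
  updateResource(native, "tool", id, changes)
  updateResource(emulated, "tool", id, changes)
  expect_identical(getResource(emulated, "tool", id)@name, "renamedTool")
  # same id, references intact, byte-identical stores on both routes
  expect_identical(registrySnapshot(native), registrySnapshot(emulated))
  expect_length(validateRegistry(emulated), 0L)
})

test_that("cascade delete removes the dependency closure, reject leaves all", {
  reg <- buildUsecaseRegistry()
  # a descendant of GenericSequence is referenced by runRPSBlast's input
  expect_error(deleteResource(reg, "datatype", "GenericSequence", cascade = FALSE),
               class = "tw_dependency_exists")
  expect_true("GenericSequence" %in% listResources(reg, "datatype"))

  rep <- deleteResource(reg, "datatype", "GenericSequence", cascade = TRUE)
  # exactly the descendant nodes and the dependent parameters are removed
  expect_true(all(c("GenericSequence", "AminoAcidSequence") %in% rep$removed))
  expect_true(any(grepl("^parameter-", rep$removed)))
  expect_false(any(grepl("^tool-", rep$removed)))
  expect_length(getToolList(reg), 2L)           # tools survive
  expect_length(validateRegistry(reg), 0L)      # dangling-free

  # independent closure oracle: removed set == full-scan dependency closure
  reg2 <- buildUsecaseRegistry()
  doomed <- c("GenericSequence")
  repeat {
    grew <- FALSE
    for (n in listResources(reg2, "datatype")) {
      node <- getResource(reg2, "datatype", n)
      if (length(node@isParent) && node@isParent %in% doomed && !(n %in% doomed)) {
        doomed <- c(doomed, n); grew <- TRUE
      }
    }
    if (!grew) break
  }
  doomedParams <- character()
  for (o in listResources(reg2, "operation"))
    for (p in getResource(reg2, "operation", o)@parameters)
      if (p@datatypeRef %in% doomed) doomedParams <- c(doomedParams, p@id)
  expect_setequal(rep$removed, c(doomed, doomedParams))
})

test_that("deleting an unreferenced record reports just that id", {
  reg <- buildUsecaseRegistry()
  addNamespace(reg, "orphan")
  rep <- deleteResource(reg, "namespace", "orphan", cascade = FALSE)
  expect_identical(rep$removed, "orphan")
  expect_error(deleteResource(reg, "namespace", "orphan"), class = "tw_not_found")
})

test_that("deleting a category strips annotations but keeps the tools", {
  reg <- buildUsecaseRegistry()
  rep <- deleteResource(reg, "category", "Alignment", cascade = TRUE)
  expect_identical(rep$removed, "Alignment")
  expect_length(getToolList(reg), 2L)
  rps <- getToolList(reg, list(nameFilter("RPS")))[[1]]
  expect_false("Alignment" %in% rps@categoryRefs)
  expect_length(validateRegistry(reg), 0L)
})

test_that("a cache layer changes call counts, never results", {
  counting <- countingBackend(memoryBackend())
  reg <- newRegistry(backend = counting)
  t <- newTool(reg, "cachedTool")
  attachLayer(reg, "cache")
  g1 <- getResource(reg, "tool", t@id)
  n1 <- backendCounts(counting)[["get"]]
  g2 <- getResource(reg, "tool", t@id)
  n2 <- backendCounts(counting)[["get"]]
  expect_identical(n2, n1)            # second read served from the cache
  expect_identical(g1@name, g2@name)
  # a write invalidates: the next read sees the new value
  updateResource(reg, "tool", t@id, list(name = "renamed"))
  expect_identical(getResource(reg, "tool", t@id)@name, "renamed")
  expect_error(attachLayer(reg, "bogus"), class = "tw_unknown_layer")
})

test_that("cached and uncached registries agree on random call sequences", {
  set.seed(11)
  for (rep in 1:3) {
    plain <- newRegistry()
    cached <- newRegistry(layers = "cache")
    for (reg in list(plain, cached)) {
      set.seed(100 + rep)
      addDatatype(reg, "Object")
      for (i in 1:10) {
        t <- newTool(reg, sprintf("t%02d", i))
        if (i %% 2 == 0) updateResource(reg, "tool", t@id,
                                        list(description = sprintf("d%d", i)))
        if (i %% 3 == 0) deleteResource(reg, "tool", t@id, cascade = TRUE)
      }
    }
    expect_identical(registrySnapshot(plain), registrySnapshot(cached))
    ids <- listResources(plain, "tool")
    for (id in ids)
      expect_identical(getResource(plain, "tool", id)@name,
                       getResource(cached, "tool", id)@name)
  }
})

test_that("referential integrity survives random edit sequences", {
  set.seed(23)
  for (rep in 1:3) {
    reg <- generateSyntheticRegistry(fixtureSpec(seed = 500 + rep, nTools = 4))
    dts <- listResources(reg, "datatype")
    for (k in 1:6) {
      victim <- sample(dts, 1)
      res <- tryCatch(deleteResource(reg, "datatype", victim,
                                     cascade = sample(c(TRUE, FALSE), 1)),
                      tw_error = function(e) NULL)
      dts <- listResources(reg, "datatype")
      expect_length(validateRegistry(reg), 0L)
    }
  }
})
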