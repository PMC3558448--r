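# Workers, the task lifecycle, enactment, statistics, mirror selection.

test_that("worker registration routes by protocol and rejects duplicates", {
  fix <- twoMirrorRegistry()
  reg <- fix$reg
  expect_error(addTask(reg, fix$locA@id, fix$op@id,
                       list(x = newData(reg, "Object"))),
               class = "tw_no_worker")
  registerWorker(reg, echoWorker("local"))
  expect_error(registerWorker(reg, echoWorker("local")),
               class = "tw_duplicate_protocol")
  task <- addTask(reg, fix$locA@id, fix$op@id, list(x = newData(reg, "Object")))
  expect_identical(taskStatus(task), "SUCCEEDED")
})

test_that("the echo worker returns its inputs and failures are wrapped", {
  fix <- twoMirrorRegistry()
  reg <- fix$reg
  registerWorker(reg, echoWorker("local"))
  d <- newData(reg, "Object")
  task <- addTask(reg, fix$locA@id, fix$op@id, list(x = d))
  expect_identical(task@results$x@datatype, "Object")
  expect_identical(task@results$y@datatype, "Object")

  registerWorker(reg, newWorker("flaky", function(l, o, i) stop("worker broke")))
  locC <- newToolLocation(reg, fix$tool@id, "flaky", "flaky://c")
  failed <- addTask(reg, locC@id, fix$op@id, list(x = d))
  expect_identical(taskStatus(failed), "FAILED")
  expect_match(failed@error$message, "worker broke")
  stat <- getStatistics(reg, locC@id)[[1]]
  expect_identical(c(stat@count, stat@success), c(1, 0))
})

test_that("input checking: presence and subtype acceptance", {
  reg <- buildUsecaseRegistry()
  registerWorker(reg, echoWorker("biomoby"))
  rps <- getToolList(reg, list(nameFilter("RPS")))[[1]]
  op <- getOperations(reg, rps@id)[[1]]
  loc <- getLocations(reg, rps@id)[[1]]
  expect_error(addTask(reg, loc@id, op@id, list()), class = "tw_missing_input")
  # an AminoAcidSequence is accepted for the GenericSequence parameter
  aa <- newData(reg, "AminoAcidSequence",
                attributes = list(id = "P1", SequenceString = "MKT"))
  expect_identical(taskStatus(addTask(reg, loc@id, op@id, list(sequence = aa))),
                   "SUCCEEDED")
  # but a non-subtype is rejected
  blast <- newData(reg, "BLAST-Text")
  expect_error(addTask(reg, loc@id, op@id, list(sequence = blast)),
               class = "tw_type_mismatch")
})

test_that("task querying follows the submit/poll/retrieve contract", {
  fix <- twoMirrorRegistry()
  reg <- fix$reg
  registerWorker(reg, echoWorker("local"))
  ok <- addTask(reg, fix$locA@id, fix$op@id, list(x = newData(reg, "Object")))
  expect_identical(getStatus(reg, ok@id), "SUCCEEDED")
  expect_named(getResults(reg, ok@id))
  expect_identical(getTask(reg, ok@id)@log,
                   c("SUBMITTED", "RUNNING", "SUCCEEDED"))

  registerWorker(reg, newWorker("bad", function(l, o, i) stop("nope")))
  locC <- newToolLocation(reg, fix$tool@id, "bad", "bad://c")
  failed <- addTask(reg, locC@id, fix$op@id, list(x = newData(reg, "Object")))
  err <- tryCatch(getResults(reg, failed@id), tw_not_finished = function(e) e)
  expect_s3_class(err, "tw_not_finished")
  expect_match(err$data$error$message, "nope")
  expect_error(getStatus(reg, "task-999999"), class = "tw_not_found")
})

test_that("mirror selection round-robins and retries once on failure", {
  fix <- twoMirrorRegistry()
  reg <- fix$reg
  registerWorker(reg, echoWorker("local"))
  picks <- vapply(1:4, function(i) selectLocation(reg, fix$tool@id)@id,
                  character(1))
  expect_identical(picks, rep(c(fix$locA@id, fix$locB@id), 2))

  # single-location tool always yields that location
  t2 <- newTool(reg, "single")
  op2 <- addOperation(reg, t2@id, "only")
  addParameter(reg, op2@id, "x", "input", "Object")
  loc <- newToolLocation(reg, t2@id, "local", "local://only")
  expect_identical(selectLocation(reg, t2@id)@id, loc@id)
  t3 <- newTool(reg, "nowhere")
  expect_error(selectLocation(reg, t3@id), class = "tw_no_location")

  # failure injection: first mirror broken, retry succeeds on the second
  reg2 <- newRegistry()
  addDatatype(reg2, "Object")
  t <- newTool(reg2, "flakyTool")
  op <- addOperation(reg2, t@id, "go")
  addParameter(reg2, op@id, "x", "input", "Object")
  addParameter(reg2, op@id, "y", "output", "Object")
  badLoc <- newToolLocation(reg2, t@id, "deadmirror", "dead://a")
  okLoc <- newToolLocation(reg2, t@id, "livemirror", "live://b")
  registerWorker(reg2, newWorker("deadmirror", function(l, o, i) stop("down")))
  registerWorker(reg2, echoWorker("livemirror"))
  task <- invokeTool(reg2, t@id, op@id, list(x = newData(reg2, "Object")))
  expect_identical(taskStatus(task), "SUCCEEDED")
  expect_identical(task@locationRef, okLoc@id)
  # both attempts were recorded in the statistics
  stats <- getStatistics(reg2)
  tally <- vapply(stats, function(s) s@count, numeric(1))
  expect_identical(sum(tally), 2)
})

test_that("pipeline enactment adapts data between stages", {
  reg <- buildUsecaseRegistry()
  aaXml <- serializeData(reg, applyLoaders(reg, newData(reg, "AminoAcidSequence",
    attributes = list(id = "P12345", SequenceString = "MKTAYIAK")))$data,
    "moby-xml")
  opIds <- listResources(reg, "operation")
  stageOutputs <- list()
  worker <- newWorker("biomoby", function(location, operation, inputs) {
    if (operation@name == "getAminoAcidSequence") list(sequence = aaXml)
    else list(blast_report = "<BLAST-Text id=\"\" namespace=\"\"></BLAST-Text>")
  }, wireFormat = "moby-xml")
  registerWorker(reg, worker)
  pipe <- findPath(reg, "Object", "BLAST-Text")
  res <- enactPipeline(reg, pipe, newData(reg, "Object"))
  expect_length(res$taskIds, 2L)
  expect_s4_class(res$data, "StructuredData")
  expect_identical(res$data@datatype, "BLAST-Text")
  # stage outputs flowed through: each delivered input was subtype-compatible
  expect_true(all(vapply(res$taskIds, function(id)
    getStatus(reg, id) == "SUCCEEDED", logical(1))))
})

test_that("enactment aborts at the first failed stage", {
  reg <- buildUsecaseRegistry()
  calls <- new.env(); calls$n <- 0L
  registerWorker(reg, newWorker("biomoby", function(location, operation, inputs) {
    calls$n <- calls$n + 1L
    stop("stage one down")
  }))
  # retry is on by default; with one mirror per tool there is no second try
  pipe <- findPath(reg, "Object", "BLAST-Text")
  err <- tryCatch(enactPipeline(reg, pipe, newData(reg, "Object")),
                  tw_stage_failed = function(e) e)
  expect_s3_class(err, "tw_stage_failed")
  expect_identical(err$data$stage, 1L)
  expect_identical(calls$n, 1L)   # stage 2 never invoked

  # empty pipeline returns the input unchanged
  same <- enactPipeline(reg, findPath(reg, "Object", "Object"),
                        newData(reg, "Object"))
  expect_identical(same$data@datatype, "Object")
  expect_length(same$taskIds, 0L)
})

test_that("enactment demands cover for unresolved inputs", {
  reg <- buildUsecaseRegistry()
  rps <- getToolList(reg, list(nameFilter("RPS")))[[1]]
  op <- getOperations(reg, rps@id)[[1]]
  addParameter(reg, op@id, "database", "input", "BLAST-Text")
  aa <- newData(reg, "AminoAcidSequence",
                attributes = list(id = "P1", SequenceString = "MKT"))
  bt <- newData(reg, "BLAST-Text")
  registerWorker(reg, newWorker("biomoby", function(l, o, i)
    if (o@name == "getAminoAcidSequence") list(sequence = aa)
    else list(blast_report = bt)))
  pipe <- findPath(reg, "Object", "BLAST-Text")
  expect_error(enactPipeline(reg, pipe, newData(reg, "Object")),
               class = "tw_missing_input")
  res <- enactPipeline(reg, pipe, newData(reg, "Object"),
                       extraInputs = list(database = newData(reg, "BLAST-Text")))
  expect_length(res$taskIds, 2L)
})

test_that("statistics count invocations, successes and zero records", {
  fix <- twoMirrorRegistry()
  reg <- fix$reg
  registerWorker(reg, echoWorker("local"))
  flip <- new.env(); flip$i <- 0L
  registerWorker(reg, newWorker("maybe", function(l, o, i) {
    flip$i <- flip$i + 1L
    if (flip$i == 2L) stop("intermittent") else list(y = i$x)
  }))
  locC <- newToolLocation(reg, fix$tool@id, "maybe", "maybe://c")
  d <- newData(reg, "Object")
  for (i in 1:3) addTask(reg, locC@id, fix$op@id, list(x = d))
  s <- getStatistics(reg, locC@id)[[1]]
  expect_identical(c(s@count, s@success), c(3, 2))
  # never-invoked location reports a zero record
  z <- getStatistics(reg, fix$locA@id)[[1]]
  expect_identical(c(z@count, z@success), c(0, 0))
  expect_error(getStatistics(reg, "location-999999"), class = "tw_not_found")
})

test_that("statistics persist in the registry store", {
  fix <- twoMirrorRegistry()
  reg <- fix$reg
  registerWorker(reg, echoWorker("local"))
  addTask(reg, fix$locA@id, fix$op@id, list(x = newData(reg, "Object")))
  f <- tempfile(fileext = ".json")
  saveRegistry(reg, f)
  reg2 <- loadRegistry(f)
  s <- getStatistics(reg2, fix$locA@id)[[1]]
  expect_identical(s@count, 1)
})
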