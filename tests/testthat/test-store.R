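# Content addressing, ingestion, metadata, provenance, integrity.

test_that("unit ids are canonical, order-invariant and content-sensitive", {
  a <- list(one = "first file", two = "second file")
  expect_identical(compute_unit_id(a), compute_unit_id(rev(a)))

  flipped <- list(one = "First file", two = "second file")
  expect_false(compute_unit_id(a) == compute_unit_id(flipped))
  renamed <- list(one2 = "first file", two = "second file")
  expect_false(compute_unit_id(a) == compute_unit_id(renamed))

  # frozen values of the documented recipe (computed independently)
  expect_identical(
    compute_unit_id(list(a = raw(0))),
    "84a0bc84a8906a8501a34e9aedb06be93452d06bc32b71d61f0b334cd5559d9b")
  expect_identical(
    compute_unit_id(list(b = "hello", a = "world")),
    "1b89003fd7ce65cfdaa1f1a53ab3c2dea301cf100115746bfa2c6f2081781ba4")

  expect_error(compute_unit_id(list()), class = "depot_validation")
  expect_error(compute_unit_id(list(x = "1", x = "2")),
               class = "depot_validation")
})

test_that("unit ids match an independent implementation of the recipe", {
  skip_if_not_installed("openssl")
  set.seed(11)
  for (i in 1:25) {
    n <- sample(1:5, 1)
    members <- stats::setNames(
      lapply(seq_len(n), function(j)
        as.raw(sample(0:255, sample(0:40, 1), replace = TRUE))),
      make.unique(replicate(n, paste(
        sample(c(letters, "_", "-", "."), sample(1:10, 1), replace = TRUE),
        collapse = ""))))
    expect_identical(compute_unit_id(sample(members)),
                     oracle_unit_id(members))
  }
})

test_that("ingest stores a multi-file unit flat and deduplicates", {
  project <- new_project()
  stack <- write_files(tempfile(), list("s_001.tif" = "a", "s_002.tif" = "b",
                                        "s_003.tif" = "c"))
  unit <- ingest_unit(project, stack)
  expect_identical(unit$state, "floating")
  expect_equal(nrow(unit$members), 3)
  store <- file.path(project$root, "store")
  expect_identical(list.dirs(store, recursive = FALSE, full.names = FALSE),
                   unit$unit_id)
  expect_setequal(list.files(file.path(store, unit$unit_id)),
                  c("s_001.tif", "s_002.tif", "s_003.tif"))

  # same content again (from a different location): no-op, same id
  copy <- write_files(tempfile(), list("s_001.tif" = "a", "s_002.tif" = "b",
                                       "s_003.tif" = "c"))
  again <- ingest_unit(project, copy)
  expect_identical(again$unit_id, unit$unit_id)
  expect_length(list.dirs(store, recursive = FALSE), 1)

  expect_error(ingest_unit(project, file.path(tempfile(), "nope.txt")),
               class = "depot_io")
})

test_that("ingesting a fixture twice conserves store size and unit count", {
  project <- new_project()
  sets <- lapply(1:6, function(i)
    write_files(tempfile(), stats::setNames(list(paste0("content", i)),
                                            paste0("f", i, ".dat"))))
  for (s in sets) ingest_unit(project, s)
  store <- file.path(project$root, "store")
  n1 <- length(list.dirs(store, recursive = FALSE))
  size1 <- sum(file.size(list.files(store, recursive = TRUE, full.names = TRUE)))
  for (s in sets) ingest_unit(project, s)
  expect_identical(length(list.dirs(store, recursive = FALSE)), n1)
  expect_identical(sum(file.size(list.files(store, recursive = TRUE,
                                            full.names = TRUE))), size1)
})

test_that("metadata assignment flips state, validates keys, journals changes", {
  project <- new_project()
  uid <- quick_unit(project, attrs = NULL)

  expect_error(assign_metadata(project, uid, list()),
               class = "depot_validation")
  expect_error(assign_metadata(project, "deadbeef", list(A = "1")),
               class = "depot_not_found")
  err <- tryCatch(assign_metadata(project, uid, list("!!" = "x", OK = "y")),
                  depot_validation = function(e) conditionMessage(e))
  expect_match(err, "!!", fixed = TRUE)

  unit <- assign_metadata(project, uid, list(HONEYBEE = "HB123"))
  expect_identical(unit$state, "assigned")
  expect_identical(unname(unit$attributes[["HONEYBEE"]]), "HB123")

  # keys are normalized; re-assignment replaces and journals old -> new
  assign_metadata(project, uid, list("labor state" = "nurse"))
  assign_metadata(project, uid, list(LABOR_STATE = "forager"))
  unit <- assign_metadata(project, uid, list(AGE = "15"))
  expect_identical(unname(unit$attributes[["LABOR_STATE"]]), "forager")
  events <- datadepot:::read_journal(project)
  replaced <- Filter(function(e) {
    identical(e$action, "assign") &&
      !is.null(e$payload$changes$LABOR_STATE$old)
  }, events)
  expect_length(replaced, 1)
  expect_identical(replaced[[1]]$payload$changes$LABOR_STATE$old, "nurse")
  expect_identical(replaced[[1]]$payload$changes$LABOR_STATE$new, "forager")
})

test_that("query matches a naive scan over the attribute records", {
  set.seed(21)
  g <- random_graph(n_units = 10)
  # empty filter: all assigned units
  expect_identical(query_units(g$project), oracle_query(g$project, NULL))
  for (i in 1:12) {
    nk <- sample(1:2, 1)
    ks <- sample(g$keys, nk)
    filt <- stats::setNames(
      vapply(ks, function(k) sample(g$pools[[k]], 1), character(1)), ks)
    expect_identical(query_units(g$project, filt),
                     oracle_query(g$project, filt))
  }
  # unknown key matches nothing; contradictory duplicate key is empty
  expect_length(query_units(g$project, c(NO_SUCH_KEY = "x")), 0)
  expect_length(query_units(g$project, c(KIND = "swc", KIND = "stack")), 0)
})

test_that("provenance edges stay acyclic and materialize process params", {
  project <- new_project()
  stack <- quick_unit(project, list(FORMAT = "TIFF_STACK"), content = "stackbytes")
  swc <- quick_unit(project, list(FORMAT = "SWC"), content = "1 1 0 0 0 1 -1")
  reg <- quick_unit(project, list(FORMAT = "SWC", STAGE = "registered"),
                    content = "registered")

  record_provenance(project, stack, "SIGEN",
                    list(PARAMETERS = "D20V05C01S01"), swc)
  attrs <- datadepot:::unit_attributes(datadepot:::depot_state(project), swc)
  expect_identical(unname(attrs[["SIGEN_PARAMETERS"]]), "D20V05C01S01")

  expect_error(record_provenance(project, swc, "copy", list(), swc),
               class = "depot_cycle")
  expect_error(record_provenance(project, "feedbead", "x", list(), swc),
               class = "depot_not_found")

  record_provenance(project, swc, "REGISTER", list(BRAIN = "HSB"), reg)
  expect_identical(unit_ancestors(project, reg),
                   sort(c(swc, stack), method = "radix"))
  # closing the loop back to the stack must be refused
  expect_error(record_provenance(project, reg, "loop", list(), stack),
               class = "depot_cycle")
})

test_that("accepted provenance always forms a DAG (igraph cross-check)", {
  skip_if_not_installed("igraph")
  set.seed(31)
  project <- new_project()
  ids <- vapply(1:8, function(i)
    quick_unit(project, list(K = "v"), content = paste0("c", i)), character(1))
  edges <- character(0)
  for (i in 1:25) {
    from <- sample(ids, sample(1:2, 1))
    to <- sample(setdiff(ids, from), 1)
    ok <- tryCatch({
      record_provenance(project, from, "P", list(N = as.character(i)), to)
      TRUE
    }, depot_cycle = function(e) FALSE)
    if (ok) edges <- c(edges, as.vector(rbind(from, to)))
  }
  g <- igraph::make_graph(edges, directed = TRUE)
  expect_true(igraph::is_dag(g))
})

test_that("verify reports corruption, dangling metadata, and orphans", {
  project <- new_project()
  u1 <- quick_unit(project, list(A = "1"), content = "alpha")
  u2 <- quick_unit(project, list(A = "2"), content = "beta")
  u3 <- quick_unit(project, list(A = "3"), content = "gamma")
  expect_identical(nrow(verify_store(project)), 0L)

  # flip one byte in one stored file
  victim <- unit_files(project, u1)[[1]]
  Sys.chmod(victim, "0644")
  bytes <- readBin(victim, "raw", file.size(victim))
  bytes[1] <- xor(bytes[1], as.raw(1))
  writeBin(bytes, victim)
  rep <- verify_store(project)
  expect_identical(rep$kind, "corrupted")
  expect_identical(rep$unit_id, u1)

  # delete a stored directory but keep the metadata
  unlink(file.path(project$root, "store", u2), recursive = TRUE)
  rep <- verify_store(project)
  expect_setequal(rep$kind, c("corrupted", "dangling_unit"))
  expect_identical(rep$unit_id[rep$kind == "dangling_unit"], u2)

  # a directory nobody references
  dir.create(file.path(project$root, "store", strrep("ab", 32)))
  rep <- verify_store(project)
  expect_true("orphan_dir" %in% rep$kind)
  expect_true(u3 %in% datadepot:::depot_state(project)$units$unit_id)
})
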