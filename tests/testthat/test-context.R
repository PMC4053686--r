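# Context rules, paths, uniqueness, abstract trees, YAML rule configs.

morphology_rule <- function(...) {
  context_rule("morphology", filter = c(FORMAT = "SWC"),
               grouping = c("LABOR_STATE", "REGION", "HONEYBEE_ID",
                            "SIGEN_PARAMETERS"),
               leaf_template = "morphology.swc", ...)
}

test_that("context paths follow the grouping order and leaf template", {
  project <- new_project()
  uid <- quick_unit(project, list(
    FORMAT = "SWC", LABOR_STATE = "forager", REGION = "left_DL",
    HONEYBEE_ID = "HB130427", SIGEN_PARAMETERS = "D20V05C01S01"))

  cp <- context_path(project, uid, morphology_rule())
  expect_identical(format(cp),
                   "forager/left_DL/HB130427/D20V05C01S01/morphology.swc")

  # an image-stack view groups by bee then region, leaves = member names
  stack_files <- write_files(tempfile(), list("img_001.tiff" = "x",
                                              "img_002.tiff" = "y"))
  stack <- ingest_unit(project, stack_files)
  assign_metadata(project, stack$unit_id,
                  list(HONEYBEE_ID = "HB130427", REGION = "left-DL",
                       FORMAT = "TIFF_STACK"))
  beta <- context_rule("stacks", filter = c(FORMAT = "TIFF_STACK"),
                       grouping = c("HONEYBEE_ID", "REGION"))
  tree <- build_tree(project, beta)
  expect_identical(tree$entries$relative_path,
                   c("HB130427/left-DL/img_001.tiff",
                     "HB130427/left-DL/img_002.tiff"))
})

test_that("reordering grouping keys permutes the path identically", {
  project <- new_project()
  uid <- quick_unit(project, list(HONEYBEE = "HB123", NEURON = "NRN-1",
                                  STAGE = "segmentation"))
  r1 <- context_rule("one", grouping = c("HONEYBEE", "NEURON", "STAGE"),
                     leaf_template = "{MEMBER_NAME}")
  r2 <- context_rule("two", grouping = c("STAGE", "HONEYBEE", "NEURON"),
                     leaf_template = "{MEMBER_NAME}")
  expect_identical(context_path(project, uid, r1)$segments,
                   c("HB123", "NRN-1", "segmentation"))
  expect_identical(context_path(project, uid, r2)$segments,
                   c("segmentation", "HB123", "NRN-1"))

  # property: any permutation of grouping permutes segments the same way
  set.seed(5)
  base <- c("HONEYBEE", "NEURON", "STAGE")
  cp0 <- context_path(project, uid, r1)
  for (i in 1:6) {
    perm <- sample(3)
    r <- context_rule("p", grouping = base[perm])
    expect_identical(context_path(project, uid, r)$segments,
                     cp0$segments[perm])
  }
})

test_that("degenerate and non-matching units are handled per policy", {
  project <- new_project()
  uid <- quick_unit(project, list(FORMAT = "SWC", HONEYBEE_ID = "HB1"))

  # empty grouping: leaf at the projection root
  r0 <- context_rule("flat", filter = c(FORMAT = "SWC"),
                     leaf_template = "{HONEYBEE_ID}.swc")
  cp <- context_path(project, uid, r0)
  expect_length(cp$segments, 0)
  expect_identical(cp$leaf_name, "HB1.swc")

  # filter not matched -> not-applicable signal
  other <- context_rule("stacks", filter = c(FORMAT = "TIFF_STACK"))
  expect_error(context_path(project, uid, other),
               class = "depot_not_applicable")

  # missing grouping value: UNASSIGNED bucket + warning (default policy)
  rmiss <- context_rule("bylabor", filter = c(FORMAT = "SWC"),
                        grouping = "LABOR_STATE")
  expect_warning(cp <- context_path(project, uid, rmiss), "UNASSIGNED")
  expect_identical(cp$segments, "UNASSIGNED")

  expect_error(
    context_path(project, uid,
                 context_rule("strict", grouping = "LABOR_STATE",
                              on_missing = "fail")),
    class = "depot_missing_value")
  tree <- build_tree(project,
                     context_rule("lenient", filter = c(FORMAT = "SWC"),
                                  grouping = "LABOR_STATE",
                                  on_missing = "skip"))
  expect_identical(tree_leaves(tree), 0L)
})

test_that("uniqueness validation equals naive grouping of computed paths", {
  project <- new_project()
  mk_swc <- function(bee, content) quick_unit(project, list(
    FORMAT = "SWC", LABOR_STATE = "forager", REGION = "left_DL",
    HONEYBEE_ID = bee, SIGEN_PARAMETERS = "D20V05C01S01"), content = content)
  u1 <- mk_swc("HB001", "first")
  u2 <- mk_swc("HB002", "second")
  expect_length(validate_uniqueness(project, morphology_rule()), 0)

  # same bee/region/params twice: exactly one collision group of size 2
  u3 <- mk_swc("HB001", "rescan of the same neuron")
  groups <- validate_uniqueness(project, morphology_rule())
  expect_length(groups, 1)
  expect_setequal(groups[[1]]$unit_ids, c(u1, u3))

  # under policy=fail the tree build refuses and names the rule
  expect_error(build_tree(project, morphology_rule()),
               "morphology", class = "depot_collision")
  # under policy=suffix the colliding leaves get 8 hex of the unit id
  tree <- build_tree(project, morphology_rule(on_collision = "suffix"))
  expect_identical(tree_leaves(tree), 3L)
  expect_setequal(
    tree$entries$relative_path[tree$entries$unit_id %in% c(u1, u3)],
    paste0("forager/left_DL/HB001/D20V05C01S01/morphology.swc_",
           substr(c(u1, u3), 1, 8)))

  # degenerate rule: empty grouping + constant leaf -> one group of size n
  const <- context_rule("const", filter = c(FORMAT = "SWC"),
                        leaf_template = "data.swc")
  groups <- validate_uniqueness(project, const)
  expect_length(groups, 1)
  expect_setequal(groups[[1]]$unit_ids, c(u1, u2, u3))
})

test_that("uniqueness check matches brute force on random graphs and rules", {
  set.seed(77)
  for (i in 1:8) {
    g <- random_graph(n_units = 7)
    for (j in 1:3) {
      rule <- random_rule(g)
      entries <- oracle_rule_entries(g$project, rule)
      expected <- entries$path[duplicated(entries$path)]
      got <- validate_uniqueness(g$project, rule)
      expect_setequal(vapply(got, `[[`, character(1), "path"),
                      unique(expected))
    }
  }
})

test_that("leaf count equals the number of filtered units and tree depth is uniform", {
  project <- new_project()
  # balanced 2 labor states x 2 regions x 5 bees per cell, one SWC each
  i <- 0
  for (labor in c("forager", "nurse")) for (region in c("left_DL", "right_DL")) {
    for (b in 1:5) {
      i <- i + 1
      quick_unit(project, list(FORMAT = "SWC", LABOR_STATE = labor,
                               REGION = region,
                               HONEYBEE_ID = sprintf("HB%03d", i),
                               SIGEN_PARAMETERS = "D20V05C01S01"),
                 content = paste0("swc", i))
    }
  }
  tree <- build_tree(project, morphology_rule())
  expect_identical(tree_leaves(tree), 20L)
  expect_identical(nrow(tree$entries), 20L)
  depth <- lengths(strsplit(tree$entries$relative_path, "/", fixed = TRUE))
  expect_true(all(depth == 5))  # 4 grouping levels + leaf file
  expect_identical(tree_leaves(tree),
                   length(query_units(project, c(FORMAT = "SWC"))))

  # sibling order is bytewise sorted
  expect_identical(tree$entries$relative_path,
                   sort(tree$entries$relative_path, method = "radix"))

  # single unit -> single path; empty filter match -> empty tree
  solo <- new_project()
  quick_unit(solo, list(FORMAT = "SWC", LABOR_STATE = "forager",
                        REGION = "left_DL", HONEYBEE_ID = "HB1",
                        SIGEN_PARAMETERS = "P"))
  expect_identical(nrow(build_tree(solo, morphology_rule())$entries), 1L)
  none <- build_tree(solo, context_rule("none", filter = c(FORMAT = "NOPE")))
  expect_identical(tree_leaves(none), 0L)
  expect_identical(nrow(none$entries), 0L)
})

test_that("YAML rule configs parse, validate, and reject bad schemas", {
  yaml_text <- "
rules:
  - name: morphology
    filter: {FORMAT: SWC}
    grouping: [LABOR_STATE, REGION, HONEYBEE_ID, SIGEN_PARAMETERS]
    leaf_template: morphology.swc
  - name: stacks
    filter: {FORMAT: TIFF_STACK}
    grouping: [HONEYBEE_ID, REGION]
"
  rules <- load_rules(yaml_text)
  expect_named(rules, c("morphology", "stacks"))
  expect_identical(rules$morphology$grouping,
                   c("LABOR_STATE", "REGION", "HONEYBEE_ID",
                     "SIGEN_PARAMETERS"))
  expect_identical(rules$stacks$grouping, c("HONEYBEE_ID", "REGION"))
  expect_identical(rules$stacks$leaf_template, "{MEMBER_NAME}")

  err <- tryCatch(
    load_rules("rules:\n  - name: r\n    grouping: [A, A]\n"),
    depot_schema = function(e) conditionMessage(e))
  expect_match(err, "rules\\[1\\]")
  expect_match(err, "A")

  err <- tryCatch(
    load_rules("rules:\n  - name: r\n    grooping: [A]\n"),
    depot_schema = function(e) conditionMessage(e))
  expect_match(err, "grooping")

  expect_error(load_rules("rules:\n  - name: r\n  - name: r\n"),
               class = "depot_schema")
  expect_error(
    context_rule("x", filter = c(A = "1"), grouping = c("A", "B")),
    class = "depot_validation")
})
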