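# Context trees: rule-driven views of the metadata graph.
#
# A context rule selects a subset of units (a conjunction of key=value
# terms) and arranges them under an ordered list of grouping attributes; the
# grouping order becomes the directory hierarchy, so the same data can be
# browsed as HONEYBEE/NEURON/STAGE or STAGE/HONEYBEE/NEURON at will. Leaves
# are named by a template over the unit's attributes.

RULE_FIELDS <- c("name", "filter", "grouping", "leaf_template",
                 "on_missing", "on_collision")

#' Define a context-tree rule
#'
#' @param name Rule identifier (unique within a configuration).
#' @param filter Named character vector of `KEY = "value"` terms selecting
#'   the units this view covers; empty selects all assigned units.
#' @param grouping Ordered character vector of attribute keys; each becomes
#'   one directory level, in order.
#' @param leaf_template Template for the leaf name. Placeholders: `{KEY}`
#'   for any attribute, `{UNIT_ID8}` for the first 8 hex digits of the unit
#'   id, `{MEMBER_NAME}` for the member file name (expands multi-file units
#'   to one leaf per member, placed directly under the last grouping level).
#' @param on_missing Policy when a unit lacks a grouping attribute:
#'   `"unassigned"` (default; route into an `UNASSIGNED` bucket with a
#'   warning), `"skip"` (drop the unit from the view) or `"fail"`.
#' @param on_collision Policy when two units map to the same path: `"fail"`
#'   (default) or `"suffix"` (append `_` plus 8 hex digits of the unit id).
#' @return A `context_rule` object.
#' @examples
#' context_rule("morphology", filter = c(FORMAT = "SWC"),
#'              grouping = c("LABOR_STATE", "REGION", "HONEYBEE_ID"),
#'              leaf_template = "morphology.swc")
#' @export
context_rule <- function(name, filter = NULL, grouping = character(0),
                         leaf_template = "{MEMBER_NAME}",
                         on_missing = c("unassigned", "skip", "fail"),
                         on_collision = c("fail", "suffix")) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    stop_depot("depot_validation", "rule name must be a non-empty string")
  }
  f <- as_filter(filter)
  grouping <- normalize_key(as.character(grouping))
  if (anyDuplicated(grouping)) {
    stop_depot("depot_validation", paste0(
      "rule '", name, "': grouping key repeated: ",
      paste(unique(grouping[duplicated(grouping)]), collapse = ", ")))
  }
  fixed <- intersect(grouping, names(f))
  if (length(fixed)) {
    stop_depot("depot_validation", paste0(
      "rule '", name, "': key(s) ", paste(fixed, collapse = ", "),
      " appear both as a fixed filter value and in grouping"))
  }
  structure(list(name = name, filter = f, grouping = grouping,
                 leaf_template = leaf_template,
                 on_missing = match.arg(on_missing),
                 on_collision = match.arg(on_collision)),
            class = "context_rule")
}

#' @export
print.context_rule <- function(x, ...) {
  cat("<context rule> ", x$name, "\n", sep = "")
  if (length(x$filter)) {
    cat("  filter:   ", paste0(names(x$filter), "=", x$filter, collapse = " AND "),
        "\n", sep = "")
  }
  cat("  grouping: ", if (length(x$grouping)) paste(x$grouping, collapse = " / ")
      else "(none)", "\n", sep = "")
  cat("  leaf:     ", x$leaf_template, "\n", sep = "")
  invisible(x)
}

#' Load context rules from a YAML configuration
#'
#' Accepts either a bare YAML list of rules or a mapping with a top-level
#' `rules:` key (as in `.depot.yaml`). Unknown fields and duplicate rule
#' names are schema errors, reported with the path of the offending field.
#'
#' @param config A file path, a YAML string, or an already-parsed list.
#' @return List of [context_rule()] objects.
#' @export
load_rules <- function(config) {
  if (is.character(config) && length(config) == 1) {
    parsed <- if (file.exists(config)) yaml::read_yaml(config)
              else yaml::yaml.load(config)
  } else {
    parsed <- config
  }
  if (!is.null(parsed$rules)) parsed <- parsed$rules
  if (!is.list(parsed)) {
    stop_depot("depot_schema", "rule config must be a list of rules")
  }
  rules <- vector("list", length(parsed))
  for (i in seq_along(parsed)) {
    entry <- parsed[[i]]
    where <- paste0("rules[", i, "]")
    if (!is.list(entry)) stop_depot("depot_schema", paste0(where, ": not a mapping"))
    unknown <- setdiff(names(entry), RULE_FIELDS)
    if (length(unknown)) {
      stop_depot("depot_schema", paste0(
        where, ".", unknown[1], ": unknown field"))
    }
    if (is.null(entry$name)) {
      stop_depot("depot_schema", paste0(where, ".name: missing"))
    }
    rules[[i]] <- tryCatch(
      context_rule(name = entry$name, filter = entry$filter,
                   grouping = unlist(entry$grouping) %||% character(0),
                   leaf_template = entry$leaf_template %||% "{MEMBER_NAME}",
                   on_missing = entry$on_missing %||% "unassigned",
                   on_collision = entry$on_collision %||% "fail"),
      depot_validation = function(e) {
        stop_depot("depot_schema", paste0(where, ": ", conditionMessage(e)))
      })
  }
  nms <- vapply(rules, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop_depot("depot_schema", paste0(
      "duplicate rule name(s): ", paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  stats::setNames(rules, nms)
}

project_rules <- function(project) load_rules(project$config$rules)

render_template <- function(template, attrs, unit_id, member_name = NULL) {
  out <- template
  out <- gsub("{UNIT_ID8}", substr(unit_id, 1, 8), out, fixed = TRUE)
  if (!is.null(member_name)) {
    out <- gsub("{MEMBER_NAME}", member_name, out, fixed = TRUE)
  }
  for (k in names(attrs)) {
    out <- gsub(paste0("{", k, "}"), attrs[[k]], out, fixed = TRUE)
  }
  out
}

#' Compute the context path of a unit under a rule
#'
#' The context path is the ordered list of the unit's values for the rule's
#' grouping attributes, plus the rendered leaf name: the unit's address in
#' the corresponding directory view. Reordering the grouping keys permutes
#' the path segments identically.
#'
#' @param project A depot handle.
#' @param unit_id Unit identifier.
#' @param rule A [context_rule()].
#' @return A `context_path`: list with `segments` (sanitized path
#'   components), `leaf_name` (may still contain `{MEMBER_NAME}` for
#'   per-member expansion) and `unit_id`. Errors with class
#'   `depot_not_applicable` when the unit fails the rule's filter.
#' @export
context_path <- function(project, unit_id, rule) {
  st <- depot_state(project)
  context_path_state(st, unit_id, rule)
}

context_path_state <- function(st, unit_id, rule) {
  if (!unit_id %in% st$units$unit_id) {
    stop_depot("depot_not_found", paste0("unknown unit ", unit_id))
  }
  attrs <- unit_attributes(st, unit_id)
  f <- rule$filter
  matched <- all(names(f) %in% names(attrs)) &&
    all(attrs[names(f)] == unname(f))
  if (length(f) && !matched) {
    stop_depot("depot_not_applicable",
               paste0("unit ", substr(unit_id, 1, 8),
                      " does not match the filter of rule '", rule$name, "'"))
  }
  segments <- character(length(rule$grouping))
  for (i in seq_along(rule$grouping)) {
    key <- rule$grouping[i]
    if (key %in% names(attrs)) {
      segments[i] <- attrs[[key]]
    } else {
      switch(rule$on_missing,
        fail = stop_depot("depot_missing_value", paste0(
          "unit ", substr(unit_id, 1, 8), " has no value for grouping key ",
          key, " (rule '", rule$name, "')")),
        skip = stop_depot("depot_skip_unit", paste0(
          "unit ", substr(unit_id, 1, 8), " skipped: no value for ", key)),
        unassigned = {
          warning(sprintf("unit %s has no value for %s; routed to UNASSIGNED",
                          substr(unit_id, 1, 8), key), call. = FALSE)
          segments[i] <- "UNASSIGNED"
        })
    }
  }
  leaf <- render_template(rule$leaf_template, attrs, unit_id)
  structure(list(segments = sanitize_component(segments),
                 leaf_name = leaf, unit_id = unit_id),
            class = "context_path")
}

#' @export
print.context_path <- function(x, ...) {
  cat(paste(c(x$segments, x$leaf_name), collapse = "/"), "\n")
  invisible(x)
}

#' @export
format.context_path <- function(x, ...) {
  paste(c(x$segments, x$leaf_name), collapse = "/")
}

# Expand the filtered units of a rule into concrete leaf entries
# (relative_path, unit_id, member_name). Units hitting the `skip` policy are
# dropped; `fail` propagates. No collision handling here.
tree_entries <- function(st, rule) {
  ids <- query_units_state(st, rule$filter)
  rows <- list()
  kept <- character(0)
  for (uid in ids) {
    cp <- tryCatch(context_path_state(st, uid, rule),
                   depot_skip_unit = function(e) NULL)
    if (is.null(cp)) next
    kept <- c(kept, uid)
    mem <- unit_members(st, uid)
    dir <- paste(cp$segments, collapse = "/")
    if (grepl("{MEMBER_NAME}", rule$leaf_template, fixed = TRUE)) {
      # one leaf per member, directly under the grouping levels
      for (m in mem$name) {
        leaf <- sanitize_member(render_template(cp$leaf_name, character(0),
                                                uid, member_name = m))
        rows[[length(rows) + 1]] <- data.frame(
          relative_path = if (nzchar(dir)) paste(dir, leaf, sep = "/") else leaf,
          unit_id = uid, member_name = m, leaf_root = leaf,
          stringsAsFactors = FALSE)
      }
    } else if (nrow(mem) == 1) {
      leaf <- sanitize_member(cp$leaf_name)
      rows[[length(rows) + 1]] <- data.frame(
        relative_path = if (nzchar(dir)) paste(dir, leaf, sep = "/") else leaf,
        unit_id = uid, member_name = mem$name, leaf_root = leaf,
        stringsAsFactors = FALSE)
    } else {
      # multi-file unit: leaf is a directory holding the member links
      leaf <- sanitize_member(cp$leaf_name)
      for (m in mem$name) {
        rows[[length(rows) + 1]] <- data.frame(
          relative_path = paste(c(if (nzchar(dir)) dir, leaf, m), collapse = "/"),
          unit_id = uid, member_name = m, leaf_root = leaf,
          stringsAsFactors = FALSE)
      }
    }
  }
  entries <- if (length(rows)) do.call(rbind, rows) else data.frame(
    relative_path = character(0), unit_id = character(0),
    member_name = character(0), leaf_root = character(0),
    stringsAsFactors = FALSE)
  list(entries = entries, unit_ids = kept)
}

#' Check that a rule addresses every unit by a unique path
#'
#' A context tree is well formed only when the map unit -> path is
#' injective. This reports every group of units whose leaves would land on
#' the identical relative path.
#'
#' @param project A depot handle.
#' @param rule A [context_rule()].
#' @return A list of collision groups, each a list with `path` and
#'   `unit_ids` (two or more). Empty list when the rule is injective.
#' @export
validate_uniqueness <- function(project, rule) {
  st <- depot_state(project)
  validate_uniqueness_state(st, rule)
}

validate_uniqueness_state <- function(st, rule) {
  te <- suppressWarnings(tree_entries(st, rule))
  entries <- te$entries
  groups <- list()
  if (nrow(entries)) {
    split_by <- split(entries$unit_id, entries$relative_path)
    for (path in names(split_by)) {
      uids <- unique(split_by[[path]])
      if (length(split_by[[path]]) > 1) {
        groups[[length(groups) + 1]] <- list(path = path, unit_ids = uids)
      }
    }
  }
  groups
}

#' Build the abstract context tree of a rule
#'
#' Computes the full set of leaf entries (relative path, unit, member) for
#' the units selected by the rule's filter, bytewise-sorted, after applying
#' the rule's missing-value and collision policies.
#'
#' @param project A depot handle.
#' @param rule A [context_rule()] or the name of a configured rule.
#' @return A `context_tree`: list with `rule`, `entries` data frame
#'   (`relative_path`, `unit_id`, `member_name`), and `unit_ids` of the
#'   units represented. Leaf count equals the number of represented units.
#' @export
build_tree <- function(project, rule) {
  if (is.character(rule)) {
    rules <- project_rules(project)
    if (!rule %in% names(rules)) {
      stop_depot("depot_not_found", paste0("no configured rule named '", rule, "'"))
    }
    rule <- rules[[rule]]
  }
  st <- depot_state(project)
  build_tree_state(st, rule)
}

build_tree_state <- function(st, rule) {
  collisions <- validate_uniqueness_state(st, rule)
  te <- tree_entries(st, rule)
  entries <- te$entries
  if (length(collisions)) {
    if (rule$on_collision == "fail") {
      desc <- vapply(collisions, function(g) {
        paste0(g$path, " <- {", paste(substr(g$unit_ids, 1, 8), collapse = ", "), "}")
      }, character(1))
      stop_depot("depot_collision", paste0(
        "rule '", rule$name, "' maps several units to the same path:\n  ",
        paste(desc, collapse = "\n  ")))
    }
    # suffix policy: disambiguate colliding leaves with 8 hex of the unit id
    bad_paths <- vapply(collisions, `[[`, character(1), "path")
    hit <- entries$relative_path %in% bad_paths
    entries$relative_path[hit] <- paste0(
      entries$relative_path[hit], "_", substr(entries$unit_id[hit], 1, 8))
    entries$leaf_root[hit] <- paste0(
      entries$leaf_root[hit], "_", substr(entries$unit_id[hit], 1, 8))
  }
  entries <- entries[order(entries$relative_path, method = "radix"), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(rule = rule, entries = entries, unit_ids = te$unit_ids),
            class = "context_tree")
}

#' Number of data-unit leaves in a context tree
#' @param tree A `context_tree`.
#' @return Integer count of units represented in the tree.
#' @export
tree_leaves <- function(tree) length(tree$unit_ids)

#' @export
print.context_tree <- function(x, ...) {
  cat("<context tree> rule '", x$rule$name, "': ", tree_leaves(x),
      " leaves, ", nrow(x$entries), " files\n", sep = "")
  paths <- x$entries$relative_path
  shown <- utils::head(paths, 20)
  cat(paste0("  ", shown, collapse = "\n"), "\n", sep = "")
  if (length(paths) > 20) cat("  ... (", length(paths) - 20, " more)\n", sep = "")
  invisible(x)
}
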