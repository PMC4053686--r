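# Depot project handle: on-disk layout, configuration, state tables, journal.
#
# A depot project is a directory holding
#   .depot.yaml    project configuration (store/floating locations, context
#                  rules, projections, hooks) -- all paths relative, so a
#                  project is relocatable and sync-friendly
#   .depot/        state tables (single JSON document, replaced atomically)
#                  and the append-only JSON-lines journal
#   store/         the flat content-addressed store: store/<unit_id>/<member>
#   floating/      the inbox for unassigned incoming files
#
# All mutating operations funnel through commit_state(), whose single
# rename() is the atomic commit point: a crash leaves either the previous or
# the new state, never a torn one.

STATE_VERSION <- 1L

empty_units <- function() {
  data.frame(unit_id = character(0), state = character(0),
             created_at = character(0), stringsAsFactors = FALSE)
}
empty_members <- function() {
  data.frame(unit_id = character(0), name = character(0),
             digest = character(0), size = numeric(0), stringsAsFactors = FALSE)
}
empty_attributes <- function() {
  data.frame(unit_id = character(0), key = character(0),
             value = character(0), stringsAsFactors = FALSE)
}
empty_provenance <- function() {
  data.frame(input_ids = character(0), process_name = character(0),
             params = character(0), output_id = character(0),
             recorded_at = character(0), stringsAsFactors = FALSE)
}

# shallow merge: user-provided top-level keys replace the defaults wholesale
# (rules/projections/hooks are unnamed lists, which modifyList would drop)
merge_config <- function(defaults, cfg) {
  for (n in names(cfg)) defaults[[n]] <- cfg[[n]]
  defaults
}

default_config <- function() {
  list(
    version = 1L,
    store = "store",
    floating = "floating",
    settle_seconds = 5,
    rules = list(),
    projections = list(),
    hooks = list(),
    grouping = list(
      stack_pattern = "^(.+?)[_-]([0-9]+)\\.([A-Za-z0-9]+)$"
    )
  )
}

#' Initialize a depot project directory
#'
#' Creates the flat store, the floating (inbox) folder, the state tables and
#' the journal, plus a default `.depot.yaml` configuration.
#'
#' @param root Directory to initialize (created if absent).
#' @param config Optional named list merged over the default configuration.
#' @return A depot project handle (class `depot`).
#' @seealso [depot_open()]
#' @export
depot_init <- function(root, config = list()) {
  if (file.exists(file.path(root, ".depot.yaml"))) {
    stop_depot("depot_validation", paste0(root, " already holds a depot project"))
  }
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  cfg <- merge_config(default_config(), config)
  yaml::write_yaml(cfg, file.path(root, ".depot.yaml"))
  dir.create(file.path(root, ".depot"), showWarnings = FALSE)
  dir.create(file.path(root, cfg$store), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(root, cfg$floating), recursive = TRUE, showWarnings = FALSE)
  project <- depot_open(root)
  commit_state(project, list(units = empty_units(), members = empty_members(),
                             attributes = empty_attributes(),
                             provenance = empty_provenance()))
  file.create(depot_paths(project)$journal)
  journal_event(project, "init", payload = list(root = basename(root)))
  project
}

#' Open an existing depot project
#'
#' @param root Project directory containing `.depot.yaml`.
#' @return A depot project handle (class `depot`).
#' @export
depot_open <- function(root) {
  cfg_path <- file.path(root, ".depot.yaml")
  if (!file.exists(cfg_path)) {
    stop_depot("depot_not_found", paste0("no depot project at ", root))
  }
  cfg <- merge_config(default_config(), yaml::read_yaml(cfg_path))
  structure(list(root = normalizePath(root), config = cfg), class = "depot")
}

#' @export
print.depot <- function(x, ...) {
  st <- depot_state(x)
  cat("<depot project> ", x$root, "\n", sep = "")
  cat("  units: ", nrow(st$units),
      " (", sum(st$units$state == "floating"), " floating, ",
      sum(st$units$state == "assigned"), " assigned)\n", sep = "")
  cat("  rules: ", length(x$config$rules), "  projections: ",
      length(x$config$projections), "\n", sep = "")
  invisible(x)
}

depot_paths <- function(project) {
  list(
    depot_dir = file.path(project$root, ".depot"),
    state = file.path(project$root, ".depot", "state.json"),
    journal = file.path(project$root, ".depot", "journal.jsonl"),
    store = file.path(project$root, project$config$store),
    floating = file.path(project$root, project$config$floating)
  )
}

as_state_df <- function(x, empty) {
  if (is.null(x) || (is.list(x) && length(x) == 0)) return(empty)
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  df[, names(empty), drop = FALSE]
}

depot_state <- function(project) {
  path <- depot_paths(project)$state
  if (!file.exists(path)) {
    stop_depot("depot_not_found", "state file missing; project not initialized")
  }
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  list(
    units = as_state_df(raw$units, empty_units()),
    members = as_state_df(raw$members, empty_members()),
    attributes = as_state_df(raw$attributes, empty_attributes()),
    provenance = as_state_df(raw$provenance, empty_provenance())
  )
}

commit_state <- function(project, state) {
  path <- depot_paths(project)$state
  doc <- list(version = STATE_VERSION, units = state$units,
              members = state$members, attributes = state$attributes,
              provenance = state$provenance)
  write_atomic(function(tmp) {
    jsonlite::write_json(doc, tmp, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }, path)
  invisible(state)
}

# ---- journal ---------------------------------------------------------------

journal_event <- function(project, action, unit_id = NULL, payload = NULL) {
  rec <- list(ts = depot_now(),
              actor = Sys.info()[["user"]] %||% "unknown",
              action = action)
  if (!is.null(unit_id)) rec$unit_id <- unit_id
  if (!is.null(payload)) rec$payload <- payload
  append_jsonl(depot_paths(project)$journal, rec)
}

read_journal <- function(project) {
  read_jsonl(depot_paths(project)$journal)
}

# attributes of one unit as a named character vector
unit_attributes <- function(state, unit_id) {
  rows <- state$attributes[state$attributes$unit_id == unit_id, , drop = FALSE]
  stats::setNames(rows$value, rows$key)
}

unit_members <- function(state, unit_id) {
  state$members[state$members$unit_id == unit_id, , drop = FALSE]
}
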