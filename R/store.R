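# The flat content-addressed store and the metadata/provenance graph.
#
# Units live at store/<unit_id>/<member_name>, flat at the top level; all
# organization is expressed through metadata and projections. Files under an
# assigned unit are never modified in place -- verify_store() detects drift.

# Deliberate fault injection for crash-safety tests: when the option
# datadepot.crash_at equals the running crash-point counter, abort. Ordinary
# use never sets the option, so this is a no-op.
crash_point <- function(label) {
  at <- getOption("datadepot.crash_at", NULL)
  if (is.null(at)) return(invisible(NULL))
  n <- getOption("datadepot.crash_counter", 0L) + 1L
  options(datadepot.crash_counter = n)
  if (n == at) {
    stop_depot("depot_injected_crash", paste0("injected crash at ", label))
  }
  invisible(NULL)
}

#' Ingest files into the flat store as one data unit
#'
#' Copies the files under `store/<unit_id>/`, preserving their (relative)
#' member names, and registers the unit in the floating state. Re-ingesting
#' identical content is a no-op that returns the already-stored unit.
#'
#' @param project A depot handle from [depot_open()].
#' @param files Paths of the files forming the unit.
#' @param names Member names inside the unit (default: base names).
#' @param state Initial unit state, `"floating"` (default) or `"assigned"`.
#' @return A `data_unit`: list with `unit_id`, `members` (data frame of
#'   name/digest/size), `state`, `created_at`.
#' @export
ingest_unit <- function(project, files, names = basename(files),
                        state = "floating") {
  if (length(files) == 0) {
    stop_depot("depot_validation", "a data unit must have at least one member")
  }
  unreadable <- files[!file.exists(files) | dir.exists(files)]
  if (length(unreadable)) {
    stop_depot("depot_io",
               paste0("cannot read: ", paste(unreadable, collapse = ", ")))
  }
  digests <- vapply(files, sha256_file, character(1), USE.NAMES = FALSE)
  unit_id <- unit_id_from_digests(names, digests)
  st <- depot_state(project)

  if (unit_id %in% st$units$unit_id) {           # dedup: content already stored
    return(depot_unit(project, unit_id))
  }

  store_place_files(project, unit_id, files, names)

  crash_point("before_state_commit")
  st$units <- rbind(st$units, data.frame(
    unit_id = unit_id, state = state, created_at = depot_now(),
    stringsAsFactors = FALSE))
  st$members <- rbind(st$members, data.frame(
    unit_id = unit_id, name = names, digest = digests,
    size = as.numeric(file.size(files)), stringsAsFactors = FALSE))
  commit_state(project, st)
  crash_point("after_state_commit")
  journal_event(project, "ingest", unit_id,
                payload = list(members = as.list(names)))
  depot_unit(project, unit_id)
}

# Copy member files under store/<unit_id>/ via a temp directory plus one
# rename, so a crash never leaves a partially visible unit directory.
store_place_files <- function(project, unit_id, files, names) {
  store <- depot_paths(project)$store
  dest <- file.path(store, unit_id)
  if (dir.exists(dest)) return(invisible(dest))   # content already present
  tmp <- file.path(store, paste0(".tmp-", unit_id, "-", Sys.getpid()))
  tryCatch({
    crash_point("before_copy")
    for (i in seq_along(files)) {
      target <- file.path(tmp, names[i])
      dir.create(dirname(target), recursive = TRUE, showWarnings = FALSE)
      if (!file.copy(files[i], target, copy.date = TRUE)) {
        stop_depot("depot_io", paste0("copy failed for ", files[i]))
      }
      crash_point("mid_copy")
    }
  }, error = function(e) {
    # injected crashes simulate a hard kill: leave the temp dir for recovery
    if (!inherits(e, "depot_injected_crash")) unlink(tmp, recursive = TRUE)
    stop(e)
  })
  crash_point("before_rename")
  if (!file.rename(tmp, dest)) {
    unlink(tmp, recursive = TRUE)
    stop_depot("depot_io", paste0("could not place unit ", unit_id, " in store"))
  }
  invisible(dest)
}

depot_unit <- function(project, unit_id, state = NULL) {
  st <- state %||% depot_state(project)
  row <- st$units[st$units$unit_id == unit_id, , drop = FALSE]
  if (nrow(row) == 0) {
    stop_depot("depot_not_found", paste0("unknown unit ", unit_id))
  }
  structure(list(unit_id = unit_id, state = row$state,
                 created_at = row$created_at,
                 members = unit_members(st, unit_id),
                 attributes = unit_attributes(st, unit_id)),
            class = "data_unit")
}

#' @export
print.data_unit <- function(x, ...) {
  cat("<data unit> ", substr(x$unit_id, 1, 12), "...  [", x$state, "]\n", sep = "")
  cat("  members: ", paste(x$members$name, collapse = ", "), "\n", sep = "")
  if (length(x$attributes)) {
    cat("  ", paste0(names(x$attributes), "=", x$attributes, collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}

unit_store_dir <- function(project, unit_id) {
  file.path(depot_paths(project)$store, unit_id)
}

#' Member file paths of a stored unit
#' @param project A depot handle.
#' @param unit_id Unit identifier.
#' @return Character vector of absolute paths, named by member name.
#' @export
unit_files <- function(project, unit_id) {
  st <- depot_state(project)
  mem <- unit_members(st, unit_id)
  if (nrow(mem) == 0) stop_depot("depot_not_found", paste0("unknown unit ", unit_id))
  stats::setNames(file.path(unit_store_dir(project, unit_id), mem$name), mem$name)
}

# ---- metadata --------------------------------------------------------------

#' Assign metadata attributes to a unit
#'
#' Upserts single-valued key--value attributes on the unit and flips its
#' state from floating to assigned. Keys are normalized with
#' [normalize_key()]; the old and new values of replaced keys are journaled.
#'
#' @param project A depot handle.
#' @param unit_id Unit identifier.
#' @param attributes Named list or character vector of attribute values;
#'   must be non-empty, values non-empty strings.
#' @return The updated `data_unit`, invisibly.
#' @export
assign_metadata <- function(project, unit_id, attributes) {
  st <- depot_state(project)
  if (!unit_id %in% st$units$unit_id) {
    stop_depot("depot_not_found", paste0("unknown unit ", unit_id))
  }
  if (length(attributes) == 0) {
    stop_depot("depot_validation",
               "a unit cannot become assigned with zero attributes")
  }
  raw_keys <- names(attributes) %||% character(0)
  bad <- raw_keys[!valid_key(raw_keys)]
  if (length(raw_keys) != length(attributes) || length(bad)) {
    stop_depot("depot_validation",
               paste0("malformed attribute keys: ",
                      paste(if (length(bad)) bad else "<missing>", collapse = ", ")))
  }
  vals <- vapply(attributes, as.character, character(1))
  if (any(!nzchar(vals))) {
    stop_depot("depot_validation", paste0(
      "empty values for keys: ",
      paste(raw_keys[!nzchar(vals)], collapse = ", ")))
  }
  keys <- normalize_key(raw_keys)
  if (anyDuplicated(keys)) {
    stop_depot("depot_validation", paste0(
      "keys collide after normalization: ",
      paste(unique(keys[duplicated(keys)]), collapse = ", ")))
  }

  changes <- list()
  for (i in seq_along(keys)) {
    hit <- which(st$attributes$unit_id == unit_id & st$attributes$key == keys[i])
    if (length(hit)) {
      old <- st$attributes$value[hit]
      if (!identical(old, vals[[i]])) {
        changes[[keys[i]]] <- list(old = old, new = vals[[i]])
      }
      st$attributes$value[hit] <- vals[[i]]
    } else {
      changes[[keys[i]]] <- list(old = NULL, new = vals[[i]])
      st$attributes <- rbind(st$attributes, data.frame(
        unit_id = unit_id, key = keys[i], value = vals[[i]],
        stringsAsFactors = FALSE))
    }
  }
  st$units$state[st$units$unit_id == unit_id] <- "assigned"
  commit_state(project, st)
  journal_event(project, "assign", unit_id, payload = list(changes = changes))
  invisible(depot_unit(project, unit_id))
}

#' Query assigned units by a conjunction of key=value terms
#'
#' @param project A depot handle.
#' @param filter Named character vector / list of `KEY = "value"` terms; the
#'   empty filter matches every assigned unit. Unknown keys match nothing.
#' @return Character vector of unit ids (bytewise sorted).
#' @export
query_units <- function(project, filter = NULL) {
  st <- depot_state(project)
  query_units_state(st, filter)
}

query_units_state <- function(st, filter = NULL) {
  f <- as_filter(filter)
  ids <- st$units$unit_id[st$units$state == "assigned"]
  for (i in seq_along(f)) {
    hit <- st$attributes$unit_id[st$attributes$key == names(f)[i] &
                                 st$attributes$value == f[[i]]]
    ids <- ids[ids %in% hit]
  }
  sort_bytes(ids)
}

# ---- provenance ------------------------------------------------------------

prov_inputs <- function(x) strsplit(x, ";", fixed = TRUE)

#' Record a provenance edge: inputs -> process(params) -> output
#'
#' The edge is rejected if it would make a unit its own ancestor. Process
#' parameters are also materialized as attributes on the output unit,
#' namespaced by the process name (`<PROCESS>_<KEY>`), so that projections
#' can group by them.
#'
#' @param project A depot handle.
#' @param input_ids Character vector of input unit ids.
#' @param process_name Name of the process/script (e.g. `"SIGEN"`).
#' @param params Named list of process parameters (may be empty).
#' @param output_id Unit id of the produced unit.
#' @return The recorded edge as a list, invisibly.
#' @export
record_provenance <- function(project, input_ids, process_name, params,
                              output_id) {
  st <- depot_state(project)
  all_ids <- unique(c(input_ids, output_id))
  unknown <- all_ids[!all_ids %in% st$units$unit_id]
  if (length(unknown)) {
    stop_depot("depot_not_found",
               paste0("unknown units: ", paste(unknown, collapse = ", ")))
  }
  if (output_id %in% input_ids) {
    stop_depot("depot_cycle", "output unit cannot be one of its own inputs")
  }
  for (inp in input_ids) {
    path <- ancestry_path(st, from = inp, to = output_id)
    if (!is.null(path)) {
      stop_depot("depot_cycle", paste0(
        "edge would create a cycle: ",
        paste(substr(c(output_id, rev(path)), 1, 8), collapse = " -> ")))
    }
  }
  params <- params %||% list()
  edge <- data.frame(
    input_ids = paste(input_ids, collapse = ";"),
    process_name = process_name,
    params = as.character(jsonlite::toJSON(params, auto_unbox = TRUE)),
    output_id = output_id, recorded_at = depot_now(),
    stringsAsFactors = FALSE)
  st$provenance <- rbind(st$provenance, edge)
  commit_state(project, st)
  journal_event(project, "provenance", output_id,
                payload = list(inputs = as.list(input_ids),
                               process = process_name, params = params))
  if (length(params)) {
    attrs <- stats::setNames(
      lapply(params, as.character),
      normalize_key(paste(process_name, names(params), sep = "_")))
    assign_metadata(project, output_id, attrs)
  }
  invisible(as.list(edge))
}

# walk provenance upward from `from`; return a path of unit ids ending at
# `to` if `to` is an ancestor of (or equal to) `from`, else NULL
ancestry_path <- function(st, from, to) {
  if (identical(from, to)) return(from)
  pred <- list()  # unit -> the unit we reached it from (towards `from`)
  queue <- from
  seen <- character(0)
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    edges <- st$provenance[st$provenance$output_id == cur, , drop = FALSE]
    parents <- unique(unlist(prov_inputs(edges$input_ids)))
    for (p in parents) {
      if (!p %in% seen && !p %in% queue) {
        pred[[p]] <- cur
        if (identical(p, to)) {
          path <- p
          while (!identical(path[[1]], from)) path <- c(pred[[path[[1]]]], path)
          return(path)
        }
        queue <- c(queue, p)
      }
    }
  }
  NULL
}

#' All ancestor units of a unit in the provenance graph
#'
#' @param project A depot handle.
#' @param unit_id Unit identifier.
#' @return Character vector of ancestor unit ids (transitive inputs).
#' @export
unit_ancestors <- function(project, unit_id) {
  st <- depot_state(project)
  out <- character(0)
  queue <- unit_id
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    edges <- st$provenance[st$provenance$output_id == cur, , drop = FALSE]
    parents <- setdiff(unique(unlist(prov_inputs(edges$input_ids))), out)
    out <- c(out, parents)
    queue <- c(queue, parents)
  }
  sort_bytes(out)
}

# ---- integrity -------------------------------------------------------------

#' Verify store integrity against the metadata tables
#'
#' Recomputes every stored member digest and cross-checks the store directory
#' against the unit tables. Problems are report rows, never exceptions.
#'
#' @param project A depot handle.
#' @return A data frame (class `depot_report`) with columns `kind`
#'   (`corrupted`, `missing_file`, `dangling_unit`, `orphan_dir`), `unit_id`,
#'   `path`, `detail`; zero rows for a clean store.
#' @export
verify_store <- function(project) {
  st <- depot_state(project)
  store <- depot_paths(project)$store
  findings <- list()
  add <- function(kind, unit_id, path, detail) {
    findings[[length(findings) + 1]] <<- data.frame(
      kind = kind, unit_id = unit_id, path = path, detail = detail,
      stringsAsFactors = FALSE)
  }
  for (uid in st$units$unit_id) {
    dir <- file.path(store, uid)
    if (!dir.exists(dir)) {
      add("dangling_unit", uid, dir, "metadata references a missing store directory")
      next
    }
    mem <- unit_members(st, uid)
    for (i in seq_len(nrow(mem))) {
      f <- file.path(dir, mem$name[i])
      if (!file.exists(f)) {
        add("missing_file", uid, f, "member file missing from store")
      } else if (!identical(sha256_file(f), mem$digest[i])) {
        add("corrupted", uid, f, "content digest does not match recorded digest")
      }
    }
  }
  dirs <- list.dirs(store, recursive = FALSE, full.names = FALSE)
  for (d in setdiff(dirs, st$units$unit_id)) {
    add("orphan_dir", NA_character_, file.path(store, d),
        "store directory not referenced by metadata")
  }
  out <- if (length(findings)) do.call(rbind, findings) else data.frame(
    kind = character(0), unit_id = character(0), path = character(0),
    detail = character(0), stringsAsFactors = FALSE)
  class(out) <- c("depot_report", class(out))
  out
}

#' @export
print.depot_report <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("store verification: clean (0 findings)\n")
  } else {
    cat("store verification: ", nrow(x), " finding(s)\n", sep = "")
    print.data.frame(x)
  }
  invisible(x)
}

# ---- crash recovery --------------------------------------------------------

#' Replay the journal to restore a consistent state after a crash
#'
#' An interrupted assignment leaves one of a small number of well-defined
#' intermediate layouts (temp copy in the store, renamed-but-uncommitted
#' unit directory, committed unit with leftover floating files). Recovery
#' rolls an uncommitted assignment back to its pre-state and rolls a
#' committed one forward to its post-state.
#'
#' @param project A depot handle.
#' @return Character vector describing the actions taken, invisibly.
#' @export
depot_recover <- function(project) {
  st <- depot_state(project)
  paths <- depot_paths(project)
  actions <- character(0)

  # stray temp copies from interrupted ingests
  tmps <- list.files(paths$store, pattern = "^\\.tmp-", all.files = TRUE,
                     full.names = TRUE)
  for (t in tmps) {
    unlink(t, recursive = TRUE)
    actions <- c(actions, paste0("removed temp copy ", basename(t)))
  }

  # assign_begin without assign_commit: roll back or forward
  events <- read_journal(project)
  begun <- list()
  for (ev in events) {
    if (identical(ev$action, "assign_begin")) begun[[ev$unit_id]] <- ev
    if (identical(ev$action, "assign_commit")) begun[[ev$unit_id]] <- NULL
  }
  for (uid in names(begun)) {
    ev <- begun[[uid]]
    if (uid %in% st$units$unit_id) {
      # committed (or content pre-existing): roll forward to the post-state
      attrs <- ev$payload$attributes
      if (length(attrs)) assign_metadata(project, uid, attrs)
      left <- unlist(ev$payload$files)
      left <- left[file.exists(file.path(project$root, left))]
      if (length(left)) {
        unlink(file.path(project$root, left))
        actions <- c(actions, paste0("removed ", length(left),
                                     " leftover floating file(s) for ", substr(uid, 1, 8)))
      }
      journal_event(project, "assign_commit", uid,
                    payload = list(recovered = TRUE))
    } else {
      # uncommitted: drop the half-placed store directory, keep floating files
      dir <- file.path(paths$store, uid)
      if (dir.exists(dir)) {
        unlink(dir, recursive = TRUE)
        actions <- c(actions, paste0("rolled back uncommitted unit ", substr(uid, 1, 8)))
      }
      journal_event(project, "assign_rollback", uid)
    }
  }
  if (length(actions)) {
    journal_event(project, "recover", payload = list(actions = as.list(actions)))
  }
  invisible(actions)
}
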