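# Materialized projections: context trees realized on disk as read-only
# hierarchies of links into the flat store -- the filesystem analogue of a
# database's materialized views. A JSON manifest at the target root records
# every managed entry plus a fingerprint of the inputs, so refreshes are
# idempotent and apply a minimal diff (sync-tool friendly: unchanged entries
# keep their mtimes).

MANIFEST_NAME <- ".projection.json"
MANIFEST_VERSION <- 1L

#' Sanitize a metadata value into a path component
#'
#' Deterministic, collision-safe mapping from attribute values to filesystem
#' path components: characters outside `[A-Za-z0-9._-]` become `_`; empty
#' values become `_EMPTY_`; `.` and `..` are escaped. When two distinct
#' values in the input coincide after replacement, the altered ones receive
#' an 8-hex disambiguator derived from the original value, so the mapping
#' stays injective over the vector.
#'
#' @param values Character vector of raw values.
#' @return Character vector of path-safe components, same length.
#' @examples
#' sanitize_component(c("left_DL", "a/b"))
#' sanitize_component(c("a/b", "a_b"))  # collision-safe
#' @export
sanitize_component <- function(values) {
  if (length(values) == 0) return(character(0))
  clean1 <- function(v) {
    if (!nzchar(v)) return("_EMPTY_")
    if (v == ".") return("_DOT_")
    if (v == "..") return("_DOTDOT_")
    gsub("[^A-Za-z0-9._-]", "_", v)
  }
  out <- vapply(values, clean1, character(1), USE.NAMES = FALSE)
  changed <- out != values
  # injectivity over the vector: if distinct originals collide, suffix the
  # altered ones with a digest of their original value
  for (o in unique(out)) {
    idx <- which(out == o)
    if (length(unique(values[idx])) > 1) {
      fix <- idx[changed[idx]]
      out[fix] <- paste0(out[fix], "_",
                         substr(vapply(values[fix], function(v)
                           sha256_raw(charToRaw(enc2utf8(v))), character(1)), 1, 8))
    }
  }
  out
}

# member names may be nested relative paths: sanitize per component
sanitize_member <- function(x) {
  vapply(x, function(p) {
    paste(sanitize_component(strsplit(p, "/", fixed = TRUE)[[1]]), collapse = "/")
  }, character(1), USE.NAMES = FALSE)
}

# Fingerprint of everything a projection depends on: the rule itself, the
# selected units' attributes and member digests, and the link mode.
projection_fingerprint <- function(st, rule, link_mode) {
  ids <- query_units_state(st, rule$filter)
  att <- st$attributes[st$attributes$unit_id %in% ids, , drop = FALSE]
  att <- att[order(att$unit_id, att$key, method = "radix"), , drop = FALSE]
  mem <- st$members[st$members$unit_id %in% ids, , drop = FALSE]
  mem <- mem[order(mem$unit_id, mem$name, method = "radix"), , drop = FALSE]
  doc <- list(rule = unclass(rule), link_mode = link_mode,
              attributes = att[c("unit_id", "key", "value")],
              members = mem[c("unit_id", "name", "digest")])
  sha256_raw(charToRaw(jsonlite::toJSON(doc, dataframe = "rows",
                                        auto_unbox = TRUE)))
}

read_manifest <- function(target_root) {
  path <- file.path(target_root, MANIFEST_NAME)
  if (!file.exists(path)) return(NULL)
  m <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  m$entries <- as_state_df(m$entries, data.frame(
    path = character(0), unit_id = character(0), member = character(0),
    kind = character(0), stringsAsFactors = FALSE))
  m
}

write_manifest <- function(target_root, manifest) {
  write_atomic(function(tmp) {
    jsonlite::write_json(manifest, tmp, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }, file.path(target_root, MANIFEST_NAME))
}

# one link according to mode; returns the kind actually used
make_link <- function(source, link, mode) {
  chain <- switch(mode,
    auto = c("symlink", "hardlink", "copy"),
    symlink = "symlink", hardlink = "hardlink", copy = "copy",
    stop_depot("depot_validation", paste0("unknown link mode '", mode, "'")))
  for (kind in chain) {
    ok <- switch(kind,
      symlink = suppressWarnings(file.symlink(source, link)),
      hardlink = suppressWarnings(file.link(source, link)),
      copy = suppressWarnings(file.copy(source, link, copy.date = TRUE)))
    if (isTRUE(ok)) {
      if (kind != chain[1] && length(chain) > 1) {
        message("link mode downgraded to ", kind, " for ", link)
      }
      return(kind)
    }
  }
  stop_depot("depot_io", paste0("could not create link ", link))
}

# make every existing directory under (and including) root user-writable so
# a previously read-only projection can be refreshed
unlock_dirs <- function(root) {
  dirs <- c(root, list.dirs(root, recursive = TRUE, full.names = TRUE))
  Sys.chmod(unique(dirs), mode = "0755", use_umask = FALSE)
  invisible(NULL)
}

prune_empty_dirs <- function(root) {
  repeat {
    dirs <- setdiff(list.dirs(root, recursive = TRUE, full.names = TRUE), root)
    empty <- dirs[vapply(dirs, function(d)
      length(list.files(d, all.files = TRUE, no.. = TRUE)) == 0, logical(1))]
    if (!length(empty)) break
    unlink(empty, recursive = TRUE)
  }
  invisible(NULL)
}

#' Materialize a context tree on disk
#'
#' Builds the rule's context tree and realizes it under `target_root` as a
#' hierarchy of links into the flat store, writing a manifest
#' (`.projection.json`) that records every managed entry. The target must be
#' empty or owned by a previous projection of the same rule; materializing
#' is implemented as a refresh, so repeated calls are idempotent.
#'
#' @param project A depot handle.
#' @param rule A [context_rule()] or configured rule name.
#' @param target_root Directory to hold the projection (created if absent).
#' @param link_mode `"auto"` (symlink, falling back to hardlink then copy),
#'   `"symlink"`, `"hardlink"` or `"copy"`.
#' @return The projection manifest (list), invisibly. The attribute `ops`
#'   carries the number of filesystem changes performed.
#' @export
materialize <- function(project, rule, target_root, link_mode = "auto") {
  refresh_projection(project, rule, target_root, link_mode)
}

#' Refresh a materialized projection with a minimal diff
#'
#' Recomputes the context tree and brings the target up to date, touching
#' only entries that changed: refreshing on unchanged inputs performs zero
#' filesystem operations, and an attribute edit moves exactly the affected
#' entries. Foreign (unmanaged) files found in the target are warned about
#' and left alone.
#'
#' @inheritParams materialize
#' @return The projection manifest, invisibly, with attribute `ops` (number
#'   of filesystem changes: links created plus entries removed).
#' @export
refresh_projection <- function(project, rule, target_root, link_mode = "auto") {
  if (is.character(rule)) {
    rules <- project_rules(project)
    if (!rule %in% names(rules)) {
      stop_depot("depot_not_found", paste0("no configured rule named '", rule, "'"))
    }
    rule <- rules[[rule]]
  }
  st <- depot_state(project)
  old <- if (dir.exists(target_root)) read_manifest(target_root) else NULL
  if (!is.null(old) && !identical(old$rule_name, rule$name)) {
    stop_depot("depot_validation", paste0(
      "target ", target_root, " is owned by rule '", old$rule_name,
      "', refusing to project rule '", rule$name, "' into it"))
  }
  if (is.null(old) && dir.exists(target_root) &&
      length(list.files(target_root, all.files = TRUE, no.. = TRUE))) {
    stop_depot("depot_validation", paste0(
      "target ", target_root, " is not empty and holds no projection manifest"))
  }

  fingerprint <- projection_fingerprint(st, rule, link_mode)
  if (!is.null(old) && identical(old$graph_fingerprint, fingerprint)) {
    out <- old
    attr(out, "ops") <- 0L
    return(invisible(out))    # byte-level no-op
  }

  tree <- build_tree_state(st, rule)
  entries <- tree$entries
  store <- depot_paths(project)$store
  dir.create(target_root, recursive = TRUE, showWarnings = FALSE)
  unlock_dirs(target_root)

  old_entries <- if (is.null(old)) data.frame(
    path = character(0), unit_id = character(0), member = character(0),
    kind = character(0), stringsAsFactors = FALSE) else old$entries
  old_key <- paste(old_entries$path, old_entries$unit_id, old_entries$member,
                   old_entries$kind)
  new_kind <- rep(NA_character_, nrow(entries))

  ops <- 0L
  # drop entries that are gone or changed
  keep <- logical(nrow(old_entries))
  new_key_by_path <- stats::setNames(
    paste(entries$relative_path, entries$unit_id, entries$member_name),
    entries$relative_path)
  for (i in seq_len(nrow(old_entries))) {
    p <- old_entries$path[i]
    same <- !is.na(new_key_by_path[p]) &&
      identical(unname(new_key_by_path[p]),
                paste(p, old_entries$unit_id[i], old_entries$member[i]))
    if (same && file.exists(file.path(target_root, p))) {
      keep[i] <- TRUE
    } else {
      if (file.exists(file.path(target_root, p))) {
        unlink(file.path(target_root, p))
        ops <- ops + 1L
      }
    }
  }
  kept <- old_entries[keep, , drop = FALSE]

  # create missing entries
  for (i in seq_len(nrow(entries))) {
    p <- entries$relative_path[i]
    j <- which(kept$path == p)
    if (length(j)) { new_kind[i] <- kept$kind[j[1]]; next }
    link <- file.path(target_root, p)
    dir.create(dirname(link), recursive = TRUE, showWarnings = FALSE)
    source <- file.path(store, entries$unit_id[i], entries$member_name[i])
    new_kind[i] <- make_link(source, link, link_mode)
    ops <- ops + 1L
  }
  prune_empty_dirs(target_root)

  # warn about unmanaged files, leave them untouched
  managed <- c(entries$relative_path, MANIFEST_NAME)
  foreign <- setdiff(list_files_rel(target_root), managed)
  foreign <- foreign[!grepl("\\.tmp-", foreign)]
  if (length(foreign)) {
    warning("unmanaged file(s) in projection target left alone: ",
            paste(foreign, collapse = ", "), call. = FALSE)
  }

  manifest <- list(
    version = MANIFEST_VERSION,
    rule_name = rule$name,
    link_mode = link_mode,
    built_at = depot_now(),
    graph_fingerprint = fingerprint,
    entries = data.frame(path = entries$relative_path,
                         unit_id = entries$unit_id,
                         member = entries$member_name,
                         kind = new_kind, stringsAsFactors = FALSE))
  write_manifest(target_root, manifest)
  journal_event(project, "project",
                payload = list(rule = rule$name, target = target_root,
                               entries = nrow(entries), ops = ops))
  attr(manifest, "ops") <- ops
  invisible(manifest)
}

#' Make a materialized projection read-only
#'
#' Best-effort removal of write permission from every projected entry and
#' directory, so project members cannot mutate the view in place; the store
#' remains the single writable source of truth (and [verify_store()] is the
#' safety net for any bypass). A later refresh re-opens the directories it
#' needs to touch.
#'
#' @param target_root Projection directory.
#' @return Invisibly, the paths whose permissions were changed.
#' @export
enforce_read_only <- function(target_root) {
  files <- list_files_rel(target_root)
  files <- setdiff(files, MANIFEST_NAME)
  paths <- file.path(target_root, files)
  if (length(paths)) Sys.chmod(paths, mode = "0444", use_umask = FALSE)
  dirs <- setdiff(list.dirs(target_root, recursive = TRUE), target_root)
  if (length(dirs)) Sys.chmod(dirs, mode = "0555", use_umask = FALSE)
  invisible(c(paths, dirs))
}
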