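# Floating-folder ingestion: detect candidate data units in the inbox,
# drive their assignment into the store, and fire processing hooks.
#
# The floating folder is a plain directory, typically populated by a file
# sync client; a polling scan (not a platform inotify daemon) groups its
# stable files into candidates. Grouping rules apply in fixed priority
# order: a top-level subdirectory is one unit regardless of naming; flat
# files sharing a stem with a numeric suffix form one stack unit; anything
# else is a single-file unit.

#' Scan the floating folder for candidate data units
#'
#' @param project A depot handle.
#' @param settle_seconds Files modified more recently than this are
#'   considered still in flight (a sync client may be writing them) and are
#'   deferred to the next scan. Defaults to the configured value (5 s).
#' @return List of `floating_candidate` objects, each with `candidate_id`
#'   (the unit id the files would receive on ingest), `files` (paths
#'   relative to the project root), `names` (member names),
#'   `grouping_rule_matched` and `detected_at`.
#' @export
scan_floating <- function(project, settle_seconds = NULL) {
  paths <- depot_paths(project)
  floating <- paths$floating
  if (!dir.exists(floating)) {
    stop_depot("depot_not_found", paste0("floating folder missing: ", floating))
  }
  settle <- settle_seconds %||% project$config$settle_seconds %||% 5
  now <- Sys.time()

  rel_all <- list_files_rel(floating)
  abs_all <- file.path(floating, rel_all)
  stable <- difftime(now, file.mtime(abs_all), units = "secs") >= settle
  rel_all <- rel_all[stable]

  candidates <- list()
  add_candidate <- function(rel_files, names, rule) {
    abs <- file.path(floating, rel_files)
    cid <- compute_unit_id(abs, names = names)
    candidates[[length(candidates) + 1]] <<- structure(list(
      candidate_id = cid,
      files = file.path(project$config$floating, rel_files),
      names = names,
      grouping_rule_matched = rule,
      detected_at = depot_now()), class = "floating_candidate")
  }

  # 1. directory-as-unit: each top-level subdirectory, whatever its contents
  in_dir <- grepl("/", rel_all, fixed = TRUE)
  if (any(in_dir)) {
    tops <- sub("/.*$", "", rel_all[in_dir])
    for (d in sort_bytes(unique(tops))) {
      rel <- rel_all[in_dir][tops == d]
      add_candidate(rel, names = sub(paste0("^", d, "/"), "", rel),
                    rule = "directory")
    }
  }

  # 2. numeric-suffix stacks among the flat files
  flat <- rel_all[!in_dir]
  pat <- project$config$grouping$stack_pattern
  m <- regmatches(flat, regexec(pat, flat))
  is_stack <- vapply(m, length, integer(1)) == 4L
  stems <- rep(NA_character_, length(flat))
  stems[is_stack] <- vapply(m[is_stack], function(g)
    paste0(g[2], ".", g[4]), character(1))
  grouped <- logical(length(flat))
  for (s in sort_bytes(unique(stats::na.omit(stems)))) {
    idx <- which(!is.na(stems) & stems == s)
    if (length(idx) >= 2) {
      add_candidate(flat[idx], names = flat[idx], rule = "stack")
      grouped[idx] <- TRUE
    }
  }

  # 3. single-file fallback
  for (f in flat[!grouped]) add_candidate(f, names = f, rule = "single")

  journal_event(project, "scan", payload = list(
    candidates = lapply(candidates, function(cand)
      list(candidate_id = cand$candidate_id, n_files = length(cand$files),
           rule = cand$grouping_rule_matched))))
  candidates
}

#' @export
print.floating_candidate <- function(x, ...) {
  cat("<floating candidate> ", substr(x$candidate_id, 1, 12), "...  (",
      x$grouping_rule_matched, ", ", length(x$files), " file(s))\n", sep = "")
  invisible(x)
}

#' Assign a floating candidate into the store
#'
#' Revalidates the candidate (its files must be unchanged since the scan),
#' copies them into the flat store, records the attributes, removes the
#' originals from the floating folder, fires `on_assign` hooks and journals
#' the event. The metadata commit is atomic: an interrupted assignment is
#' rolled back or forward by [depot_recover()], never left half done.
#'
#' @param project A depot handle.
#' @param candidate A `floating_candidate` from [scan_floating()].
#' @param attributes Named list of attribute values (non-empty).
#' @param hooks Optional list of [hook_spec()]s overriding the configured
#'   ones.
#' @return The assigned `data_unit`.
#' @export
assign_candidate <- function(project, candidate, attributes, hooks = NULL) {
  if (!inherits(candidate, "floating_candidate")) {
    stop_depot("depot_validation", "candidate must come from scan_floating()")
  }
  if (length(attributes) == 0) {
    stop_depot("depot_validation",
               "a unit cannot become assigned with zero attributes")
  }
  abs <- file.path(project$root, candidate$files)
  if (!all(file.exists(abs)) ||
      !identical(tryCatch(compute_unit_id(abs, names = candidate$names),
                          error = function(e) NA_character_),
                 candidate$candidate_id)) {
    stop_depot("depot_stale_candidate",
               "candidate files changed or vanished since the scan; rescan required")
  }
  unit_id <- candidate$candidate_id
  st <- depot_state(project)

  journal_event(project, "assign_begin", unit_id, payload = list(
    files = as.list(candidate$files), attributes = as.list(attributes)))
  crash_point("after_begin")

  if (!unit_id %in% st$units$unit_id) {
    store_place_files(project, unit_id, abs, candidate$names)
    crash_point("before_commit")
    digests <- vapply(abs, sha256_file, character(1), USE.NAMES = FALSE)
    st$units <- rbind(st$units, data.frame(
      unit_id = unit_id, state = "floating", created_at = depot_now(),
      stringsAsFactors = FALSE))
    st$members <- rbind(st$members, data.frame(
      unit_id = unit_id, name = candidate$names, digest = digests,
      size = as.numeric(file.size(abs)), stringsAsFactors = FALSE))
    commit_state(project, st)
  }
  # single-commit attribute application (also flips state to assigned)
  assign_metadata(project, unit_id, attributes)
  crash_point("after_commit")

  crash_point("before_floating_cleanup")
  unlink(abs)
  # a directory candidate may leave empty shells behind
  prune_empty_dirs(depot_paths(project)$floating)
  # journaled only once the floating originals are gone, so recovery knows
  # whether the cleanup still needs rolling forward
  journal_event(project, "assign_commit", unit_id)

  run_hooks(project, "on_assign", unit_id, hooks = hooks)
  depot_unit(project, unit_id)
}

# ---- hooks -----------------------------------------------------------------

#' Declare a processing hook
#'
#' Hooks plug external scripts or R functions into the data-transition
#' workflow. A hook fires on an event when its matcher applies to the unit;
#' it receives the unit's stored file paths and attributes, and may return
#' extra attributes, which are merged under the namespace
#' `HOOK_<NAME>_<KEY>` so they never clobber user metadata. Hooks are
#' advisory: failures and timeouts are captured and journaled, never
#' propagated.
#'
#' @param name Hook name (used for the attribute namespace).
#' @param event One of `"on_detect"`, `"on_assign"`, `"on_project"`.
#' @param match Matcher: a list with `suffix` (file-name suffix, e.g.
#'   `".swc"`) and/or `attrs` (named key=value terms that must all hold).
#'   An empty matcher matches every unit.
#' @param command External executable run with a JSON description of the
#'   unit on stdin; JSON printed on stdout is read back as attributes.
#'   Either `command` or `fun` must be given.
#' @param fun An R function `function(files, attributes)` returning a named
#'   list of extra attributes (or NULL), or the name of one.
#' @param args Extra command-line arguments for `command`.
#' @param timeout Seconds before the hook is killed (must be > 0).
#' @return A `hook_spec` object.
#' @export
hook_spec <- function(name, event = c("on_assign", "on_detect", "on_project"),
                      match = list(), command = NULL, fun = NULL,
                      args = character(0), timeout = 30) {
  event <- match.arg(event)
  if (!is.numeric(timeout) || timeout <= 0) {
    stop_depot("depot_validation", "hook timeout must be > 0")
  }
  if (is.null(command) && is.null(fun)) {
    stop_depot("depot_validation", "hook needs a command or an R function")
  }
  bad <- setdiff(names(match), c("suffix", "attrs"))
  if (length(bad)) {
    stop_depot("depot_validation",
               paste0("unknown matcher field(s): ", paste(bad, collapse = ", ")))
  }
  structure(list(name = name, event = event, match = match, command = command,
                 fun = fun, args = args, timeout = timeout),
            class = "hook_spec")
}

config_hooks <- function(project) {
  lapply(project$config$hooks, function(h) {
    hook_spec(name = h$name, event = h$event %||% "on_assign",
              match = h$match %||% list(), command = h$command,
              fun = h$fun, args = unlist(h$args) %||% character(0),
              timeout = h$timeout %||% 30)
  })
}

hook_matches <- function(hook, files, attrs) {
  m <- hook$match
  if (!is.null(m$suffix) &&
      !any(endsWith(tolower(names(files)), tolower(m$suffix)))) {
    return(FALSE)
  }
  if (!is.null(m$attrs)) {
    want <- as_filter(m$attrs)
    if (!all(names(want) %in% names(attrs)) ||
        !all(attrs[names(want)] == unname(want))) {
      return(FALSE)
    }
  }
  TRUE
}

run_one_hook <- function(hook, files, attrs) {
  started <- Sys.time()
  res <- list(hook = hook$name, status = "ok", attributes = NULL, output = "")
  if (!is.null(hook$command)) {
    payload <- jsonlite::toJSON(
      list(files = as.list(unname(files)), attributes = as.list(attrs)),
      auto_unbox = TRUE)
    out <- tryCatch(
      suppressWarnings(system2(hook$command, args = hook$args,
                               input = as.character(payload),
                               stdout = TRUE, stderr = FALSE,
                               timeout = hook$timeout)),
      error = function(e) structure("", status = 127L))
    status <- attr(out, "status") %||% 0L
    res$output <- paste(out, collapse = "\n")
    if (identical(status, 124L)) {
      res$status <- "timeout"
    } else if (!identical(status, 0L)) {
      res$status <- "error"
    } else if (nzchar(trimws(res$output))) {
      res$attributes <- tryCatch(
        jsonlite::fromJSON(res$output, simplifyVector = TRUE),
        error = function(e) NULL)
    }
  } else {
    fn <- if (is.function(hook$fun)) hook$fun else {
      parts <- strsplit(hook$fun, "::", fixed = TRUE)[[1]]
      if (length(parts) == 2) get(parts[2], envir = asNamespace(parts[1]))
      else match.fun(hook$fun)
    }
    res <- tryCatch({
      setTimeLimit(elapsed = hook$timeout, transient = TRUE)
      on.exit(setTimeLimit(elapsed = Inf), add = TRUE)
      val <- fn(files, attrs)
      res$attributes <- val
      res
    }, error = function(e) {
      elapsed <- as.numeric(difftime(Sys.time(), started, units = "secs"))
      res$status <- if (elapsed >= hook$timeout) "timeout" else "error"
      res$output <- conditionMessage(e)
      res
    })
  }
  res
}

#' Run the hooks registered for an event on a unit
#'
#' @param project A depot handle.
#' @param event `"on_detect"`, `"on_assign"` or `"on_project"`.
#' @param unit_id Unit identifier (must be in the store).
#' @param hooks Optional list of [hook_spec()]s; defaults to the configured
#'   hooks of the project.
#' @return List of hook results (`hook`, `status`, `attributes`, `output`);
#'   empty when no hook matches. Attributes returned by successful hooks
#'   are merged onto the unit under `HOOK_<NAME>_<KEY>`.
#' @export
run_hooks <- function(project, event, unit_id, hooks = NULL) {
  hooks <- hooks %||% config_hooks(project)
  hooks <- Filter(function(h) identical(h$event, event), hooks)
  if (!length(hooks)) return(list())
  files <- unit_files(project, unit_id)
  st <- depot_state(project)
  attrs <- unit_attributes(st, unit_id)
  results <- list()
  for (hook in hooks) {
    if (!hook_matches(hook, files, attrs)) next
    res <- run_one_hook(hook, files, attrs)
    results[[length(results) + 1]] <- res
    journal_event(project, "hook", unit_id, payload = list(
      hook = hook$name, event = event, status = res$status,
      output = if (res$status == "ok") NULL else res$output))
    if (res$status == "ok" && length(res$attributes)) {
      extra <- stats::setNames(
        lapply(res$attributes, as.character),
        normalize_key(paste("HOOK", hook$name, names(res$attributes), sep = "_")))
      assign_metadata(project, unit_id, extra)
    }
  }
  results
}
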