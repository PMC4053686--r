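# State and recent-changes reports: pure functions of the metadata graph,
# the store, and the journal, rendered as plain text or minimal HTML.

#' Report the current state of a depot project
#'
#' Counts units by state and by every attribute key's values, lists the
#' floating candidates awaiting assignment, and (when the configuration
#' defines context rules) the per-rule leaf counts.
#'
#' @param project A depot handle.
#' @return A `depot_state_report` list with `total_units`, `by_state`,
#'   `by_attribute` (one value-count table per key), `floating_candidates`,
#'   and `rule_leaves`.
#' @export
state_report <- function(project) {
  st <- depot_state(project)
  by_state <- c(floating = sum(st$units$state == "floating"),
                assigned = sum(st$units$state == "assigned"))
  by_attribute <- lapply(split(st$attributes$value, st$attributes$key),
                         function(v) sort(table(v), decreasing = TRUE))
  candidates <- tryCatch(
    scan_floating_quiet(project, settle_seconds = 0),
    depot_not_found = function(e) list())
  rules <- tryCatch(project_rules(project), depot_schema = function(e) list())
  rule_leaves <- vapply(rules, function(r) {
    tryCatch(tree_leaves(build_tree_state(st, r)),
             depot_error = function(e) NA_integer_)
  }, integer(1))
  structure(list(total_units = nrow(st$units), by_state = by_state,
                 by_attribute = by_attribute,
                 floating_candidates = candidates,
                 rule_leaves = rule_leaves),
            class = "depot_state_report")
}

# scan without touching the journal (reports must be side-effect free)
scan_floating_quiet <- function(project, settle_seconds = 0) {
  journal <- depot_paths(project)$journal
  before <- file.size(journal)
  out <- scan_floating(project, settle_seconds = settle_seconds)
  # truncate the scan event we just appended
  if (!is.na(before) && file.size(journal) > before) {
    lines <- readLines(journal, warn = FALSE)
    writeLines(utils::head(lines, -1), journal)
  }
  out
}

#' @export
print.depot_state_report <- function(x, ...) {
  cat("== depot state ==\n")
  cat(sprintf("units: %d total | %d floating | %d assigned\n",
              x$total_units, x$by_state[["floating"]], x$by_state[["assigned"]]))
  cat(sprintf("floating candidates awaiting assignment: %d\n",
              length(x$floating_candidates)))
  if (length(x$by_attribute)) {
    cat("attributes:\n")
    for (k in sort_bytes(names(x$by_attribute))) {
      tab <- x$by_attribute[[k]]
      cat(sprintf("  %-18s %s\n", k,
                  paste0(names(tab), "=", as.integer(tab), collapse = "  ")))
    }
  }
  if (length(x$rule_leaves)) {
    cat("context rules:\n")
    for (r in names(x$rule_leaves)) {
      cat(sprintf("  %-18s %s leaves\n", r,
                  ifelse(is.na(x$rule_leaves[[r]]), "?", x$rule_leaves[[r]])))
    }
  }
  invisible(x)
}

#' Report journal events since a point in time
#'
#' @param project A depot handle.
#' @param since `NULL` (everything), a `POSIXct`, or an ISO-8601 timestamp
#'   string; only events strictly after it are reported.
#' @return A `depot_changes_report`: list with `events` (data frame of
#'   `ts`, `actor`, `action`, `unit_id`), `by_action` counts, and
#'   `malformed` (count of unparseable journal lines, skipped with a
#'   warning).
#' @export
changes_report <- function(project, since = NULL) {
  events <- read_journal(project)
  malformed <- attr(events, "malformed") %||% 0L
  if (malformed > 0) {
    warning(malformed, " malformed journal line(s) skipped", call. = FALSE)
  }
  parse_ts <- function(s) {
    as.POSIXct(strptime(s, "%Y-%m-%dT%H:%M:%OS%z", tz = "UTC"))
  }
  if (!is.null(since)) {
    cutoff <- if (inherits(since, "POSIXt")) since else parse_ts(since)
    if (is.na(cutoff)) {
      stop_depot("depot_validation", paste0("cannot parse timestamp: ", since))
    }
    events <- Filter(function(ev) {
      ts <- parse_ts(ev$ts)
      !is.na(ts) && ts > cutoff
    }, events)
  }
  df <- data.frame(
    ts = vapply(events, function(e) e$ts %||% NA_character_, character(1)),
    actor = vapply(events, function(e) e$actor %||% NA_character_, character(1)),
    action = vapply(events, function(e) e$action %||% NA_character_, character(1)),
    unit_id = vapply(events, function(e) e$unit_id %||% NA_character_, character(1)),
    stringsAsFactors = FALSE)
  df <- df[order(df$ts, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(events = df,
                 by_action = if (nrow(df)) table(df$action) else table(character(0)),
                 malformed = malformed),
            class = "depot_changes_report")
}

#' @export
print.depot_changes_report <- function(x, ...) {
  cat("== recent changes ==\n")
  if (nrow(x$events) == 0) {
    cat("(no events in window)\n")
    return(invisible(x))
  }
  for (a in names(x$by_action)) {
    cat(sprintf("%s: %d\n", a, x$by_action[[a]]))
  }
  utils::head(x$events, 50) |> print.data.frame()
  invisible(x)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a report as a minimal standalone HTML document
#'
#' @param report A `depot_state_report` or `depot_changes_report`.
#' @return A single HTML string.
#' @export
report_html <- function(report) {
  row <- function(...) paste0("<tr>", paste0("<td>", html_escape(c(...)),
                                             "</td>", collapse = ""), "</tr>")
  if (inherits(report, "depot_state_report")) {
    rows <- c(
      row("units total", report$total_units),
      row("floating", report$by_state[["floating"]]),
      row("assigned", report$by_state[["assigned"]]),
      row("floating candidates", length(report$floating_candidates)),
      unlist(lapply(names(report$by_attribute), function(k) {
        tab <- report$by_attribute[[k]]
        row(k, paste0(names(tab), "=", as.integer(tab), collapse = " "))
      })))
    title <- "Depot state"
  } else if (inherits(report, "depot_changes_report")) {
    rows <- apply(report$events, 1, function(r)
      row(r[["ts"]], r[["action"]], r[["unit_id"]] %||% ""))
    title <- "Recent changes"
  } else {
    stop_depot("depot_validation", "unknown report type")
  }
  paste0("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"><title>",
         title, "</title></head>\n<body><h1>", title,
         "</h1>\n<table border=\"1\">\n",
         paste0(rows, collapse = "\n"), "\n</table></body></html>\n")
}
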