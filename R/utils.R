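# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

depot_now <- function() {
  format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z", tz = "UTC")
}

#' Normalize a metadata key
#'
#' Attribute keys are stored in a canonical form: upper case, with every
#' character outside `[A-Za-z0-9]` mapped to an underscore. This matches the
#' conventional spelling of keys such as `LABOR_STATE` or `HONEYBEE_ID`.
#'
#' @param keys Character vector of raw keys.
#' @return Character vector of normalized keys.
#' @examples
#' normalize_key(c("labor state", "Honeybee-ID"))
#' @export
normalize_key <- function(keys) {
  if (!is.character(keys)) stop("keys must be character", call. = FALSE)
  toupper(gsub("[^A-Za-z0-9]", "_", keys))
}

# A key is malformed when, after normalization, it contains no alphanumeric
# character at all (empty, or pure punctuation).
valid_key <- function(keys) {
  nzchar(keys) & grepl("[A-Z0-9]", normalize_key(keys))
}

# Bytewise (C locale) sort, stable across platforms and locales.
sort_bytes <- function(x) x[order(x, method = "radix")]

# Validate and coerce a conjunction-of-equalities filter to a named
# character vector with normalized keys. NULL / empty -> empty filter.
as_filter <- function(filter) {
  if (is.null(filter) || length(filter) == 0) {
    return(stats::setNames(character(0), character(0)))
  }
  if (is.list(filter)) filter <- unlist(filter)
  if (is.null(names(filter)) || any(!nzchar(names(filter)))) {
    stop("filter must be a named key=value vector", call. = FALSE)
  }
  stats::setNames(as.character(filter), normalize_key(names(filter)))
}

# Atomic file replacement: write to a sibling temp file, then rename.
write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp-", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop("atomic replace of ", path, " failed", call. = FALSE)
  }
  invisible(path)
}

# Minimal JSON-lines append (one compact object per line).
append_jsonl <- function(path, record) {
  line <- jsonlite::toJSON(record, auto_unbox = TRUE, null = "null")
  con <- file(path, open = "ab")
  on.exit(close(con), add = TRUE)
  writeLines(line, con, useBytes = TRUE)
  invisible(path)
}

read_jsonl <- function(path) {
  if (!file.exists(path)) return(list())
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  bad <- 0L
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(rec)) bad <- bad + 1L else out[[i]] <- rec
  }
  out <- out[!vapply(out, is.null, logical(1))]
  attr(out, "malformed") <- bad
  out
}

list_files_rel <- function(root) {
  files <- list.files(root, recursive = TRUE, all.files = TRUE, no.. = TRUE)
  sort_bytes(files[!dir.exists(file.path(root, files))])
}

stop_depot <- function(class, msg, ...) {
  stop(structure(class = c(class, "depot_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}
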