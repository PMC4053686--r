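# Content addressing of data units.
#
# A data unit is identified by a digest that is a pure function of its member
# files: SHA-256 of each member's bytes, then SHA-256 over the member lines
# "name \0 hex \n" sorted bytewise by name. Any change to a member's name or
# content, or adding/removing a member, changes the unit id; presentation
# order never does.

sha256_file <- function(path) {
  digest::digest(file = path, algo = "sha256")
}

sha256_raw <- function(bytes) {
  digest::digest(bytes, algo = "sha256", serialize = FALSE)
}

# unit id from parallel vectors of member names and content digests
unit_id_from_digests <- function(names, digests) {
  if (length(names) == 0) {
    stop_depot("depot_validation", "a data unit must have at least one member")
  }
  if (anyDuplicated(names)) {
    stop_depot("depot_validation", paste0(
      "duplicate member names: ",
      paste(unique(names[duplicated(names)]), collapse = ", ")))
  }
  ord <- order(names, method = "radix")
  blob <- unlist(lapply(ord, function(i) {
    c(charToRaw(enc2utf8(names[i])), as.raw(0L),
      charToRaw(tolower(digests[i])), as.raw(0x0aL))
  }))
  sha256_raw(blob)
}

#' Compute the content-addressed identifier of a data unit
#'
#' The unit id is deterministic and invariant to the order in which members
#' are presented: members are canonically sorted bytewise by name before
#' hashing. Each member contributes the SHA-256 of its bytes; the unit id is
#' the SHA-256 over the newline-terminated `name NUL hex` member lines.
#'
#' @param members A named list mapping member names to content (raw vectors
#'   or single character strings), or an unnamed character vector of file
#'   paths (member names default to the base names).
#' @param names Optional character vector of member names overriding the
#'   defaults when `members` is a vector of paths.
#' @return A 64-character lowercase hex string.
#' @examples
#' compute_unit_id(list(a = "hello", b = "world"))
#' @export
compute_unit_id <- function(members, names = NULL) {
  if (is.character(members)) {
    paths <- members
    nm <- names %||% basename(paths)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop_depot("depot_io", paste0("cannot read: ", paste(missing, collapse = ", ")))
    }
    return(unit_id_from_digests(nm, vapply(paths, sha256_file, character(1))))
  }
  if (!is.list(members)) {
    stop_depot("depot_validation", "members must be a named list or a vector of paths")
  }
  nm <- base::names(members)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop_depot("depot_validation", "every member needs a name")
  }
  digests <- vapply(members, function(content) {
    if (is.character(content)) content <- charToRaw(enc2utf8(content))
    if (!is.raw(content)) {
      stop_depot("depot_validation", "member content must be raw bytes or a string")
    }
    sha256_raw(content)
  }, character(1))
  unit_id_from_digests(nm, digests)
}
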