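# SWC neuron morphology: reading, validation, writing, summaries.
#
# Dialect: seven whitespace-separated columns per line
#   index type x y z radius parent
# with "#" comment lines and no required header. Coordinates and radii are
# in micrometres; parent is -1 for a root. Unknown type codes are accepted
# (usage in the wild varies); the parent pointers must form a forest.

#' Parse SWC neuron morphology text
#'
#' @param text SWC content as a single string or vector of lines.
#' @param file Alternatively, path of an SWC file.
#' @return A data frame of class `swc` with integer `index`, `type`,
#'   `parent` and numeric `x`, `y`, `z`, `radius`, one row per node, input
#'   order preserved. Structural problems (wrong column count, non-numeric
#'   fields, duplicate indices, dangling parents, cycles) raise validation
#'   errors naming the offending line numbers.
#' @export
parse_swc <- function(text = NULL, file = NULL) {
  if (is.null(text) && is.null(file)) {
    stop_depot("depot_validation", "either text or file must be given")
  }
  lines <- if (!is.null(file)) readLines(file, warn = FALSE)
           else unlist(strsplit(text, "\n", fixed = TRUE))
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]; lineno <- lineno[keep]
  if (!length(lines)) {
    return(structure(data.frame(index = integer(0), type = integer(0),
                                x = numeric(0), y = numeric(0), z = numeric(0),
                                radius = numeric(0), parent = integer(0)),
                     class = c("swc", "data.frame")))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  ncol_ok <- vapply(fields, length, integer(1)) == 7L
  if (any(!ncol_ok)) {
    stop_depot("depot_validation", paste0(
      "expected 7 columns at line(s) ",
      paste(lineno[!ncol_ok], collapse = ", ")))
  }
  mat <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE))
  bad_num <- lineno[apply(is.na(mat), 1, any)]
  if (length(bad_num)) {
    stop_depot("depot_validation", paste0(
      "non-numeric field at line(s) ", paste(bad_num, collapse = ", ")))
  }
  nodes <- data.frame(index = as.integer(mat[, 1]), type = as.integer(mat[, 2]),
                      x = mat[, 3], y = mat[, 4], z = mat[, 5],
                      radius = mat[, 6], parent = as.integer(mat[, 7]))
  dup <- duplicated(nodes$index)
  if (any(dup)) {
    stop_depot("depot_validation", paste0(
      "duplicate node index at line(s) ", paste(lineno[dup], collapse = ", ")))
  }
  dangling <- nodes$parent != -1L & !(nodes$parent %in% nodes$index)
  if (any(dangling)) {
    stop_depot("depot_validation", paste0(
      "dangling parent at line(s) ", paste(lineno[dangling], collapse = ", ")))
  }
  # cycle check: follow parent pointers; a forest never revisits a node
  pos <- match(nodes$parent, nodes$index)      # row of each node's parent
  color <- integer(nrow(nodes))                # 0 new, 1 in progress, 2 done
  for (start in seq_len(nrow(nodes))) {
    i <- start; trail <- integer(0)
    while (!is.na(i) && color[i] == 0L) {
      color[i] <- 1L; trail <- c(trail, i); i <- pos[i]
    }
    if (!is.na(i) && color[i] == 1L) {
      stop_depot("depot_validation", paste0(
        "cycle in parent pointers involving line(s) ",
        paste(lineno[trail], collapse = ", ")))
    }
    color[trail] <- 2L
  }
  structure(nodes, class = c("swc", "data.frame"))
}

#' Write SWC nodes to a file
#'
#' @param nodes An `swc` data frame (as from [parse_swc()]).
#' @param file Output path.
#' @return The path, invisibly. Numeric columns are written with full
#'   precision, so `parse -> write -> parse` is the identity.
#' @export
write_swc <- function(nodes, file) {
  lines <- sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                   nodes$index, nodes$type, nodes$x, nodes$y, nodes$z,
                   nodes$radius, nodes$parent)
  writeLines(lines, file)
  invisible(file)
}

#' Summary statistics of an SWC morphology
#'
#' @param nodes An `swc` data frame.
#' @return Named list: `N_NODES` (node count), `N_TREES` (roots, parent ==
#'   -1), `N_BRANCH_POINTS` (nodes with at least two children) and
#'   `TOTAL_LENGTH` (sum of parent--child Euclidean distances, micrometres).
#'   An empty node list yields the all-zero summary.
#' @examples
#' swc_summary(parse_swc("1 1 0 0 0 1 -1\n2 3 0 0 3 0.5 1\n3 3 0 4 0 0.5 1"))
#' @export
swc_summary <- function(nodes) {
  if (nrow(nodes) == 0) {
    return(list(N_NODES = 0L, N_TREES = 0L, N_BRANCH_POINTS = 0L,
                TOTAL_LENGTH = 0))
  }
  child <- nodes$parent != -1L
  parent_row <- match(nodes$parent[child], nodes$index)
  seg <- sqrt((nodes$x[child] - nodes$x[parent_row])^2 +
              (nodes$y[child] - nodes$y[parent_row])^2 +
              (nodes$z[child] - nodes$z[parent_row])^2)
  kids <- table(factor(nodes$parent[child], levels = nodes$index))
  list(N_NODES = nrow(nodes),
       N_TREES = sum(!child),
       N_BRANCH_POINTS = sum(kids >= 2L),
       TOTAL_LENGTH = sum(seg))
}

#' Metadata-extraction hook for SWC morphologies
#'
#' A ready-made `on_assign` hook body: parses the unit's `.swc` member and
#' returns the [swc_summary()] statistics as extra attributes (merged onto
#' the unit as `HOOK_<NAME>_N_NODES` etc.).
#'
#' @param files Named character vector of the unit's stored file paths.
#' @param attributes Named character vector of the unit's attributes
#'   (unused, part of the hook signature).
#' @return Named list of summary attributes, or NULL when the unit holds no
#'   SWC member.
#' @export
swc_extract_hook <- function(files, attributes = NULL) {
  swc <- files[endsWith(tolower(names(files)), ".swc")]
  if (!length(swc)) return(NULL)
  s <- swc_summary(parse_swc(file = swc[[1]]))
  list(N_NODES = s$N_NODES, N_TREES = s$N_TREES,
       N_BRANCH_POINTS = s$N_BRANCH_POINTS,
       TOTAL_LENGTH = format(s$TOTAL_LENGTH, digits = 10))
}
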