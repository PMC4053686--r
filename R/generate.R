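# Seeded synthetic-project generator.
#
# Emulates the data kinds of a multi-animal insect-neuroscience project so
# the whole pipeline is testable without any download: per honeybee, a
# multi-file confocal-style image stack (tiny valid single-page TIFFs), a
# generated SWC morphology (as if produced by a segmentation run), and an
# opaque electrophysiology trace blob, together with per-unit attribute
# sidecar sheets and a ground-truth ledger of every expected unit,
# attribute, and provenance edge. Fully reproducible from the seed.

#' Specify a synthetic project
#'
#' @param n_bees Number of animals (>= 1). Each bee receives one labor
#'   state and one brain region, cycling through the value lists so the
#'   design is balanced.
#' @param labor_states,regions Non-empty value lists for the `LABOR_STATE`
#'   and `REGION` attributes.
#' @param stack_files_per_bee Number of image files per stack (>= 1).
#' @param swc_nodes_per_neuron Nodes per generated morphology (>= 1).
#' @param seed Integer seed; identical specs generate byte-identical output.
#' @param stack_payload `"tiff"` writes tiny valid single-page TIFFs,
#'   `"blob"` writes random bytes under `.tiff` names (projection logic is
#'   content-agnostic either way).
#' @return A validated `synthetic_project_spec` list.
#' @export
synthetic_project_spec <- function(n_bees = 5,
                                   labor_states = c("forager", "nurse"),
                                   regions = c("left-DL", "right-DL"),
                                   stack_files_per_bee = 40,
                                   swc_nodes_per_neuron = 60,
                                   seed = 42,
                                   stack_payload = c("tiff", "blob")) {
  counts <- c(n_bees = n_bees, stack_files_per_bee = stack_files_per_bee,
              swc_nodes_per_neuron = swc_nodes_per_neuron)
  if (any(counts < 1)) {
    stop_depot("depot_validation", paste0(
      "counts must be >= 1: ", paste(names(counts)[counts < 1], collapse = ", ")))
  }
  if (!length(labor_states) || !length(regions)) {
    stop_depot("depot_validation", "value lists must be non-empty")
  }
  structure(list(n_bees = as.integer(n_bees),
                 labor_states = as.character(labor_states),
                 regions = as.character(regions),
                 stack_files_per_bee = as.integer(stack_files_per_bee),
                 swc_nodes_per_neuron = as.integer(swc_nodes_per_neuron),
                 seed = as.integer(seed),
                 stack_payload = match.arg(stack_payload)),
            class = "synthetic_project_spec")
}

# run code under a local RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a random SWC morphology
#'
#' A random rooted tree: each node attaches to a uniformly chosen earlier
#' node, with Gaussian coordinate steps. Useful as a property-test input.
#'
#' @param n_nodes Number of nodes (>= 1).
#' @param step Standard deviation of the coordinate increments
#'   (micrometres).
#' @return An `swc` data frame with one root.
#' @export
generate_swc <- function(n_nodes, step = 5) {
  n <- as.integer(n_nodes)
  parent <- c(-1L, if (n > 1)
    vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  xyz <- matrix(0, n, 3)
  for (i in seq_len(n)[-1]) {
    xyz[i, ] <- xyz[parent[i], ] + stats::rnorm(3, sd = step)
  }
  structure(data.frame(index = seq_len(n),
                       type = c(1L, rep(3L, n - 1L)),
                       x = round(xyz[, 1], 3), y = round(xyz[, 2], 3),
                       z = round(xyz[, 3], 3),
                       radius = round(stats::runif(n, 0.3, 1.5), 3),
                       parent = parent),
            class = c("swc", "data.frame"))
}

#' Generate a synthetic multi-bee project into a floating folder
#'
#' Writes, per bee, an image stack, an SWC morphology and a trace blob into
#' `floating_root`, one attribute sidecar sheet per expected unit under
#' `out_dir/sidecars/`, and the ground-truth ledger to `out_dir/ledger.json`.
#'
#' @param spec A [synthetic_project_spec()].
#' @param out_dir Directory for the ledger and sidecars (created; must not
#'   already contain a ledger).
#' @param floating_root Folder receiving the data files (defaults to
#'   `out_dir/floating`; must be empty) -- point it at a depot project's
#'   floating folder to feed the ingestion workflow directly.
#' @return The ledger, invisibly: list with `spec`, `units` (each with
#'   `key`, `kind`, `unit_id`, `bee`, `files`, `attributes`, `sidecar`) and
#'   `provenance` (expected stack -> SIGEN -> morphology edges).
#' @export
generate_project <- function(spec, out_dir,
                             floating_root = file.path(out_dir, "floating")) {
  stopifnot(inherits(spec, "synthetic_project_spec"))
  ledger_path <- file.path(out_dir, "ledger.json")
  if (file.exists(ledger_path)) {
    stop_depot("depot_validation", paste0(out_dir, " already holds a ledger"))
  }
  if (dir.exists(floating_root) &&
      length(list.files(floating_root, all.files = TRUE, no.. = TRUE))) {
    stop_depot("depot_validation", paste0(floating_root, " is not empty"))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(floating_root, recursive = TRUE, showWarnings = FALSE)
  sidecar_dir <- file.path(out_dir, "sidecars")
  dir.create(sidecar_dir, showWarnings = FALSE)

  units <- list()
  prov <- list()
  with_local_seed(spec$seed, {
    for (i in seq_len(spec$n_bees)) {
      bee <- sprintf("HB%06d", 130400L + i)
      labor <- spec$labor_states[(i - 1L) %% length(spec$labor_states) + 1L]
      region <- spec$regions[
        ((i - 1L) %/% length(spec$labor_states)) %% length(spec$regions) + 1L]
      age <- as.character(sample(5:30, 1))
      date <- sprintf("1305%02d", sample(1:28, 1))
      common <- list(HONEYBEE_ID = bee, LABOR_STATE = labor, AGE = age,
                     DATE = date)

      # image stack: numeric-suffix member files
      stack_files <- sprintf("%s_%s_%03d.tiff", bee, region,
                             seq_len(spec$stack_files_per_bee))
      for (f in stack_files) {
        path <- file.path(floating_root, f)
        if (spec$stack_payload == "tiff") {
          tiff::writeTIFF(matrix(stats::runif(16), 4, 4), path,
                          bits.per.sample = 8L)
        } else {
          writeBin(as.raw(sample(0:255, 64, replace = TRUE)), path)
        }
      }
      stack_attrs <- c(common, list(REGION = region, FORMAT = "TIFF_STACK"))
      stack_id <- compute_unit_id(file.path(floating_root, stack_files),
                                  names = stack_files)
      units[[length(units) + 1]] <- list(
        key = paste0(bee, "_stack"), kind = "stack", unit_id = stack_id,
        bee = bee, files = as.list(stack_files), attributes = stack_attrs)

      # morphology: one SWC file, as if segmented from the stack
      swc_file <- sprintf("%s_%s_morphology.swc", bee, region)
      nodes <- generate_swc(spec$swc_nodes_per_neuron)
      write_swc(nodes, file.path(floating_root, swc_file))
      swc_attrs <- c(common, list(REGION = region, FORMAT = "SWC",
                                  SIGEN_PARAMETERS = "D20V05C01S01"))
      swc_id <- compute_unit_id(file.path(floating_root, swc_file),
                                names = swc_file)
      units[[length(units) + 1]] <- list(
        key = paste0(bee, "_morphology"), kind = "swc", unit_id = swc_id,
        bee = bee, files = as.list(swc_file), attributes = swc_attrs,
        n_nodes = nrow(nodes))
      prov[[length(prov) + 1]] <- list(
        inputs = list(stack_id), process = "SIGEN",
        params = list(PARAMETERS = "D20V05C01S01"), output = swc_id)

      # electrophysiology trace: opaque blob
      trace_file <- sprintf("%s_trace.dat", bee)
      writeBin(as.raw(sample(0:255, 1024, replace = TRUE)),
               file.path(floating_root, trace_file))
      trace_attrs <- c(common, list(FORMAT = "TRACE"))
      trace_id <- compute_unit_id(file.path(floating_root, trace_file),
                                  names = trace_file)
      units[[length(units) + 1]] <- list(
        key = paste0(bee, "_trace"), kind = "trace", unit_id = trace_id,
        bee = bee, files = as.list(trace_file), attributes = trace_attrs)
    }
  })

  for (u in units) {
    sidecar <- file.path(sidecar_dir, paste0(u$key, ".csv"))
    utils::write.csv(
      data.frame(key = names(u$attributes),
                 value = unlist(u$attributes, use.names = FALSE),
                 stringsAsFactors = FALSE),
      sidecar, row.names = FALSE, quote = TRUE)
  }
  ledger <- list(spec = unclass(spec), units = units, provenance = prov)
  jsonlite::write_json(ledger, ledger_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(ledger)
}

#' Read a generator ledger back from disk
#' @param path Path of `ledger.json`.
#' @return The ledger list.
#' @export
read_ledger <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}
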