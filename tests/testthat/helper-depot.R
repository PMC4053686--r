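# Shared fixtures and independent oracles for the suite.

new_project <- function(config = list()) {
  root <- tempfile("depot-")
  depot_init(root, config = config)
}

# write small files and return their paths
write_files <- function(dir, contents) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, names(contents))
  for (i in seq_along(contents)) {
    content <- contents[[i]]
    if (is.raw(content)) writeBin(content, paths[i])
    else writeLines(content, paths[i])
  }
  paths
}

# ingest one tiny unit with given attributes; returns unit_id
quick_unit <- function(project, attrs, content = NULL, name = "payload.txt") {
  content <- content %||% paste0("unit-", paste(attrs, collapse = "-"), "-",
                                 sample.int(.Machine$integer.max, 1))
  paths <- write_files(tempfile("files-"), stats::setNames(list(content), name))
  unit <- ingest_unit(project, paths)
  if (length(attrs)) assign_metadata(project, unit$unit_id, as.list(attrs))
  unit$unit_id
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- independent oracles ---------------------------------------------------

# Reference implementation of the unit-id recipe using a different hashing
# library (openssl) and string construction than the package's digest-based
# implementation.
oracle_unit_id <- function(members) {
  hexes <- vapply(members, function(content) {
    if (is.character(content)) content <- charToRaw(content)
    paste(as.character(openssl::sha256(content)), collapse = "")
  }, character(1))
  nms <- names(members)
  ord <- order(nms, method = "radix")
  blob <- raw(0)
  for (i in ord) {
    blob <- c(blob, charToRaw(nms[i]), as.raw(0), charToRaw(hexes[i]),
              charToRaw("\n"))
  }
  paste(as.character(openssl::sha256(blob)), collapse = "")
}

# brute-force conjunctive query over the raw attribute table
oracle_query <- function(project, filter) {
  st <- datadepot:::depot_state(project)
  ids <- st$units$unit_id[st$units$state == "assigned"]
  keep <- vapply(ids, function(uid) {
    attrs <- datadepot:::unit_attributes(st, uid)
    all(vapply(seq_along(filter), function(i) {
      k <- names(filter)[i]
      k %in% names(attrs) && attrs[[k]] == filter[[i]]
    }, logical(1)))
  }, logical(1))
  sort(ids[keep], method = "radix")
}

# naive SWC summary: explicit per-node loops, no vectorization shared with
# the implementation
oracle_swc_summary <- function(nodes) {
  n_nodes <- nrow(nodes)
  n_trees <- 0L; total <- 0
  children <- integer(0)
  for (i in seq_len(n_nodes)) {
    p <- nodes$parent[i]
    if (p == -1) {
      n_trees <- n_trees + 1L
    } else {
      j <- which(nodes$index == p)
      total <- total + sqrt(sum((c(nodes$x[i], nodes$y[i], nodes$z[i]) -
                                 c(nodes$x[j], nodes$y[j], nodes$z[j]))^2))
      children <- c(children, p)
    }
  }
  n_branch <- sum(table(children) >= 2)
  list(N_NODES = n_nodes, N_TREES = n_trees,
       N_BRANCH_POINTS = as.integer(n_branch), TOTAL_LENGTH = total)
}

# independent walk of a projection target: managed leaf files, relative
# paths, bytewise sorted (excludes the manifest)
walk_target <- function(target_root) {
  files <- list.files(target_root, recursive = TRUE, all.files = TRUE,
                      no.. = TRUE)
  files <- files[files != ".projection.json"]
  sort(files[!dir.exists(file.path(target_root, files))], method = "radix")
}

# brute-force leaf entries (path, unit_id) of a rule over a project's
# state, computed from first principles (no tree machinery); collision
# handling is NOT applied here
oracle_rule_entries <- function(project, rule) {
  st <- datadepot:::depot_state(project)
  ids <- oracle_query(project, rule$filter)
  paths <- character(0); uids <- character(0)
  for (uid in ids) {
    attrs <- datadepot:::unit_attributes(st, uid)
    segs <- character(0)
    skip <- FALSE
    for (k in rule$grouping) {
      if (k %in% names(attrs)) {
        segs <- c(segs, sanitize_component(attrs[[k]]))
      } else if (rule$on_missing == "unassigned") {
        segs <- c(segs, "UNASSIGNED")
      } else {
        skip <- TRUE; break
      }
    }
    if (skip) next
    mem <- datadepot:::unit_members(st, uid)
    leaf <- rule$leaf_template
    leaf <- gsub("{UNIT_ID8}", substr(uid, 1, 8), leaf, fixed = TRUE)
    for (k in names(attrs)) {
      leaf <- gsub(paste0("{", k, "}"), attrs[[k]], leaf, fixed = TRUE)
    }
    prefix <- if (length(segs)) paste0(paste(segs, collapse = "/"), "/") else ""
    new <- if (grepl("{MEMBER_NAME}", rule$leaf_template, fixed = TRUE)) {
      paste0(prefix, vapply(mem$name, function(m)
        gsub("{MEMBER_NAME}", m, leaf, fixed = TRUE), character(1)))
    } else if (nrow(mem) == 1) {
      paste0(prefix, leaf)
    } else {
      paste0(prefix, leaf, "/", mem$name)
    }
    paths <- c(paths, new); uids <- c(uids, rep(uid, length(new)))
  }
  data.frame(path = paths, unit_id = uids, stringsAsFactors = FALSE)
}

# expected final on-disk paths after the suffix collision policy
oracle_final_paths <- function(entries) {
  dup <- entries$path %in% entries$path[duplicated(entries$path)]
  out <- entries$path
  out[dup] <- paste0(out[dup], "_", substr(entries$unit_id[dup], 1, 8))
  sort(out, method = "radix")
}

# a small random metadata graph for property tests: returns the project
# and the unit ids it created
random_graph <- function(n_units = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  project <- new_project()
  keys <- c("KIND", "ANIMAL", "SIDE", "STAGE")
  pools <- list(KIND = c("swc", "stack", "trace"),
                ANIMAL = sprintf("A%02d", 1:4),
                SIDE = c("left", "right"),
                STAGE = c("raw", "seg"))
  ids <- character(n_units)
  for (i in seq_len(n_units)) {
    present <- keys[stats::runif(4) < c(1, 0.95, 0.8, 0.8)]
    attrs <- stats::setNames(
      lapply(present, function(k) sample(pools[[k]], 1)), present)
    ids[i] <- quick_unit(project, attrs,
                         content = paste0("blob-", i, "-", sample.int(1e9, 1)))
  }
  list(project = project, unit_ids = ids, keys = keys, pools = pools)
}

random_rule <- function(g, name = "r") {
  grouping <- sample(g$keys, sample(0:3, 1))
  filt <- NULL
  if (stats::runif(1) < 0.5) {
    k <- sample(setdiff(g$keys, grouping), 1)
    filt <- stats::setNames(sample(g$pools[[k]], 1), k)
  }
  context_rule(name, filter = filt, grouping = grouping,
               leaf_template = "{MEMBER_NAME}", on_missing = "unassigned",
               on_collision = "suffix")
}
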