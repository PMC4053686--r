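# datadepot

A content-addressed store for multi-file research data units, organized by
a key–value metadata graph and *projected* on demand into any number of
directory hierarchies of links ("context trees"), with a watch-folder
ingestion workflow, pluggable processing hooks, provenance tracking, SWC
neuron-morphology support, and a command-line interface.

## Who this is for

Collaborations that pass large file-based datasets between labs — image
stacks, neuron reconstructions, electrophysiology traces — and that today
encode their metadata in hand-maintained folder names like
`forager/left_DL/HB130427/…`. That convention fixes one ordering of the
metadata forever and forces copies whenever a different grouping is needed.
`datadepot` keeps each data unit exactly once and derives every directory
layout from metadata instead.

## The model

* **Data unit** — an immutable group of one or more files produced by a
  single process, identified by a content hash:
  per member `h_i = SHA-256(bytes_i)`, and

  ```
  unit_id = SHA-256( sort_bytewise_by_name( name_i \0 hex(h_i) \n ) )
  ```

  The id is order-invariant, rename-sensitive, and byte-sensitive. The
  store is flat: `store/<unit_id>/<member>`.
* **Metadata graph** — single-valued `KEY=value` attributes per unit
  (keys normalized to `[A-Z0-9_]`), plus acyclic provenance edges
  *inputs → process(params) → output*; process parameters are materialized
  on the output unit as `<PROCESS>_<KEY>` attributes.
* **Context rule** — filter (conjunction of `KEY=value` facets) + ordered
  grouping keys + leaf-name template. A unit's **context path** is its
  grouping values in rule order; a rule is valid when unit → path is
  injective.
* **Projection** — the rule's tree materialized as links into the store
  (symlink/hardlink/copy), with a manifest enabling idempotent,
  minimal-diff refreshes: unchanged inputs mean zero filesystem
  operations.

## Worked example

Create a project, generate a small synthetic three-bee dataset into its
floating (inbox) folder, scan, assign from the generator's ground-truth
attributes, and project a morphology view:

```r
library(datadepot)

project <- depot_init("beeproj")
spec <- synthetic_project_spec(n_bees = 3, stack_files_per_bee = 4, seed = 42)
generate_project(spec, "gen", floating_root = "beeproj/floating")

cands <- scan_floating(project, settle_seconds = 0)
#> <floating candidate> 3bdd28e4c13c...  (stack, 4 file(s))
#> <floating candidate> e7c09b056276...  (single, 1 file(s))
#> ... (9 candidates: per bee one stack, one morphology, one trace)

led <- read_ledger("gen/ledger.json")
by_id <- setNames(led$units, vapply(led$units, `[[`, "", "unit_id"))
for (cand in cands)
  assign_candidate(project, cand, by_id[[cand$candidate_id]]$attributes)

alpha <- context_rule("morphology", filter = c(FORMAT = "SWC"),
  grouping = c("LABOR_STATE", "REGION", "HONEYBEE_ID", "SIGEN_PARAMETERS"),
  leaf_template = "morphology.swc")
build_tree(project, alpha)
#> <context tree> rule 'morphology': 3 leaves, 3 files
#>   forager/left-DL/HB130401/D20V05C01S01/morphology.swc
#>   forager/right-DL/HB130403/D20V05C01S01/morphology.swc
#>   nurse/left-DL/HB130402/D20V05C01S01/morphology.swc

materialize(project, alpha, "beeproj/views/morphology")
state_report(project)
#> == depot state ==
#> units: 9 total | 0 floating | 9 assigned
#> floating candidates awaiting assignment: 0
#> attributes:
#>   FORMAT             SWC=3  TIFF_STACK=3  TRACE=3
#>   HONEYBEE_ID        HB130401=3  HB130402=3  HB130403=3
#>   LABOR_STATE        forager=6  nurse=3
#>   ...
```

Each projected leaf is a link into the flat store: the same morphology can
simultaneously appear in a second view grouped `HONEYBEE_ID/REGION` without
copying a byte. Reordering the grouping keys reorders the hierarchy:
`c("HONEYBEE", "NEURON", "STAGE")` yields `HB123/NRN-1/segmentation/` while
`c("STAGE", "HONEYBEE", "NEURON")` yields `segmentation/HB123/NRN-1/`.

The same operations are available from a shell via the installed
`exec/depot` script (`depot init`, `scan`, `assign`, `project`, `verify`,
`report state|changes`, `provenance`, `rules check`), with exit codes 0 /
1 (validation findings) / 2 (usage) for scripting.

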