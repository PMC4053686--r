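---
title: "Content-addressed data units and context-tree projections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Content-addressed data units and context-tree projections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Collaborative experimental projects — the motivating case is a multi-lab
insect-neuroscience collaboration passing confocal image stacks, segmented
neuron morphologies (SWC files), and electrophysiology traces between
sites — usually organize files in deep directory trees whose folder names
*are* the metadata: `forager/left_DL/HB130427/...`. That convention is
familiar and tool-friendly, but it hard-codes one fixed ordering of the
metadata, so every analysis that needs a different grouping (by processing
stage first, by animal first, ...) needs a manual reorganization, and the
same file ends up copied into several trees.

`datadepot` inverts this. Files are grouped into immutable **data units**
held once in a flat, content-addressed store; all organization lives in a
key–value metadata graph; and any number of directory hierarchies —
**context trees** — are *projected* from the metadata on demand, as
hierarchies of links into the store. A projection is the filesystem
analogue of a materialized view in a relational database: cheap to rebuild,
safe to discard, always derivable from the authoritative tables.

## The model

### Data units and content addressing

A data unit is the atom of storage: one file or a set of files produced by
a single process (an image stack of *n* TIFF pages is one unit with *n*
members). Its identity is a pure function of its content:

* each member file contributes `h_i = SHA-256(bytes_i)`;
* the unit id is `SHA-256` over the member lines `name_i \0 hex(h_i) \n`,
  sorted bytewise by member name.

Sorting makes the id invariant to presentation order; including the names
makes renames identity-changing; the per-file digests make any byte flip
detectable. The store layout is simply `store/<unit_id>/<member_name>`,
flat at the top level. Re-ingesting identical content is a no-op
(deduplication), and `verify_store()` can always recompute every digest and
flag drift, orphan directories, and dangling metadata.

### The metadata graph

Attributes are single-valued `KEY = value` pairs per unit, with keys
normalized to `[A-Z0-9_]` (`labor state` → `LABOR_STATE`). Single-valuedness
is a deliberate restriction: context paths must be *functions* of a unit's
attributes, and a multi-valued key would make a unit's position in a tree
ambiguous. Where a genuinely multi-valued annotation is needed, suffixed
keys (`REGION_2`) keep the model functional.

Provenance is recorded as edges *inputs → process(params) → output*. The
induced graph over units must stay acyclic — an edge that would make a unit
its own ancestor is rejected with the offending path. Process parameters
are additionally materialized onto the output unit as
`<PROCESS>_<KEY>` attributes (a segmentation run with parameters
`D20V05C01S01` leaves `SIGEN_PARAMETERS = D20V05C01S01` on the produced
morphology), so that views can group by them like any other attribute.

### Context rules, paths, and trees

A **context rule** is a declarative view definition:

* a *filter* — a conjunction of `KEY = value` terms selecting the units the
  view covers (only equality terms: facets, not a query language);
* an ordered *grouping* list of attribute keys — each key becomes one
  directory level, in order, so permuting the grouping permutes the path
  segments identically (`HB123/NRN-1/segmentation/` versus
  `segmentation/HB123/NRN-1/`);
* a *leaf template* naming the unit inside the last level, with
  `{KEY}`, `{UNIT_ID8}` and `{MEMBER_NAME}` placeholders.

The **context path** of a unit under a rule is its ordered list of grouping
values plus the rendered leaf name. A rule is well formed over a graph only
when the map unit → path is injective; `validate_uniqueness()` reports every
collision group. Rules are expressible in YAML (in `.depot.yaml` or a
standalone file) and validated with field-level error paths.

### Projection

`materialize()` realizes the abstract tree under a target directory, with a
manifest (`.projection.json`) recording every managed entry plus a
fingerprint over all inputs (the rule, the selected units' attributes and
member digests, and the link mode). `refresh_projection()` therefore

* returns without touching the filesystem when the fingerprint is
  unchanged (a byte-level no-op, so folder-sync tools transfer nothing);
* otherwise applies a minimal diff — only entries whose path, unit, or
  member changed are removed or created; unchanged entries keep their
  mtimes;
* warns about, and never deletes, foreign files a user placed inside a
  target.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `settle_seconds` (scan) | 5 s | sync clients write incrementally; a file whose mtime is younger than the interval may still be in flight and is deferred to the next scan |
| `link_mode` | `auto` = symlink → hardlink → copy | symlinks are the cheapest faithful projection; hardlinks survive sync clients that dereference; copies work everywhere. All three produce identical logical content |
| `on_missing` (rule) | `UNASSIGNED` bucket + warning | keeps projections total: a unit missing a grouping value stays visible instead of silently disappearing; `skip` and `fail` available |
| `on_collision` (rule) | `fail` | uniqueness of context paths is definitional; opting into `suffix` appends `_` + 8 hex of the unit id to colliding leaves |
| hook `timeout` | 30 s | hooks are advisory; a hung extraction script must never block assignment |
| stack grouping pattern | `^(.+?)[_-]([0-9]+)\.([A-Za-z0-9]+)$` | groups `stem_001.ext … stem_040.ext` sets; configurable per project |

## The ingestion workflow

New files land in a writable **floating folder** (an inbox, typically
populated by a sync client). `scan_floating()` groups its stable files into
candidates by fixed priority: a top-level subdirectory is one unit
regardless of naming; flat files sharing a stem with a numeric suffix form
one stack; everything else is a single-file unit. A candidate's provisional
id *is* the unit id its files would receive, so assignment can revalidate
cheaply: if anything changed since the scan, the candidate is stale and a
rescan is required.

`assign_candidate()` is atomic in the database sense. The state tables live
in one JSON document replaced via write-temp-then-rename, so there is a
single commit point; member files enter the store through a temp directory
and one rename. The journal (append-only JSON lines) brackets the operation
with `assign_begin` / `assign_commit`, and `depot_recover()` replays it
after a crash: an uncommitted assignment is rolled back (temp copies and
half-placed store directories removed, inbox untouched), a committed one is
rolled forward (attributes applied, leftover inbox originals removed). We
chose the single-document commit over an embedded relational database
precisely because it makes this crash contract auditable: there is exactly
one rename that flips the state, and everything before or after it is
re-derivable. The crash-safety tests drive assignment through deterministic
in-process abort points covering every step of that sequence; this models a
hard kill faithfully because the injected aborts bypass all in-process
cleanup.

Hooks plug into the workflow (`on_detect`, `on_assign`, `on_project`),
either as R functions or as external executables speaking JSON over
stdin/stdout. Returned attributes are merged under `HOOK_<NAME>_<KEY>` so a
hook can never clobber user metadata; failures and timeouts are journaled
and never propagate. The built-in `swc_extract_hook()` parses an assigned
morphology and contributes `N_NODES`, `N_TREES`, `N_BRANCH_POINTS`, and
`TOTAL_LENGTH` (the sum of parent–child Euclidean segment lengths, in
micrometres).

## The synthetic project generator

Because no public accessions exist for this kind of project layout, the
package ships a seeded generator (`generate_project()`) that emulates the
data shapes end to end: per bee, a multi-file image stack (tiny valid
single-page TIFFs), a random SWC morphology standing in for a segmentation
output, and an opaque trace blob, plus per-unit sidecar attribute sheets
(CSV) and a ground-truth ledger of every expected unit id, attribute, and
provenance edge. Defaults are five bees, two labor states and two brain
regions assigned cyclically (one cell per bee), forty files per stack, and
sixty SWC nodes — sizes chosen to mirror a realistic single-experiment batch
while keeping a full pipeline run in seconds. Output is byte-identical for
a fixed seed.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: TIFF payloads are 4×4 dummy pages, not confocal
volumes, so nothing about image content or size-dependent I/O is exercised;
SWC trees are random attachment trees, not biologically shaped arbors (only
the format and the summary statistics are meaningful); attribute sheets are
complete and correct by construction, whereas real metadata entry has gaps
and typos (the `UNASSIGNED` routing and stale-candidate paths are tested
separately, not by the generator); and sync-client behavior (partial
writes, conflicts) is reduced to the mtime settle heuristic.

## Numerical and representational choices

* **Bytewise ordering everywhere.** Member names, tree siblings, and query
  results are sorted with C-locale radix order, so ids and layouts are
  identical across platforms and locales.
* **Path sanitization** maps anything outside `[A-Za-z0-9._-]` to `_`,
  escapes empty values and `.`/`..`, and appends an 8-hex digest of the
  original value only when two *distinct* values would otherwise coincide —
  deterministic, and injective over any value set. Values are otherwise
  taken verbatim: `left_DL` and `left-DL` are different values and are not
  conflated.
* **Fingerprints** hash the rule together with the sorted relevant
  attribute and member rows, so refresh no-op detection is exact: the
  fingerprint changes iff an input to the projection changed.
* **Degenerate inputs** are defined, not accidental: an empty grouping
  places leaves at the projection root; an empty filter selects all
  assigned units; an empty floating folder scans to zero candidates; an
  empty SWC file summarizes to zeros.
* **Timestamps** are ISO-8601 UTC strings in state and journal; reports
  parse rather than string-compare them.

## Problem sizes in the shipped tests

The suite exercises: 200 random (graph, rule) projection instances checked
against a brute-force path oracle; 100 random units against an independent
implementation of the hash recipe (different hashing library, different
string construction); 100 random morphologies against a loop-based summary
reference; 20 randomized crash-injection points; and one full pipeline at
the default generator conditions (5 bees × 40 stack files). These sizes
keep the whole suite under half a minute while giving the property checks
enough variety to hit collisions, missing values, and empty-filter edge
cases.

## Known limitations

* Single-writer: the state document and journal assume one process mutates
  a project at a time (concurrent assigns of the same candidate are safe —
  one wins, the other is stale — but there is no cross-process lock).
* The projection is a concrete link tree, not a mounted virtual
  filesystem; a consumer that resolves symlinks and *writes* through them
  is stopped only by the read-only enforcement and, failing that, detected
  by `verify_store()`.
* Attributes are unit-level only. Entity-level metadata (facts about an
  animal rather than about one unit) must currently be repeated on each
  unit; an entity layer would be an extension, not a reinterpretation.
* The filter language is conjunctive equality only — by design, matching
  what directory facets can express.
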