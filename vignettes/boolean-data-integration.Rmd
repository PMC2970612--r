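---
title: "Boolean integration of annotation tables with alias resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boolean integration of annotation tables with alias resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolmerge)
```

## The data model

`boolmerge` treats every input as a spreadsheet-like table: a header
row, one column designated the *touch point* (the identifier column
used to map rows of one table to rows of another), and arbitrary
attribute columns carried along as uninterpreted string payload. No
type inference is performed — the algebra operates only on
identifiers. Duplicate identifier values across rows are legal; a gene
may carry several annotation rows, and merging aggregates them.

Cell values are whitespace-trimmed when a dataset is constructed.
This is a deliberate model property rather than a parsing detail: it
makes the write/read round trip exact for every valid dataset
(including cells containing the delimiter or quotes, which are written
with RFC-style quoting), while still tolerating the stray padding that
spreadsheet copy-paste produces. TSV is the canonical dialect; CSV is
accepted with the same quoting rules.

## Fingerprints and hash keys

The identifier problem — one entity, many names — is addressed without
any semantic cross-reference database. Instead, an identifier may be
registered against a *fingerprint*: content that defines the entity's
identity independent of naming, such as a protein's sequence, a
compound's formula, or a URI. Fingerprints are canonicalized first
(sequences: all whitespace removed, upper-cased; formulas, URIs and
opaque text: surrounding whitespace trimmed), then digested.

The digest is a 160-bit value rendered as exactly 40 lower-case
hexadecimal characters, computed over the UTF-8 bytes of the canonical
text. The default function is SHA-1, the standard 160-bit hash; a
`"sha2-truncated"` option (SHA-256 truncated to its leading 160 bits)
is provided for users who prefer a SHA-2 primitive, and the choice is
fixed per registry so all keys in one registry are comparable. The
fingerprint *kind* is deliberately not mixed into the digest: two
identical canonical texts registered under different kinds make the
same identity claim, and should collide. Collision of *distinct*
fingerprints is cryptographically negligible at 160 bits; the test
suite includes an injectivity smoke test over random fingerprints
(a sanity check, not a proof).

The registry is a many-to-many relation: one identifier may hold
several keys (a gene whose aliases point to multiple protein
variants), and one key several identifiers (synonymous accessions
sharing a sequence). Looking up an unregistered identifier returns the
empty key set rather than an error — such identifiers still
participate in consolidation through exact string matches.

## Consolidation into entity groups

Before any Boolean step, all identifiers across the queried datasets
are partitioned into *entity groups*. Two identifiers are linked when

* their strings are equal under the configured case rule
  (case-sensitive by default; a global case-insensitive option exists
  for symbol-case conventions), or
* their resolved key sets share at least one hash key,

and groups are the connected components of this link relation — that
is, pairwise links are closed transitively. The transitive reading
matters: two protein variants with distinct sequence keys share no key
with each other, yet both share a key with a gene-parent identifier
registered against both sequences, so all three (and their external
aliases) merge into one entity. A clique reading ("one key shared by
every member") would never merge the variants and is inconsistent with
that behavior, which is why the component reading was chosen.

Registry entries whose identifiers appear in no queried dataset do
**not** create links: otherwise a gene-parent entry sitting in the
registry would merge its variants even when no dataset mentions the
parent, and a variants-only consolidation would stop distinguishing
them. Such registry-only identifiers are instead attached passively to
a group as extra members (aliases in the output) when their keys
intersect the group's key set. In the pathological case of a
registry-only identifier whose keys span two distinct groups, the
alias is attached to each group it touches; since such aliases never
drive merging, the partition of dataset identifiers is unaffected.

Group ids are assigned by first appearance (dataset order, then row
order) and are presentation-only; group identity across operations is
carried by the member and key sets. Internally components are computed
on the identifier–key bipartite graph, which is equivalent to the
pairwise shared-key graph but avoids materializing per-key cliques;
the test suite checks this equivalence against a brute-force
transitive-closure oracle on random instances.

## The query algebra

Queries are strings over dataset names and three operators, parsed by
a recursive-descent parser with this precedence (tightest first):

1. parenthesized groups,
2. `-` — NOT, the left-relative complement (`A - B`: entities of `A`
   not in `B`); no universal set exists, so complement is always
   relative,
3. `+` — AND, intersection,
4. `U` — OR, union,

with runs of the same operator associating left-to-right, in the order
they appear. `U` is a reserved word; a dataset actually named `U`, or
containing spaces or operator characters, is written double-quoted.
Unknown dataset names are rejected at parse time with a position.

Evaluation consolidates **once**, globally, over every dataset the
query references, then folds the expression tree bottom-up on sets of
group ids: a group survives `A + B` when it has at least one row in
both operands, `A U B` with a row in either, `A - B` with a row in the
left and none in the right. Consolidating globally rather than
pairwise per operation keeps results independent of the parse shape —
`A + B` and `B + A` yield the same entities — which is what the
Boolean operator names promise. A strictly pairwise
match-until-exhausted loop reaches the same fixed point for the
operations supported here; the global formulation is simply the
order-free statement of that result.

The merged output has one row per surviving group: `id` (the group's
first-appearing member), `aliases` (all members, sorted, `;`-joined),
then each source dataset's attribute columns prefixed
`<dataset>.<column>` in dataset order. Groups spanning several rows of
one dataset aggregate cell values in row order with `"; "`
(configurable); groups absent from a union operand leave that
dataset's cells empty. An empty result is a legal answer — an empty
intersection is science, not an error — and the CLI exits 0 on it.

`switch_touch_point()` re-keys a table on another column (dropping,
with a reported count, rows whose new identifier cell is empty), so a
merge keyed on drugs can be re-keyed on targets and chained into a
further round of comparisons.

## The synthetic fixture generator

`fixture_spec()` / `generate_fixtures()` produce seeded families of
datasets for verification: `n_datasets` TSV tables of
`ids_per_dataset` rows, a shared pool of
`floor(overlap_fraction * ids_per_dataset)` identifiers present in
every dataset, per-dataset unique identifiers elsewhere, one random
attribute column, and `alias_families` gene-parent families (variants
`FAM0001-PA`, `FAM0001-PB`, … with random 60-mer sequence
fingerprints, one external alias per variant, and the parent
registered with every variant's fingerprint). Variants are placed in
the first dataset and parents in the second, so a two-dataset
intersection exercises exactly the variants-separate / parent-merges
behavior. The manifest records the expected chained-intersection sizes
(with and without aliasing) and the total combined identifier count;
the same spec and seed always regenerate byte-identical files.

What the generator emulates is the *shape* of multi-dataset gene-list
integration — controlled overlap, alias networks, benchmark scale —
not the content of real data: identifiers are synthetic tokens,
sequences are random, and attribute values are meaningless. Passing
tests therefore demonstrate the correctness of the algebra and the
alias machinery, not the biological validity of any particular merged
result, and real curated datasets (with their messier alias networks
and inconsistent capitalization) remain the user's responsibility to
inspect.

## Problem sizes and numerical choices

The verification suite runs at sizes chosen to exercise the contracts
thoroughly while staying comfortable on a single CPU: the brute-force
oracle comparisons use 1,000 random instances of up to 5 datasets and
50 identifiers each (the oracle is quadratic and would not scale
further, which is exactly why it is trustworthy); the algebraic
identity suite uses 100 seeded fixtures; the scale check generates the
benchmark shape of 10 datasets × 20,000 identifiers (200,000 combined)
and evaluates the 10-way chained intersection, asserting completion
and the exact expected intersection size. Absolute runtimes are
hardware-dependent and are not asserted beyond generous bounds.

Ties and ordering are everywhere resolved by first appearance (dataset
order, then row order), which makes every operation deterministic
given its inputs; the only randomness in the package is the fixture
generator's, and it is fully governed by the spec seed.

## Known limitations

* Alias matching is exact (string or key); no fuzzy, probabilistic or
  ontology-aware matching.
* The in-memory model targets desk-scale tables (hundreds of thousands
  of rows), not multi-GB streaming inputs.
* Registry-only identifiers never bridge groups (see above); users who
  want bridge behavior must include the bridging identifiers in a
  dataset.
* The workspace is single-user and local; no sharing, accounts, or
  server components.
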