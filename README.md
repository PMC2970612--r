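# boolmerge

Boolean integration of heterogeneous annotation tables with
fingerprint-hash alias resolution.

## The problem

Biological datasets name the same entity in different ways: a gene
symbol in one table, an Ensembl accession in another, a protein-variant
ID in a third. Naively intersecting such tables on identifier strings
misses every match that crosses a nomenclature boundary. `boolmerge`
merges tabular datasets (gene lists, expression tables, drug–target
maps — any table with a designated identifier column, the *touch
point*) with Boolean set algebra computed over *entity groups* rather
than raw strings, so differently-named rows for the same entity meet.

The model, in brief:

1. **Fingerprint hash keys.** An identifier may be registered against a
   *fingerprint* — content that defines identity independent of naming:
   a sequence, a chemical formula, a URI. Each fingerprint is
   canonicalized and digested to a 160-bit hash rendered as 40
   hexadecimal characters (default SHA-1; a truncated SHA-2 digest is
   available). Equal keys assert identity; the key is a non-semantic
   identifier of arbitrary-length content.
2. **Consolidation.** All identifiers across the queried datasets are
   partitioned into entity groups: two identifiers belong together when
   their strings match exactly (case-sensitive by default) or their
   resolved key sets share a hash key, and this pairwise relation is
   closed transitively (connected components). Two protein variants
   with distinct sequence keys stay separate — until a gene-parent
   identifier registered with both sequences bridges them, at which
   point the entire group merges.
3. **Boolean algebra over groups.** A query such as
   `A - B + (C U D)` is parsed with the precedence
   *parentheses* > `-` (NOT, left-relative subtraction) > `+` (AND,
   intersection) > `U` (OR, union), same-operator runs associating
   left-to-right. Each operation keeps or drops whole entity groups by
   their row presence in the operand datasets; because consolidation is
   global, `+` and `U` are commutative.

## Worked example

Two protein variants, each with an external database alias, and a gene
parent whose aliases point at both variant sequences:

```r
library(boolmerge)

reg <- alias_registry()
reg <- register_alias(reg,
  c("CG6995-PA", "FPpp00084077", "CG6995-PC", "NP_001034066", "CG6995", "CG6995"),
  c("ATGAAA",    "ATGAAA",       "ATGCCC",    "ATGCCC",       "ATGAAA", "ATGCCC"))

variants <- bm_dataset(data.frame(id = c("CG6995-PA", "CG6995-PC")), "variants")
parents  <- bm_dataset(data.frame(id = "CG6995"), "parents")

consolidate(list(variants), reg)$n_groups
#> [1] 2            # distinct sequence keys: kept separate

res <- evaluate_query("variants + parents", list(variants = variants, parents = parents), reg)
res
#> <bm_merge_result> query (variants + parents): 1 surviving entity groups
res$dataset$table
#>          id                                              aliases
#> 1 CG6995-PA CG6995;CG6995-PA;CG6995-PC;FPpp00084077;NP_001034066
```

Alone, the variants consolidate into 2 groups; intersected with the
gene-parent list the whole family merges into a single entity whose
`aliases` column records every member name. Attribute columns of the
inputs would appear as `variants.<col>` / `parents.<col>`, aggregated
with `"; "` when a group spans several rows.

`switch_touch_point()` re-keys a result on a different column (say,
drug → target) so it can feed a further chain of Boolean comparisons,
and `generate_fixtures()` builds seeded synthetic dataset families with
controlled overlap and alias networks for verification.

The same operations are available from the shell via the installed
`exec/boolmerge` script (or `run_cli()`):

```sh
boolmerge import genes.tsv --name A
boolmerge alias-load aliases.tsv
boolmerge query "A + B" --out merged.tsv
```

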