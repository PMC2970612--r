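test_that("exact string matches group identifiers without any registry", {
  A <- mk_ds("A", c("TP53", "BRCA1"))
  B <- mk_ds("B", c("TP53", "EGFR"))
  cons <- consolidate(list(A, B))
  expect_equal(cons$n_groups, 3L)
  # degenerate equivalence: groups are exactly the distinct strings
  expect_setequal(unlist(cons$members), c("TP53", "BRCA1", "EGFR"))
  expect_true(all(lengths(cons$members) == 1L))
})

test_that("protein variants with distinct sequence keys stay separate until the gene parent bridges them", {
  reg <- variant_family_registry()
  variants <- mk_ds("variants", c("CG6995-PA", "CG6995-PC"))
  parents <- mk_ds("parents", "CG6995")

  # variants alone: different unique sequence keys, kept separate
  c1 <- consolidate(list(variants), reg)
  expect_equal(c1$n_groups, 2L)

  # gene parent holds both variants' keys: the entire group merges
  c2 <- consolidate(list(variants, parents), reg)
  expect_equal(c2$n_groups, 1L)
  expect_true(all(c("CG6995", "CG6995-PA", "CG6995-PC",
                    "FPpp00084077", "NP_001034066") %in% c2$members[[1L]]))

  # entity graph view: no PA--PC edge without the parent, connected with it
  g1 <- build_entity_graph(list(variants), reg)
  expect_equal(igraph::ecount(g1), 0)
  g2 <- build_entity_graph(list(variants, parents), reg)
  expect_equal(igraph::components(g2)$no, 1)
})

test_that("pairwise key sharing closes transitively (chain with no key common to all)", {
  # a--k1--b, b--k2--c: no key common to all three, one group anyway
  reg <- alias_registry()
  reg <- register_alias(reg, c("a", "b", "b", "c"), c("k1", "k1", "k2", "k2"),
                        kind = "opaque")
  cons <- consolidate(list(mk_ds("D", c("a", "b", "c"))), reg)
  expect_equal(cons$n_groups, 1L)
  expect_identical(
    oracle_partition(list(c("a", "b", "c")), list(a = "k1", b = c("k1", "k2"), c = "k2")),
    list(c("a", "b", "c")))
})

test_that("consolidation is a partition, invariant under dataset and row permutations", {
  inst <- random_instance(101)
  base <- consolidate(inst$datasets, inst$registry)
  # every dataset identifier in exactly one group
  all_ids <- unique(unlist(inst$ids_by))
  counts <- vapply(all_ids, function(id)
    sum(vapply(base$members, function(m) id %in% m, logical(1))), integer(1))
  expect_true(all(counts == 1L))

  for (s in 1:5) {
    set.seed(s)
    perm <- sample(length(inst$datasets))
    shuffled <- lapply(inst$datasets[perm], function(d) {
      d$table <- d$table[sample(nrow(d$table)), , drop = FALSE]
      rownames(d$table) <- NULL
      d
    })
    alt <- consolidate(shuffled, inst$registry)
    norm <- function(cons) {
      x <- lapply(cons$members, sort)
      x[order(vapply(x, `[[`, character(1), 1L))]
    }
    expect_identical(norm(alt), norm(base))
  }
})

test_that("consolidation matches the brute-force transitive-closure oracle on random instances", {
  for (seed in 1:100) {
    inst <- random_instance(seed)
    cons <- consolidate(inst$datasets, inst$registry)
    got <- engine_group_sets(cons$members, inst$ids_by)
    want <- oracle_partition(inst$ids_by, inst$reg_map)
    expect_identical(got, want)
  }
})

test_that("case-insensitive mode merges case variants; default keeps them distinct", {
  A <- mk_ds("A", c("TP53", "tp53"))
  expect_equal(consolidate(list(A))$n_groups, 2L)
  ci <- consolidate(list(A), case_insensitive = TRUE)
  expect_equal(ci$n_groups, 1L)
  expect_setequal(ci$members[[1L]], c("TP53", "tp53"))
})

test_that("group export lists members and keys per group", {
  reg <- variant_family_registry()
  cons <- consolidate(list(mk_ds("v", c("CG6995-PA", "CG6995-PC")),
                           mk_ds("p", "CG6995")), reg)
  out <- export_groups(cons)
  expect_equal(nrow(out), 1L)
  expect_match(out$members, "CG6995-PA")
  expect_equal(length(strsplit(out$keys, ";")[[1L]]), 2L)
  p <- withr::local_tempfile(fileext = ".tsv")
  export_groups(cons, p)
  expect_true(file.exists(p))
})
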