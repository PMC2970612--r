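test_that("parser honors precedence: parens, then -, then +, then U, left-associative", {
  known <- c("A", "B", "C", "D")
  shape <- function(q) format(parse_query(q, known))
  expect_equal(shape("A - B + C"), "((A - B) + C)")     # NOT binds before AND
  expect_equal(shape("A + B U C"), "((A + B) U C)")     # AND binds before OR
  expect_equal(shape("A - B - C"), "((A - B) - C)")     # same operator: order of appearance
  expect_equal(shape("A + B + C"), "((A + B) + C)")
  expect_equal(shape("A U B U C"), "((A U B) U C)")
  expect_equal(shape("A + (B U C)"), "(A + (B U C))")   # parens override
  expect_equal(shape("A U B - C + D"), "(A U ((B - C) + D))")
  expect_equal(shape("(A U B) - C"), "((A U B) - C)")
})

test_that("parser handles quoted names and reports positions for malformed queries", {
  expect_equal(format(parse_query('"my set" + B', c("my set", "B"))), "(my set + B)")
  # a dataset literally named "U" must be quoted; bare U is the union operator
  expect_equal(format(parse_query('"U" U B', c("U", "B"))), "(U U B)")
  expect_error(parse_query("A + (B U C", c("A", "B", "C")), "unbalanced parenthesis")
  expect_error(parse_query("A +", c("A")), "dangling operator")
  expect_error(parse_query("A + + B", c("A", "B")), "unexpected '\\+' at position 5")
  expect_error(parse_query("A + X", c("A", "B")), "unknown dataset name 'X' at position 5")
  expect_error(parse_query("A ) B", c("A", "B")), "position")
  expect_error(parse_query("", c("A")), "non-empty")
})

test_that("evaluate implements plain set algebra on exact strings without aliases", {
  A <- mk_ds("A", c("x", "y"))
  B <- mk_ds("B", c("y", "z"))
  ds <- list(A = A, B = B)
  expect_equal(evaluate_query("A + B", ds)$n_groups, 1L)
  expect_equal(evaluate_query("A U B", ds)$n_groups, 3L)
  expect_equal(evaluate_query("A - B", ds)$n_groups, 1L)
  expect_equal(evaluate_query("A - B", ds)$dataset$table$id, "x")
  # intersection with an empty dataset is empty, and legal
  E <- bm_dataset(data.frame(id = character(0)), "E")
  r <- evaluate_query("A + E", list(A = A, E = E))
  expect_equal(r$n_groups, 0L)
  expect_equal(nrow(r$dataset$table), 0L)
})

test_that("alias resolution merges a variant list with its gene parent during evaluation", {
  reg <- variant_family_registry()
  A <- mk_ds("A", c("CG6995-PA", "CG6995-PC"))
  B <- mk_ds("B", "CG6995")
  r <- evaluate_query("A + B", list(A = A, B = B), reg)
  expect_equal(r$n_groups, 1L)
  expect_setequal(strsplit(r$dataset$table$aliases, ";")[[1L]],
                  c("CG6995", "CG6995-PA", "CG6995-PC",
                    "FPpp00084077", "NP_001034066"))
  # with aliases off the same query is a plain string intersection: empty
  expect_equal(evaluate_query("A + B", list(A = A, B = B), reg,
                              use_aliases = FALSE)$n_groups, 0L)
})

test_that("evaluation agrees with the canonicalize-then-set-algebra oracle on random instances", {
  for (seed in 1:100) {
    inst <- random_instance(seed)
    q <- random_query(names(inst$datasets))
    expr <- parse_query(q, names(inst$datasets))
    res <- evaluate_query(expr, inst$datasets, inst$registry)
    # the engine consolidates over the datasets the query references,
    # so the oracle must see the same universe
    ids_by <- inst$ids_by[query_refs(expr)]
    got <- engine_group_sets(res$members, ids_by)
    want <- oracle_evaluate(expr, ids_by, inst$reg_map)
    expect_identical(got, want)
  }
})

test_that("group-set algebra satisfies idempotence, annihilation and commutativity", {
  # group identity is carried by member sets, not group_id integers,
  # so results from differently-ordered queries are compared as
  # canonical sets of member sets
  sets_of <- function(res, inst)
    engine_group_sets(res$members, inst$ids_by)
  for (seed in 1:25) {
    inst <- random_instance(seed)
    ds <- inst$datasets
    reg <- inst$registry
    ev <- function(q) evaluate_query(q, ds, reg)
    a <- names(ds)[[1L]]; b <- names(ds)[[2L]]

    expect_identical(ev(sprintf("%s + %s", a, a))$group_ids, ev(a)$group_ids)  # A + A = A
    expect_identical(ev(sprintf("%s U %s", a, a))$group_ids, ev(a)$group_ids)  # A U A = A
    expect_equal(ev(sprintf("%s - %s", a, a))$n_groups, 0L)                    # A - A = empty
    expect_identical(sets_of(ev(sprintf("%s + %s", a, b)), inst),
                     sets_of(ev(sprintf("%s + %s", b, a)), inst))
    expect_identical(sets_of(ev(sprintf("%s U %s", a, b)), inst),
                     sets_of(ev(sprintf("%s U %s", b, a)), inst))

    # a group surviving A - B has, by construction, no row in B
    sub <- ev(sprintf("%s - %s", a, b))
    rows_b <- sub$consolidation$rows
    expect_length(intersect(sub$group_ids,
                            rows_b$group_id[rows_b$dataset == b]), 0L)

    # monotonicity within the joint consolidation universe
    uni <- ev(sprintf("%s U %s", a, b))
    rows <- uni$consolidation$rows
    pres_a <- unique(rows$group_id[rows$dataset == a])
    both <- ev(sprintf("%s + %s", a, b))
    expect_true(all(both$group_ids %in% pres_a))
    expect_true(all(pres_a %in% uni$group_ids))
  }
})

test_that("merged output has provenance schema with prefixed, aggregated attribute columns", {
  A <- mk_ds("A", c("x", "y", "y"), attr = c("a1", "a2", "a3"))
  B <- mk_ds("B", c("y", "z"), attr = c("b1", "b2"))
  r <- evaluate_query("A U B", list(A = A, B = B))
  tab <- r$dataset$table
  expect_equal(colnames(tab), c("id", "aliases", "A.attr", "B.attr"))
  expect_equal(tab$id, c("x", "y", "z"))                 # first-appearance order
  yrow <- tab[tab$id == "y", ]
  expect_equal(yrow$A.attr, "a2; a3")                    # multi-row aggregation in row order
  expect_equal(yrow$B.attr, "b1")
  expect_equal(tab[tab$id == "z", "A.attr"], "")         # absent operand leaves cells empty
  expect_equal(r$dataset$id_column, "id")
})

test_that("switch_touch_point re-keys a table and reports dropped rows", {
  drug <- bm_dataset(data.frame(drug = c("aspirin", "ibuprofen", "unknown"),
                                target = c("PTGS1", "PTGS2", "")),
                     "drugs", id_column = "drug")
  # identity switch: nothing changes, nothing dropped
  same <- suppressMessages(switch_touch_point(drug, "drug"))
  expect_identical(same$table, drug$table)
  expect_equal(attr(same, "dropped_rows"), 0L)
  # re-key on target: empty target rows are dropped with a count
  expect_message(sw <- switch_touch_point(drug, "target"), "dropped 1 row")
  expect_equal(sw$id_column, "target")
  expect_equal(identifiers(sw), c("PTGS1", "PTGS2"))
  expect_equal(attr(sw, "dropped_rows"), 1L)
  expect_error(switch_touch_point(drug, "nope"), "unknown column")
  expect_error(switch_touch_point(drug, "target", drop_empty = FALSE), "empty")
})
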