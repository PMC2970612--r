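# Brute-force oracles and random-instance builders, independent of the
# engine's igraph/bipartite implementation path.

# Quick dataset builder: identifiers plus one attribute column.
mk_ds <- function(name, ids, attr = NULL, id_column = "id") {
  tab <- data.frame(id = ids, stringsAsFactors = FALSE)
  if (!is.null(attr)) tab$attr <- attr
  names(tab)[1] <- id_column
  bm_dataset(tab, name = name, id_column = id_column)
}

# Figure-style two-variant alias registry: variants PA/PC with distinct
# sequence fingerprints, one external alias each, and a gene parent
# registered with both sequences.
variant_family_registry <- function() {
  reg <- alias_registry()
  register_alias(reg,
    c("CG6995-PA", "FPpp00084077", "CG6995-PC", "NP_001034066", "CG6995", "CG6995"),
    c("ATGAAA",    "ATGAAA",       "ATGCCC",    "ATGCCC",       "ATGAAA", "ATGCCC"))
}

# Transitive-closure partition oracle.  ids_by_dataset: list of
# character vectors.  reg_map: named list identifier -> character
# vector of abstract key labels.  Returns the partition of the
# (canonicalized) dataset identifiers as a sorted list of sorted
# member sets.  Merging rule: two groups merge when their key sets
# intersect; repeated until a fixed point (pairwise links closed
# transitively).
oracle_partition <- function(ids_by_dataset, reg_map = list(), case_insensitive = FALSE) {
  canon <- if (case_insensitive) tolower else identity
  ids <- unique(canon(unlist(ids_by_dataset, use.names = FALSE)))
  names(reg_map) <- canon(names(reg_map))
  groups <- lapply(ids, function(x) x)
  keyset <- function(g) unique(unlist(reg_map[g], use.names = FALSE))
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < length(groups)) {
      j <- i + 1L
      while (j <= length(groups)) {
        if (length(intersect(keyset(groups[[i]]), keyset(groups[[j]])))) {
          groups[[i]] <- c(groups[[i]], groups[[j]])
          groups[[j]] <- NULL
          merged <- TRUE
        } else j <- j + 1L
      }
      i <- i + 1L
    }
    if (!merged) break
  }
  out <- lapply(groups, function(g) sort(unique(g)))
  out[order(vapply(out, `[[`, character(1), 1L))]
}

# Canonicalize-then-naive-set-algebra oracle for query evaluation:
# every identifier is first replaced by its entity-group label (the
# lexicographically smallest member of its oracle partition group),
# then the expression is folded with plain set operations on label
# sets.  Returns the sorted list of sorted surviving member sets.
oracle_evaluate <- function(expr, ids_by_dataset, reg_map = list(),
                            case_insensitive = FALSE) {
  canon <- if (case_insensitive) tolower else identity
  part <- oracle_partition(ids_by_dataset, reg_map, case_insensitive)
  label_of <- list()
  for (g in part) for (m in g) label_of[[m]] <- g[[1L]]
  labels_in <- lapply(ids_by_dataset, function(ids)
    unique(unlist(label_of[unique(canon(ids))], use.names = FALSE)))
  fold <- function(e) {
    switch(e$op,
           ref = labels_in[[e$name]],
           not = setdiff(fold(e$left), fold(e$right)),
           and = intersect(fold(e$left), fold(e$right)),
           or  = union(fold(e$left), fold(e$right)))
  }
  surv <- fold(expr)
  out <- part[vapply(part, function(g) g[[1L]] %in% surv, logical(1))]
  out[order(vapply(out, `[[`, character(1), 1L))]
}

# Engine-side view comparable to the oracles: surviving groups as
# sorted sets of canonicalized *dataset* identifiers (registry-only
# attached aliases stripped).
engine_group_sets <- function(members_list, ids_by_dataset, case_insensitive = FALSE) {
  canon <- if (case_insensitive) tolower else identity
  ds_ids <- unique(canon(unlist(ids_by_dataset, use.names = FALSE)))
  out <- lapply(members_list, function(m) sort(unique(intersect(canon(m), ds_ids))))
  out[order(vapply(out, `[[`, character(1), 1L))]
}

# Random instance: <= 5 datasets of <= 50 identifiers drawn from a
# 30-token pool (so overlaps are common), plus <= 20 random alias
# entries over abstract fingerprints fp01..fp08; some alias
# identifiers never occur in any dataset.
random_instance <- function(seed) {
  set.seed(seed)
  nd <- sample(2:5, 1)
  pool <- sprintf("id%02d", 1:30)
  ids_by <- lapply(seq_len(nd), function(i)
    sample(pool, sample(1:50, 1), replace = TRUE))
  names(ids_by) <- paste0("D", seq_len(nd))
  n_ent <- sample(0:20, 1)
  ent_ids <- sample(c(pool, sprintf("ext%02d", 1:5)), max(n_ent, 1), replace = TRUE)[seq_len(n_ent)]
  ent_fps <- sample(sprintf("fp%02d", 1:8), max(n_ent, 1), replace = TRUE)[seq_len(n_ent)]
  reg <- alias_registry()
  if (n_ent > 0) reg <- register_alias(reg, ent_ids, ent_fps, kind = "opaque")
  reg_map <- if (n_ent > 0) lapply(split(ent_fps, ent_ids), unique) else list()
  datasets <- lapply(names(ids_by), function(nm) mk_ds(nm, ids_by[[nm]]))
  names(datasets) <- names(ids_by)
  list(datasets = datasets, ids_by = ids_by, registry = reg, reg_map = reg_map)
}

# Dataset names referenced by a parsed query, first-appearance order.
query_refs <- function(e) {
  if (e$op == "ref") return(e$name)
  unique(c(query_refs(e$left), query_refs(e$right)))
}

# Random query string over the instance's dataset names: a random
# binary tree of -, +, U with occasional parenthesized subtrees.
random_query <- function(ds_names, n_ops = NULL) {
  if (is.null(n_ops)) n_ops <- sample(1:4, 1)
  terms <- sample(ds_names, n_ops + 1L, replace = TRUE)
  expr <- terms[[1L]]
  for (k in seq_len(n_ops)) {
    op <- sample(c("-", "+", "U"), 1)
    rhs <- terms[[k + 1L]]
    expr <- if (stats::runif(1) < 0.3) sprintf("(%s %s %s)", expr, op, rhs)
            else sprintf("%s %s %s", expr, op, rhs)
  }
  expr
}
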