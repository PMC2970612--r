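# --- tokenizer -------------------------------------------------------------

# Token types: name, op (-, +, U), lparen, rparen.  Bare names are runs
# of letters, digits, '_' and '.'; anything else (spaces, operators,
# a dataset literally named "U") must be double-quoted.
.tokenize_query <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  toks <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[[i]]
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = if (ch == "(") "lparen" else "rparen",
                                        value = ch, pos = i)
      i <- i + 1L
    } else if (ch %in% c("-", "+")) {
      toks[[length(toks) + 1L]] <- list(type = "op", value = ch, pos = i)
      i <- i + 1L
    } else if (ch == "\"") {
      j <- i + 1L
      while (j <= n && chars[[j]] != "\"") j <- j + 1L
      if (j > n) stop(sprintf("query parse error: unterminated quote at position %d", i))
      toks[[length(toks) + 1L]] <- list(type = "name",
                                        value = paste(chars[seq(i + 1L, length.out = j - i - 1L)],
                                                      collapse = ""),
                                        pos = i)
      i <- j + 1L
    } else if (grepl("^[A-Za-z0-9_.]$", ch)) {
      j <- i
      while (j <= n && grepl("^[A-Za-z0-9_.]$", chars[[j]])) j <- j + 1L
      word <- paste(chars[i:(j - 1L)], collapse = "")
      if (word == "U") {
        toks[[length(toks) + 1L]] <- list(type = "op", value = "U", pos = i)
      } else {
        toks[[length(toks) + 1L]] <- list(type = "name", value = word, pos = i)
      }
      i <- j
    } else {
      stop(sprintf("query parse error: unexpected character '%s' at position %d", ch, i))
    }
  }
  toks
}

# --- recursive-descent parser ---------------------------------------------

# Grammar (tightest first, all levels left-associative):
#   primary  := "(" or_expr ")" | name
#   not_expr := primary  ( "-" primary  )*
#   and_expr := not_expr ( "+" not_expr )*
#   or_expr  := and_expr ( "U" and_expr )*
.node <- function(op, ...) structure(list(op = op, ...), class = "bm_query")

#' Parse a Boolean query over named datasets
#'
#' Operator precedence, tightest to loosest: parenthesized groups,
#' then `-` (NOT / left-relative subtraction), then `+`
#' (AND / intersection), then `U` (OR / union).  Repeated instances of
#' the same operator associate in the order they appear
#' (left-to-right).  Dataset names are bare tokens of letters, digits,
#' `_` and `.`, or double-quoted strings (required for names
#' containing spaces or operator characters, or the name `U`).
#' Unknown dataset names are rejected at parse time.
#'
#' @param text the query string, e.g. `'A - B + (C U D)'`.
#' @param known_datasets character vector of legal dataset names.
#' @return the root of the parsed expression, class `bm_query`; nodes
#'   are `ref` (field `name`) or binary `not`/`and`/`or` (fields
#'   `left`, `right`).
#' @export
parse_query <- function(text, known_datasets) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("query text must be a non-empty string")
  toks <- .tokenize_query(text)
  if (!length(toks)) stop("query parse error: empty query")
  st <- new.env(parent = emptyenv())
  st$i <- 1L

  peek <- function() if (st$i <= length(toks)) toks[[st$i]] else NULL
  advance <- function() { t <- toks[[st$i]]; st$i <- st$i + 1L; t }

  parse_primary <- function() {
    t <- peek()
    if (is.null(t)) stop("query parse error: dangling operator at end of query")
    if (t$type == "lparen") {
      advance()
      e <- parse_or()
      t2 <- peek()
      if (is.null(t2) || t2$type != "rparen")
        stop(sprintf("query parse error: unbalanced parenthesis opened at position %d", t$pos))
      advance()
      return(e)
    }
    if (t$type == "name") {
      advance()
      if (!t$value %in% known_datasets)
        stop(sprintf("unknown dataset name '%s' at position %d", t$value, t$pos))
      return(.node("ref", name = t$value))
    }
    stop(sprintf("query parse error: unexpected '%s' at position %d", t$value, t$pos))
  }
  parse_binary <- function(sub, opval, type) {
    force(sub); force(opval); force(type)
    function() {
      left <- sub()
      repeat {
        t <- peek()
        if (is.null(t) || t$type != "op" || t$value != opval) return(left)
        advance()
        left <- .node(type, left = left, right = sub())
      }
    }
  }
  parse_not <- parse_binary(parse_primary, "-", "not")
  parse_and <- parse_binary(parse_not, "+", "and")
  parse_or  <- parse_binary(parse_and, "U", "or")

  expr <- parse_or()
  t <- peek()
  if (!is.null(t))
    stop(sprintf("query parse error: unexpected '%s' at position %d", t$value, t$pos))
  attr(expr, "source_text") <- text
  expr
}

#' @export
format.bm_query <- function(x, ...) {
  if (x$op == "ref") return(x$name)
  sym <- c(not = "-", and = "+", or = "U")[[x$op]]
  sprintf("(%s %s %s)", format(x$left), sym, format(x$right))
}

#' @export
print.bm_query <- function(x, ...) {
  cat("<bm_query>", format(x), "\n")
  invisible(x)
}

.query_refs <- function(expr) {
  if (expr$op == "ref") return(expr$name)
  unique(c(.query_refs(expr$left), .query_refs(expr$right)))
}

# --- evaluation ------------------------------------------------------------

#' Evaluate a Boolean query over consolidated entity groups
#'
#' Consolidation is computed once, globally, over every dataset the
#' query references (with the alias registry when `use_aliases`); each
#' expression node then filters sets of entity groups:
#' `A + B` keeps groups with at least one row in both operands,
#' `A U B` groups with a row in either, and `A - B` groups with a row
#' in the left operand and none in the right (left-relative
#' complement; no universal set exists).  Because grouping happens
#' before any Boolean step, results do not depend on how the
#' expression tree is shaped, and `+`/`U` are commutative.  With
#' `use_aliases = FALSE` the algebra reduces to plain string-keyed set
#' operations.
#'
#' @param query a `bm_query` from [parse_query()], or a query string.
#' @param datasets named list of `bm_dataset` (names must match the
#'   dataset names used in the query).
#' @param registry optional `bm_alias_registry`.
#' @param use_aliases use the registry's hash keys during
#'   consolidation (default TRUE when a registry is supplied).
#' @param case_insensitive compare identifier strings ignoring case.
#' @param aggregate_delimiter separator used when a group aggregates
#'   several rows into one output cell.
#' @param result_name name given to the merged output dataset.
#' @return object of class `bm_merge_result`: fields `dataset` (the
#'   merged `bm_dataset`, one row per surviving group), `group_ids`,
#'   `members`/`keys` of the surviving groups, `n_groups`, and the
#'   underlying `consolidation`.
#' @export
evaluate_query <- function(query, datasets, registry = NULL, use_aliases = TRUE,
                           case_insensitive = FALSE, aggregate_delimiter = "; ",
                           result_name = "result") {
  if (is.null(names(datasets)) || any(!nzchar(names(datasets))))
    names(datasets) <- vapply(datasets, function(d) d$name, character(1L))
  if (is.character(query)) query <- parse_query(query, names(datasets))
  stopifnot(inherits(query, "bm_query"))
  refs <- .query_refs(query)
  missing <- setdiff(refs, names(datasets))
  if (length(missing))
    stop(sprintf("unknown dataset name '%s'", missing[[1L]]))
  ds <- datasets[refs]
  for (d in ds)
    if (ncol(d$table) == 0L)
      stop(sprintf("dataset '%s' has zero columns", d$name))

  cons <- consolidate(ds, registry = if (isTRUE(use_aliases)) registry else NULL,
                      case_insensitive = case_insensitive)
  presence <- lapply(stats::setNames(refs, refs), function(nm)
    unique(cons$rows$group_id[cons$rows$dataset == nm]))

  fold <- function(e) {
    switch(e$op,
           ref = presence[[e$name]],
           not = setdiff(fold(e$left), fold(e$right)),
           and = intersect(fold(e$left), fold(e$right)),
           or  = union(fold(e$left), fold(e$right)),
           stop("unknown query node"))
  }
  surviving <- sort(fold(query))
  out <- assemble_output(cons, surviving, ds,
                         aggregate_delimiter = aggregate_delimiter,
                         result_name = result_name)
  structure(list(dataset = out,
                 group_ids = surviving,
                 members = cons$members[surviving],
                 keys = cons$keys[surviving],
                 n_groups = length(surviving),
                 consolidation = cons,
                 query = query),
            class = "bm_merge_result")
}

#' @export
print.bm_merge_result <- function(x, ...) {
  cat(sprintf("<bm_merge_result> query %s: %d surviving entity groups\n",
              format(x$query), x$n_groups))
  invisible(x)
}

#' Assemble the merged output table for surviving entity groups
#'
#' One output row per surviving group, ordered by group first
#' appearance.  Columns: `id` (the group's first-appearing member),
#' `aliases` (all member identifiers, sorted, `";"`-joined), then each
#' source dataset's attribute columns prefixed `"<dataset>.<column>"`
#' in dataset order.  When a group has several rows in one dataset,
#' cell values aggregate in row order, joined by
#' `aggregate_delimiter`; a group absent from a dataset leaves that
#' dataset's cells empty.
#'
#' @param consolidation a `bm_consolidation`.
#' @param group_ids integer ids of the surviving groups.
#' @param operand_datasets the datasets that took part, in order.
#' @param aggregate_delimiter separator for multi-row cells.
#' @param result_name name of the output dataset.
#' @return a `bm_dataset` with id_column `"id"`.
#' @export
assemble_output <- function(consolidation, group_ids, operand_datasets,
                            aggregate_delimiter = "; ", result_name = "result") {
  stopifnot(inherits(consolidation, "bm_consolidation"))
  group_ids <- sort(unique(as.integer(group_ids)))
  rows <- consolidation$rows
  gpos <- match(rows$group_id, group_ids)   # NA for non-surviving

  id_col <- vapply(consolidation$members[group_ids],
                   function(m) m[[1L]], character(1L))
  aliases <- vapply(consolidation$members[group_ids],
                    function(m) paste(sort(m), collapse = ";"), character(1L))
  out <- data.frame(id = id_col, aliases = aliases,
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (!nrow(out)) out <- data.frame(id = character(0), aliases = character(0),
                                    stringsAsFactors = FALSE)

  for (d in operand_datasets) {
    sel <- which(rows$dataset == d$name & !is.na(gpos))
    attr_cols <- setdiff(colnames(d$table), d$id_column)
    rix <- rows$row[sel]
    grp <- gpos[sel]
    for (col in attr_cols) {
      vals <- d$table[[col]][rix]
      agg <- rep("", length(group_ids))
      if (length(sel)) {
        joined <- vapply(split(vals, grp), paste, character(1L),
                         collapse = aggregate_delimiter)
        agg[as.integer(names(joined))] <- joined
      }
      out[[paste0(d$name, ".", col)]] <- agg
    }
  }
  bm_dataset(out, name = result_name, id_column = "id")
}

#' Switch a dataset's touch point to a different column
#'
#' Re-keys the table on another column so a result can feed a further
#' chain of Boolean comparisons under a new identifier space (e.g. a
#' drug-target table switched from drug names to target genes).  Rows
#' whose new identifier cell is empty are dropped by default; the
#' count of dropped rows is reported via a message and the
#' `"dropped_rows"` attribute.
#'
#' @param dataset a `bm_dataset`.
#' @param new_id_column column to become the identifier column.
#' @param drop_empty drop rows with an empty cell in `new_id_column`
#'   (default TRUE; with FALSE such rows are an error, since
#'   identifiers must be non-empty).
#' @return a `bm_dataset` keyed on `new_id_column`, with attribute
#'   `dropped_rows`.
#' @export
switch_touch_point <- function(dataset, new_id_column, drop_empty = TRUE) {
  stopifnot(inherits(dataset, "bm_dataset"))
  if (!new_id_column %in% colnames(dataset$table))
    stop(sprintf("unknown column '%s' (available: %s)", new_id_column,
                 paste(colnames(dataset$table), collapse = ", ")))
  tab <- dataset$table
  empty <- !nzchar(tab[[new_id_column]])
  n_drop <- 0L
  if (any(empty)) {
    if (!drop_empty)
      stop(sprintf("%d rows have an empty '%s' cell; cannot switch touch point without dropping them",
                   sum(empty), new_id_column))
    n_drop <- sum(empty)
    tab <- tab[!empty, , drop = FALSE]
    rownames(tab) <- NULL
  }
  message(sprintf("switch_touch_point: '%s' -> '%s', dropped %d row(s) with empty identifier",
                  dataset$id_column, new_id_column, n_drop))
  out <- bm_dataset(tab, name = dataset$name, id_column = new_id_column)
  attr(out, "dropped_rows") <- n_drop
  out
}
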