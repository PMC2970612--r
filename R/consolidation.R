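# Canonical form of an identifier under the configured case rule.
.canon_id <- function(x, case_insensitive) if (case_insensitive) tolower(x) else x

# Long-form row table over a list of datasets: one record per dataset
# row, in dataset order then row order.  This ordering defines "first
# appearance" everywhere downstream.
.row_table <- function(datasets) {
  stopifnot(length(datasets) > 0L)
  nms <- vapply(datasets, function(d) d$name, character(1L))
  if (anyDuplicated(nms))
    stop(sprintf("dataset names must be unique; duplicated: %s",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  do.call(rbind, lapply(datasets, function(d) {
    ids <- identifiers(d)
    data.frame(dataset = rep(d$name, length(ids)),
               row = seq_along(ids), identifier = ids,
               stringsAsFactors = FALSE)
  }))
}

#' Build the entity graph over dataset identifiers
#'
#' Nodes are the identifiers appearing in any participating dataset
#' (canonicalized under the case rule); an edge joins two identifiers
#' iff their strings are equal under the case rule, or their resolved
#' key sets share at least one hash key.  Entity groups are the
#' connected components of this graph: two protein variants that share
#' no key directly still merge when a gene-parent identifier holds
#' both variants' keys.
#'
#' @param datasets list of `bm_dataset` with unique names.
#' @param registry a `bm_alias_registry`, or NULL for none.
#' @param case_insensitive compare identifier strings ignoring case.
#' @return an undirected `igraph` whose vertices are canonical
#'   identifiers.
#' @export
build_entity_graph <- function(datasets, registry = NULL, case_insensitive = FALSE) {
  rows <- .row_table(datasets)
  uids <- unique(.canon_id(rows$identifier, case_insensitive))
  edges <- NULL
  if (!is.null(registry) && nrow(registry$entries)) {
    ent <- registry$entries
    rid <- .canon_id(ent$identifier, case_insensitive)
    keep <- rid %in% uids
    if (any(keep)) {
      by_key <- split(rid[keep], ent$key[keep])
      pairs <- lapply(by_key, function(ids) {
        ids <- unique(ids)
        if (length(ids) < 2L) return(NULL)
        t(utils::combn(ids, 2L))
      })
      pairs <- do.call(rbind, pairs)
      if (!is.null(pairs) && nrow(pairs)) edges <- pairs
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(uids), name = uids)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(matrix(match(edges, uids), ncol = 2L)))
  igraph::simplify(g)
}

#' Consolidate identifiers across datasets into entity groups
#'
#' Partitions every identifier occurring in the datasets into entity
#' groups: the connected components of the entity graph (exact string
#' matches under the case rule, plus shared hash keys, closed
#' transitively).  Registry identifiers that appear in no dataset do
#' not bridge groups; they are attached passively as members of any
#' group whose key set their own keys intersect.  Group ids are
#' assigned by first appearance (dataset order, then row order).
#'
#' @param datasets list of `bm_dataset` with unique names.
#' @param registry a `bm_alias_registry`, or NULL to consolidate on
#'   exact string matches alone.
#' @param case_insensitive compare identifier strings ignoring case.
#' @return an object of class `bm_consolidation` with components
#'   `members` (list of character vectors per group, first-appearance
#'   order, registry-only aliases appended), `keys` (list of key sets
#'   per group), `rows` (data.frame dataset/row/identifier/group_id),
#'   and `dataset_names`.
#' @export
consolidate <- function(datasets, registry = NULL, case_insensitive = FALSE) {
  rows <- .row_table(datasets)
  rows$canon <- .canon_id(rows$identifier, case_insensitive)
  uids <- unique(rows$canon)
  n <- length(uids)

  ent <- if (!is.null(registry)) registry$entries else NULL
  if (!is.null(ent) && nrow(ent)) {
    ent$canon <- .canon_id(ent$identifier, case_insensitive)
  } else ent <- NULL

  # Components of the identifier--key bipartite graph restricted to
  # identifier vertices equal the components of the pairwise
  # shared-key graph, without materializing per-key cliques.
  if (!is.null(ent)) {
    in_ds <- ent$canon %in% uids
    e_ds <- ent[in_ds, , drop = FALSE]
  } else e_ds <- NULL
  if (!is.null(e_ds) && nrow(e_ds)) {
    keys <- unique(e_ds$key)
    g <- igraph::make_empty_graph(n = n + length(keys), directed = FALSE)
    ei <- rbind(match(e_ds$canon, uids), n + match(e_ds$key, keys))
    g <- igraph::add_edges(g, as.vector(ei))
    comp <- igraph::components(g)$membership[seq_len(n)]
  } else {
    comp <- seq_len(n)
  }
  gid_of_uid <- match(comp, unique(comp))   # number groups by first appearance
  ngroups <- max(gid_of_uid)
  rows$group_id <- gid_of_uid[match(rows$canon, uids)]

  # members: dataset identifiers (original spelling) in first-appearance order
  first <- !duplicated(rows$identifier)
  members <- split(rows$identifier[first], rows$group_id[first])
  members <- lapply(seq_len(ngroups), function(i) members[[as.character(i)]])

  # keys per group: union of dataset members' resolved keys
  keysets <- rep(list(character(0)), ngroups)
  if (!is.null(e_ds) && nrow(e_ds)) {
    kg <- split(e_ds$key, gid_of_uid[match(e_ds$canon, uids)])
    for (nm in names(kg)) keysets[[as.integer(nm)]] <- unique(kg[[nm]])
  }

  # attach registry-only identifiers whose keys intersect a group's keys
  if (!is.null(ent)) {
    only <- ent[!(ent$canon %in% uids), , drop = FALSE]
    if (nrow(only)) {
      key_gid <- stats::setNames(rep(seq_len(ngroups), lengths(keysets)),
                                 unlist(keysets))
      hit <- only$key %in% names(key_gid)
      if (any(hit)) {
        add <- unique(data.frame(identifier = only$identifier[hit],
                                 gid = unname(key_gid[only$key[hit]]),
                                 stringsAsFactors = FALSE))
        for (i in unique(add$gid)) {
          extra <- setdiff(add$identifier[add$gid == i], members[[i]])
          members[[i]] <- c(members[[i]], extra)
        }
      }
    }
  }

  rows$canon <- NULL
  structure(list(members = members, keys = keysets, rows = rows,
                 n_groups = ngroups,
                 dataset_names = vapply(datasets, function(d) d$name, character(1L)),
                 case_insensitive = case_insensitive),
            class = "bm_consolidation")
}

#' @export
print.bm_consolidation <- function(x, ...) {
  cat(sprintf("<bm_consolidation> %d entity groups over %d rows from %d datasets\n",
              x$n_groups, nrow(x$rows), length(x$dataset_names)))
  invisible(x)
}

#' Export entity groups as a table (debug aid)
#'
#' @param consolidation a `bm_consolidation`.
#' @param path optional TSV output path.
#' @return data.frame with columns `group_id`, `members` and `keys`
#'   (`";"`-joined), invisibly written to `path` when given.
#' @export
export_groups <- function(consolidation, path = NULL) {
  stopifnot(inherits(consolidation, "bm_consolidation"))
  out <- data.frame(
    group_id = seq_len(consolidation$n_groups),
    members = vapply(consolidation$members, paste, character(1L), collapse = ";"),
    keys = vapply(consolidation$keys, paste, character(1L), collapse = ";"),
    stringsAsFactors = FALSE)
  if (!is.null(path))
    data.table::fwrite(out, path, sep = "\t", quote = "auto", qmethod = "double")
  out
}
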