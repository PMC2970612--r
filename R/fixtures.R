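#' Specify a synthetic multi-dataset fixture
#'
#' Describes a family of seeded gene-list fixtures with controlled
#' overlap and an alias network: `n_datasets` tables of
#' `ids_per_dataset` rows each, a shared identifier pool of size
#' `floor(overlap_fraction * ids_per_dataset)` present in every
#' dataset, and `alias_families` gene-parent families, each with
#' `variant_count` protein variants carrying one external alias
#' apiece; the parent identifier is registered with every variant's
#' fingerprint, so consolidation merges a family exactly when the
#' parent participates.  Variants are placed in the first dataset and
#' parents in the second, mirroring the variant-list/parent-list
#' arrangement that motivates alias resolution.  The same spec
#' (including seed) always generates byte-identical files.
#'
#' @param n_datasets number of datasets (>= 1).
#' @param ids_per_dataset rows per dataset (>= 1).
#' @param overlap_fraction fraction in \\[0, 1\\] of each dataset drawn
#'   from a pool shared by every dataset.
#' @param alias_families number of gene-parent alias families.
#' @param variant_count protein variants per family.
#' @param seed RNG seed; part of the fixture's identity.
#' @return object of class `bm_fixture_spec`.
#' @export
fixture_spec <- function(n_datasets, ids_per_dataset, overlap_fraction = 0.5,
                         alias_families = 0L, variant_count = 2L, seed = 1L) {
  stopifnot(length(n_datasets) == 1L, n_datasets >= 1, n_datasets == floor(n_datasets),
            length(ids_per_dataset) == 1L, ids_per_dataset >= 1,
            ids_per_dataset == floor(ids_per_dataset),
            length(overlap_fraction) == 1L, overlap_fraction >= 0, overlap_fraction <= 1,
            alias_families >= 0, variant_count >= 1,
            length(seed) == 1L, is.finite(seed))
  n_shared <- as.integer(floor(overlap_fraction * ids_per_dataset))
  n_free <- ids_per_dataset - n_shared
  if (alias_families > 0) {
    if (n_datasets < 2L)
      stop("alias families need at least 2 datasets (variants and parents)")
    if (alias_families * variant_count > n_free)
      stop(sprintf("dataset 1 has only %d non-shared rows; cannot place %d variant identifiers",
                   n_free, alias_families * variant_count))
    if (alias_families > n_free)
      stop(sprintf("dataset 2 has only %d non-shared rows; cannot place %d parent identifiers",
                   n_free, alias_families))
  }
  structure(list(n_datasets = as.integer(n_datasets),
                 ids_per_dataset = as.integer(ids_per_dataset),
                 overlap_fraction = overlap_fraction,
                 alias_families = as.integer(alias_families),
                 variant_count = as.integer(variant_count),
                 seed = as.integer(seed)),
            class = "bm_fixture_spec")
}

#' @export
print.bm_fixture_spec <- function(x, ...) {
  cat(sprintf("<bm_fixture_spec> %d datasets x %d ids (overlap %.2f, %d alias families, seed %d)\n",
              x$n_datasets, x$ids_per_dataset, x$overlap_fraction,
              x$alias_families, x$seed))
  invisible(x)
}

.random_sequences <- function(n, len = 60L) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1L))
}

#' Generate a seeded fixture on disk
#'
#' Writes `n_datasets` TSV datasets (`D01.tsv`, ..., identifier column
#' `id` plus one random attribute column `attr`), an alias table
#' `aliases.tsv`, and a key-value `manifest.txt` recording the
#' expected chained-intersection sizes (with and without alias
#' resolution) and the total combined identifier count
#' (`n_datasets * ids_per_dataset`).
#'
#' @param spec a `bm_fixture_spec`.
#' @param out_dir output directory, created if needed.
#' @return list with `dataset_paths`, `alias_table_path`,
#'   `manifest_path` and the `manifest` as a named list.
#' @export
generate_fixtures <- function(spec, out_dir) {
  stopifnot(inherits(spec, "bm_fixture_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)

  n_shared <- as.integer(floor(spec$overlap_fraction * spec$ids_per_dataset))
  n_free <- spec$ids_per_dataset - n_shared
  n_total <- n_shared + spec$n_datasets * n_free
  if (n_total > 999999L) stop("fixture too large for the G###### identifier space")
  pool <- sprintf("G%06d", sample.int(999999L, n_total))
  shared <- pool[seq_len(n_shared)]
  free <- if (n_free > 0)
    split(pool[n_shared + seq_len(spec$n_datasets * n_free)],
          rep(seq_len(spec$n_datasets), each = n_free))
  else rep(list(character(0)), spec$n_datasets)

  # alias families: parent FAM%04d with variants FAM%04d-PA, -PB, ...;
  # each variant has its own sequence fingerprint and one external
  # alias; the parent is registered with every variant's fingerprint.
  alias <- data.frame(identifier = character(0), kind = character(0),
                      fingerprint = character(0), stringsAsFactors = FALSE)
  variants_all <- character(0)
  parents_all <- character(0)
  if (spec$alias_families > 0) {
    for (f in seq_len(spec$alias_families)) {
      parent <- sprintf("FAM%04d", f)
      vtags <- paste0("P", LETTERS[seq_len(spec$variant_count)])
      variants <- paste0(parent, "-", vtags)
      seqs <- .random_sequences(spec$variant_count)
      ext <- sprintf("XA%07d", (f - 1L) * spec$variant_count + seq_len(spec$variant_count))
      alias <- rbind(alias,
                     data.frame(identifier = c(variants, ext, rep(parent, spec$variant_count)),
                                kind = "sequence",
                                fingerprint = c(seqs, seqs, seqs),
                                stringsAsFactors = FALSE))
      variants_all <- c(variants_all, variants)
      parents_all <- c(parents_all, parent)
    }
    # variants displace the tail of dataset 1's free ids, parents of dataset 2's
    nv <- length(variants_all)
    free[[1L]] <- c(free[[1L]][seq_len(n_free - nv)], variants_all)
    np <- length(parents_all)
    free[[2L]] <- c(free[[2L]][seq_len(n_free - np)], parents_all)
  }

  dataset_paths <- character(spec$n_datasets)
  for (k in seq_len(spec$n_datasets)) {
    ids <- c(shared, free[[k]])
    tab <- data.frame(id = ids,
                      attr = sprintf("v%04d", sample.int(9999L, length(ids), replace = TRUE)),
                      stringsAsFactors = FALSE)
    p <- file.path(out_dir, sprintf("D%02d.tsv", k))
    write_dataset(bm_dataset(tab, name = sprintf("D%02d", k)), p)
    dataset_paths[[k]] <- p
  }

  alias_path <- file.path(out_dir, "aliases.tsv")
  data.table::fwrite(alias, alias_path, sep = "\t", quote = "auto", qmethod = "double")

  # with alias resolution and exactly two datasets, each family merges
  # (variants in D1, parent in D2) and adds one group to the intersection
  manifest <- list(
    n_datasets = spec$n_datasets,
    ids_per_dataset = spec$ids_per_dataset,
    overlap_fraction = spec$overlap_fraction,
    alias_families = spec$alias_families,
    variant_count = spec$variant_count,
    seed = spec$seed,
    total_combined_identifiers = spec$n_datasets * spec$ids_per_dataset,
    expected_intersection = n_shared +
      if (spec$n_datasets == 2L) spec$alias_families else 0L,
    expected_intersection_no_alias = n_shared)
  manifest_path <- file.path(out_dir, "manifest.txt")
  writeLines(paste(names(manifest), unlist(manifest), sep = "\t"), manifest_path)

  list(dataset_paths = dataset_paths, alias_table_path = alias_path,
       manifest_path = manifest_path, manifest = manifest)
}

#' Read a fixture manifest
#'
#' @param path path to a `manifest.txt` written by [generate_fixtures()].
#' @return named list of manifest values (numeric where possible).
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\t", fixed = TRUE)
  out <- lapply(kv, function(x) {
    v <- x[[2L]]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(out, vapply(kv, `[[`, character(1L), 1L))
}
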