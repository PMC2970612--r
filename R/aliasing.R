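# Accepted fingerprint kinds; "opaque" covers any content class the
# other three do not.
FINGERPRINT_KINDS <- c("sequence", "formula", "uri", "opaque")

#' Canonicalize fingerprint text
#'
#' A fingerprint is content that defines an entity's identity
#' independent of naming: a sequence, a chemical formula, a URI, or an
#' opaque blob.  Canonicalization makes textually different renderings
#' of the same content hash identically: sequences have all whitespace
#' removed and are upper-cased; other kinds are trimmed of surrounding
#' whitespace only.
#'
#' @param kind one of `"sequence"`, `"formula"`, `"uri"`, `"opaque"`.
#' @param raw character vector of raw fingerprint text; must be
#'   non-empty after whitespace removal.
#' @return character vector of canonical fingerprint text.
#' @export
canonicalize_fingerprint <- function(kind, raw) {
  kind <- match.arg(kind, FINGERPRINT_KINDS)
  raw <- as.character(raw)
  out <- if (kind == "sequence") toupper(gsub("[[:space:]]+", "", raw)) else trimws(raw)
  if (any(is.na(out) | !nzchar(out)))
    stop("fingerprint text is empty (or whitespace-only) after canonicalization")
  out
}

#' Construct a fingerprint object
#'
#' @param raw raw fingerprint text (length 1).
#' @param kind fingerprint kind; `"sequence"` by default.
#' @return object of class `bm_fingerprint` with fields `kind` and
#'   canonical `text`.
#' @export
fingerprint <- function(raw, kind = "sequence") {
  kind <- match.arg(kind, FINGERPRINT_KINDS)
  stopifnot(length(raw) == 1L)
  structure(list(kind = kind, text = canonicalize_fingerprint(kind, raw)),
            class = "bm_fingerprint")
}

#' @export
print.bm_fingerprint <- function(x, ...) {
  cat(sprintf("<bm_fingerprint> kind=%s text=%s\n", x$kind,
              if (nchar(x$text) > 40) paste0(substr(x$text, 1, 37), "...") else x$text))
  invisible(x)
}

# Digest dispatch: both choices render a 160-bit value as 40 lower-case
# hex characters.  "sha1" is the standard 160-bit hash; "sha2-truncated"
# is SHA-256 truncated to its leading 160 bits.
.hash_texts <- function(texts, digest = c("sha1", "sha2-truncated")) {
  digest <- match.arg(digest)
  algo <- if (digest == "sha1") "sha1" else "sha256"
  out <- vapply(enc2utf8(texts),
                function(t) digest::digest(t, algo = algo, serialize = FALSE),
                character(1L), USE.NAMES = FALSE)
  substr(out, 1L, 40L)
}

#' Compute the 160-bit hash key of a fingerprint
#'
#' The hash key is the digest of the canonical fingerprint text
#' (UTF-8 bytes), rendered as exactly 40 lower-case hexadecimal
#' characters.  Equal fingerprints (after canonicalization) yield
#' equal keys, regardless of kind, so the key serves as a
#' non-semantic identifier: two names with the same key are asserted
#' to denote the same entity.
#'
#' @param fp a `bm_fingerprint`, or a character vector of canonical
#'   fingerprint text.
#' @param digest `"sha1"` (default: the standard 160-bit hash) or
#'   `"sha2-truncated"` (SHA-256 truncated to 160 bits).
#' @return character vector of 40-character lower-case hex keys.
#' @export
hash_key <- function(fp, digest = c("sha1", "sha2-truncated")) {
  if (inherits(fp, "bm_fingerprint")) fp <- fp$text
  if (!is.character(fp) || any(is.na(fp) | !nzchar(fp)))
    stop("`fp` must be a bm_fingerprint or non-empty character text")
  .hash_texts(fp, match.arg(digest))
}

#' Create an empty alias registry
#'
#' The registry is a many-to-many relation between identifier strings
#' and hash keys: one identifier may map to several keys (a gene whose
#' aliases point to distinct protein variants) and one key to several
#' identifiers (synonymous accessions sharing a sequence).  The digest
#' function is fixed per registry.
#'
#' @param digest digest choice, see [hash_key()].
#' @return object of class `bm_alias_registry`.
#' @export
alias_registry <- function(digest = c("sha1", "sha2-truncated")) {
  structure(list(entries = data.frame(identifier = character(0),
                                      kind = character(0),
                                      fingerprint = character(0),
                                      key = character(0),
                                      source = character(0),
                                      stringsAsFactors = FALSE),
                 digest = match.arg(digest)),
            class = "bm_alias_registry")
}

#' @export
print.bm_alias_registry <- function(x, ...) {
  cat(sprintf("<bm_alias_registry> %d entries, %d identifiers, %d keys (digest: %s)\n",
              nrow(x$entries), length(unique(x$entries$identifier)),
              length(unique(x$entries$key)), x$digest))
  invisible(x)
}

#' Register identifier/fingerprint aliases
#'
#' Vectorized; repeated registration of the same (identifier,
#' fingerprint) pair is idempotent.
#'
#' @param registry a `bm_alias_registry`.
#' @param identifier character vector of non-empty identifiers.
#' @param raw raw fingerprint text, recycled against `identifier`.
#' @param kind fingerprint kind (scalar or vector).
#' @param source optional provenance label per entry.
#' @return the updated registry.
#' @export
register_alias <- function(registry, identifier, raw, kind = "sequence", source = "") {
  stopifnot(inherits(registry, "bm_alias_registry"))
  identifier <- as.character(identifier)
  if (any(is.na(identifier) | !nzchar(trimws(identifier))))
    stop("alias identifiers must be non-empty")
  n <- max(length(identifier), length(raw))
  identifier <- rep_len(trimws(identifier), n)
  raw <- rep_len(as.character(raw), n)
  kind <- rep_len(as.character(kind), n)
  source <- rep_len(as.character(source), n)
  bad_kind <- which(!kind %in% FINGERPRINT_KINDS)
  if (length(bad_kind))
    stop(sprintf("unknown fingerprint kind '%s'", kind[[bad_kind[[1L]]]]))
  canon <- character(n)
  for (k in unique(kind)) {
    sel <- kind == k
    canon[sel] <- canonicalize_fingerprint(k, raw[sel])
  }
  new <- data.frame(identifier = identifier, kind = kind, fingerprint = canon,
                    key = .hash_texts(canon, registry$digest), source = source,
                    stringsAsFactors = FALSE)
  all <- rbind(registry$entries, new)
  registry$entries <- all[!duplicated(paste0(all$identifier, "\r", all$key)), ,
                          drop = FALSE]
  rownames(registry$entries) <- NULL
  registry
}

#' Resolve the hash keys registered for an identifier
#'
#' Lookup of an unregistered identifier is legal and returns the empty
#' key set: such identifiers still take part in consolidation through
#' exact string matches.
#'
#' @param registry a `bm_alias_registry`.
#' @param identifier a single identifier string.
#' @param case_insensitive match identifiers ignoring case.
#' @return character vector (possibly empty) of 40-hex keys.
#' @export
resolve_keys <- function(registry, identifier, case_insensitive = FALSE) {
  stopifnot(inherits(registry, "bm_alias_registry"), length(identifier) == 1L)
  ids <- registry$entries$identifier
  hit <- if (case_insensitive) tolower(ids) == tolower(identifier) else ids == identifier
  unique(registry$entries$key[hit])
}

#' Read an alias table
#'
#' The alias table is a header-bearing TSV with columns `identifier`,
#' `kind` and `fingerprint`; `kind` must be one of `sequence`,
#' `formula`, `uri`, `opaque`.  A malformed line is an error naming
#' the line.
#'
#' @param path file path.
#' @param digest digest choice for the resulting registry.
#' @return a `bm_alias_registry`.
#' @export
load_alias_table <- function(path, digest = c("sha1", "sha2-truncated")) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- .read_delim(path, "\t")
  need <- c("identifier", "kind", "fingerprint")
  if (!all(need %in% colnames(tab)))
    stop(sprintf("alias table '%s' must have columns: %s", path,
                 paste(need, collapse = ", ")))
  reg <- alias_registry(digest)
  if (!nrow(tab)) return(reg)
  tab[] <- lapply(tab, trimws)
  bad <- which(!tab$kind %in% FINGERPRINT_KINDS)
  if (length(bad))
    stop(sprintf("alias table '%s' line %d: unknown kind '%s'",
                 path, bad[[1L]] + 1L, tab$kind[[bad[[1L]]]]))
  bad <- which(!nzchar(trimws(tab$identifier)) | !nzchar(trimws(tab$fingerprint)))
  if (length(bad))
    stop(sprintf("alias table '%s' line %d: empty identifier or fingerprint",
                 path, bad[[1L]] + 1L))
  register_alias(reg, tab$identifier, tab$fingerprint, tab$kind)
}

#' Write an alias registry to its table form
#'
#' Fingerprints are written in canonical form; the round trip through
#' [load_alias_table()] preserves the identifier/key relation.
#'
#' @param registry a `bm_alias_registry`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_alias_table <- function(registry, path) {
  stopifnot(inherits(registry, "bm_alias_registry"))
  data.table::fwrite(registry$entries[, c("identifier", "kind", "fingerprint")],
                     file = path, sep = "\t", quote = "auto", qmethod = "double",
                     eol = "\n")
  invisible(path)
}
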