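#' Taxonomy-annotated reference databases
#'
#' A reference database is a tibble with one row per SSU sequence and
#' columns:
#' \describe{
#'   \item{id}{unique record identifier (token before the first whitespace
#'     of the FASTA header)}
#'   \item{taxonomy}{list column; ordered character vector of rank labels,
#'     root to leaf, from the semicolon-separated header tail}
#'   \item{sequence}{uppercase DNA over the IUPAC alphabet; U normalized to
#'     T and alignment gaps stripped at ingest}
#'   \item{flagged}{TRUE when more than 10\% of positions are ambiguity
#'     codes; such records are retained, never silently dropped}
#' }
#'
#' @name reference_db
NULL

.AMBIG_FLAG_FRAC <- 0.10

new_ref_db <- function(id, taxonomy, sequence) {
  tibble::tibble(
    id = as.character(id),
    taxonomy = taxonomy,
    sequence = as.character(sequence),
    flagged = vapply(sequence, function(s) {
      n <- nchar(s)
      n > 0L && sum(seq_masks(s) %in% c(1L, 2L, 4L, 8L)) < (1 - .AMBIG_FLAG_FRAC) * n
    }, logical(1L), USE.NAMES = FALSE)
  )
}

validate_ref_db <- function(db) {
  stopifnot(is.data.frame(db), all(c("id", "taxonomy", "sequence") %in% names(db)))
  if (anyDuplicated(db$id)) {
    stop("duplicate record ids: ",
         paste(unique(db$id[duplicated(db$id)]), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(db$id))) stop("empty record id", call. = FALSE)
  if (any(!nzchar(db$sequence))) {
    stop("empty sequence for record ",
         paste(db$id[!nzchar(db$sequence)], collapse = ", "), call. = FALSE)
  }
  bad_tax <- vapply(db$taxonomy, function(tx) length(tx) < 1L || any(!nzchar(tx)),
                    logical(1L))
  if (any(bad_tax)) {
    stop("invalid taxonomy (empty path or empty label) for record ",
         paste(db$id[bad_tax], collapse = ", "), call. = FALSE)
  }
  invisible(db)
}

# Normalize a raw sequence string: uppercase, U->T, strip Silva alignment
# gaps ('-', '.'). Errors mention `id`.
normalize_sequence <- function(seq, id) {
  s <- gsub("[-.]", "", toupper(seq))
  s <- chartr("U", "T", s)
  check_iupac(s, paste0("record '", id, "'"))
  s
}

parse_silva_header <- function(header) {
  header <- trimws(header)
  sp <- regexpr("[ \t]", header)
  if (sp < 0L) {
    return(list(id = header, taxonomy = NULL))
  }
  id <- substr(header, 1L, sp - 1L)
  tax_str <- trimws(substr(header, sp + 1L, nchar(header)))
  labels <- strsplit(tax_str, ";", fixed = TRUE)[[1L]]
  labels <- trimws(labels)
  labels <- labels[nzchar(labels)] # trailing/duplicated separators ignored
  list(id = id, taxonomy = labels)
}

#' Read a Silva-style reference FASTA
#'
#' Headers are `>ID taxonomy;separated;by;semicolons`. Sequences are
#' normalized at ingest: uppercase, U to T, alignment gaps (`-`, `.`)
#' stripped. Records with more than 10\% ambiguity codes are kept and
#' marked in the `flagged` column.
#'
#' @param path Path to a FASTA file.
#' @return A reference-database tibble (see [reference_db]); zero rows for
#'   an empty file.
#' @export
read_reference_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(new_ref_db(character(0L), list(), character(0L)))
  }
  parsed <- lapply(names(set), parse_silva_header)
  no_tax <- vapply(parsed, function(p) is.null(p$taxonomy) || length(p$taxonomy) == 0L,
                   logical(1L))
  if (any(no_tax)) {
    k <- which(no_tax)[1L]
    header_lines <- grep("^>", readLines(path))
    stop("malformed header (no taxonomy) at line ", header_lines[k],
         " of ", path, ": '>", names(set)[k], "'", call. = FALSE)
  }
  ids <- vapply(parsed, `[[`, character(1L), "id")
  seqs <- vapply(seq_along(set), function(i) {
    normalize_sequence(as.character(set[[i]]), ids[i])
  }, character(1L))
  db <- new_ref_db(ids, lapply(parsed, `[[`, "taxonomy"), seqs)
  validate_ref_db(db)
  db
}

#' Write a reference database as Silva-style FASTA
#'
#' Inverse of [read_reference_fasta()]: headers are
#' `id taxonomy;...;labels`, sequences wrapped at 80 columns.
#'
#' @param db Reference-database tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(db, path) {
  validate_ref_db(db)
  set <- Biostrings::DNAStringSet(db$sequence)
  names(set) <- paste(db$id,
                      vapply(db$taxonomy, paste, character(1L), collapse = ";"))
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Does a taxonomy path contain a label?
#'
#' Case-insensitive exact-label membership (no substring matching), so
#' "Metazoa" does not match "Metazoan_X".
#'
#' @param taxonomy Character vector of rank labels.
#' @param label Single label to test.
#' @return Logical.
#' @export
taxonomy_contains <- function(taxonomy, label) {
  tolower(label) %in% tolower(taxonomy)
}

#' Partition a reference database by a taxonomy label
#'
#' Splits records into those whose taxonomy path contains `label`
#' (case-insensitive exact-label match) and the rest. This is the
#' metazoan/non-metazoan split used when scoring blocking-primer
#' specificity.
#'
#' @param db Reference-database tibble.
#' @param label Taxonomy label, e.g. "Metazoa".
#' @return List with elements `matching` and `non_matching`; together they
#'   partition `db` with input order preserved.
#' @export
partition_by_label <- function(db, label) {
  validate_ref_db(db)
  hit <- vapply(db$taxonomy, taxonomy_contains, logical(1L), label = label)
  list(matching = db[hit, , drop = FALSE],
       non_matching = db[!hit, , drop = FALSE])
}

#' Export a (id, taxonomy, length) summary table
#'
#' @param db Reference-database tibble.
#' @param path Optional TSV output path; when NULL the tibble is returned
#'   only.
#' @return Tibble with columns id, taxonomy (semicolon-joined), length.
#' @export
reference_summary <- function(db, path = NULL) {
  validate_ref_db(db)
  out <- tibble::tibble(
    id = db$id,
    taxonomy = vapply(db$taxonomy, paste, character(1L), collapse = ";"),
    length = nchar(db$sequence)
  )
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
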