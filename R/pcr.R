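#' In silico PCR: primer-site search and amplicon extraction
#'
#' Degenerate primers are matched against template windows under IUPAC
#' set-intersection semantics (a position matches when the two base sets
#' share at least one base), with a configurable mismatch allowance. All
#' coordinates are 0-based half-open on the stored (sense) strand, so
#' `end - start` is always the primer or amplicon length.
#'
#' @name insilico_pcr
NULL

empty_sites <- function() {
  tibble::tibble(record_id = character(0L), strand = character(0L),
                 start = integer(0L), end = integer(0L),
                 mismatches = integer(0L))
}

# Mismatch counts of `pmask` against every window of `smask`, vectorized
# over windows. Returns integer vector of length nchar(seq) - L + 1.
window_mismatches <- function(smask, pmask) {
  L <- length(pmask)
  W <- length(smask) - L + 1L
  if (W < 1L) return(integer(0L))
  mm <- integer(W)
  for (i in seq_len(L)) {
    mm <- mm + (bitwAnd(pmask[i], smask[i:(i + W - 1L)]) == 0L)
  }
  mm
}

#' Locate all binding sites of a primer in a sequence
#'
#' Scans every window of both strands. A minus-strand row means the
#' primer matches the reverse complement of the reported sense-strand
#' interval (the orientation in which a reverse primer binds).
#'
#' @param sequence Template string (IUPAC alphabet).
#' @param primer IUPAC primer string, 5' to 3'.
#' @param max_mismatch Maximum number of mismatching positions.
#' @param record_id Optional id copied into the result.
#' @return Tibble with columns record_id, strand ("+"/"-"), start, end
#'   (0-based half-open on the sense sequence) and mismatches, sorted by
#'   start; zero rows when there is no site.
#' @export
find_primer_sites <- function(sequence, primer, max_mismatch = 1L,
                              record_id = NA_character_) {
  stopifnot(length(sequence) == 1L, length(primer) == 1L)
  smask <- seq_masks(sequence)
  pmask <- seq_masks(primer, "primer")
  L <- length(pmask)
  if (L == 0L) stop("empty primer", call. = FALSE)
  if (L > length(smask)) return(empty_sites())

  hits <- function(pm, strand) {
    mm <- window_mismatches(smask, pm)
    idx <- which(mm <= max_mismatch)
    if (length(idx) == 0L) return(NULL)
    tibble::tibble(record_id = record_id, strand = strand,
                   start = idx - 1L, end = idx - 1L + L,
                   mismatches = mm[idx])
  }
  out <- rbind(hits(pmask, "+"),
               hits(seq_masks(revcomp(primer)), "-"))
  if (is.null(out)) return(empty_sites())
  out <- out[order(out$start, out$strand), , drop = FALSE]
  tibble::as_tibble(out)
}

empty_amplicons <- function() {
  tibble::tibble(record_id = character(0L), strand = character(0L),
                 start = integer(0L), end = integer(0L), length = integer(0L),
                 sequence = character(0L),
                 fwd_mismatches = integer(0L), rev_mismatches = integer(0L),
                 primary = logical(0L), multi_site = logical(0L))
}

#' Extract the amplicons a primer set would produce from one template
#'
#' Pairs every forward site with every compatible reverse site in both
#' template orientations: plus-strand amplicons pair a forward site on
#' "+" with a reverse site on "-" downstream of it; minus-strand
#' amplicons the mirror image. Amplicon coordinates span from the first
#' to the last primer base (primer regions included, matching the usual
#' "expected product size" of a PCR product). The `sequence` column is
#' always in primer orientation (starts with the forward-primer region),
#' so for minus-strand amplicons it is the reverse complement of the
#' stored substring.
#'
#' When several pairings exist all are emitted, `multi_site` is set, and
#' the shortest product is flagged `primary` (ties broken by leftmost
#' start).
#'
#' @param sequence Template string.
#' @param pset A [primer_set()].
#' @param max_mismatch Per-primer mismatch allowance; defaults to the
#'   set's own.
#' @param record_id Optional id copied into the result.
#' @return Amplicon tibble (possibly zero rows); see Details for columns.
#' @export
extract_amplicons <- function(sequence, pset, max_mismatch = NULL,
                              record_id = NA_character_) {
  stopifnot(inherits(pset, "primer_set"))
  if (is.null(max_mismatch)) max_mismatch <- pset$max_mismatch
  fwd <- find_primer_sites(sequence, pset$forward, max_mismatch, record_id)
  rev <- find_primer_sites(sequence, pset$reverse, max_mismatch, record_id)
  if (nrow(fwd) == 0L || nrow(rev) == 0L) return(empty_amplicons())

  pair_up <- function(f, r, strand) {
    if (nrow(f) == 0L || nrow(r) == 0L) return(NULL)
    grid <- expand.grid(fi = seq_len(nrow(f)), ri = seq_len(nrow(r)))
    if (strand == "+") {
      keep <- f$start[grid$fi] < r$start[grid$ri]
      a_start <- f$start[grid$fi]; a_end <- r$end[grid$ri]
    } else {
      keep <- r$start[grid$ri] < f$start[grid$fi]
      a_start <- r$start[grid$ri]; a_end <- f$end[grid$fi]
    }
    grid <- grid[keep, , drop = FALSE]
    if (nrow(grid) == 0L) return(NULL)
    a_start <- a_start[keep]; a_end <- a_end[keep]
    sub <- substr(rep(sequence, nrow(grid)), a_start + 1L, a_end)
    if (strand == "-") {
      sub <- vapply(sub, revcomp, character(1L), USE.NAMES = FALSE)
    }
    tibble::tibble(
      record_id = record_id, strand = strand,
      start = a_start, end = a_end, length = a_end - a_start,
      sequence = sub,
      fwd_mismatches = f$mismatches[grid$fi],
      rev_mismatches = r$mismatches[grid$ri]
    )
  }

  out <- rbind(
    pair_up(fwd[fwd$strand == "+", ], rev[rev$strand == "-", ], "+"),
    pair_up(fwd[fwd$strand == "-", ], rev[rev$strand == "+", ], "-")
  )
  if (is.null(out) || nrow(out) == 0L) return(empty_amplicons())
  out <- out[order(out$start, out$end), , drop = FALSE]
  out$primary <- seq_len(nrow(out)) == order(out$length, out$start)[1L]
  out$multi_site <- nrow(out) > 1L
  tibble::as_tibble(out)
}

#' Run in silico PCR over a whole reference database
#'
#' @param db Reference-database tibble.
#' @param pset A [primer_set()].
#' @param max_mismatch Per-primer mismatch allowance; defaults to the
#'   set's own.
#' @param primary_only Keep only the primary amplicon of each record.
#' @return Amplicon tibble over all records.
#' @export
amplify_db <- function(db, pset, max_mismatch = NULL, primary_only = TRUE) {
  validate_ref_db(db)
  res <- lapply(seq_len(nrow(db)), function(i) {
    extract_amplicons(db$sequence[i], pset, max_mismatch, db$id[i])
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) return(empty_amplicons())
  if (primary_only) out <- out[out$primary, , drop = FALSE]
  out
}
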