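#' Blocking-primer design
#'
#' A blocking primer is an oligo, 3'-end chemically capped (Spacer C3) so
#' the polymerase cannot extend it, that anneals over a host-specific
#' region overlapping the universal reverse primer's binding site and so
#' suppresses amplification of host templates. Candidates are enumerated
#' from the 3'-terminal window of host amplicons: each candidate shares a
#' fixed number of bases with the 3' end of the reverse primer and
#' extends into host-specific sequence, in the same orientation as the
#' reverse primer (it anneals to the amplicon sense strand).
#'
#' @name blocking_design
NULL

#' Design constraints for blocking-primer candidates
#'
#' @param window_len Length (nt) of the 3'-terminal amplicon window the
#'   candidates are drawn from (default 40: the reverse-primer region
#'   plus upstream host-specific sequence).
#' @param min_len,max_len Candidate length bounds in nt (defaults 18 and
#'   29, i.e. strictly shorter than 30).
#' @param overlap_len Number of candidate 5' bases that sit on the 3'
#'   end of the reverse-primer binding site (default 10).
#' @param tm_tolerance Maximum allowed |Tm(candidate) - mean pair Tm| in
#'   degrees Celsius (default 3).
#' @param block_max_mismatch Mismatch allowance when deciding whether a
#'   candidate "blocks" a reference record (default 0: exact
#'   IUPAC-compatible sites only).
#' @return A `design_constraints` list.
#' @export
design_constraints <- function(window_len = 40L, min_len = 18L, max_len = 29L,
                               overlap_len = 10L, tm_tolerance = 3,
                               block_max_mismatch = 0L) {
  window_len <- as.integer(window_len); min_len <- as.integer(min_len)
  max_len <- as.integer(max_len); overlap_len <- as.integer(overlap_len)
  block_max_mismatch <- as.integer(block_max_mismatch)
  if (min_len > max_len) stop("min_len must be <= max_len", call. = FALSE)
  if (window_len < max_len) stop("window_len must be >= max_len", call. = FALSE)
  if (overlap_len >= min_len) {
    stop("overlap_len must be smaller than min_len (a candidate must extend ",
         "into host-specific sequence)", call. = FALSE)
  }
  if (tm_tolerance < 0 || block_max_mismatch < 0L) {
    stop("tm_tolerance and block_max_mismatch must be non-negative", call. = FALSE)
  }
  structure(list(window_len = window_len, min_len = min_len, max_len = max_len,
                 overlap_len = overlap_len, tm_tolerance = tm_tolerance,
                 block_max_mismatch = block_max_mismatch),
            class = "design_constraints")
}

#' Extract the 3'-terminal window of an amplicon
#'
#' Returns the last `window_len` bases of each amplicon sequence (primer
#' orientation, so the reverse-primer binding region sits at the extreme
#' 3' end of the window).
#'
#' @param amplicon_sequence Character vector of amplicon sequences in
#'   primer orientation (the `sequence` column of [extract_amplicons()]).
#' @param window_len Window length in nt.
#' @return Character vector of windows.
#' @export
extract_host_window <- function(amplicon_sequence, window_len = 40L) {
  n <- nchar(amplicon_sequence)
  if (any(n < window_len)) {
    stop("amplicon shorter (", min(n), " nt) than the requested window (",
         window_len, " nt)", call. = FALSE)
  }
  substr(amplicon_sequence, n - window_len + 1L, n)
}

#' Column-wise IUPAC consensus of right-anchored windows
#'
#' Stacks equal-length windows (they must be right-anchored at the
#' reverse-primer site) and emits, per column, the minimal IUPAC code
#' covering every base observed in that column.
#'
#' @param windows Character vector of equal-length IUPAC strings.
#' @return A single IUPAC string of the same length.
#' @export
window_consensus <- function(windows) {
  if (length(windows) < 1L) stop("need at least one window", call. = FALSE)
  if (length(unique(nchar(windows))) != 1L) {
    stop("windows must have equal length; right-anchor them at the ",
         "reverse-primer site before stacking", call. = FALSE)
  }
  masks <- lapply(windows, seq_masks)
  masks_to_seq(mask_union(masks))
}

# Modal (most frequent) base per column over concrete windows, restricted
# to columns [from, to] (1-based). Ties broken alphabetically.
modal_window <- function(windows, from, to) {
  mat <- do.call(rbind, strsplit(substr(windows, from, to), "", fixed = TRUE))
  paste0(apply(mat, 2L, function(col) {
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[tab == tab[1L]][1L]
  }), collapse = "")
}

#' Enumerate blocking-primer candidates from a host window
#'
#' Candidates are reverse complements of substrings of the host window
#' whose 5' end sits exactly `overlap_len` bases inside the
#' reverse-primer binding site, one candidate per length in
#' `[min_len, max_len]`. Each candidate therefore covers the 3'-terminal
#' `overlap_len` bases of the reverse primer and extends into
#' host-specific sequence. Every candidate is annotated with its Tm and
#' the difference to the mean Tm of the primer pair; candidates outside
#' `tm_tolerance` are reported with `passes_tm = FALSE` rather than
#' dropped.
#'
#' @param host_window Host consensus window from [window_consensus()] (or
#'   a single concrete window); its 3' end must be the reverse-primer
#'   binding region.
#' @param pset The [primer_set()] whose reverse primer the candidates
#'   overlap.
#' @param constraints A [design_constraints()] object.
#' @param windows Optional concrete windows underlying a degenerate
#'   consensus; Tm is then computed on the per-column modal base. Without
#'   them, degenerate candidate positions fall back to the
#'   alphabetically first base of the code's set for Tm only.
#' @return Tibble with columns sequence, length, overlap_len, tm,
#'   tm_delta, passes_tm; zero rows (with a warning) when the window is
#'   too short for any length.
#' @export
enumerate_candidates <- function(host_window, pset,
                                 constraints = design_constraints(),
                                 windows = NULL) {
  stopifnot(inherits(pset, "primer_set"),
            inherits(constraints, "design_constraints"))
  W <- nchar(host_window)
  rlen <- nchar(pset$reverse)
  if (W < rlen) stop("host window shorter than the reverse primer", call. = FALSE)
  # 1-based column of the window where the candidate footprint ends: the
  # reverse-primer site occupies [W - rlen + 1, W]; the candidate's 5' end
  # maps to column W - rlen + overlap_len.
  anchor <- W - rlen + constraints$overlap_len
  lens <- seq(constraints$min_len, constraints$max_len)
  lens <- lens[anchor - lens + 1L >= 1L]
  if (length(lens) == 0L) {
    warning("host window too short for any candidate length", call. = FALSE)
    return(tibble::tibble(sequence = character(0L), length = integer(0L),
                          overlap_len = integer(0L), tm = numeric(0L),
                          tm_delta = numeric(0L), passes_tm = logical(0L)))
  }
  pair_tm <- mean(c(primer_mean_tm(pset$forward), primer_mean_tm(pset$reverse)))
  rows <- lapply(lens, function(L) {
    from <- anchor - L + 1L
    cand <- revcomp(substr(host_window, from, anchor))
    concrete <- if (grepl("^[ACGT]+$", cand)) {
      cand
    } else if (!is.null(windows)) {
      revcomp(modal_window(windows, from, anchor))
    } else {
      # deterministic fallback: first base of each code's set
      paste0(vapply(strsplit(cand, "", fixed = TRUE)[[1L]],
                    function(ch) iupac_sets(ch)[1L], character(1L)),
             collapse = "")
    }
    tm <- melting_temperature(concrete)
    tibble::tibble(sequence = cand, length = L,
                   overlap_len = constraints$overlap_len,
                   tm = tm, tm_delta = tm - pair_tm)
  })
  out <- dplyr::bind_rows(rows)
  out$passes_tm <- abs(out$tm_delta) <= constraints$tm_tolerance
  out
}

#' Maximal IUPAC-aware 5' overlap between a blocking primer and the
#' reverse primer's 3' suffix
#'
#' Finds the largest `k` such that the first `k` bases of the blocking
#' oligo match the last `k` bases of the reverse primer with at most
#' `max_mismatch` IUPAC mismatches; 0 when no `k` qualifies.
#'
#' @param blocking Blocking-oligo string, 5' to 3'.
#' @param reverse_primer Reverse primer IUPAC string, 5' to 3'.
#' @param max_mismatch Mismatch allowance within the overlap (default 1).
#' @return Integer overlap length in bp.
#' @examples
#' overlap_length(blocking_18sv4bp(), primer_18sv4()$reverse) # 10
#' @export
overlap_length <- function(blocking, reverse_primer, max_mismatch = 1L) {
  stopifnot(nzchar(blocking), nzchar(reverse_primer))
  rlen <- nchar(reverse_primer)
  for (k in seq(min(nchar(blocking), rlen), 1L)) {
    if (mismatch_count(substr(blocking, 1L, k),
                       substr(reverse_primer, rlen - k + 1L, rlen)) <= max_mismatch) {
      return(k)
    }
  }
  0L
}

#' Score a candidate's blocking specificity against two pools
#'
#' A record is "blocked" when the candidate has at least one binding site
#' in it (either strand) within `block_max_mismatch` mismatches. Pools
#' should already be restricted to records the primer set amplifies.
#'
#' @param candidate Candidate oligo string.
#' @param target_db,offtarget_db Reference-database tibbles (or plain
#'   character vectors of sequences): the host pool the candidate should
#'   hit and the pool it should not.
#' @param block_max_mismatch Mismatch allowance (default 0).
#' @return List with `target_blocked_fraction` and
#'   `offtarget_blocked_fraction`, both in [0, 1].
#' @export
score_candidate <- function(candidate, target_db, offtarget_db,
                            block_max_mismatch = 0L) {
  seqs_of <- function(x) if (is.data.frame(x)) x$sequence else as.character(x)
  tg <- seqs_of(target_db)
  ot <- seqs_of(offtarget_db)
  if (length(tg) == 0L) {
    stop("empty target pool: blocking specificity is undefined", call. = FALSE)
  }
  hit <- function(s) nrow(find_primer_sites(s, candidate, block_max_mismatch)) > 0L
  list(
    target_blocked_fraction = mean(vapply(tg, hit, logical(1L))),
    offtarget_blocked_fraction = if (length(ot) == 0L) 0 else
      mean(vapply(ot, hit, logical(1L)))
  )
}

#' Rank scored candidates and pick the best
#'
#' Deterministic lexicographic ranking: maximize the target blocked
#' fraction, then minimize the off-target blocked fraction, then
#' minimize |tm_delta|, then prefer the shorter candidate, then
#' alphabetical sequence order. Permuting the input never changes the
#' winner.
#'
#' @param scored Tibble with columns sequence, length,
#'   target_blocked_fraction, offtarget_blocked_fraction, tm_delta.
#' @return The input tibble with a `rank` column added, ordered by rank;
#'   row 1 is the selected candidate.
#' @export
rank_candidates <- function(scored) {
  if (nrow(scored) == 0L) stop("no candidates to rank", call. = FALSE)
  ord <- order(-scored$target_blocked_fraction,
               scored$offtarget_blocked_fraction,
               abs(scored$tm_delta),
               scored$length,
               scored$sequence)
  out <- scored[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

#' @rdname rank_candidates
#' @param ... Passed to `rank_candidates()`.
#' @export
select_best <- function(scored, ...) {
  rank_candidates(scored, ...)[1L, , drop = FALSE]
}

#' Full blocking-primer design pipeline
#'
#' Amplifies the target (host) records in silico, stacks the 3'-terminal
#' windows of their amplicons into an IUPAC consensus, enumerates
#' candidates under the design constraints, scores each against the
#' target and off-target pools (both restricted to records the primer
#' set amplifies), and selects the best candidate among those passing
#' the Tm filter.
#'
#' @param target_db,offtarget_db Reference-database tibbles: the host
#'   clade to block and the community that must stay amplifiable.
#' @param pset The universal [primer_set()].
#' @param constraints A [design_constraints()] object.
#' @param max_mismatch Primer-matching allowance for the amplification
#'   step; defaults to the set's own.
#' @return List with `selected` (one-row tibble incl. a `spacer_3prime`
#'   flag marking the required 3' chemical cap), `candidates` (all
#'   enumerated candidates with scores and ranks), `consensus` (the host
#'   window consensus), and the pool sizes `n_target` / `n_offtarget`.
#' @export
design_blocking_primer <- function(target_db, offtarget_db, pset,
                                   constraints = design_constraints(),
                                   max_mismatch = NULL) {
  stopifnot(inherits(pset, "primer_set"))
  t_amps <- amplify_db(target_db, pset, max_mismatch)
  if (nrow(t_amps) == 0L) {
    stop(no_target_error("no target record is amplified by the primer set; ",
                         "cannot design a blocking primer"))
  }
  usable <- t_amps$length >= constraints$window_len
  if (!any(usable)) {
    stop(no_target_error("all target amplicons are shorter than the design ",
                         "window (", constraints$window_len, " nt)"))
  }
  windows <- extract_host_window(t_amps$sequence[usable], constraints$window_len)
  consensus <- window_consensus(windows)
  cands <- enumerate_candidates(consensus, pset, constraints, windows = windows)
  if (nrow(cands) == 0L) {
    stop(no_target_error("design window yields no candidate under the ",
                         "length constraints"))
  }

  o_amps <- amplify_db(offtarget_db, pset, max_mismatch)
  target_pool <- target_db[target_db$id %in% t_amps$record_id, , drop = FALSE]
  offtarget_pool <- offtarget_db[offtarget_db$id %in% o_amps$record_id, , drop = FALSE]

  scores <- lapply(cands$sequence, score_candidate,
                   target_db = target_pool, offtarget_db = offtarget_pool,
                   block_max_mismatch = constraints$block_max_mismatch)
  cands$target_blocked_fraction <- vapply(scores, `[[`, numeric(1L),
                                          "target_blocked_fraction")
  cands$offtarget_blocked_fraction <- vapply(scores, `[[`, numeric(1L),
                                             "offtarget_blocked_fraction")
  eligible <- cands[cands$passes_tm, , drop = FALSE]
  if (nrow(eligible) == 0L) {
    stop(no_target_error("no candidate passes the Tm tolerance (",
                         constraints$tm_tolerance, " degrees C)"))
  }
  ranked <- rank_candidates(eligible)
  selected <- ranked[1L, , drop = FALSE]
  selected$spacer_3prime <- TRUE
  # full report: ranked eligibles first, then Tm-filtered candidates unranked
  rest <- cands[!cands$passes_tm, , drop = FALSE]
  if (nrow(rest) > 0L) rest$rank <- NA_integer_
  list(selected = selected,
       candidates = dplyr::bind_rows(ranked, rest),
       consensus = consensus,
       n_target = nrow(target_pool),
       n_offtarget = nrow(offtarget_pool))
}

no_target_error <- function(...) {
  structure(class = c("blockprimr_no_target", "error", "condition"),
            list(message = paste0(...), call = NULL))
}
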