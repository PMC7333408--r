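#' IUPAC nucleotide codes and degenerate-sequence primitives
#'
#' Every matching operation in the package reduces to the question "can the
#' base sets denoted by two IUPAC codes intersect?". Sequences are encoded
#' internally as 4-bit masks (A=1, C=2, G=4, T=8); two positions are
#' compatible iff the bitwise AND of their masks is non-zero. A template `N`
#' therefore matches any primer code (permissive set-intersection
#' semantics).
#'
#' @name iupac
NULL

# 4-bit base masks, one per IUPAC code. U is normalized to T at ingest but
# accepted here for robustness.
.iupac_masks <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # C/G
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  B = 14L, # C/G/T
  D = 13L, # A/G/T
  H = 11L, # A/C/T
  V = 7L,  # A/C/G
  N = 15L
)

# mask -> canonical code (U collapses to T, so 16 distinct masks minus 0)
.mask_codes <- local({
  m <- .iupac_masks[names(.iupac_masks) != "U"]
  codes <- character(15L)
  codes[m] <- names(m)
  codes
})

.iupac_complement <- c(
  A = "T", C = "G", G = "C", T = "A", U = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Expand an IUPAC code to its base set
#'
#' @param code Single character, a valid IUPAC nucleotide code (case
#'   insensitive).
#' @return Character vector of the plain bases (subset of A, C, G, T) the
#'   code denotes.
#' @examples
#' iupac_sets("Y") # C T
#' iupac_sets("N") # A C G T
#' @export
iupac_sets <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 1L) {
    stop("`code` must be a single character", call. = FALSE)
  }
  m <- .iupac_masks[toupper(code)]
  if (is.na(m)) {
    stop("invalid IUPAC code: '", code, "'", call. = FALSE)
  }
  c("A", "C", "G", "T")[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L]
}

# Encode a sequence as an integer mask vector; stops on invalid characters.
# `what` names the offending sequence in error messages.
seq_masks <- function(seq, what = "sequence") {
  if (nchar(seq) == 0L) return(integer(0L))
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  m <- .iupac_masks[chars]
  if (anyNA(m)) {
    bad <- unique(chars[is.na(m)])
    stop("invalid IUPAC character(s) ", paste0("'", bad, "'", collapse = ", "),
         " in ", what, call. = FALSE)
  }
  unname(m)
}

masks_to_seq <- function(masks) {
  if (length(masks) == 0L) return("")
  paste0(.mask_codes[masks], collapse = "")
}

check_iupac <- function(seq, what = "sequence") {
  invisible(seq_masks(seq, what))
}

#' Reverse complement of an IUPAC string
#'
#' Ambiguity codes map to their set complements (Y to R, S to S, W to W,
#' K to M, N to N, ...), so `revcomp(revcomp(x)) == x`.
#'
#' @param seq IUPAC nucleotide string (may be empty).
#' @return The reverse complement, uppercase, with U written as A-pairing
#'   (U complements to A).
#' @examples
#' revcomp("CCAGCASCYGCGGTAATTCC")
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return("")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  comp <- .iupac_complement[chars]
  if (anyNA(comp)) {
    bad <- unique(chars[is.na(comp)])
    stop("invalid IUPAC character(s) ", paste0("'", bad, "'", collapse = ", "),
         call. = FALSE)
  }
  paste0(rev(unname(comp)), collapse = "")
}

#' Count IUPAC-aware mismatches between two equal-length strings
#'
#' Position i mismatches when the base sets of the two codes are disjoint;
#' any shared base counts as a match (so primer `Y` matches template `T`,
#' and template `N` matches everything).
#'
#' @param primer,window Equal-length IUPAC strings.
#' @return Integer number of mismatching positions.
#' @examples
#' mismatch_count("ACYT", "ACTT") # 0
#' @export
mismatch_count <- function(primer, window) {
  if (nchar(primer) != nchar(window)) {
    stop("`primer` and `window` must have equal length (",
         nchar(primer), " vs ", nchar(window), ")", call. = FALSE)
  }
  pm <- seq_masks(primer, "primer")
  wm <- seq_masks(window, "window")
  sum(bitwAnd(pm, wm) == 0L)
}

# Union consensus code over a character vector of equal-length strings,
# column-wise. Used by window_consensus().
mask_union <- function(masks_list) {
  Reduce(bitwOr, masks_list)
}
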