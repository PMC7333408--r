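#' Primer sets
#'
#' A primer set is a named forward/reverse pair of degenerate IUPAC
#' oligos (both written 5' to 3') with a default mismatch allowance used
#' by the in silico PCR functions.
#'
#' @param name Short set name, e.g. "18SV4".
#' @param forward,reverse IUPAC strings, 5' to 3', each at least 10 nt.
#' @param max_mismatch Default per-primer mismatch allowance (must not
#'   exceed a quarter of the shorter primer's length).
#' @return An object of class `primer_set`.
#' @examples
#' primer_set("18SV4", "CCAGCASCYGCGGTAATTCC", "ACTTTCGTTCTTGATYRA")
#' @export
primer_set <- function(name, forward, reverse, max_mismatch = 1L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  forward <- toupper(forward)
  reverse <- toupper(reverse)
  check_iupac(forward, "forward primer")
  check_iupac(reverse, "reverse primer")
  if (nchar(forward) < 10L || nchar(reverse) < 10L) {
    stop("primers must be at least 10 nt long", call. = FALSE)
  }
  max_mismatch <- as.integer(max_mismatch)
  if (max_mismatch < 0L || max_mismatch > min(nchar(forward), nchar(reverse)) / 4) {
    stop("max_mismatch must be in [0, primer length / 4]", call. = FALSE)
  }
  structure(
    list(name = name, forward = forward, reverse = reverse,
         max_mismatch = max_mismatch),
    class = "primer_set"
  )
}

#' @export
print.primer_set <- function(x, ...) {
  cat("<primer_set> ", x$name, "\n",
      "  forward: 5'-", x$forward, "-3'  (", nchar(x$forward), " nt)\n",
      "  reverse: 5'-", x$reverse, "-3'  (", nchar(x$reverse), " nt)\n",
      "  default max mismatches: ", x$max_mismatch, "\n", sep = "")
  invisible(x)
}

#' Built-in primer sets and the oyster blocking primer
#'
#' `primer_18sv4()` is the universal eukaryote V4 pair
#' (CCAGCASCYGCGGTAATTCC / ACTTTCGTTCTTGATYRA) whose reverse primer the
#' oyster blocking oligo overlaps; `primer_18sv1v2()` is the V1-V2
#' excluding pair (ACCTGGTTGATCCTGCCAGT / ARKCCWMTAYMYTACC).
#' `blocking_18sv4bp()` returns the published 25-nt Crassostrea-blocking
#' oligo TCTTGACTAATGAAAACATGCTTGG (its first 10 bases sit on the 3' end
#' of the V4 reverse primer).
#'
#' @return `primer_set` objects; `blocking_18sv4bp()` returns a character
#'   string.
#' @export
primer_18sv4 <- function() {
  primer_set("18SV4", "CCAGCASCYGCGGTAATTCC", "ACTTTCGTTCTTGATYRA",
             max_mismatch = 1L)
}

#' @rdname primer_18sv4
#' @export
primer_18sv1v2 <- function() {
  primer_set("18SV1V2", "ACCTGGTTGATCCTGCCAGT", "ARKCCWMTAYMYTACC",
             max_mismatch = 1L)
}

#' @rdname primer_18sv4
#' @export
blocking_18sv4bp <- function() {
  "TCTTGACTAATGAAAACATGCTTGG"
}
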