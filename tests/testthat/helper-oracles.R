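# Independent oracles used across the suite. These deliberately re-derive
# matching semantics from literal IUPAC tables and naive enumeration so they
# share no code path with the package internals (which use bit masks and
# vectorized sliding windows).

oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# code-vs-code compatibility matrix: TRUE when the base sets intersect
oracle_compat <- local({
  codes <- names(oracle_iupac)
  m <- matrix(FALSE, length(codes), length(codes), dimnames = list(codes, codes))
  for (a in codes) for (b in codes) {
    m[a, b] <- length(intersect(oracle_iupac[[a]], oracle_iupac[[b]])) > 0L
  }
  m
})

oracle_complement <- c(A = "T", C = "G", G = "C", T = "A",
                       R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                       B = "V", D = "H", H = "D", V = "B", N = "N")

oracle_revcomp <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  paste0(rev(unname(oracle_complement[chars])), collapse = "")
}

oracle_mismatch <- function(a, b) {
  ac <- strsplit(a, "", fixed = TRUE)[[1L]]
  bc <- strsplit(b, "", fixed = TRUE)[[1L]]
  sum(!oracle_compat[cbind(ac, bc)])
}

# Naive all-window, both-strand site scan.
oracle_sites <- function(sequence, primer, max_mismatch) {
  L <- nchar(primer)
  n <- nchar(sequence)
  rows <- list()
  if (L <= n) {
    prc <- oracle_revcomp(primer)
    for (s in 1:(n - L + 1L)) {
      win <- substr(sequence, s, s + L - 1L)
      mm_p <- oracle_mismatch(primer, win)
      if (mm_p <= max_mismatch) {
        rows[[length(rows) + 1L]] <- data.frame(
          strand = "+", start = s - 1L, end = s - 1L + L, mismatches = mm_p)
      }
      mm_m <- oracle_mismatch(prc, win)
      if (mm_m <= max_mismatch) {
        rows[[length(rows) + 1L]] <- data.frame(
          strand = "-", start = s - 1L, end = s - 1L + L, mismatches = mm_m)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(strand = character(0L), start = integer(0L),
                      end = integer(0L), mismatches = integer(0L)))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

random_seq <- function(n, ambig_frac = 0) {
  pool <- c("A", "C", "G", "T")
  chars <- sample(pool, n, replace = TRUE)
  if (ambig_frac > 0) {
    k <- rbinom(1L, n, ambig_frac)
    if (k > 0L) {
      pos <- sample.int(n, k)
      chars[pos] <- sample(c("R", "Y", "S", "W", "K", "M", "N"), k, replace = TRUE)
    }
  }
  paste0(chars, collapse = "")
}

random_primer <- function(len, n_degenerate = 0L) {
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (n_degenerate > 0L) {
    pos <- sample.int(len, n_degenerate)
    chars[pos] <- sample(c("R", "Y", "S", "W", "K", "M"), n_degenerate,
                         replace = TRUE)
  }
  paste0(chars, collapse = "")
}
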