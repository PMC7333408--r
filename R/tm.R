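#' Nearest-neighbor oligonucleotide melting temperature
#'
#' Implements the unified nearest-neighbor thermodynamic model for
#' DNA/DNA duplexes: the duplex enthalpy and entropy are the sum of the
#' ten Watson-Crick stacking contributions plus terminal initiation
#' terms, the entropy is salt-corrected, and
#' \deqn{T_m = \Delta H / (\Delta S + R \ln(C_T/4)) - 273.15}
#' for a non-self-complementary oligo at total strand concentration
#' \eqn{C_T}.
#'
#' @name melting
NULL

# Unified NN parameters (SantaLucia-type): dH in kcal/mol, dS in cal/(mol K),
# keyed by the 5'->3' top-strand dinucleotide.
.nn_dh <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
            TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
            CC = -8.0)
.nn_ds <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
            CC = -19.9)
# Duplex initiation with a terminal G.C / A.T pair
.init_dh <- c(GC = 0.1, AT = 2.3)
.init_ds <- c(GC = -2.8, AT = 4.1)

.GAS_CONSTANT <- 1.987 # cal/(mol K)

#' Melting temperature of a non-degenerate oligo
#'
#' @param seq DNA string over A/C/G/T only (degenerate candidates are
#'   evaluated on a concrete expansion chosen upstream); at least 8 nt,
#'   below which the nearest-neighbor model is unreliable.
#' @param na_molar Monovalent cation concentration in mol/L (default
#'   0.05, i.e. 50 mM); enters as the entropy correction
#'   `0.368 * (N - 1) * log(na_molar)`.
#' @param oligo_molar Total oligo concentration in mol/L (default 2.5e-7,
#'   i.e. 0.25 uM).
#' @return Tm in degrees Celsius.
#' @examples
#' melting_temperature("ACGTACGTACGTACGTACGT")
#' @export
melting_temperature <- function(seq, na_molar = 0.05, oligo_molar = 2.5e-7) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% c("A", "C", "G", "T"))) {
    stop("melting_temperature() requires a non-degenerate A/C/G/T sequence; ",
         "got '", seq, "'", call. = FALSE)
  }
  n <- length(chars)
  if (n < 8L) {
    stop("sequence too short (", n, " nt) for the nearest-neighbor model; ",
         "need at least 8 nt", call. = FALSE)
  }
  steps <- paste0(chars[-n], chars[-1L])
  dh <- sum(.nn_dh[steps])
  ds <- sum(.nn_ds[steps])
  term <- function(base) if (base %in% c("G", "C")) "GC" else "AT"
  for (b in c(chars[1L], chars[n])) {
    dh <- dh + .init_dh[[term(b)]]
    ds <- ds + .init_ds[[term(b)]]
  }
  ds_salt <- ds + 0.368 * (n - 1L) * log(na_molar)
  dh * 1000 / (ds_salt + .GAS_CONSTANT * log(oligo_molar / 4)) - 273.15
}

# Mean Tm of the full expansion of a degenerate primer (used for the
# "Tm similar to the targeted primer set" criterion). Errors if the
# primer has more than `max_expansions` concrete variants.
primer_mean_tm <- function(primer, max_expansions = 64L, ...) {
  variants <- expand_iupac(primer, max_expansions)
  mean(vapply(variants, melting_temperature, numeric(1L), ...))
}

# All concrete A/C/G/T expansions of a degenerate IUPAC string.
expand_iupac <- function(seq, max_expansions = 64L) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  sets <- lapply(chars, iupac_sets)
  n_var <- prod(lengths(sets))
  if (n_var > max_expansions) {
    stop("primer '", seq, "' has ", n_var, " expansions (> ", max_expansions,
         ")", call. = FALSE)
  }
  apply(expand.grid(sets, stringsAsFactors = FALSE), 1L, paste0, collapse = "")
}
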