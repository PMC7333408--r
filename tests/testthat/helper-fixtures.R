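# Shared fixtures built in code at test time.

V4 <- primer_18sv4()
BLK <- blocking_18sv4bp()

# A template carrying one exact amplicon of the V4 pair:
# pad5 + forward + insert + revcomp(reverse instance) + pad3.
planted_template <- function(pad5 = "AAAAAAAAAA", insert_len = 152L,
                             pad3 = "TTTTTTTTTT", rev_instance = NULL,
                             seed = 7L) {
  withr::with_seed(seed, {
    insert <- random_seq(insert_len)
    fwd_inst <- paste0(vapply(strsplit(V4$forward, "")[[1L]],
                              function(ch) oracle_iupac[[ch]][1L],
                              character(1L)), collapse = "")
    if (is.null(rev_instance)) {
      rev_instance <- paste0(vapply(strsplit(V4$reverse, "")[[1L]],
                                    function(ch) oracle_iupac[[ch]][1L],
                                    character(1L)), collapse = "")
    }
    list(sequence = paste0(pad5, fwd_inst, insert,
                           oracle_revcomp(rev_instance), pad3),
         fwd_instance = fwd_inst, rev_instance = rev_instance,
         amp_start = nchar(pad5),
         amp_end = nchar(pad5) + nchar(fwd_inst) + insert_len +
           nchar(rev_instance))
  })
}

# Small taxonomy-annotated database in memory.
toy_db <- function() {
  blockprimr:::new_ref_db(
    id = c("M1", "M2", "M3", "P1", "P2"),
    taxonomy = list(
      c("Eukaryota", "Opisthokonta", "Metazoa", "Mollusca", "Ostreoida", "Crassostrea"),
      c("Eukaryota", "Opisthokonta", "Metazoa", "Mollusca", "Ostreoida", "Ostrea"),
      c("Eukaryota", "Opisthokonta", "Metazoa", "Chordata"),
      c("Eukaryota", "Alveolata", "Dinophyceae"),
      c("Eukaryota", "Stramenopiles", "Bacillariophyta")
    ),
    sequence = vapply(1:5, function(i) withr::with_seed(11L + i, random_seq(120L)),
                      character(1L))
  )
}

# Standard synthetic study conditions: one oyster-like host clade carrying
# the blocking motif (its reverse site differs from the universal primer at
# exactly one position, implied by the motif) and three protist clades
# without it.
oyster_sim_spec <- function(seed = 101L, n_host = 20L, n_protist = 50L) {
  host <- synthetic_clade(
    "Crassostrea",
    c("Eukaryota", "Opisthokonta", "Metazoa", "Mollusca", "Ostreoida", "Crassostrea"),
    n = n_host, p_block = 1)
  protists <- list(
    synthetic_clade("Dinophyceae", c("Eukaryota", "Alveolata", "Dinophyceae"),
                    n = n_protist),
    synthetic_clade("Bacillariophyta",
                    c("Eukaryota", "Stramenopiles", "Bacillariophyta"),
                    n = n_protist),
    synthetic_clade("Chlorophyta", c("Eukaryota", "Archaeplastida", "Chlorophyta"),
                    n = n_protist)
  )
  synthetic_db_spec(c(list(host), protists), seed = seed)
}
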