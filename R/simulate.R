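#' Seeded simulator of Silva-style reference databases
#'
#' Generates reference records with planted primer sites so every other
#' module can be validated against known ground truth. Each record is
#' built as
#' `5' pad + forward-site instance + insert + [blocking motif] +
#' reverse-site instance + 3' pad`,
#' where the forward/reverse instances are concrete expansions of the
#' degenerate primers with a clade-specific number of planted
#' mismatches, the blocking motif (present with clade probability
#' `p_block`) is the sense-strand complement of the blocking oligo laid
#' so that its 3' bases coincide with the reverse-primer site (the
#' overlap geometry a blocking primer requires), and the record is
#' truncated before the reverse site with probability `q_trunc`.
#'
#' The default host clade mirrors the oyster system: a blocking-motif
#' carrying clade whose reverse-primer site differs from the universal
#' primer at exactly one position (implied by the published blocking
#' oligo itself).
#'
#' @name synthetic_db
NULL

#' Describe one simulated clade
#'
#' @param name Clade label (used in record ids).
#' @param taxonomy Character vector of rank labels, root to leaf.
#' @param n Number of records.
#' @param fwd_mismatch,rev_mismatch Mismatches planted in the forward /
#'   reverse primer site of every record (the reverse value is ignored
#'   for records that carry the blocking motif, whose site variant is
#'   dictated by the motif).
#' @param p_block Probability that a record carries the blocking motif.
#' @param q_trunc Probability that a record is truncated before the
#'   reverse-primer site.
#' @return A `synthetic_clade` list.
#' @export
synthetic_clade <- function(name, taxonomy, n, fwd_mismatch = 0L,
                            rev_mismatch = 0L, p_block = 0, q_trunc = 0) {
  stopifnot(nzchar(name), length(taxonomy) >= 1L, all(nzchar(taxonomy)),
            n >= 0L, fwd_mismatch >= 0L, rev_mismatch >= 0L,
            p_block >= 0, p_block <= 1, q_trunc >= 0, q_trunc <= 1)
  structure(list(name = name, taxonomy = taxonomy, n = as.integer(n),
                 fwd_mismatch = as.integer(fwd_mismatch),
                 rev_mismatch = as.integer(rev_mismatch),
                 p_block = p_block, q_trunc = q_trunc),
            class = "synthetic_clade")
}

#' Specification of a synthetic reference database
#'
#' @param clades List of [synthetic_clade()] objects.
#' @param seed Integer master seed; each clade derives its own stream
#'   from it, so adding a clade never perturbs earlier clades'
#'   sequences.
#' @param pset [primer_set()] whose sites are planted (default the
#'   universal V4 pair).
#' @param block_motif Blocking oligo whose sense-strand complement is
#'   planted in motif-carrying records (default the published oyster
#'   blocking oligo).
#' @param block_overlap How many 5' bases of the blocking oligo lie on
#'   the reverse-primer site (default 10).
#' @param insert_mean,insert_sd Normal insert-length distribution in nt
#'   (defaults 152 and 10; inserts shorter than 40 nt are clamped so an
#'   amplicon always accommodates the design window).
#' @param background_rate Per-base substitution rate applied to pads and
#'   insert (never to planted sites, so truth labels stay exact).
#' @param pad_range Length-2 integer range of the random pads.
#' @return A `synthetic_db_spec` list.
#' @export
synthetic_db_spec <- function(clades, seed = 1L, pset = primer_18sv4(),
                              block_motif = blocking_18sv4bp(),
                              block_overlap = 10L,
                              insert_mean = 152, insert_sd = 10,
                              background_rate = 0, pad_range = c(5L, 30L)) {
  if (inherits(clades, "synthetic_clade")) clades <- list(clades)
  stopifnot(all(vapply(clades, inherits, logical(1L), "synthetic_clade")),
            inherits(pset, "primer_set"),
            background_rate >= 0, background_rate <= 1,
            insert_mean > 0, insert_sd >= 0,
            length(pad_range) == 2L, pad_range[1L] >= 1L)
  check_iupac(block_motif, "block motif")
  stopifnot(block_overlap >= 1L, block_overlap < nchar(block_motif),
            block_overlap < nchar(pset$reverse))
  for (cl in clades) {
    if (cl$fwd_mismatch > nchar(pset$forward) ||
        cl$rev_mismatch > nchar(pset$reverse)) {
      stop("planted mismatch count exceeds primer length for clade ",
           cl$name, call. = FALSE)
    }
  }
  structure(list(clades = clades, seed = as.integer(seed), pset = pset,
                 block_motif = toupper(block_motif),
                 block_overlap = as.integer(block_overlap),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 background_rate = background_rate,
                 pad_range = as.integer(pad_range)),
            class = "synthetic_db_spec")
}

# Deterministic per-clade seed, independent of how many clades exist.
clade_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + i * 16807) %% 2147483563) + 1L
}

random_bases <- function(n) {
  if (n <= 0L) return("")
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Concrete expansion of a degenerate primer with `n_mm` planted mismatches
# (each substituted base lies outside the primer code's set).
instantiate_primer <- function(primer, n_mm) {
  chars <- strsplit(primer, "", fixed = TRUE)[[1L]]
  sets <- lapply(chars, iupac_sets)
  inst <- vapply(sets, function(s) s[sample.int(length(s), 1L)], character(1L))
  if (n_mm > 0L) {
    eligible <- which(lengths(sets) < 4L) # an N position cannot mismatch
    pos <- eligible[sample.int(length(eligible), n_mm)]
    for (p in pos) {
      alt <- setdiff(c("A", "C", "G", "T"), sets[[p]])
      inst[p] <- alt[sample.int(length(alt), 1L)]
    }
  }
  paste0(inst, collapse = "")
}

mutate_bases <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (p in hit) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste0(chars, collapse = "")
}

#' Simulate a reference database with planted truth
#'
#' Deterministic for a fixed spec and seed (two runs give byte-identical
#' FASTA output when written).
#'
#' @param spec A [synthetic_db_spec()].
#' @return List with `db` (reference-database tibble) and `truth`
#'   (tibble: record_id, clade, has_fwd_site, has_rev_site,
#'   has_block_site, truncated, fwd_mismatches, rev_mismatches,
#'   amp_start, amp_end - planted amplicon coordinates, NA when
#'   truncated).
#' @export
simulate_reference_db <- function(spec) {
  stopifnot(inherits(spec, "synthetic_db_spec"))
  pset <- spec$pset
  rlen <- nchar(pset$reverse)
  sense_block <- revcomp(spec$block_motif)
  host_tail_len <- nchar(spec$block_motif) - spec$block_overlap
  rev_head <- substr(pset$reverse, 1L, rlen - spec$block_overlap)

  all_rec <- list(); all_truth <- list()
  for (ci in seq_along(spec$clades)) {
    cl <- spec$clades[[ci]]
    if (cl$n == 0L) next
    set.seed(clade_seed(spec$seed, ci))
    ids <- sprintf("%s_%04d", cl$name, seq_len(cl$n))
    rows <- vector("list", cl$n)
    for (ri in seq_len(cl$n)) {
      pad5 <- mutate_bases(
        random_bases(sample(spec$pad_range[1L]:spec$pad_range[2L], 1L)),
        spec$background_rate)
      fwd_inst <- instantiate_primer(pset$forward, cl$fwd_mismatch)
      insert_len <- max(40L, as.integer(round(stats::rnorm(
        1L, spec$insert_mean, spec$insert_sd))))
      has_block <- stats::runif(1L) < cl$p_block
      if (has_block) {
        # reverse-site variant dictated by the blocking motif: sense-strand
        # motif followed by the complement of the primer's 5' head
        rev_head_inst <- instantiate_primer(rev_head, 0L)
        tail_sense <- paste0(sense_block, revcomp(rev_head_inst))
        rev_inst <- paste0(rev_head_inst,
                           substr(spec$block_motif, 1L, spec$block_overlap))
        insert_len <- insert_len - host_tail_len # motif replaces insert tail
      } else {
        rev_inst <- instantiate_primer(pset$reverse, cl$rev_mismatch)
        tail_sense <- revcomp(rev_inst)
      }
      insert <- mutate_bases(random_bases(insert_len), spec$background_rate)
      pad3 <- mutate_bases(
        random_bases(sample(spec$pad_range[1L]:spec$pad_range[2L], 1L)),
        spec$background_rate)
      truncated <- stats::runif(1L) < cl$q_trunc
      amp_start <- nchar(pad5)
      if (truncated) {
        seqs <- paste0(pad5, fwd_inst,
                       substr(insert, 1L, insert_len %/% 2L))
        amp_end <- NA_integer_
      } else {
        seqs <- paste0(pad5, fwd_inst, insert, tail_sense, pad3)
        amp_end <- amp_start + nchar(fwd_inst) + insert_len + nchar(tail_sense)
      }
      rows[[ri]] <- list(
        sequence = seqs,
        truth = tibble::tibble(
          record_id = ids[ri], clade = cl$name,
          has_fwd_site = TRUE,
          has_rev_site = !truncated,
          has_block_site = has_block && !truncated,
          truncated = truncated,
          fwd_mismatches = cl$fwd_mismatch,
          rev_mismatches = if (truncated) NA_integer_ else
            mismatch_count(rev_inst, pset$reverse),
          amp_start = amp_start, amp_end = amp_end
        )
      )
    }
    all_rec[[ci]] <- new_ref_db(
      ids, rep(list(cl$taxonomy), cl$n),
      vapply(rows, `[[`, character(1L), "sequence"))
    all_truth[[ci]] <- dplyr::bind_rows(lapply(rows, `[[`, "truth"))
  }
  db <- dplyr::bind_rows(all_rec)
  if (nrow(db) == 0L) {
    db <- new_ref_db(character(0L), list(), character(0L))
  }
  list(db = db, truth = dplyr::bind_rows(all_truth))
}

#' Analytic expectations for a simulated database
#'
#' Closed-form per-clade expectations of the profile fractions, for
#' comparison against observed [profile_groups()] output: a record is
#' amplifiable when it is not truncated and both planted sites fall
#' within the matching allowance, and blocked when it additionally
#' carries the blocking motif (found exactly, per the default blocking
#' allowance of 0).
#'
#' @param spec A [synthetic_db_spec()].
#' @param max_mismatch Matching allowance assumed for amplification
#'   (default the primer set's own).
#' @param with_blocking Whether the profile being predicted uses the
#'   blocking oligo.
#' @return Tibble with one row per clade: expected_amplifiable,
#'   expected_amplified, expected_blocked, expected_incomplete.
#' @export
planted_truth_profile <- function(spec, max_mismatch = NULL,
                                  with_blocking = TRUE) {
  stopifnot(inherits(spec, "synthetic_db_spec"))
  if (is.null(max_mismatch)) max_mismatch <- spec$pset$max_mismatch
  rlen <- nchar(spec$pset$reverse)
  # mismatches of the motif-implied reverse-site variant vs the primer
  block_rev_mm <- mismatch_count(
    substr(spec$block_motif, 1L, spec$block_overlap),
    substr(spec$pset$reverse, rlen - spec$block_overlap + 1L, rlen))
  rows <- lapply(spec$clades, function(cl) {
    fwd_ok <- cl$fwd_mismatch <= max_mismatch
    amp_block <- fwd_ok && block_rev_mm <= max_mismatch
    amp_plain <- fwd_ok && cl$rev_mismatch <= max_mismatch
    amplifiable <- (1 - cl$q_trunc) *
      (cl$p_block * amp_block + (1 - cl$p_block) * amp_plain)
    blocked <- if (with_blocking) (1 - cl$q_trunc) * cl$p_block * amp_block else 0
    tibble::tibble(
      clade = cl$name,
      expected_amplifiable = amplifiable,
      expected_amplified = amplifiable - blocked,
      expected_blocked = blocked,
      expected_incomplete = cl$q_trunc
    )
  })
  dplyr::bind_rows(rows)
}
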