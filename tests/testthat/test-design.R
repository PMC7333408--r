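test_that("host windows are the 3'-terminal slice of the amplicon", {
  tpl <- planted_template(insert_len = 152L)
  amp <- extract_amplicons(tpl$sequence, V4, 1L)
  expect_identical(amp$length, 190L)
  w <- extract_host_window(amp$sequence, 40L)
  expect_identical(w, substr(amp$sequence, 151L, 190L))
  # window ends with the planted reverse-primer binding region
  expect_identical(substr(w, 23L, 40L), revcomp(tpl$rev_instance))
  expect_identical(extract_host_window(amp$sequence, amp$length), amp$sequence)
  expect_error(extract_host_window("ACGT", 40L), "shorter")
})

test_that("window_consensus stacks columns into minimal IUPAC codes", {
  expect_identical(window_consensus("ACGT"), "ACGT")
  expect_identical(window_consensus(c("ACGT", "ACTT")), "ACKT")
  expect_identical(window_consensus(c("ACGT", "TGCA")), "WSSW")
  expect_error(window_consensus(c("ACGT", "ACG")), "right-anchor")
  # zero divergence: 50 copies of one haplotype give the haplotype back
  set.seed(41)
  hap <- random_seq(40L)
  expect_identical(window_consensus(rep(hap, 50L)), hap)
})

test_that("candidates obey the length and overlap constraints", {
  tpl <- planted_template(insert_len = 152L)
  w <- extract_host_window(extract_amplicons(tpl$sequence, V4, 1L)$sequence, 40L)
  cands <- enumerate_candidates(w, V4)
  expect_identical(cands$length, 18:29)
  expect_true(all(cands$length < 30L))
  expect_true(all(cands$overlap_len == 10L))
  # each candidate's 5' end sits 10 bases inside the reverse-primer site:
  # its first 10 bases must match the primer's 3' suffix here (site planted
  # exactly, so zero mismatches)
  for (s in cands$sequence) {
    expect_identical(overlap_length(s, V4$reverse, 0L), 10L)
  }
  # degenerate constraint: min_len = max_len = L gives exactly one candidate
  one <- enumerate_candidates(w, V4, design_constraints(min_len = 25L, max_len = 25L))
  expect_identical(nrow(one), 1L)
  expect_identical(one$length, 25L)
})

test_that("the published oyster blocking oligo arises from its own window", {
  # sense-strand window: pad + host-specific motif + the rest of the
  # reverse-primer site the oligo implies (the motif's last 10 sense bases
  # ARE the start of the site)
  set.seed(45)
  rev_head <- substr(V4$reverse, 1L, 8L) # ACTTTCGT, no ambiguity codes
  window <- paste0(random_seq(7L), revcomp(BLK), revcomp(rev_head))
  expect_identical(nchar(window), 40L)
  cands <- enumerate_candidates(window, V4)
  expect_true(BLK %in% cands$sequence)
  expect_identical(cands$sequence[cands$length == 25L], BLK)
})

test_that("overlap_length scans k down from the full primer length", {
  expect_identical(overlap_length(BLK, V4$reverse, 1L), 10L)
  expect_identical(overlap_length(BLK, V4$reverse, 0L), 0L) # the single
  # mismatch inside the 10-base overlap forbids any exact-match k
  x <- "ACGTACGTACGTACG"
  expect_identical(overlap_length(x, x, 0L), nchar(x))
  expect_identical(overlap_length(strrep("G", 12L), strrep("A", 12L), 0L), 0L)
})

test_that("score_candidate counts hit fractions over both pools", {
  set.seed(51)
  motif <- random_seq(22L)
  host <- vapply(1:20, function(i) paste0(random_seq(30L), motif, random_seq(30L)),
                 character(1L))
  prot <- vapply(1:50, function(i) random_seq(82L), character(1L))
  sc <- score_candidate(revcomp(motif), host, prot, 0L)
  expect_identical(sc$target_blocked_fraction, 1)
  expect_identical(sc$offtarget_blocked_fraction, 0)
  none <- score_candidate(strrep("ACGTG", 5L), host, prot, 0L)
  expect_identical(none$target_blocked_fraction, 0)
  expect_error(score_candidate(motif, character(0L), prot), "empty target")
})

test_that("a partially conserved pool scores inside the binomial interval", {
  set.seed(52)
  p <- 0.82; n <- 500L
  motif <- random_seq(25L)
  keep <- runif(n) < p
  pool <- vapply(seq_len(n), function(i) {
    core <- if (keep[i]) motif else random_seq(25L)
    paste0(random_seq(20L), core, random_seq(20L))
  }, character(1L))
  sc <- score_candidate(revcomp(motif), pool, character(0L), 0L)
  ci <- p + c(-1, 1) * qnorm(0.995) * sqrt(p * (1 - p) / n)
  expect_gte(sc$target_blocked_fraction, ci[1L])
  expect_lte(sc$target_blocked_fraction, ci[2L])
})

test_that("candidate ranking is lexicographic and order-invariant", {
  scored <- tibble::tibble(
    sequence = c("CCCC", "AAAA", "GGGG", "TTTT", "AATT"),
    length = c(20L, 20L, 20L, 18L, 18L),
    target_blocked_fraction = c(1, 1, 0.9, 1, 1),
    offtarget_blocked_fraction = c(0, 0.1, 0, 0, 0),
    tm_delta = c(1.5, 0.2, 0.1, 1.5, 1.5)
  )
  best <- select_best(scored)
  # (1, 0) beats (1, .1) and (.9, 0); ties through Tm resolved by length,
  # then sequence
  expect_identical(best$sequence, "AATT")
  set.seed(53)
  for (i in 1:10) {
    perm <- scored[sample.int(nrow(scored)), ]
    expect_identical(select_best(perm)$sequence, "AATT")
    expect_identical(rank_candidates(perm)$sequence,
                     rank_candidates(scored)$sequence)
  }
  expect_error(select_best(scored[0L, ]), "no candidates")
})

test_that("end-to-end design on a planted database is perfectly specific", {
  sim <- simulate_reference_db(oyster_sim_spec(seed = 404L))
  parts <- partition_by_label(sim$db, "Metazoa")
  res <- design_blocking_primer(parts$matching, parts$non_matching, V4)
  expect_identical(res$selected$target_blocked_fraction, 1)
  expect_identical(res$selected$offtarget_blocked_fraction, 0)
  expect_identical(res$n_target, 20L)
  expect_identical(res$n_offtarget, 150L)
  # selected primer satisfies every constraint post hoc
  cons <- design_constraints()
  expect_lt(res$selected$length, 30L)
  expect_gte(res$selected$length, cons$min_len)
  expect_identical(overlap_length(res$selected$sequence, V4$reverse, 1L),
                   cons$overlap_len)
  expect_lte(abs(res$selected$tm_delta), cons$tm_tolerance)
  expect_true(res$selected$spacer_3prime)
  # the published oligo is among the fully specific candidates
  hit <- res$candidates[res$candidates$sequence == BLK, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$target_blocked_fraction, 1)
  expect_identical(hit$offtarget_blocked_fraction, 0)
})

test_that("design fails loudly when nothing is amplifiable", {
  db <- toy_db() # random 120-mers: no primer sites
  expect_error(design_blocking_primer(db, db[0L, ], V4),
               class = "blockprimr_no_target")
})
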