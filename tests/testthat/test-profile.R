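test_that("classification covers all four exclusive states", {
  # a full amplicon whose 3' region carries the blocking motif: the motif's
  # last 10 sense bases double as the start of the reverse-primer site
  rev_head <- substr(V4$reverse, 1L, 8L)
  fwd_inst <- chartr("SY", "CC", V4$forward)
  insert <- withr::with_seed(4L, random_seq(140L))
  seq_blk <- paste0(strrep("A", 10L), fwd_inst, insert,
                    revcomp(BLK), revcomp(rev_head), strrep("T", 10L))
  tpl <- list(amp_start = 10L)

  with_bp <- classify_record(seq_blk, V4, blocking = BLK)
  expect_identical(with_bp$status, "BLOCKED")
  no_bp <- classify_record(seq_blk, V4)
  expect_identical(no_bp$status, "AMPLIFIED")
  expect_identical(no_bp$amplicon_length, with_bp$amplicon_length)

  # truncation before the reverse site
  trunc <- substr(seq_blk, 1L, tpl$amp_start + 80L)
  expect_identical(classify_record(trunc, V4, blocking = BLK)$status, "INCOMPLETE")
  # no sites at all
  expect_identical(classify_record(withr::with_seed(5L, random_seq(200L)),
                                   V4)$status, "NO_SITE")
})

test_that("removing the blocking oligo only converts BLOCKED to AMPLIFIED", {
  host <- synthetic_clade("Host", c("Eukaryota", "Metazoa", "Crassostrea"),
                          30L, p_block = 0.5, q_trunc = 0.2)
  prot <- synthetic_clade("Prot", c("Eukaryota", "Alveolata"), 30L, q_trunc = 0.1)
  db <- simulate_reference_db(synthetic_db_spec(list(host, prot), seed = 66L))$db
  with_bp <- classify_db(db, V4, blocking = BLK)
  no_bp <- classify_db(db, V4)
  changed <- with_bp$status != no_bp$status
  expect_true(all(with_bp$status[changed] == "BLOCKED"))
  expect_true(all(no_bp$status[changed] == "AMPLIFIED"))
  # one status per record per config
  expect_identical(nrow(with_bp), nrow(db))
  expect_true(all(with_bp$status %in%
                    c("AMPLIFIED", "BLOCKED", "NO_SITE", "INCOMPLETE")))
})

test_that("completeness filtering keeps full-span records inside the bounds", {
  spec <- synthetic_db_spec(
    list(synthetic_clade("Full", c("Eukaryota", "A"), 10L),
         synthetic_clade("Cut", c("Eukaryota", "B"), 5L, q_trunc = 1)),
    seed = 91L)
  db <- simulate_reference_db(spec)$db
  kept <- completeness_filter(db, V4, length_bounds = c(100L, 400L))
  expect_identical(kept$id, db$id[startsWith(db$id, "Full")])
  # bounds excluding the planted length
  expect_identical(nrow(completeness_filter(db, V4, length_bounds = c(10L, 50L))), 0L)
  # widening the bounds never removes records
  set.seed(92)
  prev <- character(0L)
  for (width in c(0L, 50L, 200L, 1000L)) {
    ids <- completeness_filter(db, V4, length_bounds = c(190L - width, 200L + width))$id
    expect_true(all(prev %in% ids))
    prev <- ids
  }
})

test_that("group profiles conserve counts and refine across ranks", {
  sim <- simulate_reference_db(oyster_sim_spec(seed = 31L, n_host = 15L,
                                               n_protist = 20L))
  cfgs <- list(primer_config(V4, blocking = BLK),
               primer_config(V4, name = "18SV4-noBP"))
  prof <- profile_groups(sim$db, cfgs, rank = 2L)
  for (cfg in unique(prof$config)) {
    p <- prof[prof$config == cfg, ]
    expect_identical(sum(p$n), nrow(sim$db))
    expect_identical(p$n_amplified + p$n_blocked + p$n_no_site + p$n_incomplete,
                     p$n)
    expect_true(all(p$fraction_blocked >= 0 & p$fraction_blocked <= 1))
    # ordered by descending group size
    expect_true(all(diff(p$n) <= 0L))
  }
  # rank-3 groups partition their rank-2 parents
  prof3 <- profile_groups(sim$db, cfgs[[1L]], rank = 3L)
  tax2 <- blockprimr:::group_at_rank(sim$db$taxonomy, 2L)
  tax3 <- blockprimr:::group_at_rank(sim$db$taxonomy, 3L)
  parent_of <- tapply(tax2, tax3, unique)
  child_sum <- tapply(prof3$n[match(names(parent_of), prof3$group)],
                      unlist(parent_of), sum)
  p2 <- prof[prof$config == "18SV4+BP", ]
  expect_identical(as.integer(child_sum[p2$group]), as.integer(p2$n))

  # planted truth: host fully blocked, protists untouched
  host_row <- prof[prof$config == "18SV4+BP" & prof$group == "Opisthokonta", ]
  expect_identical(host_row$fraction_blocked, 1)
  other <- prof[prof$config == "18SV4+BP" & prof$group != "Opisthokonta", ]
  expect_true(all(other$fraction_blocked == 0))
  expect_true(all(other$fraction_amplified == 1))
})

test_that("records annotated shallower than the rank go to 'unresolved'", {
  db <- toy_db()
  prof <- profile_groups(db, primer_config(V4), rank = 5L)
  expect_true("unresolved" %in% prof$group)
  expect_identical(sum(prof$n), nrow(db))
})

test_that("configuration deltas are zero on identity and bounded in [-1, 1]", {
  sim <- simulate_reference_db(oyster_sim_spec(seed = 32L, n_host = 10L,
                                               n_protist = 15L))
  pa <- profile_groups(sim$db, primer_config(V4, name = "A"), rank = 2L)
  pb <- profile_groups(sim$db, primer_config(V4, name = "B"), rank = 2L)
  d0 <- compare_primer_sets(pa, pb)
  expect_true(all(d0$delta_amplified == 0))
  expect_true(all(!d0$exclusive))

  pc <- profile_groups(sim$db, primer_config(V4, blocking = BLK, name = "C"),
                       rank = 2L)
  d1 <- compare_primer_sets(pa, pc)
  expect_true(all(d1$delta_amplified >= -1 & d1$delta_amplified <= 1))
  # the host group is amplified by A only under C's blocking -> delta 1, exclusive
  host <- d1[d1$group == "Opisthokonta", ]
  expect_identical(host$delta_amplified, 1)
  expect_true(host$exclusive)

  expect_error(compare_primer_sets(pa, pc[-1L, ]), "same records")
})
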