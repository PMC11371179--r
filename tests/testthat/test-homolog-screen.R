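test_that("domain coverage merges overlapping hits and matches brute force", {
  hits <- tibble::tibble(hmm_from = c(10L, 30L), hmm_to = c(40L, 80L))
  expect_equal(domain_coverage(hits, model_length = 100), 0.71)
  expect_equal(domain_coverage(tibble::tibble(hmm_from = 1L, hmm_to = 100L),
                               model_length = 100), 1)
  expect_equal(domain_coverage(tibble::tibble(hmm_from = integer(),
                                              hmm_to = integer()),
                               model_length = 100), 0)

  set.seed(11)
  for (i in 1:50) {
    k <- sample(1:10, 1)
    ml <- sample(50:300, 1)
    from <- sample(seq_len(ml), k, replace = TRUE)
    to <- pmin(ml, from + sample(0:80, k, replace = TRUE))
    h <- tibble::tibble(hmm_from = from, hmm_to = to)
    expect_equal(domain_coverage(h, ml), brute_coverage(from, to, ml))
  }
})

test_that("family completeness uses strict per-family thresholds", {
  expect_false(family_completeness(list(Enolase_N = 0.95, Enolase_C = 0.85),
                                   "enolase"))
  expect_false(family_completeness(list(Enolase_N = 0.90, Enolase_C = 0.95),
                                   "enolase"))
  expect_true(family_completeness(list(Enolase_N = 0.91, Enolase_C = 0.95),
                                  "enolase"))
  expect_true(family_completeness(list(His_Phos = 0.51), "pgam1"))
  expect_false(family_completeness(list(His_Phos = 0.50), "pgam2"))
  # missing model counts as zero coverage
  expect_false(family_completeness(list(Enolase_N = 0.99), "enolase"))
})

test_that("presequence room is a strict 20-aa boundary on 1-based ali_from", {
  hit_at <- function(p) tibble::tibble(ali_from = p)
  expect_false(presequence_room(hit_at(15L)))
  expect_false(presequence_room(hit_at(20L)))
  expect_true(presequence_room(hit_at(21L)))
  expect_false(presequence_room(hit_at(c(40L, 1L))))
  expect_error(presequence_room(hit_at(integer())), "without domain hits")
})

test_that("Met trimming takes the first methionine at position >= 2", {
  expect_equal(trim_to_first_met("MAAMKL"), "MKL")
  expect_equal(trim_to_first_met("AKLMR"), "MR")
  expect_true(is.na(trim_to_first_met("AKLPR")))
  expect_true(is.na(trim_to_first_met("MAAAA")))
})

test_that("consensus localization follows lineage rules and precedence", {
  mk <- function(...) tibble::tibble(...)
  # secondary plastid: HECTAR or ASAFind on either variant
  calls <- mk(predictor = c("HECTAR", "ASAFind"),
              variant = "complete", call = c("plastid", "other"),
              score = NA_real_)
  expect_equal(consensus_localization(calls, "secondary_plastid")$consensus,
               "plastid")
  # trimmed-variant call alone suffices
  calls <- mk(predictor = c("ASAFind", "ASAFind"),
              variant = c("complete", "met_trimmed"),
              call = c("other", "plastid"), score = NA_real_)
  expect_equal(consensus_localization(calls, "secondary_plastid")$consensus,
               "plastid")
  # TargetP does not qualify for secondary-plastid lineages
  calls <- mk(predictor = "TargetP", variant = "complete", call = "plastid",
              score = NA_real_)
  expect_equal(consensus_localization(calls, "secondary_plastid")$consensus,
               "other")
  expect_equal(consensus_localization(calls, "primary_plastid")$consensus,
               "plastid")
  # MitoFates threshold at 0.35
  calls <- mk(predictor = "MitoFates", variant = "complete", call = "other",
              score = 0.40)
  expect_equal(consensus_localization(calls, "primary_plastid")$consensus,
               "mitochondrion")
  calls$score <- 0.30
  expect_equal(consensus_localization(calls, "primary_plastid")$consensus,
               "other")
  # plastid precedence over mitochondrion
  calls <- mk(predictor = c("HECTAR", "MitoFates"), variant = "complete",
              call = c("plastid", "other"), score = c(NA, 0.9))
  expect_equal(consensus_localization(calls, "secondary_plastid")$consensus,
               "plastid")
  # prokaryotes and empty call sets give other
  expect_equal(consensus_localization(calls, "prokaryote")$consensus, "other")
  expect_equal(consensus_localization(calls[0, ], "primary_plastid")$consensus,
               "other")
  # WoLFPSORT never drives the call
  calls <- mk(predictor = "WoLFPSORT", variant = "complete", call = "plastid",
              score = NA_real_)
  expect_equal(consensus_localization(calls, "secondary_plastid")$consensus,
               "other")
})

test_that("consensus localization is order-independent", {
  set.seed(5)
  calls <- tibble::tibble(
    predictor = c("HECTAR", "ASAFind", "MitoFates", "WoLFPSORT"),
    variant = c("complete", "met_trimmed", "complete", "complete"),
    call = c("other", "plastid", "other", "secretory"),
    score = c(NA, NA, 0.6, NA)
  )
  ref <- consensus_localization(calls, "secondary_plastid")
  for (i in 1:10) {
    shuf <- calls[sample(nrow(calls)), ]
    expect_identical(consensus_localization(shuf, "secondary_plastid"), ref)
  }
})

test_that("reciprocal best hit keeps only queries whose top hit is in set", {
  rows <- tibble::tibble(
    qseqid = c("q1", "q1", "q2", "q3", "q3"),
    sseqid = c("bad", "good", "good", "s_b", "s_a"),
    evalue = c(1e-80, 1e-60, 1e-40, 1e-40, 1e-50),
    bitscore = c(250, 200, 150, 200, 200)
  )
  # q1: best (250) not in set; q2: single hit in set; q3: bitscore tie broken
  # by lower e-value -> s_a
  expect_equal(reciprocal_best_hit(rows, c("good", "s_a")), c("q2", "q3"))
  expect_equal(reciprocal_best_hit(rows[0, ], "good"), character())
  # invariant under row shuffling
  set.seed(9)
  for (i in 1:10) {
    expect_equal(reciprocal_best_hit(rows[sample(nrow(rows)), ],
                                     c("good", "s_a")), c("q2", "q3"))
  }
  # bitscore and evalue tie -> lexicographic subject
  tie <- tibble::tibble(qseqid = "q", sseqid = c("zz", "aa"),
                        evalue = 1e-10, bitscore = 100)
  expect_equal(reciprocal_best_hit(tie, "aa"), "q")
  expect_equal(reciprocal_best_hit(tie, "zz"), character())
})

test_that("screen_proteins forces other when structural gates fail", {
  prot <- simulate_protein_set(seed = 21)
  calls <- simulate_predictor_table(prot$truth, 1, 1, seed = 22)
  v <- screen_proteins(prot$records, prot$hits, calls, family = "enolase")
  truth <- prot$truth[match(v$seq_id, prot$truth$seq_id), ]
  expect_equal(v$consensus, truth$true_localization)
  # plastid verdicts imply both gates passed
  pl <- v[v$consensus == "plastid", ]
  expect_true(all(pl$domain_complete & pl$presequence_room))
  expect_true(all(nzchar(pl$evidence)))
  # no-room and incomplete classes end as other despite plastid calls
  expect_true(all(v$consensus[truth$class %in% c("no_room", "incomplete")] ==
                    "other"))
  expect_error(
    screen_proteins(tibble::tibble(seq_id = "ghost", sequence = "MA",
                                   lineage_class = "secondary_plastid"),
                    prot$hits, calls, family = "enolase"),
    "undeterminable"
  )
})

test_that("domtblout parsing round-trips and validates coordinates", {
  hits <- tibble::tibble(
    seq_id = c("s1", "s1", "s2"),
    model_name = c("Enolase_N", "Enolase_C", "His_Phos"),
    model_length = c(130L, 296L, 176L),
    hmm_from = c(5L, 1L, 10L), hmm_to = c(120L, 296L, 100L),
    ali_from = c(40L, 170L, 25L), ali_to = c(155L, 465L, 115L),
    i_evalue = c(1e-40, 2.5e-60, 1e-12)
  )
  path <- withr::local_tempfile(fileext = ".domtblout")
  write_domtblout(hits, path)
  parsed <- parse_domtblout(path)
  expect_equal(parsed[, names(hits)], hits, tolerance = 1e-6)

  # comment lines are skipped; an empty file gives an empty table
  empty <- withr::local_tempfile(fileext = ".domtblout")
  writeLines(c("# comment", "#"), empty)
  expect_equal(nrow(parse_domtblout(empty)), 0L)

  bad <- withr::local_tempfile(fileext = ".domtblout")
  hits_bad <- hits[1, ]
  hits_bad$hmm_from <- 200L  # > hmm_to
  write_domtblout(hits_bad, bad)
  expect_error(parse_domtblout(bad), "line")
})
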