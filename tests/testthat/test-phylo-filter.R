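test_that("e-value prefilter is inclusive at the threshold", {
  ev <- c(a = 1e-12, b = 1e-9, c = 1e-10, d = 0)
  expect_equal(prefilter_evalue(ev), c("a", "c", "d"))
  expect_equal(prefilter_evalue(ev, threshold = 1e-8), c("a", "b", "c", "d"))
})

test_that("midpoint rooting equalises the diameter endpoints", {
  # two tips: root exactly halfway
  tr <- ape::read.tree(text = "(A:3,B:1);")
  expect_equal(midpoint_root(tr)$edge.length, c(2, 2))
  # midpoint on C's edge, 2.5 from every tip here
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:3);")
  rt <- midpoint_root(tr)
  expect_equal(max_root_to_tip(rt), 2.5, tolerance = 1e-12)
  d <- ape::dist.nodes(rt)
  root <- ape::Ntip(rt) + 1L
  expect_equal(unname(d[root, which(rt$tip.label == "C")]), 2.5)
  expect_equal(unname(d[root, which(rt$tip.label == "A")]), 2.5)
  # degenerate input
  tr0 <- ape::read.tree(text = "(A:0,B:0);")
  expect_error(midpoint_root(tr0), "midpoint undefined")
})

test_that("midpoint rooting matches the exhaustive edge-placement oracle", {
  set.seed(42)
  for (i in 1:40) {
    tr <- ape::rtree(sample(4:12, 1))
    rt <- midpoint_root(tr)
    expect_equal(max_root_to_tip(rt), brute_min_eccentricity(tr),
                 tolerance = 1e-9)
    # max root-to-tip equals half the diameter
    expect_equal(max_root_to_tip(rt), max(ape::cophenetic.phylo(tr)) / 2,
                 tolerance = 1e-9)
  }
})

test_that("midpoint rooting agrees with phangorn's implementation", {
  set.seed(21)
  for (i in 1:20) {
    tr <- ape::rtree(sample(4:15, 1))
    ours <- max_root_to_tip(midpoint_root(tr))
    theirs <- max_root_to_tip(phangorn::midpoint(tr))
    expect_equal(ours, theirs, tolerance = 1e-9)
  }
})

test_that("midpoint rooting is stable under unroot-and-reroot", {
  set.seed(7)
  for (i in 1:10) {
    tr <- ape::rtree(8)
    r1 <- midpoint_root(tr)
    r2 <- midpoint_root(ape::unroot(r1))
    d1 <- unname(sort(ape::dist.nodes(r1)[ape::Ntip(r1) + 1L, 1:8]))
    d2 <- unname(sort(ape::dist.nodes(r2)[ape::Ntip(r2) + 1L, 1:8]))
    expect_equal(d1, d2, tolerance = 1e-9)
  }
})

test_that("midpoint exactly on an internal node keeps that node as root", {
  # diameter A-C = 8; the midpoint sits exactly on the (A,B) cherry node
  tr <- ape::read.tree(text = "((A:4,B:1):1,(C:2,D:1):1);")
  rt <- midpoint_root(tr)
  expect_equal(max_root_to_tip(rt), 4, tolerance = 1e-12)
  # that node becomes a basal multifurcation; no zero-length edge inserted
  root <- ape::Ntip(rt) + 1L
  expect_equal(sum(rt$edge[, 1] == root), 3L)
  expect_false(any(rt$edge.length < 1e-12))
})

test_that("outgroup rooting requires a bipartitioning outgroup", {
  tr <- ape::read.tree(text = "((O1:1,O2:1):1,(A:1,B:1):1);")
  rt <- outgroup_root(tr, c("O1", "O2"))
  expect_true(ape::is.rooted(rt))
  expect_true(ape::is.monophyletic(rt, c("O1", "O2")))
  expect_error(outgroup_root(tr, c("O1", "A")), "bipartition")
  expect_error(outgroup_root(tr, "ghost"), "not in tree")
  rt1 <- outgroup_root(tr, "O1")
  expect_true(ape::is.rooted(rt1))
})

test_that("environmental-tip retention matches the clade-enumeration oracle", {
  # worked example: env sister to diatom ref, pair sister to other_ref
  tr <- ape::read.tree(text = "(((env1:1,dia:1):1,oth:1):1,dia2:3);")
  labs <- tibble::tibble(
    tip_id = c("env1", "dia", "oth", "dia2"),
    category = c("environmental", "diatom_plastid_ref", "other_ref",
                 "diatom_plastid_ref")
  )
  res <- retain_env_tips(tr, labs)
  expect_true(res$retained)
  expect_equal(res$anchor_ref_categories, "diatom_plastid_ref")
  # env sister to other_ref is dropped
  tr2 <- ape::read.tree(text = "(((env1:1,oth:1):1,dia:1):1,dia2:3);")
  expect_false(retain_env_tips(tr2, labs)$retained)
  # an env-only cherry anchored under pure diatom refs: both retained
  tr3 <- ape::read.tree(
    text = "((((env1:1,env2:1):1,dia:1):1,dia2:1):1,oth:3);"
  )
  labs3 <- tibble::tibble(
    tip_id = c("env1", "env2", "dia", "dia2", "oth"),
    category = c("environmental", "environmental", "diatom_plastid_ref",
                 "diatom_plastid_ref", "other_ref")
  )
  expect_equal(retain_env_tips(tr3, labs3)$retained, c(TRUE, TRUE))

  set.seed(13)
  for (i in 1:60) {
    rl <- random_labeled_tree(sample(5:16, 1))
    got <- retain_env_tips(rl$tree, rl$labels)
    want <- brute_retention(rl$tree, rl$labels)
    expect_equal(got$retained, unname(want))
  }
})

test_that("retention is invariant under sibling rotation", {
  set.seed(3)
  rl <- random_labeled_tree(12)
  ref <- retain_env_tips(rl$tree, rl$labels)
  rot <- ape::rotateConstr(rl$tree, sample(rl$tree$tip.label))
  got <- retain_env_tips(rot, rl$labels)
  expect_equal(got[order(got$tip_id), ]$retained,
               ref[order(ref$tip_id), ]$retained)
})

test_that("retention errors on unusable labelings", {
  tr <- ape::read.tree(text = "((env1:1,dia:1):1,oth:1);")
  labs <- tibble::tibble(tip_id = c("env1", "dia", "oth"),
                         category = c("environmental", "diatom_plastid_ref",
                                      "other_ref"))
  expect_error(retain_env_tips(tr, labs[-1, ]), "unlabeled")
  no_dia <- labs
  no_dia$category[2] <- "other_ref"
  expect_error(retain_env_tips(tr, no_dia), "at least one")
})

test_that("run_sieve composes the stage gates in order", {
  sim <- simulate_labeled_tree(n_env = 6, p_misplaced = 0.5, seed = 31)
  env_ids <- sim$truth$tip_id
  ev <- stats::setNames(rep(1e-20, length(env_ids)), env_ids)
  ev["env_1"] <- 1e-5  # fails the hmmer gate
  genome <- tibble::tibble(
    qseqid = env_ids, sseqid = "enolase_gene", evalue = 1e-30, bitscore = 200
  )
  genome$sseqid[genome$qseqid == "env_2"] <- "unrelated_gene"
  alignment <- tibble::tibble(
    qseqid = env_ids, sseqid = "dia_1", evalue = 1e-30, bitscore = 180
  )
  res <- run_sieve(ev, genome, "enolase_gene", alignment, "dia_1",
                   sim$tree, sim$labels)
  expect_false("env_1" %in% res$retained)  # dropped before the tree stage
  expect_false("env_2" %in% res$retained)
  survivors <- setdiff(env_ids, c("env_1", "env_2"))
  truth <- sim$truth[match(survivors, sim$truth$tip_id), ]
  expect_equal(res$retained, sort(survivors[truth$retained_truth]))
  audit <- res$audit
  expect_false(audit$pass_evalue[audit$id == "env_1"])
  expect_true(audit$pass_evalue[audit$id == "env_2"])
  expect_false(audit$pass_genome_rbh[audit$id == "env_2"])
  # empty candidate set: empty result, no error
  empty <- run_sieve(stats::setNames(numeric(), character()), genome,
                     "enolase_gene", alignment, "dia_1", sim$tree, sim$labels)
  expect_equal(empty$retained, character())
  # survivor missing from the tree is an explicit error
  ev2 <- c(ev, ghost = 1e-30)
  genome2 <- dplyr::bind_rows(genome, tibble::tibble(
    qseqid = "ghost", sseqid = "enolase_gene", evalue = 1e-30, bitscore = 200
  ))
  alignment2 <- dplyr::bind_rows(alignment, tibble::tibble(
    qseqid = "ghost", sseqid = "dia_1", evalue = 1e-30, bitscore = 180
  ))
  expect_error(run_sieve(ev2, genome2, "enolase_gene", alignment2, "dia_1",
                         sim$tree, sim$labels), "ghost")
})

test_that("patristic mode retains tips nearest to diatom references", {
  tr <- ape::read.tree(text = "((env1:0.1,dia:0.1):1,(env2:0.1,oth:0.1):1);")
  labs <- tibble::tibble(
    tip_id = c("env1", "dia", "env2", "oth"),
    category = c("environmental", "diatom_plastid_ref", "environmental",
                 "other_ref")
  )
  res <- retain_env_tips(tr, labs, mode = "patristic")
  expect_equal(res$retained[res$tip_id == "env1"], TRUE)
  expect_equal(res$retained[res$tip_id == "env2"], FALSE)
})
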