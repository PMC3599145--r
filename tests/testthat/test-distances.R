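test_that("alignment distance matches hand-checkable cases", {
  expect_equal(seq_distance("ACGT", "ACGT"), 0)
  # one mismatch over four scored columns
  expect_equal(seq_distance("ACGT", "ACGA"), 0.25)
  # a strict prefix aligns under free terminal gaps at distance 0
  expect_equal(seq_distance("ACGT", "ACG"), 0)
  # ACGT vs AGT: the internal-gap alignment (A-GT, 3 matches, one gap,
  # d = 1/4) ties at score 1 with the free-leading-gap alignment
  # (CGT vs AGT after dangling the A, one mismatch, d = 1/3); the
  # deterministic traceback selects the latter
  st <- align_stats("ACGT", "AGT")
  expect_equal(st$score, 1)
  expect_equal(st$distance, 1 / 3)
  # lower case and U are normalized before aligning
  expect_equal(seq_distance("acgu", "ACGT"), 0)
  expect_error(seq_distance("ACXGT", "ACGT"), "alphabet")
})

test_that("DP score equals the exhaustive alignment-enumeration oracle", {
  set.seed(11)
  alphabet <- c("A", "C", "G", "T", "N")
  for (rep in 1:40) {
    la <- sample(1:6, 1); lb <- sample(1:6, 1)
    a <- paste(sample(alphabet, la, replace = TRUE), collapse = "")
    b <- paste(sample(alphabet, lb, replace = TRUE), collapse = "")
    st <- align_stats(a, b)
    oracle <- oracle_align(a, b)
    expect_equal(st$score, oracle$score,
                 info = sprintf("%s vs %s", a, b))
    # the DP's distance must be realised by some optimal alignment
    expect_true(any(abs(oracle$distances - st$distance) < 1e-12),
                info = sprintf("%s vs %s", a, b))
  }
})

test_that("alignment distance is symmetric, bounded, and zero on identity", {
  set.seed(12)
  for (rep in 1:25) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(3:12, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(3:12, 1), TRUE),
               collapse = "")
    d1 <- seq_distance(a, b); d2 <- seq_distance(b, a)
    expect_identical(d1, d2)
    expect_gte(d1, 0); expect_lte(d1, 1)
    expect_equal(seq_distance(a, a), 0)
  }
  # ambiguity codes mismatch everything, including themselves
  expect_gt(seq_distance("ANG", "ANG"), 0)
})

test_that("all_pairs evaluates every unordered pair in both modes", {
  recs <- tibble::tibble(id = c("a", "b", "c"),
                         sequence = rep("ACGTACGT", 3))
  dm <- all_pairs(recs)
  expect_equal(nrow(dm), 3)
  expect_true(all(dm$distance == 0))
  expect_equal(attr(dm, "mode"), "sequence")

  pts <- tibble::tibble(id = c("p", "q", "r"), x = c(0, 3, 4))
  dmp <- all_pairs(pts)
  expect_equal(sort(dmp$distance), c(1, 3, 4))
  expect_equal(attr(dmp, "mode"), "point")

  expect_error(all_pairs(recs, cutoff = 0), "positive")
  expect_error(all_pairs(recs[1, ]), "two items")
})

test_that("cutoff-limited all_pairs stores exactly the below-cutoff pairs", {
  reads <- sim_taxa_sequences(taxa_spec(n_taxa = 3, sizes = 4,
                                        seq_length = 120), seed = 5)
  full <- all_pairs(reads[c("id", "sequence")])
  part <- all_pairs(reads[c("id", "sequence")], cutoff = 0.08)
  expect_equal(tibble::as_tibble(part),
               tibble::as_tibble(full[full$distance < 0.08, ]),
               ignore_attr = TRUE)
  expect_equal(dist_labels(part), dist_labels(full))
})

test_that("greedy preclustering groups by representative distance", {
  # all mutually close: one precluster
  close_recs <- tibble::tibble(id = c("r1", "r2", "r3"),
                               sequence = c("ACGTACGTAC", "ACGTACGTAT",
                                            "ACGTACGAAC"))
  pc <- precluster_greedy(close_recs, level = 0.5)
  expect_equal(length(unique(pc$representative)), 1)

  # two well-separated groups are recovered exactly
  reads <- sim_taxa_sequences(taxa_spec(n_taxa = 2, sizes = 6,
                                        seq_length = 150,
                                        within_rate = 0.005), seed = 9)
  pc2 <- precluster_greedy(reads[c("id", "sequence")], level = 0.05)
  groups <- split(pc2$id, pc2$representative)
  expect_equal(length(groups), 2)
  truth <- split(reads$id, reads$taxon)
  expect_setequal(unname(lapply(groups, sort)), unname(lapply(truth, sort)))

  # every member sits within `level` of its representative
  seqs <- setNames(reads$sequence, reads$id)
  for (g in names(groups)) {
    for (mem in groups[[g]]) {
      expect_lt(seq_distance(seqs[[g]], seqs[[mem]]), 0.05)
    }
  }

  expect_equal(nrow(precluster_greedy(close_recs[1, ], 0.1)), 1)
  expect_error(precluster_greedy(close_recs[0, ], 0.1), "No sequences")
  expect_error(precluster_greedy(close_recs, 1.2), "\\(0, 1\\)")
})

test_that("expand_partition propagates representative clusters to members", {
  pre <- tibble::tibble(representative = c("r1", "r1", "r2"),
                        id = c("r1", "a", "r2"))
  out <- expand_partition(c(r1 = "OTU1", r2 = "OTU2"), pre)
  expect_equal(setNames(out$cluster, out$member_id),
               c(r1 = "OTU1", a = "OTU1", r2 = "OTU2"))
  # singleton preclusters: identity
  pre_id <- tibble::tibble(representative = c("x", "y"), id = c("x", "y"))
  out2 <- expand_partition(c(x = 1, y = 2), pre_id)
  expect_equal(setNames(out2$cluster, out2$member_id),
               c(x = "1", y = "2"))
  # conservation on random preclusterings
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    ids <- sprintf("s%02d", 1:n)
    rep_of <- ids[sample(3, n, replace = TRUE)]
    rep_of[1:3] <- ids[1:3]
    pre_r <- tibble::tibble(representative = rep_of, id = ids)
    part <- setNames(sample(2, 3, replace = TRUE), ids[1:3])
    expect_equal(nrow(expand_partition(part, pre_r)), n)
  }
  expect_error(expand_partition(c(r1 = 1), pre), "missing")
})
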