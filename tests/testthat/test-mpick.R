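test_that("an edgeless neighborhood graph yields all-singleton OTUs", {
  dm <- make_dist(tibble::tibble(id1 = c("a", "a", "b"),
                                 id2 = c("b", "c", "c"),
                                 distance = c(0.5, 0.6, 0.7)))
  fit <- mpick_cluster(dm, epsilon = 0.04)
  expect_equal(fit$n_otus, 3)
  expect_equal(sort(fit$otus$member_id), c("a", "b", "c"))
  expect_equal(length(unique(fit$otus$otu_id)), 3)
})

test_that("two tight cliques separated beyond epsilon give exactly two OTUs", {
  ids <- c(sprintf("x%d", 1:4), sprintf("y%d", 1:4))
  pr <- t(combn(ids, 2))
  same <- substr(pr[, 1], 1, 1) == substr(pr[, 2], 1, 1)
  dm <- make_dist(tibble::tibble(id1 = pr[, 1], id2 = pr[, 2],
                                 distance = ifelse(same, 0.01, 0.5)))
  fit <- mpick_cluster(dm, epsilon = 0.04, delta = 0.1)
  expect_equal(fit$n_otus, 2)
  groups <- split(fit$otus$member_id, fit$otus$otu_id)
  expect_setequal(lapply(groups, sort),
                  list(sprintf("x%d", 1:4), sprintf("y%d", 1:4)))
  # a complete subgraph has no internal structure: its best split has
  # Q = 0 < delta, confirmed by the exhaustive oracle
  sub <- clique_graph(4, join = FALSE)
  expect_equal(q_value(best_partition_bruteforce(sub)), 0, tolerance = 1e-12)
})

test_that("recursion splits joined cliques once and stops inside them", {
  g <- clique_graph(c(4, 4))  # two K4s joined by one unit edge
  # the two-clique cut clears delta = 0.1 by the explicit formula
  cut <- setNames(rep(1:2, each = 4), g$vertices)
  expect_gt(modularity_q(g, cut), 0.1)
  res <- recurse_component(g, delta = 0.1)
  expect_equal(length(res$leaves), 2)
  expect_setequal(lapply(res$leaves, sort),
                  list(sprintf("c1_%02d", 1:4), sprintf("c2_%02d", 1:4)))
  expect_true(res$splits$accepted[res$splits$depth == 0])
  expect_true(all(!res$splits$accepted[res$splits$depth == 1]))

  # a single K4: one leaf, no accepted split
  res4 <- recurse_component(clique_graph(4, join = FALSE), delta = 0.1)
  expect_equal(length(res4$leaves), 1)

  # single vertex: one leaf
  dm1 <- make_dist(tibble::tibble(id1 = character(), id2 = character(),
                                  distance = double()), labels = "solo")
  res1 <- recurse_component(build_graph(dm1, 0.5), delta = 0.1)
  expect_equal(res1$leaves, list("solo"))
})

test_that("OTU partitions are total and refine the graph components", {
  set.seed(61)
  for (s in 1:6) {
    n <- sample(10:20, 1)
    ids <- sprintf("v%02d", 1:n)
    pr <- t(combn(ids, 2))
    keep <- runif(nrow(pr)) < 0.25
    dm <- make_dist(tibble::tibble(id1 = pr[keep, 1], id2 = pr[keep, 2],
                                   distance = runif(sum(keep), 0, 0.5)),
                    labels = ids)
    fit <- mpick_cluster(dm, epsilon = 0.3, delta = 0.1)
    # total: every id in exactly one OTU
    expect_setequal(fit$otus$member_id, ids)
    expect_equal(nrow(fit$otus), n)
    # refinement: no OTU spans two components of the epsilon-graph
    comps <- graph_components(build_graph(dm, 0.3))
    comp_of <- setNames(rep(seq_along(comps), lengths(comps)),
                        unlist(comps))
    for (grp in split(fit$otus$member_id, fit$otus$otu_id)) {
      expect_equal(length(unique(comp_of[grp])), 1)
    }
    # every non-singleton leaf stopped below delta (or as a single cluster)
    walk <- function(node) {
      if (node$is_otu) {
        if (length(node$vertices) > 1 && !is.na(node$max_q)) {
          expect_lt(node$max_q, 0.1)
        }
      } else {
        for (ch in node$children) walk(ch)
      }
    }
    for (tr in fit$tree) walk(tr)
  }
})

test_that("identical inputs and seed give byte-identical OTU tables", {
  reads <- sim_taxa_sequences(taxa_spec(n_taxa = 3, sizes = 10,
                                        seq_length = 120), seed = 8)
  dm <- all_pairs(reads[c("id", "sequence")])
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  fit1 <- mpick_cluster(dm, seed = 42)
  fit2 <- mpick_cluster(dm, seed = 42)
  write_otu_table(membership_of(fit1), f1)
  write_otu_table(membership_of(fit2), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(fit1$otus, fit2$otus)
})

test_that("the pipeline handles each input kind and the precluster path", {
  # four identical sequences collapse into one OTU
  recs <- tibble::tibble(id = sprintf("s%d", 1:4),
                         sequence = rep("ACGTACGTACGT", 4))
  fit <- run_mpick(recs)
  expect_equal(fit$n_otus, 1)
  expect_equal(fit$n_items, 4)

  # precluster route returns a partition over all members that matches
  # the direct route on well-separated taxa
  reads <- sim_taxa_sequences(taxa_spec(n_taxa = 3, sizes = 12,
                                        seq_length = 150,
                                        within_rate = 0.005), seed = 13)
  direct <- run_mpick(reads[c("id", "sequence")])
  pre <- run_mpick(reads[c("id", "sequence")], precluster_level = 0.01)
  expect_equal(pre$n_items, nrow(reads))
  expect_setequal(pre$otus$member_id, reads$id)
  expect_equal(nmi(membership_of(pre), membership_of(direct)), 1)

  # output and log files
  out <- withr::local_tempfile(); log <- withr::local_tempfile()
  run_mpick(reads[c("id", "sequence")], out = out, log = log)
  expect_equal(readLines(out)[1], "member_id\totu_id")
  expect_true(any(grepl("picked", readLines(log))))

  expect_error(run_mpick(tibble::tibble(bad = 1)), "input")
  expect_error(run_mpick(all_pairs(recs), precluster_level = 0.01),
               "sequence input")
})

test_that("simulated taxa are recovered across replicate seeds", {
  # scaled-down replicate study: the OTU count must match the simulated
  # taxon count in at least 95% of seeds
  spec <- taxa_spec(n_taxa = 6, sizes = 30, seq_length = 150)
  hits <- 0L
  n_rep <- 20L
  for (s in seq_len(n_rep)) {
    reads <- sim_taxa_sequences(spec, seed = 1000 + s)
    fit <- mpick_cluster(all_pairs(reads[c("id", "sequence")],
                                   cutoff = 0.2),
                         epsilon = 0.04, delta = 0.1)
    hits <- hits + (fit$n_otus == 6L)
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("fit accessors expose the tidy views", {
  pts <- sim_gaussian_points(mixture_spec(sizes = c(20, 15, 25)), seed = 3)
  fit <- run_mpick(pts[c("id", "x1", "x2")], epsilon = 0.6)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("member_id", "otu_id"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_items, 60)
  expect_equal(gl$epsilon, 0.6)
  expect_output(print(fit), "OTUs from 60 items")
  p <- autoplot(fit, points = pts)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_otu_sizes(fit), "ggplot")
})
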