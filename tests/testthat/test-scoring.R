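test_that("stouffer_aggregate matches the direct formula and unit-weight identities", {
  # identity at k = 1
  for (z in c(-7.3, 0, 0.001, 42)) {
    expect_identical(stouffer_aggregate(z), z)
  }
  # equal-z case: k * z / sqrt(k)
  expect_equal(stouffer_aggregate(c(3, 3, 3, 3)), 6.0)
  expect_equal(stouffer_aggregate(rep(2.5, 9)), 9 * 2.5 / 3)

  set.seed(101)
  for (i in 1:1000) {
    k <- sample(1:20, 1)
    z <- stats::rnorm(k, sd = 3)
    w <- stats::runif(k, 0.1, 5)
    expected <- sum(w * z) / sqrt(sum(w^2))
    expect_equal(stouffer_aggregate(z, w), expected, tolerance = 1e-12)
  }
})

test_that("stouffer_aggregate rejects degenerate input and is scale-equivariant", {
  expect_error(stouffer_aggregate(numeric(0)), "usage error")
  expect_error(stouffer_aggregate(c(1, 2), weights = c(0, 0)), "usage error")
  expect_error(stouffer_aggregate(c(1, NA)), "usage error")
  set.seed(5)
  z <- rnorm(7)
  w <- runif(7)
  for (c_ in c(-2, 0.5, 10)) {
    expect_equal(stouffer_aggregate(c_ * z, w),
                 c_ * stouffer_aggregate(z, w), tolerance = 1e-12)
  }
})

test_that("evidence-path threshold is strict and respects the drug set", {
  kg <- toy_kg(z = c(3.0, -3.5, 1.0, 4.4))  # (s1,g1) (s1,g2) (s2,g3) (s3,g4)
  # |z| = 3.0 at threshold 3 is excluded (strict inequality)
  paths <- enumerate_paths(kg, c("d1", "d2"), z_threshold = 3)
  expect_setequal(paths$gene_id, c("g2", "g4"))
  # restricting the drug set drops d2's s3 path
  paths_d1 <- enumerate_paths(kg, "d1", z_threshold = 3)
  expect_equal(paths_d1$gene_id, "g2")
  expect_error(enumerate_paths(kg, character(0)), "usage error")
  expect_error(enumerate_paths(kg, "dGHOST"), "unknown drug")
})

test_that("enumerate_paths equals exhaustive triple-loop enumeration on random graphs", {
  for (seed in c(2, 9)) {
    sim <- generate_graph(synthetic_spec(n_drugs = 6, n_query_drugs = 3,
                                         n_signatures_per_drug = 4,
                                         n_genes = 40, n_true_targets = 4,
                                         edge_density = 0.6, effect_mu = 3,
                                         seed = seed))
    drugs <- sim$truth$query_drug_ids
    for (thr in c(0.5, 1, 3)) {
      got <- enumerate_paths(sim$kg, drugs, thr)
      want <- brute_force_paths(sim$kg, drugs, thr)
      expect_equal(got, want)
    }
  }
})

test_that("gene scores follow the two-mode Stouffer arithmetic", {
  # gene A: 4 paths |z| = 4; gene B: 1 path |z| = 9
  paths <- data.frame(
    drug_id = "d1",
    signature_id = paste0("s", 1:5),
    gene_id = c(rep("gA", 4), "gB"),
    z = c(4, -4, 4, 4, 9),
    stringsAsFactors = FALSE
  )
  z_scores <- score_genes(paths, score_params(mode = "Z"))
  expect_equal(z_scores$score[z_scores$gene_id == "gA"], 8.0)
  expect_equal(z_scores$score[z_scores$gene_id == "gB"], 9.0)
  expect_equal(z_scores$gene_id[z_scores$rank == 1], "gB")

  d_scores <- score_genes(paths, score_params(mode = "D"))
  expect_equal(d_scores$score[d_scores$gene_id == "gA"], 2.0)
  expect_equal(d_scores$score[d_scores$gene_id == "gB"], 1.0)
  expect_equal(d_scores$gene_id[d_scores$rank == 1], "gA")

  # signed aggregation lets opposing signatures cancel
  signed <- score_genes(paths, score_params(mode = "Z", use_absolute_z = FALSE))
  expect_equal(signed$score[signed$gene_id == "gA"], (4 - 4 + 4 + 4) / 2)

  expect_equal(nrow(score_genes(paths[0, ], score_params())), 0L)
})

test_that("score_genes equals a per-gene groupby oracle; mode D ranks by path count", {
  sim <- generate_graph(synthetic_spec(n_genes = 120, n_true_targets = 6,
                                       edge_density = 0.3, seed = 21))
  paths <- enumerate_paths(sim$kg, sim$truth$query_drug_ids, 3)
  for (mode in c("Z", "D")) {
    got <- score_genes(paths, score_params(mode = mode))
    want <- brute_force_scores(paths, mode)
    expect_equal(got, want)
  }
  d_ranked <- score_genes(paths, score_params(mode = "D"))
  counts <- table(paths$gene_id)
  expect_equal(order(-d_ranked$score),
               order(-as.integer(counts[d_ranked$gene_id])))
  # mode-D ranking equals ranking by raw path count
  expect_true(all(diff(as.integer(counts[d_ranked$gene_id])) <= 0))
})

test_that("ranked output is deterministic and independent of path order", {
  sim <- generate_graph(synthetic_spec(seed = 33))
  paths <- enumerate_paths(sim$kg, sim$truth$query_drug_ids, 3)
  shuffled <- paths[sample(nrow(paths)), , drop = FALSE]
  a <- score_genes(paths, score_params(mode = "Z"))
  b <- score_genes(shuffled, score_params(mode = "Z"))
  expect_identical(a, b)
})

test_that("appending evidence strengthens a gene's score as documented", {
  # mode Z: a new path above the current mean |z| strictly increases the score
  z <- c(4, 5, 6)
  base <- stouffer_aggregate(abs(z))
  expect_gt(stouffer_aggregate(abs(c(z, 5.5))), base)
  # mode D: any new path strictly increases sqrt(k)
  expect_gt(sqrt(4), sqrt(3))
  paths <- data.frame(drug_id = "d", signature_id = paste0("s", 1:3),
                      gene_id = "g", z = z, stringsAsFactors = FALSE)
  more <- rbind(paths, data.frame(drug_id = "d", signature_id = "s4",
                                  gene_id = "g", z = 5.5))
  s1 <- score_genes(paths, score_params(mode = "Z"))$score
  s2 <- score_genes(more, score_params(mode = "Z"))$score
  expect_gt(s2, s1)
})
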