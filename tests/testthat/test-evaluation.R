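test_that("family pair groups partition annotated pairs", {
  sim <- matrix(0.5, 3, 3, dimnames = list(c("a", "b", "c"),
                                           c("a", "b", "c")))
  diag(sim) <- 1
  fams <- c(a = "f1", b = "f1", c = "f2")
  gr <- family_pair_groups(fams, sim, seed = 1)
  expect_equal(nrow(gr$intra), 1)
  expect_equal(sort(paste(gr$inter$mirna_a, gr$inter$mirna_b)),
               c("a c", "b c"))
  # partition: intra + inter cover all annotated pairs exactly once
  expect_equal(nrow(gr$intra) + nrow(gr$inter), choose(3, 2))
  expect_length(intersect(
    paste(gr$intra$mirna_a, gr$intra$mirna_b),
    paste(gr$inter$mirna_a, gr$inter$mirna_b)), 0)
  # random group is reproducible and drawn from the union
  gr2 <- family_pair_groups(fams, sim, seed = 1)
  expect_identical(gr$random, gr2$random)
  expect_true(all(paste(gr$random$mirna_a, gr$random$mirna_b) %in%
                    paste(c(gr$intra$mirna_a, gr$inter$mirna_a),
                          c(gr$intra$mirna_b, gr$inter$mirna_b))))
  expect_error(family_pair_groups(c(a = "f1", c = "f2"), sim, seed = 1),
               "intra-family")
})

test_that("planted family effect raises intra-family similarity", {
  spec <- fixture_spec(seed = 41)
  ont <- generate_ontology(spec)
  assoc <- generate_associations(spec, ont)
  sim <- mfsp_pipeline(ont, assoc$pairs)
  gr <- family_pair_groups(assoc$families, sim, seed = 41)
  expect_gt(mean(gr$intra$score), mean(gr$inter$score))
  rep <- benchmark_report(gr)
  expect_equal(nrow(rep), 4)
  expect_true(all(rep$p_value >= 0 & rep$p_value <= 1))
  expect_lt(rep$p_value[rep$comparison == "intra-inter"][1], 0.05)
})

test_that("distance clustering follows single-linkage chaining", {
  loci <- data.frame(
    mirna = c("a", "b", "c"),
    chrom = "chr1",
    start = c(1000, 41100, 81200),
    end = c(1079, 41179, 81279),
    strand = "+")
  # consecutive gaps just over 40 kb
  cl50 <- cluster_by_distance(loci, 50000)
  expect_length(unique(cl50), 1)       # chained into one cluster of 3
  cl30 <- cluster_by_distance(loci, 30000)
  expect_length(unique(cl30), 3)
  # two loci, 40 kb apart: linked at 50 kb, split at 30 kb
  expect_length(unique(cluster_by_distance(loci[1:2, ], 50000)), 1)
  expect_length(unique(cluster_by_distance(loci[1:2, ], 30000)), 2)
  expect_error(cluster_by_distance(loci, -1), "positive")
  bad <- loci
  bad$start[1] <- bad$end[1] + 5
  expect_error(cluster_by_distance(bad, 1000), "malformed")
})

test_that("clustering matches the union-find oracle and respects strand", {
  spec <- fixture_spec(seed = 23, n_mirnas = 30)
  loci <- generate_loci(spec)
  for (cutoff in c(10e3, 50e3, 100e3)) {
    got <- cluster_by_distance(loci, cutoff)
    want <- oracle_clusters(loci, cutoff)
    # same partition (ids are arbitrary): compare co-membership
    expect_identical(outer(got, got, "=="), outer(want, want, "==")[
      names(got), names(got)])
  }
  # opposite strands are never chained when same_strand = TRUE
  pair <- data.frame(mirna = c("x", "y"), chrom = "chr1",
                     start = c(100, 300), end = c(179, 379),
                     strand = c("+", "-"))
  expect_length(unique(cluster_by_distance(pair, 1000)), 2)
  expect_length(unique(cluster_by_distance(pair, 1000,
                                           same_strand = FALSE)), 1)
})

test_that("cluster count is non-increasing in the cutoff", {
  spec <- fixture_spec(seed = 29, n_mirnas = 40)
  loci <- generate_loci(spec)
  counts <- vapply(seq(10e3, 100e3, by = 10e3), function(cutoff) {
    length(unique(cluster_by_distance(loci, cutoff)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("rank tests separate shifted samples and agree at the null", {
  r <- rank_sum_test(1:6, 101:106)
  expect_lt(r$p_value, 0.05)
  expect_false(r$underflow)
  same <- rank_sum_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p_value, 0.5)
  kw <- kruskal_wallis(list(a = c(1, 2, 3), b = c(10, 20, 30),
                            c = c(100, 200, 300)))
  expect_lt(kw$p_value, 0.05)
  expect_error(rank_sum_test(1, c(1, 2)), "at least 2")
  expect_error(kruskal_wallis(list(a = 1, b = c(1, 2))), "at least 2")
})

test_that("both rank tests hold their nominal type-I error on iid nulls", {
  reps <- 1000
  rej <- withr::with_seed(99, {
    vapply(seq_len(reps), function(k) {
      x <- rnorm(50)
      y <- rnorm(50)
      z <- rnorm(50)
      c(w = rank_sum_test(x, y)$p_value < 0.05,
        k = kruskal_wallis(list(x = x, y = y, z = z))$p_value < 0.05)
    }, logical(2))
  })
  band <- qbinom(c(0.005, 0.995), reps, 0.05) / reps
  expect_gte(mean(rej["w", ]), band[1])
  expect_lte(mean(rej["w", ]), band[2])
  expect_gte(mean(rej["k", ]), band[1])
  expect_lte(mean(rej["k", ]), band[2])
})

test_that("expression curve is constant 1 for identical profiles and has
           the documented grid", {
  sim <- matrix(0.9, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(sim) <- 1
  base <- seq_len(10)
  expr <- rbind(a = base, b = base * 2, c = base + 5, d = base * 3 + 1)
  curve <- expression_correlation_curve(sim, expr)
  expect_equal(nrow(curve), 21)
  filled <- curve$mean_pcc[curve$n_pairs > 0]
  expect_true(all(abs(filled - 1) < 1e-12))
})

test_that("expression curve couples to planted similarity and skips
           degenerate profiles", {
  spec <- fixture_spec(seed = 37, n_mirnas = 40, expression_coupling = 0.8)
  ont <- generate_ontology(spec)
  sim <- mfsp_pipeline(ont, generate_associations(spec, ont)$pairs)
  expr <- generate_expression(spec, sim)
  curve <- expression_correlation_curve(sim, expr,
                                        thresholds = seq(0, 0.9, 0.05))
  expect_gt(attr(curve, "curve_threshold_pcc"), 0)

  # a constant profile is skipped with a warning, not propagated as NA
  expr2 <- expr
  expr2[1, ] <- 3
  expect_warning(curve2 <- expression_correlation_curve(sim, expr2),
                 "constant or missing")
  expect_true(all(curve2$n_skipped >= 1))
})

test_that("uncoupled expression gives a flat curve within noise", {
  spec <- fixture_spec(seed = 43, n_mirnas = 40, expression_coupling = 0)
  ont <- generate_ontology(spec)
  sim <- mfsp_pipeline(ont, generate_associations(spec, ont)$pairs)
  expr <- generate_expression(spec, sim)
  curve <- expression_correlation_curve(sim, expr,
                                        thresholds = seq(0, 0.8, 0.1))
  filled <- curve$mean_pcc[curve$n_pairs >= 10]
  expect_lt(max(abs(filled)), 0.25)
})

test_that("parameter sweep is deterministic, long-format and monotone in b", {
  spec <- fixture_spec(seed = 47, n_diseases = 40, depth = 3, branching = 4,
                       n_mirnas = 15)
  ont <- generate_ontology(spec)
  assoc <- generate_associations(spec, ont)
  sim <- mfsp_pipeline(ont, assoc$pairs)
  gr <- family_pair_groups(assoc$families, sim, seed = 47)
  groups <- list(intra = gr$intra, inter = gr$inter)
  tab <- parameter_sweep(ont, assoc$pairs, a_grid = 0.6, b_grid = 1:6,
                         groups = groups)
  expect_equal(nrow(tab), 6 * 2)
  tab2 <- parameter_sweep(ont, assoc$pairs, a_grid = 0.6, b_grid = 1:6,
                          groups = groups)
  expect_identical(tab, tab2)
  single <- parameter_sweep(ont, assoc$pairs, a_grid = 0.6, b_grid = 5,
                            groups = groups)
  expect_equal(nrow(single), length(groups))
  # raw path weights (not the normalized scores) grow with b; check the
  # normalized group means stabilize rather than diverge
  intra <- tab$mean_similarity[tab$group == "intra"]
  expect_lt(abs(intra[6] - intra[5]), abs(intra[2] - intra[1]) + 1e-9)
})
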