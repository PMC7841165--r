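test_that("seed contract: identical configs give byte-identical cohorts", {
  cfg <- sim_config(n_genes = 200, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$fpkm, b$fpkm)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_cohort(sim_config(n_genes = 200, seed = 12))
  expect_false(identical(a$counts, c2$counts))
})

test_that("nothing is planted when de_fraction is zero, and rounding to zero warns", {
  coh <- simulate_cohort(sim_config(n_genes = 100, de_fraction = 0, seed = 3))
  expect_length(coh$truth$de_genes_up, 0)
  expect_length(coh$truth$de_genes_down, 0)
  expect_warning(
    simulate_cohort(sim_config(n_genes = 10, de_fraction = 0.04,
                               effect_log2fc = 1, seed = 3)),
    "rounds to zero"
  )
})

test_that("counts are non-negative integers and FPKM follows its formula", {
  coh <- simulate_cohort(sim_config(n_genes = 150, seed = 5))
  expect_true(all(coh$counts >= 0))
  expect_true(all(coh$counts == round(coh$counts)))
  mapped_millions <- colSums(coh$counts) / 1e6
  expected <- sweep(coh$counts / coh$gene_lengths_kb, 2, mapped_millions, "/")
  expect_equal(coh$fpkm, expected, tolerance = 1e-12)
  expect_true(all(coh$truth$de_genes_up %in% rownames(coh$counts)))
  expect_length(intersect(coh$truth$de_genes_up, coh$truth$de_genes_down), 0)
})

test_that("planted up-genes carry the configured mean fold-change (Monte-Carlo)", {
  # 20 replicate simulations; per planted up-gene, log2 ratio of group
  # mean counts (0.5 pseudocount); the grand mean must sit near the
  # planted effect of 1.
  fcs <- vapply(1:20, function(r) {
    coh <- simulate_cohort(sim_config(n_genes = 2000, n_per_group = 5,
                                      de_fraction = 0.1, effect_log2fc = 1,
                                      dispersion = 0.1, seed = 1000 + r))
    up <- coh$truth$de_genes_up
    case <- coh$counts[up, coh$groups == "case", drop = FALSE]
    ctrl <- coh$counts[up, coh$groups == "control", drop = FALSE]
    mean(log2((rowMeans(case) + 0.5) / (rowMeans(ctrl) + 0.5)))
  }, numeric(1))
  expect_lt(abs(mean(fcs) - 1), 0.15)
})

test_that("under the null the per-gene t-test p-values are uniform", {
  coh <- simulate_cohort(sim_config(n_genes = 2000, de_fraction = 0, seed = 77))
  norm <- normalize_cohort(coh$counts, coh$fpkm, coh$groups)
  st <- gene_statistics(norm$matrix, coh$groups, sd_floor_quantile = 0)
  p <- 2 * pt(-abs(st$t_stat), df = 8)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("multi-cohort planting respects the overlap fraction at its extremes", {
  cfgs <- lapply(1:3, function(i) {
    sim_config(n_genes = 600, de_fraction = 0.1, seed = 20 + i)
  })
  disjoint <- simulate_multi_cohort(cfgs, shared_term_size = 150,
                                    overlap_fraction = 0)
  ups <- lapply(disjoint$cohorts, function(ch) ch$truth$de_genes_up)
  expect_length(intersect(ups[[1]], ups[[2]]), 0)
  expect_length(intersect(ups[[1]], ups[[3]]), 0)
  expect_length(intersect(ups[[2]], ups[[3]]), 0)
  shared_term <- disjoint$gene_sets$members$SET_SHARED
  expect_true(all(unlist(ups) %in% shared_term))

  identical_sets <- simulate_multi_cohort(cfgs, shared_term_size = 150,
                                          overlap_fraction = 1)
  ups1 <- lapply(identical_sets$cohorts, function(ch) ch$truth$de_genes_up)
  expect_identical(ups1[[1]], ups1[[2]])
  expect_identical(ups1[[1]], ups1[[3]])
})

test_that("multi-cohort errors when the shared term cannot host the DE genes", {
  cfgs <- lapply(1:2, function(i) {
    sim_config(n_genes = 600, de_fraction = 0.1, seed = i)
  })
  expect_error(simulate_multi_cohort(cfgs, shared_term_size = 20),
               "smaller than the largest")
  expect_error(
    simulate_multi_cohort(cfgs, shared_term_size = 35, overlap_fraction = 0),
    "too small to plant disjoint"
  )
  expect_error(simulate_multi_cohort(cfgs[1]), "length\\(cfgs\\) >= 2")
})

test_that("simulated annotations respect the requested sizes and universe", {
  universe <- sprintf("G%05d", 1:200)
  expect_length(simulate_go_annotation(0, c(5, 10), universe), 0)
  ann <- simulate_go_annotation(25, c(5, 40), universe, seed = 9)
  ann2 <- simulate_go_annotation(25, c(5, 40), universe, seed = 9)
  expect_identical(ann$members, ann2$members)
  sizes <- lengths(ann$members)
  expect_true(all(sizes >= 5 & sizes <= 40))
  expect_true(all(unlist(ann$members) %in% universe))
  expect_error(simulate_go_annotation(3, c(5, 10), character(0)), "non-empty")
})

test_that("qPCR plates plant the requested delta-CT shift", {
  flat <- simulate_qpcr_plate(4, group_delta_ct = 0, noise_sd = 0, seed = 1)
  res <- ddct_quantify(flat)
  expect_equal(res$samples$delta_delta_ct, rep(0, 8))
  expect_equal(res$samples$rq, rep(1, 8))

  shifted <- simulate_qpcr_plate(4, group_delta_ct = 1, noise_sd = 0, seed = 1)
  res2 <- ddct_quantify(shifted)
  expect_equal(res2$samples$rq[res2$samples$group == "case"], rep(2, 4))

  expect_error(simulate_qpcr_plate(4, 1, noise_sd = -0.1), "non-negative")
})

test_that("ddct_quantify recovers the planted shift within 2 SEM (Monte-Carlo)", {
  deltas <- vapply(1:20, function(r) {
    plate <- simulate_qpcr_plate(10, group_delta_ct = 1.5, noise_sd = 0.4,
                                 seed = 500 + r)
    res <- ddct_quantify(plate)
    -mean(res$samples$delta_delta_ct[res$samples$group == "case"])
  }, numeric(1))
  sem <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas) - 1.5), 2 * sem + 1e-9)
})
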