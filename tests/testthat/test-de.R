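test_that("gene statistics match the textbook pooled-variance formulas", {
  m <- rbind(
    flat  = c(5, 6, 7, 5, 6, 7),          # identical groups
    shift = c(2, 3, 4, 1, 2, 3),          # case = control + 1
    hand  = c(2, 4, 6, 1, 2, 3)
  )
  colnames(m) <- c(sprintf("case_%d", 1:3), sprintf("control_%d", 1:3))
  st <- gene_statistics(m, make_groups(m), sd_floor_quantile = 0)

  expect_equal(st$log2fc, c(0, 1, 2))
  expect_equal(st$t_stat[1], 0)
  # case=(2,4,6) vs control=(1,2,3): sp^2 = (2*4 + 2*1)/4 = 2.5,
  # t = 2 / sqrt(2.5 * (1/3 + 1/3))
  expect_equal(st$t_stat[3], 2 / sqrt(2.5 * (2 / 3)), tolerance = 1e-12)

  tt <- t.test(c(2, 4, 6), c(1, 2, 3), var.equal = TRUE)
  expect_equal(st$t_stat[3], unname(tt$statistic), tolerance = 1e-12)

  welch <- gene_statistics(m, make_groups(m), var_method = "welch",
                           sd_floor_quantile = 0)
  expect_equal(welch$t_stat[3], unname(t.test(c(2, 4, 6), c(1, 2, 3))$statistic),
               tolerance = 1e-12)

  tiny <- m[, 1:3]
  expect_error(gene_statistics(tiny, make_groups(m)[1:3]), "at least two")
})

test_that("permutation nulls honour the size contract and the seed", {
  m <- make_log_matrix(n_genes = 100, sd = 0.5, seed = 3)
  groups <- make_groups(m)
  cfg <- de_config(n_permutations = 300, seed = 9)
  expect_warning(n1 <- permutation_null(m, groups, cfg), "252 distinct")
  expect_length(n1$pooled_t, 100 * 300)
  expect_length(n1$pooled_fc, 100 * 300)
  n2 <- suppressWarnings(permutation_null(m, groups, cfg))
  expect_identical(n1$null_t, n2$null_t)
  n3 <- suppressWarnings(permutation_null(m, groups,
                                          de_config(n_permutations = 300,
                                                    seed = 10)))
  expect_false(identical(n1$null_t, n3$null_t))
})

test_that("exhaustive 3-vs-3 permutation null matches independent enumeration", {
  m <- make_log_matrix(n_genes = 20, n_per_group = 3, sd = 1, seed = 12)
  groups <- make_groups(m)
  cfg <- de_config(sd_floor_quantile = 0)
  nulls <- permutation_null(m, groups, cfg, exhaustive = TRUE)
  expect_equal(nulls$n_permutations, choose(6, 3))

  assignments <- combn(6, 3)
  for (g in c(1, 7, 20)) {
    x <- m[g, ]
    ts <- fcs <- numeric(ncol(assignments))
    for (j in seq_len(ncol(assignments))) {
      a <- x[assignments[, j]]
      b <- x[-assignments[, j]]
      fcs[j] <- mean(a) - mean(b)
      sp2 <- (2 * var(a) + 2 * var(b)) / 4
      ts[j] <- fcs[j] / sqrt(sp2 * (2 / 3))
    }
    expect_equal(sort(nulls$null_fc[g, ]), sort(fcs), tolerance = 1e-12)
    expect_equal(sort(nulls$null_t[g, ]), sort(ts), tolerance = 1e-12)
  }
})

test_that("empirical p-values follow the plus-one two-tailed rule", {
  null599 <- seq(-1, 1, length.out = 599)
  expect_equal(empirical_pvalue(5, null599), 1 / 600)
  expect_equal(empirical_pvalue(0, null599), 1)

  null99 <- c(seq(0.1, 0.94, length.out = 94), 2, 3, -2.5, 4, 5)
  expect_equal(empirical_pvalue(1.5, null99), 6 / 100)
  expect_error(empirical_pvalue(Inf, null99), "finite")
  expect_error(empirical_pvalue(1, numeric(0)), "non-empty")
})

test_that("Stouffer combination matches the normal-quantile definition", {
  expect_equal(stouffer_combine(0.5, 0.5), 0.5)
  expect_equal(stouffer_combine(0.05, 0.05), 0.0100, tolerance = 5e-4)
  expect_equal(stouffer_combine(0.05, 0.95), 0.5, tolerance = 1e-12)
  # independent check of the 0.05/0.05 case against the z-scale numbers
  expect_equal(qnorm(0.95), 1.6449, tolerance = 1e-4)
  expect_equal(stouffer_combine(0.05, 0.05),
               pnorm(2 * 1.644854 / sqrt(2), lower.tail = FALSE),
               tolerance = 1e-5)
  expect_message(stouffer_combine(1e-20, 0.5), "clipped")
  expect_error(stouffer_combine(0, 0.5), "\\(0, 1\\]")
})

test_that("the adaptive cutoff equals the Gaussian percentile prediction", {
  set.seed(21)
  null_fc <- rnorm(1e5, 0, 0.4)
  cutoff <- adaptive_fc_cutoff(null_fc, c(10, 90))
  expect_equal(cutoff, 0.4 * qnorm(0.9), tolerance = 0.02)
  cutoff2 <- adaptive_fc_cutoff(null_fc, c(2.5, 97.5))
  expect_equal(cutoff2, 0.4 * qnorm(0.975), tolerance = 0.02)
  expect_equal(adaptive_fc_cutoff(rep(0, 100)), 0)
  expect_error(adaptive_fc_cutoff(numeric(0)), "non-empty")
})

test_that("DEG calls require all three criteria", {
  records <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    log2fc = c(1.0, 0.50, 1.0, -1.2),
    p_t_adj = c(0.03, 0.03, 0.03, 0.01),
    p_combined = c(0.01, 0.01, 0.06, 0.001)
  )
  out <- call_degs(records, fc_cutoff = 0.58)
  expect_identical(out$is_deg, c(TRUE, FALSE, FALSE, TRUE))
  expect_identical(out$direction, c("up", "none", "none", "down"))
  expect_true(all(out$direction[out$is_deg] != "none"))
})

test_that("swapping the group labels mirrors every statistic and the DEG lists", {
  coh <- simulate_cohort(sim_config(n_genes = 300, seed = 61))
  norm <- normalize_cohort(coh$counts, coh$fpkm, coh$groups)
  cfg <- de_config(n_permutations = 200, seed = 5)
  de1 <- quiet_run_de(norm$matrix, coh$groups, cfg)
  swapped <- setNames(ifelse(coh$groups == "case", "control", "case"),
                      names(coh$groups))
  de2 <- quiet_run_de(norm$matrix, swapped, cfg)

  expect_equal(de2$records$log2fc, -de1$records$log2fc, tolerance = 1e-12)
  expect_equal(de2$records$t_stat, -de1$records$t_stat, tolerance = 1e-12)
  expect_equal(de2$records$p_combined, de1$records$p_combined,
               tolerance = 1e-12)
  l1 <- deg_lists(de1)
  l2 <- deg_lists(de2)
  expect_identical(l1$up, l2$down)
  expect_identical(l1$down, l2$up)
})

test_that("run_de with the adaptive cutoff uses the null percentiles", {
  m <- make_log_matrix(n_genes = 150, sd = 0.5, seed = 31)
  groups <- make_groups(m)
  cfg <- de_config(n_permutations = 100, seed = 3, fc_cutoff = "adaptive",
                   percentile_pair = c(2.5, 97.5))
  de <- quiet_run_de(m, groups, cfg)
  expect_equal(de$fc_cutoff,
               adaptive_fc_cutoff(de$nulls$pooled_fc, c(2.5, 97.5)),
               tolerance = 1e-12)
  expect_true(all(de$records$p_t_adj > 0 & de$records$p_t_adj <= 1))
  expect_error(de_config(percentile_pair = c(10, 80)), "symmetric")
  expect_error(de_config(fc_cutoff = -1), "positive")
})
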