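test_that("the generator is deterministic given (config, seed)", {
  cfg <- small_config(seed = 9, n_probes = 300)
  g1 <- generate_study(cfg)
  g2 <- generate_study(cfg)
  expect_identical(g1$study$values, g2$study$values)
  expect_identical(g1$truth, g2$truth)
  s1 <- generate_gene_sets_and_dag(simulation_config(n_probes = 2000,
                                                     seed = 9))
  s2 <- generate_gene_sets_and_dag(simulation_config(n_probes = 2000,
                                                     seed = 9))
  expect_identical(s1$sets$sets, s2$sets$sets)
  expect_identical(s1$truth, s2$truth)
})

test_that("a null config plants no effects and requires pairs", {
  cfg <- small_config(seed = 2, n_probes = 200, de_fraction = 0,
                      baseline_de_fraction = 0)
  gs <- generate_study(cfg)
  expect_false(any(gs$truth$is_de))
  expect_true(all(gs$truth$delta == 0))
  expect_error(generate_study(small_config(seed = 2, n_subjects = 1L)),
               ">= 2")
})

test_that("planted paired log2 fold changes recover the configured delta", {
  # Monte-Carlo oracle: with delta = 1 the mean observed per-probe paired
  # fold of the planted probes should sit inside the t-based 95% CI of
  # the simulation's own spread
  cfg <- small_config(seed = 31, n_probes = 2000, n_subjects = 4L,
                      de_fraction = 0.1, delta = 1, de_scope = "all",
                      s0_slope = 0, s0_2 = 0.25, baseline_de_fraction = 0)
  gs <- generate_study(cfg)
  st <- fit_gene_stats(gs$study, paired_cmp())
  de_up <- gs$truth$is_de & gs$truth$direction > 0
  obs <- st$b[de_up]
  ci <- mean(obs) + c(-1, 1) * stats::qt(0.975, length(obs) - 1) *
    stats::sd(obs) / sqrt(length(obs))
  expect_gt(1, ci[1])
  expect_lt(1, ci[2])
})

test_that("fitted residual variances follow the scaled F marginal", {
  # with constant prior scale, s2 / s0^2 ~ F(d, d0); KS at alpha = 0.001
  cfg <- simulation_config(n_probes = 50000,
                           groups = data.frame(sex = "M", time = "4h",
                                               n_subjects = 5L),
                           d0 = 4, s0_2 = 0.05, s0_slope = 0,
                           de_fraction = 0, baseline_de_fraction = 0,
                           seed = 3)
  gs <- generate_study(cfg)
  st <- fit_gene_stats(gs$study, paired_cmp("M", "4h"))
  ks <- stats::ks.test(st$s2 / 0.05, function(q) stats::pf(q, 4, 4))
  expect_gt(ks$p.value, 0.001)
})

test_that("binned variance decreases with intensity when configured so", {
  cfg <- small_config(seed = 13, n_probes = 20000, n_subjects = 5L,
                      s0_slope = -0.3, de_fraction = 0,
                      baseline_de_fraction = 0)
  gs <- generate_study(cfg)
  st <- fit_gene_stats(gs$study, paired_cmp())
  bins <- cut(st$a, breaks = stats::quantile(st$a, 0:5 / 5),
              include.lowest = TRUE)
  mv <- tapply(st$s2, bins, mean)
  expect_true(all(diff(mv) < 0))
})

test_that("generated gene sets respect the universe and DAG structure", {
  cfg <- simulation_config(n_probes = 2000, n_sets = 50L,
                           set_size_range = c(10L, 200L), seed = 21)
  out <- generate_gene_sets_and_dag(cfg)
  expect_length(out$sets, 50L)
  universe <- sprintf("P%05d", 1:2000)
  for (s in out$sets$sets) expect_true(all(s %in% universe))
  sz <- lengths(out$sets$sets)
  expect_true(all(sz >= 10 & sz <= 200))

  # the structured tail: child strictly inside its parent with high
  # overlap, and two siblings inside the second parent
  tr <- out$truth
  parent <- out$sets$sets[[tr$set_id[tr$role == "parent_of_child"]]]
  child <- out$sets$sets[[tr$set_id[tr$role == "child"]]]
  expect_true(all(child %in% parent))
  expect_gte(length(child) / length(parent), 0.9)
  sib_parent <- out$sets$sets[[tr$set_id[tr$role == "parent_of_siblings"]]]
  sibs <- out$sets$sets[tr$set_id[tr$role == "sibling"]]
  expect_length(sibs, 2L)
  for (s in sibs) expect_true(all(s %in% sib_parent))
  expect_true(all(out$dag$edges$child %in% tr$set_id))
  expect_error(generate_gene_sets_and_dag(
    simulation_config(n_probes = 100, set_size_range = c(10L, 200L),
                      seed = 1)), "universe")
})

test_that("qPCR panel inverts to the planted fold", {
  cfg <- small_config(seed = 4, n_probes = 500, de_fraction = 0.2,
                      delta = 1, de_scope = "all")
  truth <- generate_study(cfg)$truth
  de_gene <- truth$probe_id[truth$is_de & truth$direction > 0][1]
  null_gene <- truth$probe_id[!truth$is_de][1]

  # zero technical noise: fold is exactly 2^delta and exactly 1 for null
  pan <- generate_qpcr_panel(truth, genes = c(de_gene, null_gene),
                             n_subject_pairs = 3L, noise_sd = 0,
                             seed = 10)
  ft <- qpcr_fold_table(pan)$per_gene
  expect_equal(ft$fold[ft$gene == de_gene], 2, tolerance = 1e-12)
  expect_equal(ft$fold[ft$gene == null_gene], 1, tolerance = 1e-12)

  # noisy duplicates: median recovered fold within 5% of planted
  set.seed(99)
  folds <- replicate(100, {
    p <- generate_qpcr_panel(truth, genes = de_gene, n_subject_pairs = 4L,
                             noise_sd = 0.1,
                             seed = sample.int(1e6, 1))
    qpcr_fold_table(p)$per_gene$fold
  })
  expect_lt(abs(stats::median(folds) - 2) / 2, 0.05)
})
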