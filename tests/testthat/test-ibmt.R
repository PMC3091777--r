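test_that("paired contrast fit matches the textbook paired t", {
  vals <- rbind(g1 = c(2.0, 3.2, 4.8, 1.0, 2.0, 4.0))  # diffs 1.0 1.2 0.8
  vals <- rbind(vals, g2 = c(5, 6, 7, 5, 6, 7))        # diffs all 0
  colnames(vals) <- c("s1_ex", "s2_ex", "s3_ex", "s1_ctl", "s2_ctl",
                      "s3_ctl")
  st <- fit_gene_stats(manual_study(vals), paired_cmp("M", "24h"))
  expect_equal(st$b[1], 1.0)
  expect_equal(st$s2[1], 0.04)
  expect_equal(st$d[1], 2)
  expect_equal(st$u[1], 1 / sqrt(3))
  expect_equal(st$b[1] / (st$u[1] * sqrt(st$s2[1])), 8.660254,
               tolerance = 1e-6)
  expect_equal(st$a[1], mean(vals[1, ]))
  # zero-variance probe carried through with s2 = 0
  expect_equal(st$s2[2], 0)
})

test_that("unpaired contrast fit matches the pooled two-sample t", {
  vals <- matrix(c(1, 2, 3, 2, 3, 4), 1,
                 dimnames = list("g1", paste0("s", 1:6)))
  design <- data.frame(sample_id = paste0("s", 1:6),
                       subject_id = paste0("u", 1:6),
                       sex = rep(c("M", "F"), each = 3),
                       arm = "control", time = "baseline",
                       stringsAsFactors = FALSE)
  st <- fit_gene_stats(expression_study(vals, design),
                       default_comparisons()[[1]])
  expect_equal(st$b, -1)
  expect_equal(st$s2, 1)
  expect_equal(st$d, 4)
  expect_equal(st$u, sqrt(2 / 3))
  expect_equal(st$b / (st$u * sqrt(st$s2)), -1.224745, tolerance = 1e-6)
})

test_that("a single subject pair is insufficient replication", {
  vals <- matrix(rnorm(4), 2, 2,
                 dimnames = list(c("p1", "p2"), c("s1_ex", "s1_ctl")))
  design <- data.frame(sample_id = c("s1_ex", "s1_ctl"),
                       subject_id = "s1", sex = "M",
                       arm = c("exercised", "control"), time = "24h",
                       stringsAsFactors = FALSE)
  st <- expression_study(vals, design)
  expect_error(fit_gene_stats(st, paired_cmp("M", "24h")), "2 complete")
})

test_that("identical variances drive the prior degrees of freedom to Inf", {
  n <- 200
  st <- structure(data.frame(probe_id = sprintf("p%d", 1:n), b = 0,
                             u = 0.5, s2 = 0.3, d = 4,
                             a = seq(4, 14, length.out = n), sign = 0),
                  class = c("gene_stats", "data.frame"))
  hy <- estimate_eb_hyperparameters(st)
  expect_identical(hy$d0, Inf)
  # with d0 = Inf the prior variance is the exp of the fitted trend
  # (bias-corrected log variance), identical for all probes here, and
  # moderation collapses every probe onto it
  e <- log(0.3) - digamma(2) + log(2)
  expect_equal(unname(hy$s0_2), rep(exp(e), n), tolerance = 1e-6)
  mo <- moderated_test(st, hy)
  expect_equal(mo$s_tilde2, unname(hy$s0_2))
})

test_that("hyperparameter estimation recovers the generating prior", {
  cfg <- simulation_config(n_probes = 20000,
                           groups = data.frame(sex = "F", time = "4h",
                                               n_subjects = 5L),
                           d0 = 4, s0_2 = 0.05, s0_slope = 0,
                           de_fraction = 0, baseline_de_fraction = 0,
                           seed = 17)
  st <- fit_gene_stats(generate_study(cfg)$study, paired_cmp())
  hy <- estimate_eb_hyperparameters(st)
  expect_gt(hy$d0, 3)
  expect_lt(hy$d0, 5)
  expect_lt(abs(stats::median(hy$s0_2) - 0.05) / 0.05, 0.2)
})

test_that("estimated hyperparameters agree with limma's F-distribution fit", {
  skip_if_not_installed("limma")
  cfg <- simulation_config(n_probes = 20000,
                           groups = data.frame(sex = "F", time = "4h",
                                               n_subjects = 5L),
                           d0 = 4, s0_2 = 0.05, s0_slope = 0,
                           de_fraction = 0, baseline_de_fraction = 0,
                           seed = 23)
  st <- fit_gene_stats(generate_study(cfg)$study, paired_cmp())
  hy <- estimate_eb_hyperparameters(st)
  ff <- limma::fitFDist(st$s2, df1 = st$d)
  # same method-of-moments target; trends differ (intensity lowess vs
  # none), so agreement is approximate
  expect_lt(abs(hy$d0 - ff$df2) / ff$df2, 0.15)
  expect_lt(abs(stats::median(hy$s0_2) - ff$scale) / ff$scale, 0.15)
})

test_that("moderated test reproduces the worked shrinkage example", {
  st <- structure(data.frame(probe_id = "g", b = 1.0, u = 1 / sqrt(3),
                             s2 = 0.04, d = 2, a = 8, sign = 1),
                  class = c("gene_stats", "data.frame"))
  hy <- list(d0 = 3, s0_2 = c(g = 0.09))
  mo <- moderated_test(st, hy)
  expect_equal(mo$s_tilde2, 0.07)
  expect_equal(mo$t_mod, 6.546537, tolerance = 1e-6)
  expect_equal(mo$df, 5)
  expect_equal(mo$p, 2 * stats::pt(-6.546537, 5), tolerance = 1e-6)
  expect_equal(mo$p, 1.2e-3, tolerance = 0.05)
})

test_that("d0 = 0 reduces to the ordinary t and d0 = Inf to the normal", {
  cfg <- small_config(seed = 5, n_probes = 500, n_subjects = 4L)
  st <- fit_gene_stats(generate_study(cfg)$study, paired_cmp())
  hy <- estimate_eb_hyperparameters(st)
  mo0 <- moderated_test(st, hy, d0 = 0)
  t_ord <- st$b / (st$u * sqrt(st$s2))
  expect_equal(mo0$t_mod, t_ord, tolerance = 1e-12)
  expect_equal(mo0$df, st$d)
  expect_equal(mo0$p, pmax(2 * stats::pt(-abs(t_ord), st$d), 1e-300),
               tolerance = 1e-12)
  moI <- moderated_test(st, hy, d0 = Inf)
  expect_equal(moI$s_tilde2, unname(hy$s0_2[st$probe_id]))
  expect_equal(moI$p,
               pmax(2 * stats::pnorm(-abs(moI$t_mod)), 1e-300),
               tolerance = 1e-12)
})

test_that("moderated variance is a convex combination of prior and observed", {
  cfg <- small_config(seed = 6, n_probes = 1000, n_subjects = 4L)
  st <- fit_gene_stats(generate_study(cfg)$study, paired_cmp())
  hy <- estimate_eb_hyperparameters(st)
  mo <- moderated_test(st, hy)
  lo <- pmin(st$s2, unname(hy$s0_2[st$probe_id]))
  hi <- pmax(st$s2, unname(hy$s0_2[st$probe_id]))
  expect_true(all(mo$s_tilde2 >= lo - 1e-12 & mo$s_tilde2 <= hi + 1e-12))
  expect_true(all(mo$p > 0 & mo$p <= 1))
  expect_true(all(mo$q >= mo$p - 1e-12 & mo$q <= 1))
})

test_that("moderated t follows its reference t distribution under the null", {
  # known hyperparameters, null effects: t should be t(d0 + d)
  cfg <- simulation_config(n_probes = 20000,
                           groups = data.frame(sex = "F", time = "4h",
                                               n_subjects = 5L),
                           d0 = 4, s0_2 = 0.05, s0_slope = 0,
                           de_fraction = 0, baseline_de_fraction = 0,
                           seed = 8)
  st <- fit_gene_stats(generate_study(cfg)$study, paired_cmp())
  mo <- moderated_test(st, list(d0 = 4,
                                s0_2 = stats::setNames(rep(0.05,
                                                           nrow(st)),
                                                       st$probe_id)))
  ks <- stats::ks.test(mo$t_mod, function(q) stats::pt(q, 8))
  expect_gt(ks$p.value, 0.001)
})

test_that("BH step-up matches the hand-derived and brute-force formulas", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")

  brute <- function(p, m = length(p)) {
    n <- length(p)
    o <- order(p)
    q <- numeric(n)
    for (i in seq_len(n))
      q[o[i]] <- min(1, min(p[o][i:n] * m / (i:n)))
    q
  }
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(1:1000, 1)
    p <- runif(n)
    if (rep %% 3 == 0) p <- round(p, 2)  # force ties
    p[p == 0] <- 0.5
    expect_equal(bh_fdr(p), brute(p), tolerance = 1e-14)
    expect_equal(bh_fdr(p), stats::p.adjust(p, "BH"), tolerance = 1e-14)
  }
})
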