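test_that("GMT reader intersects with the universe and validates lines", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tg1\tg2\tg3", "S2\tother\tg2\tg4"), path)
  suppressMessages(
    col <- read_gmt(path, universe = c("g1", "g2", "g4")))
  expect_equal(col$sets$S1, c("g1", "g2"))  # g3 off-array
  expect_equal(col$sets$S2, c("g2", "g4"))

  writeLines(c("S1\tdesc\tg1", "S1\tdesc\tg2"), path)
  expect_error(read_gmt(path), "duplicate set id 'S1'")
  writeLines(c("S1\tdesc\tg1", "S2\tonly-two-fields"), path)
  expect_error(read_gmt(path), "line 2")
})

test_that("a synthetic GMT round-trips through write_gmt unchanged", {
  cfg <- simulation_config(n_probes = 2000, n_sets = 50L, seed = 77)
  sets <- generate_gene_sets_and_dag(cfg)$sets
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_identical(back$sets, sets$sets)
  expect_identical(back$descriptions, sets$descriptions)
})

test_that("signed significance scores follow the directional rule", {
  mk <- function(p, s, a = 8) {
    structure(data.frame(probe_id = sprintf("g%d", seq_along(p)), b = s,
                         a = a, s2 = 1, d = 3, s0_2 = 1, s_tilde2 = 1,
                         t_mod = 1, df = 6, p = p, q = p, sign = s,
                         flagged = FALSE),
              class = c("moderated_result", "data.frame"))
  }
  sc <- build_significance_scores(mk(c(1, 0.001, 0.001), c(1, 1, -1)))
  expect_equal(sc$x[1], 0)                       # p = 1 gives 0 either way
  expect_equal(sc$x[2], 6.907755, tolerance = 1e-6)
  expect_equal(sc$x[3], -6.907755, tolerance = 1e-6)

  # gene level picks the representative probe with the highest intensity
  mo <- mk(c(0.5, 0.01), c(1, 1), a = c(6.1, 9.3))
  gm <- data.frame(probe_id = c("g1", "g2"), gene_id = c("G", "G"),
                   stringsAsFactors = FALSE)
  sc2 <- build_significance_scores(mo, gene_map = gm, level = "gene")
  expect_equal(nrow(sc2), 1L)
  expect_equal(sc2$p, 0.01)
})

test_that("logistic slope and Wald p match an independent ML fit", {
  # frozen 20-gene fixture with one 5-member set
  set.seed(2024)
  x <- round(rnorm(20, 0, 3), 6)
  ids <- sprintf("g%02d", 1:20)
  members <- ids[c(2, 5, 9, 13, 17)]
  scores <- structure(data.frame(id = ids, x = x, p = exp(-abs(x)),
                                 sign = sign(x)),
                      class = c("significance_scores", "data.frame"))
  res <- run_lrpath(scores, sets_from_list(S = members), min_size = 2L,
                    max_size = 50L)
  oracle <- stats::glm(I(ids %in% members) ~ x, family = stats::binomial(),
                       control = stats::glm.control(epsilon = 1e-12))
  co <- summary(oracle)$coefficients
  expect_equal(res$beta1, co["x", "Estimate"], tolerance = 1e-6)
  expect_equal(res$se, co["x", "Std. Error"], tolerance = 1e-6)
  expect_equal(res$p, co["x", "Pr(>|z|)"], tolerance = 1e-6)

  # 20 random small instances against glm
  for (i in 1:20) {
    n <- sample(50:500, 1)
    xx <- rnorm(n)
    yy <- rbinom(n, 1, stats::plogis(-1.5 + 0.6 * xx))
    if (sum(yy) < 3 || sum(yy) > n - 3) next
    sc <- structure(data.frame(id = sprintf("u%d", 1:n), x = xx,
                               p = exp(-abs(xx)), sign = sign(xx)),
                    class = c("significance_scores", "data.frame"))
    r <- run_lrpath(sc, sets_from_list(S = sprintf("u%d", which(yy == 1))),
                    min_size = 2L, max_size = n)
    o <- summary(stats::glm(yy ~ xx, family = stats::binomial(),
                            control = stats::glm.control(
                              epsilon = 1e-12)))$coefficients
    expect_equal(r$beta1, o["xx", "Estimate"], tolerance = 1e-6)
    expect_equal(r$se, o["xx", "Std. Error"], tolerance = 1e-6)
    expect_equal(r$p, o["xx", "Pr(>|z|)"], tolerance = 1e-5)
  }
})

test_that("degenerate inputs are flagged or rejected", {
  ids <- sprintf("g%d", 1:40)
  sc <- structure(data.frame(id = ids, x = rnorm(40), p = runif(40),
                             sign = 1),
                  class = c("significance_scores", "data.frame"))
  # set equal to the whole universe: membership has no contrast
  r <- run_lrpath(sc, sets_from_list(ALL = ids), min_size = 2L,
                  max_size = 100L)
  expect_equal(r$status, "unstable")
  expect_true(is.na(r$p))

  sc$x <- 1
  expect_error(run_lrpath(sc, sets_from_list(S = ids[1:10]),
                          min_size = 2L, max_size = 100L),
               "degenerate scores")
})

test_that("negating every score sign flips beta1 but not its magnitude", {
  set.seed(5)
  ids <- sprintf("g%d", 1:200)
  x <- rnorm(200)
  mk <- function(x) structure(
    data.frame(id = ids, x = x, p = exp(-abs(x)), sign = sign(x)),
    class = c("significance_scores", "data.frame"))
  sets <- sets_from_list(A = ids[1:30], B = ids[51:90], C = ids[101:115])
  r1 <- run_lrpath(mk(x), sets, min_size = 5L, max_size = 100L)
  r2 <- run_lrpath(mk(-x), sets, min_size = 5L, max_size = 100L)
  expect_equal(r2$beta1, -r1$beta1, tolerance = 1e-9)
  expect_equal(r2$p, r1$p, tolerance = 1e-9)
})

test_that("the enrichment matrix applies the signed -log10 fill rule", {
  mk <- function(ids, p, dir) structure(
    data.frame(set_id = ids, name = ids, n = 20, beta1 = ifelse(dir == "up", 1, -1),
               odds_ratio = 1, direction = dir, se = 1, wald = 1, p = p,
               fdr = p, enriched = p < 0.01, status = "ok"),
    class = c("enrichment_result", "data.frame"))
  m <- enrichment_matrix(list(c1 = mk("T1", 0.001, "up"),
                              c2 = mk("T2", 0.01, "down")))
  expect_equal(m["T1", "c1"], 3)
  expect_equal(m["T2", "c2"], -2)
  expect_equal(m["T1", "c2"], 0)   # absent term-comparison pair
  expect_equal(m["T2", "c1"], 0)
  expect_equal(colnames(m), c("c1", "c2"))
})
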